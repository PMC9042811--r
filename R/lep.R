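#' Ligand-bound metal fraction of a binary metal/ligand system
#'
#' Convenience wrapper used throughout the ligand-exchange analysis:
#' solves the binary system containing only the metal and one ligand
#' (every other ligand total set to zero) at the given pH and ionic
#' strength and returns the ligand-bound metal fraction.
#'
#' @param model A [speciation_model()].
#' @param ligand Ligand component name.
#' @param pH,I Condition.
#' @param zn_total,ligand_total Analytical concentrations, mol/dm3.
#'   Defaults are the standard ligand-efficiency test concentrations
#'   `[Zn] = 1e-6`, `[L] = 1e-5`.
#' @param cfg See [activity_config()].
#' @param metal Metal component, default `"Zn"`.
#' @return Fraction of total metal in mixed metal-ligand species.
#' @export
binary_fraction <- function(model, ligand, pH, I,
                            zn_total = 1e-6, ligand_total = 1e-5,
                            cfg = activity_config(), metal = "Zn") {
  totals <- stats::setNames(rep(0, 2), c(metal, ligand))
  totals[metal] <- zn_total; totals[ligand] <- ligand_total
  spec <- solution_spec(totals, pH = pH, ionic_strength = I)
  r <- solve_equilibrium(model, spec, cfg)
  if (!r$converged)
    warning("solver did not converge at pH ", pH, ", I = ", I)
  fraction_complexed(r, ligand, metal)
}

#' Locate the ligand-exchange point between two ligands
#'
#' The ligand-exchange point (LEP) is the pH (at fixed ionic strength) or
#' the ionic strength (at fixed pH) at which the metal fraction complexed
#' by the strong ligand equals that complexed by the weak ligand, the two
#' binary systems being solved independently at equal ligand totals. The
#' difference curve is scanned on a grid to bracket sign changes and each
#' bracket is refined by bisection ([stats::uniroot()]) to `tol`.
#'
#' @param model A [speciation_model()] containing both ligands.
#' @param swept `"pH"` or `"I"`.
#' @param fixed Value of the non-swept variable.
#' @param zn_total,ligand_total Totals for both binary systems (mol/dm3).
#' @param bounds Sweep bounds; defaults pH 2-12 or I 1e-3-1.0.
#' @param ligands Character vector `c(weak, strong)`; the LEP is where
#'   `fraction(strong) - fraction(weak)` crosses zero.
#' @param n_scan Scan-grid size used for bracketing.
#' @param tol Bisection tolerance (pH units or mol/dm3).
#' @param cfg See [activity_config()].
#' @param metal Metal component, default `"Zn"`.
#' @return Object of class `"lep_result"` with `lep_value` (NA when no
#'   crossing), `crossings` (all roots), `bracket`, `ambiguous`,
#'   `no_crossing`, `closest_approach` (scan point of smallest gap,
#'   useful when the curves never cross), and `curves` (the scan table).
#' @examples
#' \donttest{
#' find_lep(zn_cit_dfob_model(), swept = "pH", fixed = 0.01)
#' }
#' @export
find_lep <- function(model, swept = c("pH", "I"), fixed,
                     zn_total = 1e-6, ligand_total = 1e-5,
                     bounds = NULL, ligands = c("Cit", "DFOB"),
                     n_scan = 101L, tol = 1e-4, cfg = activity_config(),
                     metal = "Zn") {
  swept <- match.arg(swept)
  if (is.null(bounds)) bounds <- if (swept == "pH") c(2, 12) else c(1e-3, 1)
  weak <- ligands[1]; strong <- ligands[2]
  fr <- function(lig, v) {
    pH <- if (swept == "pH") v else fixed
    I <- if (swept == "pH") fixed else v
    binary_fraction(model, lig, pH, I, zn_total, ligand_total, cfg, metal)
  }
  dfun <- function(v) fr(strong, v) - fr(weak, v)
  grid <- seq(bounds[1], bounds[2], length.out = n_scan)
  fw <- vapply(grid, function(v) fr(weak, v), 0)
  fs <- vapply(grid, function(v) fr(strong, v), 0)
  dv <- fs - fw
  curves <- data.frame(value = grid, fraction_weak = fw, fraction_strong = fs,
                       diff = dv)
  names(curves)[1] <- swept
  if (max(abs(dv)) < 1e-10)
    stop("degenerate ligand pair: fraction curves are identical everywhere")
  roots <- list()
  for (k in seq_len(length(grid) - 1)) {
    if (dv[k] == 0) { roots[[length(roots) + 1]] <- grid[k]; next }
    if (dv[k] * dv[k + 1] < 0) {
      root <- tryCatch(
        stats::uniroot(dfun, c(grid[k], grid[k + 1]), tol = tol)$root,
        error = function(e) NA_real_)
      if (!is.na(root)) roots[[length(roots) + 1]] <- root
    }
  }
  if (dv[length(grid)] == 0) roots[[length(roots) + 1]] <- grid[length(grid)]
  crossings <- unlist(roots)
  no_crossing <- length(crossings) == 0L
  ambiguous <- length(crossings) > 1L
  if (ambiguous)
    warning("multiple ligand-exchange points found: ",
            paste(signif(crossings, 5), collapse = ", "))
  k_min <- which.min(abs(dv))
  lep <- if (no_crossing) NA_real_ else crossings[1]
  bracket <- if (no_crossing) c(NA_real_, NA_real_) else {
    k <- findInterval(lep, grid); c(grid[k], grid[min(k + 1, n_scan)])
  }
  structure(list(swept = swept, fixed_condition = fixed,
                 lep_value = lep, crossings = crossings,
                 bracket = bracket, ambiguous = ambiguous,
                 no_crossing = no_crossing,
                 closest_approach = c(value = grid[k_min],
                                      gap = abs(dv[k_min])),
                 ligands = c(weak = weak, strong = strong),
                 zn_total = zn_total, ligand_total = ligand_total,
                 curves = curves),
            class = "lep_result")
}

#' @export
print.lep_result <- function(x, ...) {
  unit <- if (x$swept == "pH") "" else " mol/dm3"
  other <- if (x$swept == "pH") "I" else "pH"
  if (x$no_crossing) {
    cat(sprintf("no ligand-exchange point in bounds (at %s = %g); closest approach at %s = %g (gap %.3g)\n",
                other, x$fixed_condition, x$swept,
                x$closest_approach["value"], x$closest_approach["gap"]))
  } else {
    cat(sprintf("ligand-exchange point %s/%s: %s = %.4f%s (at %s = %g)%s\n",
                x$ligands["weak"], x$ligands["strong"], x$swept,
                x$lep_value, unit, other, x$fixed_condition,
                if (x$ambiguous) sprintf(" [%d crossings]", length(x$crossings))
                else ""))
  }
  invisible(x)
}

#' Dominance windows of individual species along a sweep
#'
#' Maximal intervals of the swept variable in which a species holds more
#' than `threshold` of the total metal. Window edges are linearly
#' interpolated between grid points; results do not depend on the grid
#' orientation.
#'
#' @param model The [speciation_model()] the sweep was computed with.
#' @param sweep A [sweep_speciation()] result.
#' @param threshold Fraction threshold, default 0.5.
#' @param metal Metal component, default `"Zn"`.
#' @return `data.frame(species, from, to)`, empty when nothing dominates.
#' @export
dominance_windows <- function(model, sweep, threshold = 0.5, metal = "Zn") {
  variable <- attr(sweep, "variable")
  v <- sweep[[variable]]
  o <- order(v)
  v <- v[o]
  Tm <- attr(sweep, "zn_total")
  if (is.null(Tm)) stop("sweep carries no metal total")
  out <- list()
  for (i in seq_len(nrow(model$species))) {
    nm <- model$species$name[i]
    if (!nm %in% names(sweep)) next
    nu <- model$stoich[i, metal]
    if (nu <= 0) next
    f <- nu * sweep[[nm]][o] / Tm
    above <- f > threshold
    if (!any(above)) next
    r <- rle(above)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
    for (k in which(r$values)) {
      a <- starts[k]; b <- ends[k]
      from <- if (a == 1) v[1] else {
        v[a - 1] + (threshold - f[a - 1]) / (f[a] - f[a - 1]) * (v[a] - v[a - 1])
      }
      to <- if (b == length(v)) v[length(v)] else {
        v[b] + (threshold - f[b]) / (f[b + 1] - f[b]) * (v[b + 1] - v[b])
      }
      out[[length(out) + 1]] <- data.frame(species = nm, from = from, to = to)
    }
  }
  if (!length(out))
    return(data.frame(species = character(), from = numeric(), to = numeric()))
  do.call(rbind, out)
}

#' Compare Davies-derived and EDH-derived intrinsic speciation models
#'
#' Reproduces the activity-model consistency experiment for the
#' Zn(II)/citrate system: intrinsic constants are derived from the
#' conditional constants measured at a *single* ionic strength via the
#' Davies equation ([davies_intrinsic()]) and the resulting
#' infinite-dilution speciation is compared against the reference model
#' whose intrinsic constants come from fitting the extended Debye-Hueckel
#' model to the *full* ionic-strength series. Discrepancies between the
#' two are a direct measure of the inconsistency introduced by
#' single-ionic-strength Davies corrections.
#'
#' @param model Intrinsic-mode [zn_cit_dfob_model()]-like model whose
#'   species carry conditional series.
#' @param I_list Source ionic strengths (each must be in the series).
#' @param pH_grid pH grid for the comparison curves.
#' @param ligand Ligand subsystem to compare (default `"Cit"`).
#' @param zn_total,ligand_total Totals, mol/dm3.
#' @param cfg See [activity_config()].
#' @return `data.frame(I_source, pH, fraction_davies, fraction_edh,
#'   rel_diff_pct)` where `rel_diff_pct = 100 (f_edh - f_davies) / f_edh`
#'   (positive when the Davies-based model underpredicts complexation).
#' @export
davies_vs_edh_experiment <- function(model, I_list, pH_grid,
                                     ligand = "Cit",
                                     zn_total = 1e-6, ligand_total = 1e-5,
                                     cfg = activity_config()) {
  f_edh <- vapply(pH_grid, function(p)
    binary_fraction(model, ligand, p, 0, zn_total, ligand_total, cfg), 0)
  tab_I <- unique(unlist(lapply(model$conditional, function(s) s$I)))
  out <- list()
  for (I_src in I_list) {
    if (!any(abs(tab_I - I_src) < 1e-12))
      stop("no conditional values tabulated at I = ", I_src)
    mdav <- model
    drop <- character(0)
    for (i in seq_len(nrow(model$species))) {
      ser <- model$conditional[[i]]
      if (is.null(ser)) next
      j <- which(abs(ser$I - I_src) < 1e-12)
      if (length(j) != 1L) {
        # species not determined at this ionic strength ('nd' entries)
        # cannot enter a Davies model built from it
        drop <- c(drop, model$species$name[i])
        next
      }
      mdav$species$logbeta0[i] <- davies_intrinsic(
        ser$logbeta[j], model$stoich[i, ], model$components$charge,
        model$species$charge[i], I_src, cfg)
      mdav$species$C[i] <- 0
    }
    if (length(drop)) mdav <- .drop_species(mdav, drop)
    f_dav <- vapply(pH_grid, function(p)
      binary_fraction(mdav, ligand, p, 0, zn_total, ligand_total, cfg), 0)
    out[[length(out) + 1]] <- data.frame(
      I_source = I_src, pH = pH_grid,
      fraction_davies = f_dav, fraction_edh = f_edh,
      rel_diff_pct = 100 * (f_edh - f_dav) / f_edh)
  }
  do.call(rbind, out)
}

#' Sensitivity of the ligand-exchange point to constant uncertainties
#'
#' Recomputes the LEP with every stability constant moved to the upper and
#' to the lower end of its reported uncertainty (via
#' [perturb_constants()]) and reports the extreme displacement.
#'
#' @inheritParams find_lep
#' @param ... Passed on to [find_lep()].
#' @return List with `lep_base`, `lep_high` (+sigma), `lep_low` (-sigma)
#'   and `max_shift` (largest absolute displacement from the base LEP).
#' @export
sensitivity_lep <- function(model, swept = c("pH", "I"), fixed, ...) {
  swept <- match.arg(swept)
  base <- find_lep(model, swept, fixed, ...)
  if (base$no_crossing) stop("no ligand-exchange point at the base condition")
  hi <- find_lep(perturb_constants(model, "+sigma"), swept, fixed, ...)
  lo <- find_lep(perturb_constants(model, "-sigma"), swept, fixed, ...)
  if (hi$no_crossing || lo$no_crossing)
    stop("no ligand-exchange point at a perturbed condition")
  list(lep_base = base$lep_value, lep_high = hi$lep_value,
       lep_low = lo$lep_value,
       max_shift = max(abs(c(hi$lep_value, lo$lep_value) - base$lep_value)))
}

#' Relative reduction in ligand binding efficiency across ionic strength
#'
#' `100 * (f(I_from) - f(I_to)) / f(I_from)` for the binary system of one
#' ligand at fixed pH — the percentage of binding capacity lost between
#' the two ionic strengths (dilute reference by default).
#'
#' @inheritParams binary_fraction
#' @param I_from,I_to Ionic strengths, mol/dm3 (defaults 0 and 1).
#' @return List with `f_from`, `f_to`, `decrease` (absolute fraction
#'   difference) and `rel_reduction_pct`.
#' @export
binding_efficiency_reduction <- function(model, ligand, pH,
                                         I_from = 0, I_to = 1,
                                         zn_total = 1e-6, ligand_total = 1e-5,
                                         cfg = activity_config()) {
  f0 <- binary_fraction(model, ligand, pH, I_from, zn_total, ligand_total, cfg)
  f1 <- binary_fraction(model, ligand, pH, I_to, zn_total, ligand_total, cfg)
  list(f_from = f0, f_to = f1, decrease = f0 - f1,
       rel_reduction_pct = 100 * (f0 - f1) / f0)
}
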