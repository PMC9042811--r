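#' Describe one solution condition
#'
#' @param totals Named analytical (total) concentrations, mol/dm3, for the
#'   model components other than H; non-negative.
#' @param pH Fixed pH (`-log10` of the free proton *concentration*); give
#'   either `pH` or `total_H`, not both.
#' @param total_H Total (analytical) proton concentration relative to the
#'   fully deprotonated component reference, mol/dm3; may be negative for
#'   excess strong base.
#' @param ionic_strength Ionic strength of the background medium, mol/dm3.
#'   The supporting electrolyte is not a model component; it enters only
#'   through the conditional constants (and the conditional ion product of
#'   water).
#' @param medium Label, default "NaCl".
#' @return A list of class `"solution_spec"`.
#' @export
solution_spec <- function(totals, pH = NULL, total_H = NULL,
                          ionic_strength, medium = "NaCl") {
  if (is.null(pH) == is.null(total_H))
    stop("give exactly one of pH or total_H")
  if (any(totals < 0)) stop("negative component totals")
  if (ionic_strength < 0) stop("negative ionic strength")
  structure(list(totals = totals, pH = pH, total_H = total_H,
                 ionic_strength = ionic_strength, medium = medium),
            class = "solution_spec")
}

# log10 of the conditional ion product of water at ionic strength I:
# Kw(c) = [H][OH]; from pKw0 = 13.997 via Davies activity coefficients.
log10_kw <- function(I, cfg = activity_config()) {
  -13.997 - 2 * davies_log_gamma(1, I, cfg)
}

#' Solve the equilibrium speciation of one solution
#'
#' Damped Newton iteration on the component mass balances in
#' log-free-concentration space (which keeps all concentrations positive).
#' In fixed-pH mode the proton balance is dropped and the free proton
#' concentration is set from the pH; in total-H mode the proton is a
#' regular unknown and water autoprotolysis enters the proton balance
#' through the conditional ion product of water (pKw 13.997 at I = 0,
#' Davies-adjusted to the working ionic strength). Components with zero
#' total are excluded together with every species that contains them.
#'
#' @param model A [speciation_model()].
#' @param spec A [solution_spec()].
#' @param cfg See [activity_config()].
#' @param tol Convergence tolerance on the largest relative mass-balance
#'   residual (default 1e-10).
#' @param max_iter Maximum Newton iterations (the solver restarts from a
#'   small grid of initial guesses before giving up).
#' @param start Optional named vector of free concentrations used as warm
#'   start (e.g. the `free` element of a neighbouring result).
#' @return Object of class `"speciation_result"`: `free` (component free
#'   concentrations), `species_conc`, `residuals` (relative mass-balance
#'   errors), `totals`, `converged`, `iterations`, plus the conditional
#'   constants used.
#' @examples
#' m <- zn_cit_dfob_model()
#' s <- solution_spec(c(Zn = 1e-6, Cit = 1e-5, DFOB = 0), pH = 6,
#'                    ionic_strength = 0.01)
#' r <- solve_equilibrium(m, s)
#' fraction_complexed(r, "Cit")
#' @export
solve_equilibrium <- function(model, spec, cfg = activity_config(),
                              tol = 1e-10, max_iter = 200L, start = NULL) {
  stopifnot(inherits(model, "speciation_model"),
            inherits(spec, "solution_spec"))
  comp <- model$components$name
  fixed_pH <- !is.null(spec$pH)

  totals <- stats::setNames(rep(0, length(comp)), comp)
  known <- intersect(names(spec$totals), comp)
  totals[known] <- spec$totals[known]
  if (!fixed_pH) totals["H"] <- spec$total_H
  if (any(totals[comp != "H"] < 0)) stop("negative component totals")

  # active components: positive total (H always active; fixed in pH mode)
  active <- totals > 0 | comp == "H"
  sp_keep <- rowSums(abs(model$stoich[, !active, drop = FALSE])) == 0
  N <- model$stoich[sp_keep, active, drop = FALSE]
  lb <- conditional_constants(model, spec$ionic_strength, cfg,
                              prefer = "edh")[sp_keep]
  if (anyNA(lb))
    stop("no constants available at I = ", spec$ionic_strength,
         " for: ", paste(names(lb)[is.na(lb)], collapse = ", "))
  cn <- comp[active]
  Tvec <- totals[active]
  hcol <- match("H", cn)
  unknown <- if (fixed_pH) setdiff(seq_along(cn), hcol) else seq_along(cn)
  lKw <- log10_kw(spec$ionic_strength, cfg)
  scale <- pmax(abs(Tvec), 1e-12)

  eval_state <- function(u) {
    # u: natural-log free concentrations of all active components
    csp <- as.vector(10^(lb + N %*% (u / log(10))))
    x <- exp(u)
    totc <- x + as.vector(crossprod(N, csp))
    oh <- 10^(lKw) / x[hcol]
    if (!fixed_pH) totc[hcol] <- totc[hcol] - oh
    list(x = x, csp = csp, tot = totc, oh = oh,
         F = (totc - Tvec) / scale)
  }

  newton <- function(u0) {
    u <- u0
    st <- eval_state(u)
    for (it in seq_len(max_iter)) {
      Fv <- st$F[unknown]
      if (max(abs(Fv)) <= tol) return(list(u = u, st = st, it = it, ok = TRUE))
      nu <- length(unknown)
      J <- matrix(0, nu, nu)
      for (a in seq_len(nu)) {
        i <- unknown[a]
        for (b in seq_len(nu)) {
          j <- unknown[b]
          v <- sum(N[, i] * N[, j] * st$csp)
          if (i == j) v <- v + st$x[i]
          if (!fixed_pH && i == hcol && j == hcol) v <- v + st$oh
          J[a, b] <- v / scale[i]
        }
      }
      step <- tryCatch(solve(J, -Fv), error = function(e) -Fv)
      step <- pmin(pmax(step, -6), 6)
      f0 <- max(abs(Fv)); lam <- 1
      repeat {
        u_try <- u
        u_try[unknown] <- u[unknown] + lam * step
        st_try <- eval_state(u_try)
        if (all(is.finite(st_try$F)) && max(abs(st_try$F[unknown])) < f0) break
        lam <- lam / 2
        if (lam < 2^-30) { st_try <- NULL; break }
      }
      if (is.null(st_try)) return(list(u = u, st = st, it = it, ok = FALSE))
      u <- u_try; st <- st_try
    }
    list(u = u, st = st, it = max_iter,
         ok = max(abs(st$F[unknown])) <= tol)
  }

  guess <- function(hguess) {
    x0 <- pmax(0.1 * Tvec, 1e-20)
    x0[hcol] <- if (fixed_pH) 10^(-spec$pH) else hguess
    log(x0)
  }
  starts <- if (!is.null(start)) {
    u0 <- guess(1e-7)
    u0[match(names(start), cn, nomatch = 0)] <-
      log(pmax(start[names(start) %in% cn], 1e-30))
    if (fixed_pH) u0[hcol] <- log(10^(-spec$pH))
    list(u0)
  } else list()
  hg <- if (!fixed_pH && !is.null(spec$total_H) && spec$total_H > 0)
    c(max(spec$total_H / 2, 1e-8), 1e-4, 1e-7, 1e-10) else
    c(1e-7, 1e-3, 1e-10, 1e-12)
  starts <- c(starts, lapply(hg, guess))

  res <- NULL
  for (u0 in starts) {
    res <- newton(u0)
    if (res$ok) break
  }
  st <- res$st
  free <- stats::setNames(st$x, cn)
  structure(list(
    free = free,
    species_conc = stats::setNames(st$csp, rownames(N)),
    residuals = stats::setNames(st$F, cn)[unknown],
    totals = Tvec, converged = res$ok, iterations = res$it,
    pH = -log10(free[["H"]]),
    ionic_strength = spec$ionic_strength,
    logbeta = stats::setNames(lb, rownames(N)),
    stoich = N, mode = if (fixed_pH) "fixed_pH" else "total_H"),
    class = "speciation_result")
}

#' @export
print.speciation_result <- function(x, ...) {
  cat(sprintf("speciation result (%s, I = %g, pH = %.3f, %s in %d it., max resid %.1e)\n",
              x$mode, x$ionic_strength, x$pH,
              if (x$converged) "converged" else "NOT converged",
              x$iterations, max(abs(x$residuals))))
  cat("free:\n"); print(signif(x$free, 4))
  cat("species:\n"); print(signif(x$species_conc, 4))
  invisible(x)
}

#' Fraction of the metal bound in mixed metal-ligand species
#'
#' Sum of `nu_metal * [species]` over all species containing both the metal
#' and the given ligand, divided by the metal total. Free metal and
#' hydroxo-only metal species are excluded; binuclear species count with
#' their metal stoichiometry.
#'
#' @param result A converged [solve_equilibrium()] result.
#' @param ligand Ligand component name (e.g. `"Cit"`).
#' @param metal Metal component name, default `"Zn"`.
#' @return Fraction in `[0, 1]` of total metal bound to the ligand.
#' @export
fraction_complexed <- function(result, ligand, metal = "Zn") {
  N <- result$stoich
  if (!metal %in% colnames(N)) stop("metal ", metal, " not in result")
  Tm <- result$totals[[metal]]
  if (!isTRUE(Tm > 0)) stop("total ", metal, " is zero")
  if (!ligand %in% colnames(N)) return(0)
  sel <- N[, metal] > 0 & N[, ligand] > 0
  sum(N[sel, metal] * result$species_conc[sel]) / Tm
}

# fraction of metal present as hydroxo-only species
fraction_hydroxo <- function(result, metal = "Zn") {
  N <- result$stoich
  Tm <- result$totals[[metal]]
  lig <- setdiff(colnames(N), c(metal, "H"))
  sel <- N[, metal] > 0 & N[, "H"] < 0 &
    rowSums(abs(N[, lig, drop = FALSE])) == 0
  sum(N[sel, metal] * result$species_conc[sel]) / Tm
}

#' Sweep speciation along pH or ionic strength
#'
#' Solves the same solution over a monotone grid of pH or ionic strength
#' values, warm-starting each point from its neighbour, and tabulates free
#' concentrations, species concentrations and the ligand-bound metal
#' fractions. Non-converged points are reported per point, not fatal.
#'
#' @param model A [speciation_model()].
#' @param spec A [solution_spec()] serving as template; its `pH` (or
#'   `ionic_strength`) is replaced by the grid values.
#' @param variable `"pH"` or `"I"`.
#' @param grid Numeric grid (monotone, non-empty).
#' @param cfg See [activity_config()].
#' @return Object of class `"speciation_sweep"`: a `data.frame` with the
#'   swept variable, `free_<component>` columns, one column per species,
#'   `fraction_<ligand>` for each ligand, `fraction_hydroxo`, `free_fraction`
#'   and `converged`; attributes carry the model/spec.
#' @export
sweep_speciation <- function(model, spec, variable = c("pH", "I"), grid,
                             cfg = activity_config()) {
  variable <- match.arg(variable)
  if (!length(grid)) stop("empty grid")
  if (length(grid) > 1 && any(diff(sign(diff(grid))) != 0))
    stop("grid must be monotone")
  if (variable == "pH" && is.null(spec$pH))
    stop("pH sweep needs a fixed-pH template spec")
  metal <- "Zn"
  ligs <- intersect(setdiff(model$components$name, c("H", metal)),
                    names(spec$totals)[spec$totals > 0])
  rows <- vector("list", length(grid))
  warm <- NULL
  for (k in seq_along(grid)) {
    sp_k <- spec
    if (variable == "pH") sp_k$pH <- grid[k] else sp_k$ionic_strength <- grid[k]
    r <- solve_equilibrium(model, sp_k, cfg, start = warm)
    if (r$converged) warm <- r$free
    fr <- vapply(ligs, function(L) fraction_complexed(r, L, metal), 0)
    hyd <- fraction_hydroxo(r, metal)
    rows[[k]] <- c(stats::setNames(grid[k], variable),
                   stats::setNames(r$free, paste0("free_", names(r$free))),
                   r$species_conc,
                   stats::setNames(fr, paste0("fraction_", ligs)),
                   fraction_hydroxo = hyd,
                   free_fraction = unname(r$free[metal] / r$totals[[metal]]),
                   converged = as.numeric(r$converged))
  }
  out <- as.data.frame(do.call(rbind, rows))
  out$converged <- as.logical(out$converged)
  attr(out, "variable") <- variable
  attr(out, "ligands") <- ligs
  attr(out, "zn_total") <- unname(spec$totals[metal])
  class(out) <- c("speciation_sweep", "data.frame")
  out
}
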