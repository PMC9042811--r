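#' Generate a synthetic potentiometric study data set
#'
#' Emulates the experimental design under which the shipped constants were
#' determined: for each ligand and each background ionic strength, one
#' ligand-only protonation run (`[L]` = 5 mmol/dm3) and one metal run per
#' Zn:L ratio (1:1, 1:2, 1:5, 1:10 with `[Zn]` between 0.5 and 1.5 and
#' `[L]` between 1 and 5 mmol/dm3), all titrated with NaOH from a 30 mL
#' initial solution, ~90 points per curve, with Gaussian read-out noise of
#' 0.2 mV on the emf and 0.003 mL on the volume. Ligands are supplied in
#' their protonated forms (citric acid: 3 protons; DFOB mesylate: 4) and
#' the HCl preload is chosen to start the runs near pH 2.5 so that curves
#' open fully protonated. Every curve gets a deterministic sub-seed from
#' the master seed; the manifest records all generating truths.
#'
#' @param model A [speciation_model()] with constants at every requested
#'   ionic strength (the generating "truth").
#' @param seed Master integer seed; a fixed seed reproduces the data set
#'   exactly.
#' @param ligands Ligand components to titrate.
#' @param ionic_strengths Background NaCl ionic strengths, mol/dm3.
#' @param ratios Zn:L ratios expressed as L/Zn (1, 2, 5, 10).
#' @param n_points Points per curve (default 90, the mid-range of the
#'   80-100 collected experimentally).
#' @param noise `c(sigma_E_mV, sigma_V_dm3)`; defaults 0.2 mV, 3e-6 dm3.
#' @param electrode An [electrode_calibration()] used for all curves.
#' @param titrant_conc NaOH concentration, mol/dm3.
#' @param hcl_conc HCl preload concentration, mol/dm3.
#' @param include_ligand_only Include the ligand-only protonation runs?
#' @param cfg See [activity_config()].
#' @return Object of class `"titration_dataset"`: `curves` (named list of
#'   [simulate_titration()] results) and `manifest` (master seed, per-curve
#'   design table with sub-seeds, generating constants, noise, electrode).
#' @export
generate_study_dataset <- function(model, seed,
                                   ligands = c("Cit", "DFOB"),
                                   ionic_strengths = c(0.05, 0.15, 0.3, 0.5, 1.0),
                                   ratios = c(1, 2, 5, 10),
                                   n_points = 90L,
                                   noise = c(0.2, 3e-6),
                                   electrode = electrode_calibration(400, 59.16),
                                   titrant_conc = 0.1,
                                   hcl_conc = 3e-3,
                                   include_ligand_only = TRUE,
                                   cfg = activity_config()) {
  if (missing(seed)) stop("an explicit master seed is required")
  protons_per_ligand <- c(Cit = 3, DFOB = 4)
  # Zn/L concentrations (mmol/dm3) per ratio, within the experimental ranges
  conc_for_ratio <- function(rat) {
    L <- min(5, rat * 1.0)
    zn <- L / rat
    if (zn > 1.5) { zn <- 1.5; L <- zn * rat }
    c(zn = zn, L = L)
  }
  design <- list(); k <- 0L
  for (lig in ligands) for (I in ionic_strengths) {
    if (include_ligand_only) {
      k <- k + 1L
      design[[k]] <- data.frame(id = sprintf("%s_I%g_L_only", lig, I),
                                ligand = lig, I = I, ratio = NA,
                                zn_mM = 0, L_mM = 5)
    }
    for (rat in ratios) {
      cc <- conc_for_ratio(rat)
      k <- k + 1L
      design[[k]] <- data.frame(id = sprintf("%s_I%g_r1to%g", lig, I, rat),
                                ligand = lig, I = I, ratio = rat,
                                zn_mM = cc["zn"], L_mM = cc["L"])
    }
  }
  design <- do.call(rbind, design)
  design$seed_curve <- seed + seq_len(nrow(design))
  rownames(design) <- NULL

  V0 <- 0.030
  curves <- vector("list", nrow(design))
  names(curves) <- design$id
  for (i in seq_len(nrow(design))) {
    d <- design[i, ]
    nL <- d$L_mM * 1e-3 * V0
    nZn <- d$zn_mM * 1e-3 * V0
    nH <- protons_per_ligand[[d$ligand]] * nL + hcl_conc * V0
    im <- stats::setNames(c(nZn, nL, nH), c("Zn", d$ligand, "H"))
    im <- im[im > 0 | names(im) == "H"]
    v_end <- 1.05 * nH / titrant_conc
    prot <- titration_protocol(
      initial_volume = V0, initial_mol = im,
      ionic_strength = d$I, titrant_conc = titrant_conc,
      volumes = seq(0, v_end, length.out = n_points),
      chloride_mol = hcl_conc * V0 + 2 * nZn)
    curves[[i]] <- simulate_titration(model, prot, electrode,
                                      noise = noise, seed = design$seed_curve[i],
                                      cfg = cfg)
  }
  manifest <- list(seed = seed, design = design, noise = noise,
                   electrode = electrode, titrant_conc = titrant_conc,
                   hcl_conc = hcl_conc, n_points = n_points,
                   truth = model$species[, c("name", "logbeta0", "C", "z_star")])
  structure(list(curves = curves, manifest = manifest),
            class = "titration_dataset")
}

#' @export
print.titration_dataset <- function(x, ...) {
  cat(sprintf("synthetic titration dataset: %d curves (seed %d)\n",
              length(x$curves), x$manifest$seed))
  print(utils::head(x$manifest$design, 10), row.names = FALSE)
  if (nrow(x$manifest$design) > 10) cat("...\n")
  invisible(x)
}

#' Shift all stability constants by their reported uncertainties
#'
#' Produces the "high" / "low" model variants used in the sensitivity
#' analysis: every species' intrinsic constant is displaced by plus or
#' minus its reported standard deviation (and its conditional series by
#' the per-point sigmas), or by correlated Gaussian draws in `"random"`
#' mode (one standard-normal multiplier per species applied to both
#' representations).
#'
#' @param model A [speciation_model()] whose species carry uncertainties
#'   (`sigma_logbeta0`, and `sigma` in the conditional series). Species
#'   with zero uncertainty are left untouched; `NA` uncertainties are an
#'   error.
#' @param direction `"+sigma"`, `"-sigma"`, or `"random"`.
#' @param seed Required in `"random"` mode.
#' @return The perturbed model.
#' @export
perturb_constants <- function(model, direction = c("+sigma", "-sigma", "random"),
                              seed = NULL) {
  direction <- match.arg(direction)
  sg <- model$species$sigma_logbeta0
  if (anyNA(sg)) stop("missing uncertainties for: ",
                      paste(model$species$name[is.na(sg)], collapse = ", "))
  mult <- switch(direction,
                 "+sigma" = rep(1, nrow(model$species)),
                 "-sigma" = rep(-1, nrow(model$species)),
                 "random" = {
                   if (is.null(seed)) stop("random mode requires a seed")
                   withr_seed(seed, stats::rnorm(nrow(model$species)))
                 })
  out <- model
  out$species$logbeta0 <- model$species$logbeta0 + mult * sg
  for (i in seq_along(out$conditional)) {
    ser <- out$conditional[[i]]
    if (is.null(ser)) next
    if (anyNA(ser$sigma))
      stop("missing conditional sigmas for ", model$species$name[i])
    ser$logbeta <- ser$logbeta + mult[i] * ser$sigma
    out$conditional[[i]] <- ser
  }
  out
}

#' Recomputed ionic strength along a titration
#'
#' Diagnostic for the fixed-ionic-strength assumption: at each scheduled
#' volume the equilibrium is solved and the solute contribution
#' `0.5 * sum(c_i z_i^2)` of all free components, complexes, sample
#' counter-ions (chloride from HCl/ZnCl2, recorded in the protocol) and
#' added titrant sodium is added to the background electrolyte ionic
#' strength.
#'
#' @param model,protocol,cfg As in [simulate_titration()].
#' @return `data.frame(volume, I_total, rel_dev)` where `rel_dev` is the
#'   relative deviation from the nominal background value.
#' @export
ionic_strength_drift <- function(model, protocol, cfg = activity_config()) {
  comp_z <- stats::setNames(model$components$charge, model$components$name)
  I0 <- protocol$ionic_strength
  cl0 <- if (is.null(protocol$chloride_mol)) 0 else protocol$chloride_mol
  warm <- NULL
  out <- lapply(protocol$volumes, function(v) {
    V <- protocol$initial_volume + v
    tot <- .titration_totals(protocol, v)
    spec <- solution_spec(tot[names(tot) != "H"], total_H = tot[["H"]],
                          ionic_strength = I0)
    r <- solve_equilibrium(model, spec, cfg, start = warm)
    if (r$converged) warm <<- r$free
    zsp <- model$species$charge[match(names(r$species_conc),
                                      model$species$name)]
    solute <- 0.5 * (sum(r$free * comp_z[names(r$free)]^2) +
                       sum(r$species_conc * zsp^2) +
                       cl0 / V +                       # sample chloride
                       protocol$titrant_conc * v / V)  # titrant sodium
    c(volume = v, I_total = I0 + solute)
  })
  out <- as.data.frame(do.call(rbind, out))
  out$rel_dev <- (out$I_total - I0) / I0
  out
}
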