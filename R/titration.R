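#' Titration protocol
#'
#' Describes one potentiometric run: the initial solution (absolute
#' amounts, mol, of the model components — the proton total being counted
#' relative to the fully deprotonated ligand reference, so ligand supplied
#' as the neutral/protonated acid plus any HCl preload all enter
#' `initial_mol["H"]`), the background ionic strength, the NaOH titrant
#' and the cumulative addition schedule.
#'
#' @param initial_volume Initial volume, dm3 (default 0.030, i.e. 30 mL).
#' @param initial_mol Named amounts, mol (e.g. `c(Zn = ..., Cit = ..., H = ...)`).
#' @param ionic_strength Background ionic strength, mol/dm3, treated as
#'   constant along the run.
#' @param titrant_conc NaOH concentration, mol/dm3 (> 0).
#' @param volumes Strictly increasing cumulative titrant volumes, dm3,
#'   starting at or above 0.
#' @param chloride_mol Optional chloride amount introduced with the sample
#'   (HCl + ZnCl2), used only by the ionic-strength drift diagnostic.
#' @return A list of class `"titration_protocol"`.
#' @export
titration_protocol <- function(initial_volume = 0.030, initial_mol,
                               ionic_strength, titrant_conc, volumes,
                               chloride_mol = NULL) {
  stopifnot(initial_volume > 0, titrant_conc > 0)
  if (any(diff(volumes) <= 0)) stop("volumes must be strictly increasing")
  if (volumes[1] < 0) stop("volumes must be non-negative")
  structure(list(initial_volume = initial_volume, initial_mol = initial_mol,
                 ionic_strength = ionic_strength,
                 titrant_conc = titrant_conc, volumes = volumes,
                 chloride_mol = chloride_mol),
            class = "titration_protocol")
}

#' Electrode calibration parameters
#'
#' Nernstian emf model `E = E0 + slope * log10[H+]`. The slope is checked
#' against a sanity band of 50-62 mV/decade (the theoretical value at
#' 298.15 K is 59.16 mV/decade).
#'
#' @param E0 Standard potential, mV.
#' @param slope mV per decade of proton concentration.
#' @param rms Root-mean-square calibration residual, mV.
#' @return A list of class `"electrode_calibration"`.
#' @export
electrode_calibration <- function(E0, slope = 59.16, rms = 0) {
  if (slope < 50 || slope > 62)
    stop("electrode slope ", slope, " mV/decade outside the 50-62 sanity band")
  structure(list(E0 = E0, slope = slope, rms = rms),
            class = "electrode_calibration")
}

# totals (mol/dm3) of every component at cumulative titrant volume v
.titration_totals <- function(protocol, v) {
  V <- protocol$initial_volume + v
  tot <- protocol$initial_mol / V
  tot["H"] <- (protocol$initial_mol[["H"]] - protocol$titrant_conc * v) / V
  tot
}

#' Simulate a potentiometric titration
#'
#' At each scheduled titrant volume the component totals are updated for
#' dilution and added base, the equilibrium is solved in total-proton mode
#' and the electrode emf is emitted through the Nernstian calibration.
#' Gaussian read-out noise of the stated standard deviations is added to
#' the recorded emf and volume; with `noise = c(0, 0)` the curve is fully
#' deterministic.
#'
#' @param model A [speciation_model()] with constants available at the
#'   protocol ionic strength.
#' @param protocol A [titration_protocol()].
#' @param electrode An [electrode_calibration()].
#' @param noise Length-2 vector `c(sigma_E_mV, sigma_V_dm3)`.
#' @param seed RNG seed (required when noise is non-zero).
#' @param cfg See [activity_config()].
#' @return Object of class `"titration_curve"`: `points`
#'   (`data.frame(volume, emf)` as recorded), `true_pH` (noise-free
#'   `-log10[H+]` per point, a simulation diagnostic), `electrode`,
#'   `protocol`, and `failed` (indices of non-converged points, normally
#'   empty).
#' @export
simulate_titration <- function(model, protocol, electrode,
                               noise = c(0, 0), seed = NULL,
                               cfg = activity_config()) {
  stopifnot(inherits(protocol, "titration_protocol"),
            inherits(electrode, "electrode_calibration"))
  if (any(noise > 0) && is.null(seed))
    stop("noisy simulation requires an explicit seed")
  vols <- protocol$volumes
  n <- length(vols)
  pH <- numeric(n); emf <- numeric(n); failed <- integer(0)
  warm <- NULL
  for (k in seq_len(n)) {
    tot <- .titration_totals(protocol, vols[k])
    spec <- solution_spec(tot[names(tot) != "H"],
                          total_H = tot[["H"]],
                          ionic_strength = protocol$ionic_strength)
    r <- solve_equilibrium(model, spec, cfg, start = warm)
    if (!r$converged) failed <- c(failed, k) else warm <- r$free
    pH[k] <- r$pH
    emf[k] <- electrode$E0 + electrode$slope * log10(r$free[["H"]])
  }
  if (length(failed))
    warning("solver failed at volume(s): ",
            paste(signif(vols[failed], 4), collapse = ", "))
  rec_v <- vols; rec_e <- emf
  if (any(noise > 0)) {
    pert <- withr_seed(seed, list(e = stats::rnorm(n, 0, noise[1]),
                                  v = stats::rnorm(n, 0, noise[2])))
    rec_e <- emf + pert$e
    rec_v <- vols + pert$v
  }
  structure(list(points = data.frame(volume = rec_v, emf = rec_e),
                 true_pH = pH, electrode = electrode, protocol = protocol,
                 failed = failed, seed = seed, noise = noise),
            class = "titration_curve")
}

#' @export
print.titration_curve <- function(x, ...) {
  cat(sprintf("titration curve: %d points, I = %g, pH %.2f -> %.2f%s\n",
              nrow(x$points), x$protocol$ionic_strength,
              x$true_pH[1], x$true_pH[length(x$true_pH)],
              if (length(x$failed)) paste0(" (", length(x$failed), " failed)")
              else ""))
  invisible(x)
}

#' Calibrate an electrode from a strong acid-base titration
#'
#' For a ligand- and metal-free curve the free proton concentration at
#' every point follows in closed form from the strong-acid/strong-base
#' balance `[H] - Kw/[H] = C_net` (conditional Kw at the protocol ionic
#' strength). Points on the acid side with `[H] >= h_min` are kept and
#' `emf ~ log10[H]` is fitted by ordinary linear regression.
#'
#' Points near the equivalence jump carry volume-induced error far above
#' the emf read-out noise, so the regression is weighted by
#' `1/(sigma_E^2 + (59.16 dlog10[H]/dV sigma_V)^2)`.
#'
#' @param curve A [simulate_titration()] curve of a strong acid solution
#'   (or measured equivalent).
#' @param protocol The protocol with the known acid amount; defaults to
#'   the one attached to the curve.
#' @param h_min Minimum free proton concentration of usable points.
#' @param sigma_E,sigma_V Read-out standard deviations used in the weights.
#' @param cfg See [activity_config()].
#' @return An [electrode_calibration()] with the fitted `E0`, `slope` and
#'   weighted residual `rms`.
#' @export
calibrate_electrode <- function(curve, protocol = curve$protocol,
                                h_min = 1e-5, sigma_E = 0.2, sigma_V = 3e-6,
                                cfg = activity_config()) {
  v <- curve$points$volume
  V0 <- protocol$initial_volume; Ct <- protocol$titrant_conc
  Cnet <- (protocol$initial_mol[["H"]] - Ct * v) / (V0 + v)
  kw <- 10^log10_kw(protocol$ionic_strength, cfg)
  h <- (Cnet + sqrt(Cnet^2 + 4 * kw)) / 2
  use <- h >= h_min
  if (sum(use) < 3L) stop("fewer than 3 usable acid-side points")
  dCdv <- -(Ct + Cnet) / (V0 + v)
  dhdv <- dCdv * (0.5 + 0.5 * Cnet / sqrt(Cnet^2 + 4 * kw))
  dlogh <- dhdv / (h * log(10))
  w <- 1 / (sigma_E^2 + (59.16 * dlogh * sigma_V)^2)
  fit <- stats::lm(curve$points$emf[use] ~ log10(h[use]),
                   weights = w[use])
  r <- stats::residuals(fit)
  electrode_calibration(E0 = unname(stats::coef(fit)[1]),
                        slope = unname(stats::coef(fit)[2]),
                        rms = sqrt(sum(w[use] * r^2) / sum(w[use])))
}

#' Joint refinement of formation constants from titration curves
#'
#' Least-squares refinement of selected conditional overall constants
#' against one or more titration curves treated as a single data set
#' (all curves must share the same ionic strength). The objective is in
#' emf space with volume-error propagation: residuals
#' `E_obs - E_calc` are weighted by `w = 1/(sigma_E^2 + (dE/dV)^2
#' sigma_V^2)` where the curve slope is estimated from the observed
#' points. Minimisation uses Levenberg-Marquardt ([minpack.lm::nls.lm]).
#' The model-fit statistic `sigma_stat = sqrt(sum(w r^2) / (n - p))` is
#' about 1 when the weighting matches the actual noise; refinements with
#' `sigma_stat > 5` are flagged as rejected. Parameters whose estimated
#' standard deviation exceeds 1 log unit (or a near-singular normal
#' matrix) trigger an identifiability warning naming the species.
#'
#' @param curves A [simulate_titration()] curve or list of curves.
#' @param model A [speciation_model()] supplying all fixed constants.
#' @param free_species Names of the species whose constants are refined.
#' @param start Optional named starting values (log10 beta, conditional at
#'   the curve ionic strength); defaults to the model values.
#' @param sigma_E,sigma_V Measurement standard deviations (mV, dm3) used
#'   in the weights; defaults are the instrument precisions 0.2 mV and
#'   3e-6 dm3.
#' @param cfg See [activity_config()].
#' @param control Passed to [minpack.lm::nls.lm.control()].
#' @return Object of class `"refinement_result"`: `refined`
#'   (`data.frame(species, logbeta, sigma)`), `sigma_stat`, `converged`,
#'   `rejected`, `n_points`, `n_params`, `identifiability_warning`.
#' @export
refine_constants <- function(curves, model, free_species, start = NULL,
                             sigma_E = 0.2, sigma_V = 3e-6,
                             cfg = activity_config(),
                             control = minpack.lm::nls.lm.control(maxiter = 50)) {
  if (inherits(curves, "titration_curve")) curves <- list(curves)
  if (!length(curves)) stop("need at least one curve")
  Is <- vapply(curves, function(cu) cu$protocol$ionic_strength, 0)
  if (diff(range(Is)) > 1e-12)
    stop("joint refinement requires curves at a single ionic strength")
  I <- Is[1]

  # freeze the model at the working ionic strength
  lb0 <- conditional_constants(model, I, cfg, prefer = "edh")
  if (anyNA(lb0))
    stop("no constants at I = ", I, " for: ",
         paste(names(lb0)[is.na(lb0)], collapse = ", "))
  mfix <- model
  mfix$species$logbeta0 <- unname(lb0)
  mfix$species$C <- 0; mfix$species$z_star <- 0
  mfix$conditional <- stats::setNames(
    vector("list", nrow(mfix$species)), mfix$species$name)
  idx <- match(free_species, mfix$species$name)
  if (anyNA(idx)) stop("unknown species: ",
                       paste(free_species[is.na(idx)], collapse = ", "))
  p0 <- if (is.null(start)) lb0[idx] else {
    s <- lb0[idx]; s[names(start)] <- start; s
  }

  # per-point weights from the observed curve slope
  wts <- lapply(curves, function(cu) {
    v <- cu$points$volume; e <- cu$points$emf
    dEdV <- stats::approx(v[-1] - diff(v) / 2, diff(e) / diff(v), v,
                          rule = 2)$y
    1 / (sigma_E^2 + dEdV^2 * sigma_V^2)
  })

  resid_fn <- function(p) {
    m <- mfix
    m$species$logbeta0[idx] <- p
    unlist(lapply(seq_along(curves), function(ci) {
      cu <- curves[[ci]]
      warm <- NULL
      ec <- vapply(seq_len(nrow(cu$points)), function(k) {
        tot <- .titration_totals(cu$protocol, cu$points$volume[k])
        spec <- solution_spec(tot[names(tot) != "H"], total_H = tot[["H"]],
                              ionic_strength = I)
        r <- solve_equilibrium(m, spec, cfg, start = warm)
        if (r$converged) warm <<- r$free
        cu$electrode$E0 + cu$electrode$slope * log10(r$free[["H"]])
      }, 0)
      sqrt(wts[[ci]]) * (cu$points$emf - ec)
    }))
  }

  fit <- minpack.lm::nls.lm(par = p0, fn = resid_fn, control = control)
  n <- sum(vapply(curves, function(cu) nrow(cu$points), 0L))
  p <- length(idx)
  sigma_stat <- sqrt(fit$deviance / (n - p))
  JtJ <- fit$hessian / 2
  sig <- rep(NA_real_, p)
  ident_warn <- character(0)
  cv <- tryCatch(solve(JtJ), error = function(e) NULL)
  if (is.null(cv) || kappa(JtJ) > 1e10) {
    ident_warn <- free_species
  } else {
    sig <- sqrt(pmax(diag(cv), 0)) * sigma_stat
    ident_warn <- free_species[sig > 1]
  }
  if (length(ident_warn))
    warning("poorly identified species: ", paste(ident_warn, collapse = ", "))
  structure(list(
    refined = data.frame(species = free_species,
                         logbeta = unname(fit$par), sigma = sig),
    sigma_stat = sigma_stat,
    converged = fit$info %in% 1:4,
    rejected = sigma_stat > 5,
    n_points = n, n_params = p,
    identifiability_warning = ident_warn,
    ionic_strength = I, fit = fit),
    class = "refinement_result")
}

#' @export
print.refinement_result <- function(x, ...) {
  cat(sprintf("refinement at I = %g: sigma = %.3f (%s%s), %d points, %d parameter(s)\n",
              x$ionic_strength, x$sigma_stat,
              if (x$converged) "converged" else "NOT converged",
              if (x$rejected) ", REJECTED sigma > 5" else "",
              x$n_points, x$n_params))
  print(x$refined, row.names = FALSE)
  invisible(x)
}
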