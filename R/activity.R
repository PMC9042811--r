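#' Activity-model configuration
#'
#' Collects the constants of the two activity-correction models used
#' throughout the package: the Davies equation
#' `log10 gamma = -A z^2 (sqrt(I)/(1+sqrt(I)) - 0.3 I)` and the extended
#' Debye-Hueckel (EDH) ionic-strength model
#' `log10 beta(I) = log10 beta0 - A z* sqrt(I)/(1 + 1.5 sqrt(I)) + C I`.
#' All at 298.15 K, where the Debye-Hueckel slope is A = 0.51.
#'
#' @param A Debye-Hueckel constant (per sqrt(mol/dm3)).
#' @param davies_linear Linear coefficient of the Davies equation.
#' @param edh_denominator Coefficient of sqrt(I) in the EDH denominator.
#' @param water_activity Water activity used when converting constants of
#'   hydrolysed species (dilute-solution default 1).
#' @return A list of class `"activity_config"`.
#' @export
activity_config <- function(A = 0.51, davies_linear = 0.3,
                            edh_denominator = 1.5, water_activity = 1.0) {
  stopifnot(A > 0, davies_linear > 0, edh_denominator > 0,
            water_activity > 0, water_activity <= 1)
  structure(list(A = A, davies_linear = davies_linear,
                 edh_denominator = edh_denominator,
                 water_activity = water_activity),
            class = "activity_config")
}

#' Davies activity coefficient
#'
#' `log10 gamma` of an ion of the given charge at ionic strength `I`
#' (mol/dm3) from the Davies equation. Charge-neutral species and I = 0
#' return 0 exactly. The empirical formula is considered reliable only
#' below about 0.5 mol/dm3.
#'
#' @param charge Signed integer ionic charge.
#' @param I Ionic strength, mol/dm3 (vectorised).
#' @param cfg See [activity_config()].
#' @return log10 activity coefficient(s).
#' @examples
#' davies_log_gamma(2, 0.1)  # about -0.429
#' @export
davies_log_gamma <- function(charge, I, cfg = activity_config()) {
  if (any(I < 0)) stop("negative ionic strength")
  s <- sqrt(I)
  -cfg$A * charge^2 * (s / (1 + s) - cfg$davies_linear * I)
}

#' Conditional constant from the extended Debye-Hueckel model
#'
#' Evaluates `log10 beta(I) = log10 beta0 - A z* sqrt(I)/(1 + 1.5 sqrt(I))
#' + C I`. The sign convention (conditional constants of
#' positive-`z*` associations *decrease* with ionic strength) is fixed by
#' requiring that least-squares fits of this expression to the shipped
#' conditional series reproduce the shipped `(logbeta0, C)` values, which
#' they do for the charge factor of [z_star()]. At I = 0 the intrinsic
#' constant is returned exactly.
#'
#' @param logbeta0 Intrinsic (zero ionic strength) log10 constant.
#' @param C Linear EDH coefficient (dm3/mol).
#' @param z_star Charge factor of the formation reaction, see [z_star()].
#' @param I Ionic strength, mol/dm3 (vectorised).
#' @param cfg See [activity_config()].
#' @return log10 conditional constant(s).
#' @export
edh_conditional <- function(logbeta0, C, z_star, I, cfg = activity_config()) {
  if (any(I < 0)) stop("negative ionic strength")
  s <- sqrt(I)
  logbeta0 - cfg$A * z_star * s / (1 + cfg$edh_denominator * s) + C * I
}

#' Intrinsic constant from a conditional one (EDH, algebraic inverse)
#'
#' @inheritParams edh_conditional
#' @param logbeta Conditional log10 constant at `I`.
#' @return log10 beta0.
#' @export
edh_intrinsic <- function(logbeta, C, z_star, I, cfg = activity_config()) {
  if (any(I < 0)) stop("negative ionic strength")
  s <- sqrt(I)
  logbeta + cfg$A * z_star * s / (1 + cfg$edh_denominator * s) - C * I
}

#' Charge factor z* of a formation reaction
#'
#' Standard reactants-minus-products sum of squared charges for the
#' formation of one mole of species from its components,
#' `z* = sum(reactant nu z^2) - sum(product nu z^2)`, water counting as
#' zero. Components with positive stoichiometric coefficients are
#' reactants; the formed species and any released protons (negative H
#' coefficients) are products. E.g. `Zn2+ + Cit3- = ZnCit-` gives
#' `(4 + 9) - 1 = 12`.
#'
#' @param stoich Named (or model-ordered) integer coefficient vector.
#' @param component_charges Charges in the same order as `stoich`.
#' @param species_charge Charge of the formed species.
#' @return Integer charge factor.
#' @examples
#' z_star(c(Cit = 1, H = 1), c(Cit = -3, H = 1), -2)  # 6
#' @export
z_star <- function(stoich, component_charges, species_charge) {
  pos <- pmax(stoich, 0)           # reactant components
  neg <- pmax(-stoich, 0)          # released components (protons)
  sum(pos * component_charges^2) - species_charge^2 -
    sum(neg * component_charges^2)
}

#' Fit the extended Debye-Hueckel model to a conditional series
#'
#' Least-squares estimate of `(logbeta0, C)` from measured conditional
#' constants at several ionic strengths, with the charge factor `z_star`
#' held fixed. Because the model is linear in both parameters after moving
#' the Debye-Hueckel term to the left-hand side, the fit is a closed-form
#' weighted linear regression and is exactly reproducible.
#'
#' @param series `data.frame(I, logbeta[, sigma])` with at least two
#'   distinct ionic strengths.
#' @param z_star Fixed charge factor, see [z_star()].
#' @param cfg See [activity_config()].
#' @param weighting `"none"` (ordinary least squares, the default) or
#'   `"1/sigma^2"` (inverse-variance weights from the `sigma` column).
#' @param species Optional species label carried in the result.
#' @return Object of class `"edh_fit"`: `logbeta0`, `C`, `z_star`,
#'   `rms_residual`, `fitted`, `residuals`, the input `series`, and `ci95`
#'   (`NULL` until [monte_carlo_ci()] is run).
#' @examples
#' ser <- data.frame(I = c(0.05, 0.15, 0.3, 0.5, 1),
#'                   logbeta = c(5.9, 4.885, 4.593, 4.310, 4.207),
#'                   sigma = c(.1, .005, .006, .005, .005))
#' fit_edh(ser, z_star = 12)
#' @export
fit_edh <- function(series, z_star, cfg = activity_config(),
                    weighting = c("none", "1/sigma^2"), species = NULL) {
  weighting <- match.arg(weighting)
  series <- as.data.frame(series)
  series <- series[!is.na(series$logbeta), , drop = FALSE]
  if (nrow(series) < 2L) stop("need at least 2 conditional points")
  if (length(unique(series$I)) < 2L)
    stop("degenerate series: all points at the same ionic strength")
  s <- sqrt(series$I)
  dh <- cfg$A * z_star * s / (1 + cfg$edh_denominator * s)
  y <- series$logbeta + dh          # = logbeta0 + C * I
  w <- if (weighting == "1/sigma^2") {
    if (is.null(series$sigma) || anyNA(series$sigma))
      stop("1/sigma^2 weighting requires a complete sigma column")
    1 / series$sigma^2
  } else rep(1, nrow(series))
  fit <- stats::lm.wfit(cbind(1, series$I), y, w)
  b0 <- unname(fit$coefficients[1]); C <- unname(fit$coefficients[2])
  pred <- edh_conditional(b0, C, z_star, series$I, cfg)
  res <- series$logbeta - pred
  structure(list(species = species, logbeta0 = b0, C = C, z_star = z_star,
                 rms_residual = sqrt(mean(res^2)),
                 fitted = pred, residuals = res, series = series,
                 weighting = weighting, cfg = cfg, ci95 = NULL),
            class = "edh_fit")
}

#' @export
print.edh_fit <- function(x, ...) {
  cat("EDH fit", if (!is.null(x$species)) paste0("[", x$species, "]"), ":",
      sprintf("logbeta0 = %.3f, C = %.3f (z* = %g, rms = %.3f, n = %d)\n",
              x$logbeta0, x$C, x$z_star, x$rms_residual, nrow(x$series)))
  if (!is.null(x$ci95)) {
    cat(sprintf("  95%% CI logbeta0: [%.3f, %.3f]  C: [%.3f, %.3f]  (%d draws)\n",
                x$ci95["logbeta0", 1], x$ci95["logbeta0", 2],
                x$ci95["C", 1], x$ci95["C", 2], x$n_draws))
  }
  invisible(x)
}

#' Monte-Carlo confidence intervals for an EDH fit
#'
#' Parametric bootstrap: the fitted conditional constants are perturbed
#' with Gaussian noise of the per-point measurement standard deviations
#' (`sigma` column), drawn through the inverse cumulative normal, the fit
#' is repeated for each replicate and 2.5/97.5 percentiles of the replicate
#' parameters give the 95% interval.
#'
#' The replicate refits use inverse-variance weighting by default — the
#' standard choice when per-point noise levels are known and unequal.
#' Because the perturbed values are generated around the *fitted* curve,
#' the interval is centred on the original point estimate under any
#' weighting; the weighting only controls how the heteroscedastic noise
#' propagates into the parameter spread.
#'
#' @param fit An [fit_edh()] result whose series carries `sigma`.
#' @param n_draws Number of replicates (>= 100).
#' @param seed Integer RNG seed (required; results are reproducible).
#' @param weighting Weighting of the replicate refits (default
#'   `"1/sigma^2"`).
#' @return The fit with `ci95` (2x2 matrix) and `n_draws` filled in.
#' @export
monte_carlo_ci <- function(fit, n_draws = 1000L, seed,
                           weighting = c("1/sigma^2", "none")) {
  weighting <- match.arg(weighting)
  stopifnot(inherits(fit, "edh_fit"))
  if (missing(seed)) stop("an explicit RNG seed is required")
  if (n_draws < 100L) stop("n_draws must be at least 100")
  sg <- fit$series$sigma
  if (is.null(sg) || anyNA(sg))
    stop("Monte-Carlo CIs require per-point sigmas")
  n <- nrow(fit$series)
  draws <- withr_seed(seed, {
    vapply(seq_len(n_draws), function(k) {
      ser <- fit$series
      # inverse-CDF normal perturbation of the model-predicted constants
      ser$logbeta <- fit$fitted + stats::qnorm(stats::runif(n), 0, sg)
      f <- fit_edh(ser, fit$z_star, fit$cfg, weighting)
      c(f$logbeta0, f$C)
    }, numeric(2))
  })
  ci <- t(apply(draws, 1, stats::quantile, probs = c(0.025, 0.975)))
  dimnames(ci) <- list(c("logbeta0", "C"), c("lo", "hi"))
  fit$ci95 <- ci
  fit$n_draws <- n_draws
  fit
}

# evaluate expr with a local, restored RNG state
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Davies-based conditional/intrinsic conversion
#'
#' Converts a conditional constant measured at ionic strength `I` to the
#' intrinsic (zero ionic strength) value by applying Davies activity
#' coefficients to every participant of the formation reaction:
#' `logbeta0 = logbeta - sum(nu_k log gamma_k) + log gamma_species
#' - b log a_H2O`, where hydrolysed species (negative proton coefficients)
#' consume `b = |nu_H|` waters. With the charge-only Davies gamma this
#' collapses to `logbeta0 = logbeta + A D(I) z*_std - b log a_H2O` with
#' `D(I) = sqrt(I)/(1+sqrt(I)) - 0.3 I` and `z*_std` the standard
#' [z_star()] factor. A warning is issued above 0.5 mol/dm3 where the
#' Davies equation is outside its usual validity range.
#'
#' @param logbeta Conditional log10 constant at `I`.
#' @param stoich Named integer coefficients of the species.
#' @param component_charges Charges aligned with `stoich`.
#' @param species_charge Charge of the species.
#' @param I Ionic strength, mol/dm3.
#' @param cfg See [activity_config()].
#' @return log10 beta0 estimate.
#' @export
davies_intrinsic <- function(logbeta, stoich, component_charges,
                             species_charge, I, cfg = activity_config()) {
  if (any(I < 0)) stop("negative ionic strength")
  if (any(I > 0.5))
    warning("Davies conversion above 0.5 mol/dm3 is outside the usual validity range")
  zs <- z_star(stoich, component_charges, species_charge)
  D <- sqrt(I) / (1 + sqrt(I)) - cfg$davies_linear * I
  b <- max(-stoich[names(stoich) == "H"], 0)  # implicit waters consumed
  if (length(b) == 0L) b <- 0
  logbeta + cfg$A * zs * D - b * log10(cfg$water_activity)
}

#' @rdname davies_intrinsic
#' @param logbeta0 Intrinsic constant to project back to ionic strength `I`
#'   (exact algebraic inverse of `davies_intrinsic`).
#' @export
davies_conditional <- function(logbeta0, stoich, component_charges,
                               species_charge, I, cfg = activity_config()) {
  zs <- z_star(stoich, component_charges, species_charge)
  D <- sqrt(I) / (1 + sqrt(I)) - cfg$davies_linear * I
  b <- max(-stoich[names(stoich) == "H"], 0)
  if (length(b) == 0L) b <- 0
  logbeta0 - cfg$A * zs * D + b * log10(cfg$water_activity)
}

#' Fit the EDH model to every species of a model
#'
#' Runs [fit_edh()] on each species that carries a conditional series and
#' returns both a summary table and a model whose intrinsic constants are
#' replaced by the fitted values (species without a series keep their
#' shipped constants).
#'
#' @param model A [speciation_model()].
#' @param cfg,weighting Passed to [fit_edh()].
#' @return List with `fits` (named list of `edh_fit`), `summary`
#'   (`data.frame(species, logbeta0, C, rms, n)`), and `model` (the
#'   refitted model).
#' @export
fit_edh_model <- function(model, cfg = activity_config(),
                          weighting = c("none", "1/sigma^2")) {
  weighting <- match.arg(weighting)
  fits <- list()
  out <- model
  for (i in seq_len(nrow(model$species))) {
    ser <- model$conditional[[i]]
    if (is.null(ser)) next
    nm <- model$species$name[i]
    f <- fit_edh(ser, model$species$z_star[i], cfg, weighting, species = nm)
    fits[[nm]] <- f
    out$species$logbeta0[i] <- f$logbeta0
    out$species$C[i] <- f$C
  }
  summary <- data.frame(
    species = names(fits),
    logbeta0 = vapply(fits, `[[`, 0, "logbeta0"),
    C = vapply(fits, `[[`, 0, "C"),
    rms = vapply(fits, `[[`, 0, "rms_residual"),
    n = vapply(fits, function(f) nrow(f$series), 0L),
    row.names = NULL)
  list(fits = fits, summary = summary, model = out)
}
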