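test_that("Davies activity coefficients behave at the limits and at I = 0.1", {
  expect_identical(davies_log_gamma(0, 0.3), 0)
  expect_identical(davies_log_gamma(3, 0), 0)
  # direct arithmetic: -0.51*4*(sqrt(.1)/(1+sqrt(.1)) - 0.03)
  expect_equal(davies_log_gamma(2, 0.1),
               -0.51 * 4 * (sqrt(0.1) / (1 + sqrt(0.1)) - 0.03))
  expect_equal(davies_log_gamma(2, 0.1), -0.429, tolerance = 1e-3)
  # -> 0 as I -> 0 for all charges
  for (z in -4:4)
    expect_lt(abs(davies_log_gamma(z, 1e-10)), 1e-4)
  expect_error(davies_log_gamma(2, -0.1), "negative")
})

test_that("EDH conditional/intrinsic conversion is exact and invertible", {
  expect_identical(edh_conditional(6.583, -0.057, 12, 0), 6.583)
  set.seed(42)
  for (k in 1:20) {
    b0 <- runif(1, -20, 40); C <- runif(1, -1, 1)
    zs <- sample(-6:14, 1); I <- runif(1, 0, 1)
    lb <- edh_conditional(b0, C, zs, I)
    expect_equal(edh_intrinsic(lb, C, zs, I), b0, tolerance = 1e-12)
  }
  expect_error(edh_conditional(5, 0, 6, -1), "negative")
})

test_that("z* follows the reactants-minus-products squared-charge rule", {
  chg <- c(Zn = 2, Cit = -3, H = 1)
  expect_equal(z_star(c(Cit = 1, H = 1), chg[c("Cit", "H")], -2), 6)
  expect_equal(z_star(c(Zn = 1, Cit = 1), chg[c("Zn", "Cit")], -1), 12)
  # balanced binuclear reaction: (2*4 + 2*9) - (16 + 2*1) = 8
  expect_equal(z_star(c(Zn = 2, Cit = 2, H = -2), chg, -4), 8)
  # neutral association of neutral partners
  expect_equal(z_star(c(A = 1, B = 1), c(A = 0, B = 0), 0), 0)
})

test_that("EDH fitting matches a brute-force grid-search oracle", {
  m <- zn_cit_dfob_model()
  for (nm in c("ZnCit", "ZnDFOB", "HCit")) {
    i <- which(m$species$name == nm)
    ser <- m$conditional[[i]]
    zs <- m$species$z_star[i]
    fit <- fit_edh(ser, zs)
    # exhaustive 2-D grid around a generous window
    b0g <- seq(fit$logbeta0 - 0.5, fit$logbeta0 + 0.5, by = 0.005)
    Cg <- seq(fit$C - 0.5, fit$C + 0.5, by = 0.005)
    sse <- outer(b0g, Cg, function(b, C) {
      s <- sqrt(ser$I)
      vapply(seq_along(b), function(k) {
        pred <- b[k] - 0.51 * zs * s / (1 + 1.5 * s) + C[k] * ser$I
        sum((ser$logbeta - pred)^2)
      }, 0)
    })
    best <- arrayInd(which.min(sse), dim(sse))
    expect_lt(abs(b0g[best[1]] - fit$logbeta0), 0.005 + 1e-9)
    expect_lt(abs(Cg[best[2]] - fit$C), 0.005 + 1e-9)
  }
})

test_that("EDH fitting recovers noiseless synthetic parameters exactly", {
  I <- c(0.02, 0.1, 0.25, 0.6, 1.0)
  truth <- c(b0 = 8.31, C = -0.22)
  ser <- data.frame(I = I,
                    logbeta = edh_conditional(truth["b0"], truth["C"], 10, I),
                    sigma = rep(0.01, 5))
  fit <- fit_edh(ser, z_star = 10)
  expect_equal(fit$logbeta0, unname(truth["b0"]), tolerance = 1e-10)
  expect_equal(fit$C, unname(truth["C"]), tolerance = 1e-10)
  expect_lt(fit$rms_residual, 1e-12)
  expect_error(fit_edh(ser[1, ], 10), "at least 2")
  expect_error(fit_edh(data.frame(I = c(.1, .1), logbeta = c(1, 2)), 10),
               "degenerate")
})

test_that("conditional constants of EDH fits decrease monotonically with I", {
  # over [0,1] every fitted species with z* > 0 and |C| < 0.51 z* curve
  m <- zn_cit_dfob_model()
  refit <- fit_edh_model(m)
  I <- seq(0, 1, 0.05)
  for (nm in names(refit$fits)) {
    f <- refit$fits[[nm]]
    if (f$z_star <= 0) next
    lb <- edh_conditional(f$logbeta0, f$C, f$z_star, I)
    if (f$C <= 0) expect_true(all(diff(lb) < 0), info = nm)
  }
})

test_that("Monte-Carlo confidence intervals are reproducible and scale with sigma", {
  m <- zn_cit_dfob_model()
  i <- which(m$species$name == "ZnCit")
  fit <- fit_edh(m$conditional[[i]], m$species$z_star[i])
  a <- monte_carlo_ci(fit, 500, seed = 7)
  b <- monte_carlo_ci(fit, 500, seed = 7)
  expect_identical(a$ci95, b$ci95)
  expect_true(a$ci95["logbeta0", 1] <= fit$logbeta0 &&
                fit$logbeta0 <= a$ci95["logbeta0", 2])
  # half-width of order 0.01-0.1: consistent with the published +/-0.009
  hw <- diff(a$ci95["logbeta0", ]) / 2
  expect_gt(hw, 0.001); expect_lt(hw, 0.2)
  # sigma -> 0 collapses the interval
  tiny <- fit
  tiny$series$sigma <- rep(1e-8, nrow(tiny$series))
  ci0 <- monte_carlo_ci(tiny, 200, seed = 1)$ci95
  expect_lt(diff(ci0["logbeta0", ]), 1e-6)
  noser <- fit; noser$series$sigma <- NULL
  expect_error(monte_carlo_ci(noser, 200, seed = 1), "sigma")
})

test_that("Davies conversion is exact at I = 0, invertible, and warns past 0.5", {
  chg <- c(Zn = 2, Cit = -3, H = 1)
  st <- c(Zn = 1, Cit = 1)
  expect_equal(davies_intrinsic(4.5, st, chg[c("Zn", "Cit")], -1, 0), 4.5)
  b0 <- davies_intrinsic(4.5, st, chg[c("Zn", "Cit")], -1, 0.3)
  expect_equal(davies_conditional(b0, st, chg[c("Zn", "Cit")], -1, 0.3), 4.5,
               tolerance = 1e-12)
  expect_warning(davies_intrinsic(4.2, st, chg[c("Zn", "Cit")], -1, 1.0),
                 "validity")
})

test_that("single-I Davies intrinsic estimates bracket the EDH value for ZnCit", {
  # low-I conversions over-predict logbeta0, high-I conversions under-predict
  m <- zn_cit_dfob_model()
  i <- which(m$species$name == "ZnCit")
  ser <- m$conditional[[i]]
  chg <- c(Zn = 2, Cit = -3)
  st <- c(Zn = 1, Cit = 1)
  b0 <- vapply(seq_len(nrow(ser)), function(k)
    suppressWarnings(davies_intrinsic(ser$logbeta[k], st, chg, -1, ser$I[k])), 0)
  edh_b0 <- m$species$logbeta0[i]
  expect_gt(b0[1], edh_b0)                 # 0.05 mol/dm3
  expect_lt(b0[length(b0)], edh_b0)        # 1.0 mol/dm3
  expect_gt(max(b0), edh_b0); expect_lt(min(b0), edh_b0)
})
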