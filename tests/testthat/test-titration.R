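# shared fixtures for the titration tests: a modest 40-point Zn/Cit run
.cit_protocol <- function(I = 0.15, zn_mM = 1, L_mM = 2, n = 40,
                          hcl = 3e-3, V0 = 0.030) {
  nH <- (3 * L_mM * 1e-3 + hcl) * V0
  titration_protocol(
    initial_volume = V0,
    initial_mol = c(Zn = zn_mM * 1e-3 * V0, Cit = L_mM * 1e-3 * V0, H = nH),
    ionic_strength = I, titrant_conc = 0.1,
    volumes = seq(0, 1.05 * nH / 0.1, length.out = n))
}
.el <- function() electrode_calibration(400, 59.16)

test_that("strong acid-base titrations match the analytic curve", {
  m <- zn_cit_dfob_model()
  V0 <- 0.030; nH <- 2e-3 * V0; Ct <- 0.1
  prot <- titration_protocol(V0, c(H = nH), ionic_strength = 0.1,
                             titrant_conc = Ct,
                             volumes = seq(0, 1.8 * nH / Ct, length.out = 25))
  cv <- simulate_titration(m, prot, .el())
  expect_length(cv$failed, 0)
  kw <- 10^(-13.997 - 2 * davies_log_gamma(1, 0.1))
  Cnet <- (nH - Ct * prot$volumes) / (V0 + prot$volumes)
  h <- (Cnet + sqrt(Cnet^2 + 4 * kw)) / 2
  expect_equal(cv$points$emf, 400 + 59.16 * log10(h), tolerance = 1e-6)
  # equivalence jump sits at V_eq = n_H / C_NaOH
  veq <- nH / Ct
  before <- max(which(prot$volumes < veq - 1e-5))
  after <- min(which(prot$volumes > veq + 1e-5))
  expect_gt(cv$true_pH[after] - cv$true_pH[before], 3)
})

test_that("the first point of a zero-volume schedule is the initial solution", {
  m <- zn_cit_dfob_model()
  prot <- .cit_protocol()
  cv <- simulate_titration(m, prot, .el())
  tot <- prot$initial_mol / prot$initial_volume
  r <- solve_equilibrium(m, solution_spec(tot[c("Zn", "Cit")],
                                          total_H = tot[["H"]],
                                          ionic_strength = 0.15))
  expect_equal(cv$true_pH[1], r$pH, tolerance = 1e-9)
})

test_that("noisy simulation is reproducible for a fixed seed", {
  m <- zn_cit_dfob_model()
  prot <- .cit_protocol(n = 20)
  a <- simulate_titration(m, prot, .el(), noise = c(0.2, 3e-6), seed = 99)
  b <- simulate_titration(m, prot, .el(), noise = c(0.2, 3e-6), seed = 99)
  expect_identical(a$points, b$points)
  c2 <- simulate_titration(m, prot, .el(), noise = c(0.2, 3e-6), seed = 100)
  expect_false(identical(a$points, c2$points))
  expect_error(simulate_titration(m, prot, .el(), noise = c(0.2, 3e-6)),
               "seed")
})

test_that("electrode calibration recovers the generating parameters", {
  m <- zn_cit_dfob_model()
  V0 <- 0.030; nH <- 3e-3 * V0
  prot <- titration_protocol(V0, c(H = nH), ionic_strength = 0.15,
                             titrant_conc = 0.1,
                             volumes = seq(0, 1.5 * nH / 0.1, length.out = 80))
  noiseless <- simulate_titration(m, prot, .el())
  cal <- calibrate_electrode(noiseless)
  expect_equal(cal$E0, 400, tolerance = 1e-6)
  expect_equal(cal$slope, 59.16, tolerance = 1e-6)
  expect_lt(cal$rms, 1e-8)
  # under read-out noise E0 lands within ~1 mV (volume-error weighting)
  hits <- 0L
  for (s in 1:10) {
    cv <- simulate_titration(m, prot, .el(), noise = c(0.2, 3e-6), seed = s)
    cal_s <- calibrate_electrode(cv)
    if (abs(cal_s$E0 - 400) < 1) hits <- hits + 1L
  }
  expect_gte(hits, 9L)
})

test_that("noiseless refinement recovers the generating constants to < 0.01", {
  m <- zn_cit_dfob_model()
  curves <- list(simulate_titration(m, .cit_protocol(zn_mM = 1, L_mM = 1), .el()),
                 simulate_titration(m, .cit_protocol(zn_mM = 1, L_mM = 5), .el()))
  truth <- conditional_constants(m, 0.15, prefer = "edh")[c("ZnCit", "ZnHCit")]
  start <- truth + c(0.4, -0.4)
  ref <- refine_constants(curves, m, c("ZnCit", "ZnHCit"), start = start)
  expect_true(ref$converged)
  expect_false(ref$rejected)
  expect_lt(max(abs(ref$refined$logbeta - truth)), 0.01)
  # with (near) noiseless data the weighted misfit statistic is tiny
  expect_lt(ref$sigma_stat, 0.1)
})

test_that("refinement under instrument noise stays within its own 3 sigma", {
  m <- zn_cit_dfob_model()
  truth <- conditional_constants(m, 0.15, prefer = "edh")[["ZnCit"]]
  sigstats <- numeric(3)
  for (s in 1:3) {
    cv <- simulate_titration(m, .cit_protocol(zn_mM = 1, L_mM = 2), .el(),
                             noise = c(0.2, 3e-6), seed = 300 + s)
    ref <- refine_constants(cv, m, "ZnCit")
    expect_lt(abs(ref$refined$logbeta - truth),
              3 * max(ref$refined$sigma, 0.02))
    sigstats[s] <- ref$sigma_stat
  }
  # weighting matches the generating noise, so sigma_stat is of order 1
  expect_gt(mean(sigstats), 0.5)
  expect_lt(mean(sigstats), 2.0)
})

test_that("under-determined species trigger an identifiability warning", {
  m <- zn_cit_dfob_model()
  # a 1:1 curve carries almost no information on the 1:2 complex
  cv <- simulate_titration(m, .cit_protocol(zn_mM = 1, L_mM = 1, n = 30), .el(),
                           noise = c(0.2, 3e-6), seed = 5)
  expect_warning(
    ref <- refine_constants(cv, m, c("ZnCit", "ZnCit2")),
    "poorly identified")
  expect_true("ZnCit2" %in% ref$identifiability_warning)
})

test_that("refinement rejects mixed-ionic-strength curve sets", {
  m <- zn_cit_dfob_model()
  a <- simulate_titration(m, .cit_protocol(I = 0.15, n = 10), .el())
  b <- simulate_titration(m, .cit_protocol(I = 0.5, n = 10), .el())
  expect_error(refine_constants(list(a, b), m, "ZnCit"), "single ionic strength")
})
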