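test_that("metal with no complexing species stays fully free", {
  m <- speciation_model(
    rbind(component("M", 2), component("L", -2), component("H", 1)),
    list(species_def("HL", c(H = 1, L = 1), -1, logbeta0 = 6, C = 0,
                     z_star = 0)))
  r <- solve_equilibrium(m, solution_spec(c(M = 1e-5, L = 0), pH = 6,
                                          ionic_strength = 0))
  expect_true(r$converged)
  expect_equal(unname(r$free["M"]), 1e-5, tolerance = 1e-10)
  expect_equal(fraction_complexed(r, "L", metal = "M"), 0)
})

test_that("single-complex system matches the closed-form quadratic solution", {
  for (case in list(c(K = 5, TM = 1e-4, TL = 2e-4),
                    c(K = 8, TM = 1e-6, TL = 1e-5),
                    c(K = 3, TM = 5e-3, TL = 1e-3))) {
    m <- toy_ml_model(case["K"])
    r <- solve_equilibrium(m, solution_spec(
      c(M = case[["TM"]], L = case[["TL"]]), pH = 7, ionic_strength = 0))
    K <- 10^case[["K"]]
    a <- K; b <- -(K * case[["TM"]] + K * case[["TL"]] + 1)
    x <- (-b - sqrt(b^2 - 4 * a * K * case[["TM"]] * case[["TL"]])) / (2 * a)
    expect_true(r$converged)
    expect_equal(unname(r$species_conc["ML"]), x, tolerance = 1e-8)
  }
})

test_that("every converged result satisfies mass balance to 1e-10 relative", {
  m <- zn_cit_dfob_model()
  conds <- expand.grid(pH = c(3, 6, 8, 10.5), I = c(0, 0.01, 0.3, 1))
  for (k in seq_len(nrow(conds))) {
    spec <- solution_spec(c(Zn = 1e-6, Cit = 1e-5, DFOB = 1e-5),
                          pH = conds$pH[k], ionic_strength = conds$I[k])
    r <- solve_equilibrium(m, spec)
    expect_true(r$converged, info = paste("pH", conds$pH[k], "I", conds$I[k]))
    expect_lte(max(abs(r$residuals)), 1e-10)
    # explicit reconstruction of the totals
    tot <- r$free + as.vector(crossprod(r$stoich, r$species_conc))
    expect_equal(unname(tot["Zn"]), 1e-6, tolerance = 1e-9)
    expect_equal(unname(tot["Cit"]), 1e-5, tolerance = 1e-9)
  }
})

test_that("Newton solution agrees with a 1-D bisection oracle on random models", {
  set.seed(11)
  for (k in 1:25) {
    rb <- random_binary_model()
    T_M <- 10^runif(1, -6, -3); T_L <- 10^runif(1, -5, -2)
    pH <- runif(1, 3, 9)
    r <- solve_equilibrium(rb$model, solution_spec(
      c(M = T_M, L = T_L), pH = pH, ionic_strength = 0))
    expect_true(r$converged)
    oracle <- bisect_binary(rb$logK, rb$use, T_M, T_L, pH)
    expect_equal(unname(r$free["M"]), unname(oracle["M"]), tolerance = 1e-8)
    expect_equal(unname(r$free["L"]), unname(oracle["L"]), tolerance = 1e-8)
  }
})

test_that("total-H mode includes autoprotolysis and honours negative totals", {
  m <- zn_cit_dfob_model()
  # excess strong base, no ligands: pH from [OH] = -T_H
  r <- solve_equilibrium(m, solution_spec(c(Zn = 0, Cit = 0, DFOB = 0),
                                          total_H = -1e-3, ionic_strength = 0.1))
  expect_true(r$converged)
  kw <- 10^(-13.997 - 2 * davies_log_gamma(1, 0.1))
  expect_equal(unname(r$free["H"]), kw / 1e-3, tolerance = 1e-6)
  # strong acid: pH = -log10 T_H
  r2 <- solve_equilibrium(m, solution_spec(c(Zn = 0, Cit = 0, DFOB = 0),
                                           total_H = 1e-3, ionic_strength = 0.1))
  expect_equal(r2$pH, 3, tolerance = 1e-6)
})

test_that("fractions partition the metal exactly", {
  m <- zn_cit_dfob_model()
  sw <- sweep_speciation(
    m, solution_spec(c(Zn = 1e-6, Cit = 1e-5, DFOB = 1e-5), pH = 7,
                     ionic_strength = 0.1),
    "pH", seq(3, 11, 1))
  expect_true(all(sw$converged))
  total <- sw$fraction_Cit + sw$fraction_DFOB + sw$fraction_hydroxo +
    sw$free_fraction
  expect_true(all(abs(total - 1) < 1e-9))
})

test_that("dilution similarity: mononuclear ratios persist, binuclear shares do not", {
  # at fixed pH the concentration ratio of two mononuclear complexes of
  # the same ligand count depends only on [H], so it is exactly invariant
  # under scaling of the totals; the share of the binuclear complex is
  # second order in zinc and collapses on dilution
  m <- zn_cit_dfob_model()
  solve_at <- function(scale) solve_equilibrium(m, solution_spec(
    c(Zn = 1e-3 * scale, Cit = 2e-3 * scale, DFOB = 0), pH = 7.8,
    ionic_strength = 0.15))
  r1 <- solve_at(1); r2 <- solve_at(1e-3)
  ratio <- function(r) r$species_conc[["ZnHCit"]] / r$species_conc[["ZnCit"]]
  expect_equal(ratio(r1), ratio(r2), tolerance = 1e-8)
  # mass action consistency across the scales: c_bi / c_ZnCit^2 invariant
  ma <- function(r) r$species_conc[["Zn2OH2Cit2"]] / r$species_conc[["ZnCit"]]^2
  expect_equal(ma(r1), ma(r2), tolerance = 1e-8)
  bi_share <- function(r) 2 * r$species_conc[["Zn2OH2Cit2"]] /
    sum(r$stoich[, "Zn"] * r$species_conc)
  expect_gt(bi_share(r1) / bi_share(r2), 10)
})

test_that("DFOB complexation is negligible at pH 4 and complete by pH 9", {
  m <- zn_cit_dfob_model()
  for (I in c(0.01, 0.1, 1)) {
    expect_lt(binary_fraction(m, "DFOB", 4, I), 1e-3)
    expect_gt(binary_fraction(m, "DFOB", 9, I), 0.99)
  }
})

test_that("pH sweeps are warm-started, monotone where chemistry says so", {
  m <- zn_cit_dfob_model()
  sw <- sweep_speciation(
    m, solution_spec(c(Zn = 1e-6, Cit = 0, DFOB = 1e-5), pH = 2,
                     ionic_strength = 0.1),
    "pH", seq(2, 9, 0.1))
  expect_true(all(sw$converged))
  # sigmoidal rise: non-decreasing up to pH 8.5 (above that, hydroxide
  # competition shaves a fraction of a percent off the plateau)
  rising <- sw$pH <= 8.5
  expect_true(all(diff(sw$fraction_DFOB[rising]) > -1e-6))
  # single-point grid equals a direct solve
  one <- sweep_speciation(
    m, solution_spec(c(Zn = 1e-6, Cit = 0, DFOB = 1e-5), pH = 6.5,
                     ionic_strength = 0.1), "pH", 6.5)
  expect_equal(one$fraction_DFOB, binary_fraction(m, "DFOB", 6.5, 0.1))
  expect_error(sweep_speciation(
    m, solution_spec(c(Zn = 1e-6, Cit = 0, DFOB = 1e-5), pH = 6.5,
                     ionic_strength = 0.1), "pH", numeric(0)), "empty")
})
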