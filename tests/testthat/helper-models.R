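# Small fixture models built in code.

# one metal M2+, one ligand L2-, single ML complex with known logK
toy_ml_model <- function(logK = 5) {
  speciation_model(
    rbind(component("M", 2), component("L", -2), component("H", 1)),
    list(species_def("ML", c(M = 1, L = 1), 0, logbeta0 = logK, C = 0,
                     z_star = 0)))
}

# random 2-component model with up to 3 species (ML, ML2, HL), constants
# drawn on sensible log scales; used by the bisection-oracle tests
random_binary_model <- function() {
  k1 <- stats::runif(1, 3, 6)
  k2 <- k1 + stats::runif(1, 1, 3)
  kh <- stats::runif(1, 3, 8)
  use <- c(TRUE, stats::runif(1) < 0.7, stats::runif(1) < 0.7)
  sp <- list(
    species_def("ML", c(M = 1, L = 1), 0, logbeta0 = k1, C = 0, z_star = 0),
    species_def("ML2", c(M = 1, L = 2), -2, logbeta0 = k2, C = 0, z_star = 0),
    species_def("HL", c(H = 1, L = 1), -1, logbeta0 = kh, C = 0, z_star = 0))
  m <- speciation_model(
    rbind(component("M", 2), component("L", -2), component("H", 1)),
    sp[use])
  list(model = m, logK = c(ML = k1, ML2 = k2, HL = kh), use = use)
}

# independent 1-D bisection oracle for random_binary_model at fixed pH:
# solve the ligand balance for free [L], metal balance in closed form
bisect_binary <- function(logK, use, T_M, T_L, pH) {
  h <- 10^(-pH)
  K1 <- 10^logK[["ML"]]
  K2 <- if (use[2]) 10^logK[["ML2"]] else 0
  Kh <- if (use[3]) 10^logK[["HL"]] else 0
  g <- function(l) {
    m <- T_M / (1 + K1 * l + K2 * l^2)
    T_L - l * (1 + Kh * h) - (K1 * l + 2 * K2 * l^2) * m
  }
  l <- stats::uniroot(g, c(0, T_L), tol = 1e-18)$root
  m <- T_M / (1 + K1 * l + K2 * l^2)
  c(M = m, L = l)
}

# published constants used by several tests: conditional series
# and intrinsic parameters per species (signs as published)
published_constants <- function() {
  I <- c(0.05, 0.15, 0.3, 0.5, 1.0)
  list(
    HCit = list(lb = c(5.69, 5.44, 5.35, 5.26, 5.12), b0 = 6.198, C = 0.163),
    H2Cit = list(lb = c(10.18, 9.57, 9.45, 9.32, 9.13), b0 = 10.913, C = 0.254),
    H3Cit = list(lb = c(13.00, 12.10, 11.94, 11.70, 11.53), b0 = 13.780, C = 0.142),
    ZnHCit = list(lb = c(10.1, 8.52, 8.15, 7.83, 7.87), b0 = 10.640, C = -0.147),
    ZnCit = list(lb = c(5.9, 4.885, 4.593, 4.310, 4.207), b0 = 6.583, C = -0.057),
    ZnCit2 = list(lb = c(NA, 7.13, 6.85, 6.40, 6.88), b0 = 7.400, C = 0.284),
    Zn2OH2Cit2 = list(lb = c(-1.8, -2.61, -2.81, -3.09, -2.51), b0 = -1.142, C = 0.902),
    ZnOH3Cit = list(lb = c(-21.9, -22.46, -22.92, -22.63, -23.05), b0 = -21.601, C = -0.248),
    HDFOB = list(lb = c(11.07, 10.74, 10.36, 10.35, 10.14), b0 = 11.491, C = 0.169),
    H2DFOB = list(lb = c(20.94, 20.25, 19.84, 19.77, 19.77), b0 = 21.530, C = 0.173),
    H3DFOB = list(lb = c(30.05, 29.10, 28.61, 28.60, 28.57), b0 = 30.691, C = 0.194),
    H4DFOB = list(lb = c(38.83, 37.46, 37.00, 36.97, 36.92), b0 = 39.250, C = -0.079),
    ZnDFOB = list(lb = c(11.67, 9.91, 9.97, 9.39, 9.32), b0 = 12.027, C = -0.486),
    ZnHDFOB = list(lb = c(21.55, 19.85, 19.85, 19.34, 19.38), b0 = 22.105, C = -0.075),
    ZnH2DFOB = list(lb = c(29.30, 27.81, 27.42, 27.19, 27.25), b0 = 29.849, C = 0.009))
}
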