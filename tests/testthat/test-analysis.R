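# Asymmetry metrics, effective population size, mutational variance,
# equilibrium summaries and phase classification.

test_that("asymmetry metrics evaluate the defining ratios and flag degeneracy", {
  reps <- data.frame(strand_code = rep(c(0L, 1L), c(70, 30)),
                     kPP = 0.3, kPM = 0.7, kMP = 0.1, kMM = 0.1)
  m <- asymmetryMetrics(reps)
  expect_equal(m$kappa, 0.4)       # (0.7 - 0.3) / (0.7 + 0.3)
  expect_equal(m$theta, 0.4)       # (70 - 30) / 100
  expect_equal(m$a_f, (0.5 - 0.1) / (0.5 + 0.1))
  reps$kPM <- 0.3
  expect_equal(asymmetryMetrics(reps)$kappa, 0)
  # non-positive denominator: undefined and flagged
  reps2 <- data.frame(strand_code = c(0L, 1L), kPP = -0.2, kPM = 0.1,
                      kMP = -1, kMM = -1)
  m2 <- asymmetryMetrics(reps2)
  expect_true(is.na(m2$kappa))
  expect_false(m2$kappa_defined)
  expect_true(is.na(m2$a_f))
  expect_error(asymmetryMetrics(reps[0, ]), "empty")
  # works straight off a state
  expect_equal(asymmetryMetrics(makeFixture("broken_state"))$kappa, 0.4)
})

test_that("metrics are invariant under strand relabelling with a sign flip", {
  set.seed(1)
  for (i in 1:20) {
    reps <- data.frame(strand_code = rbinom(40, 1, 0.5),
                       kPP = runif(1), kPM = runif(1),
                       kMP = runif(1), kMM = runif(1))
    sw <- reps
    sw$strand_code <- 1L - reps$strand_code
    sw[c("kPP", "kPM", "kMP", "kMM")] <- reps[c("kMM", "kMP", "kPM", "kPP")]
    a <- asymmetryMetrics(reps)
    b <- asymmetryMetrics(sw)
    expect_equal(a$theta, -b$theta)
    expect_equal(a$a_f, -b$a_f)
  }
})

test_that("effective population size equals the harmonic mean identically", {
  expect_equal(effectivePopulationSize(50, 50), 50)
  expect_equal(effectivePopulationSize(70, 30), 42)
  expect_equal(effectivePopulationSize(100, 0), 0)
  expect_error(effectivePopulationSize(0, 0))
  expect_error(effectivePopulationSize(-1, 5))
  set.seed(2)
  NP <- sample(1:5000, 1000, replace = TRUE)
  NM <- sample(1:5000, 1000, replace = TRUE)
  ne <- effectivePopulationSize(NP, NM)
  expect_equal(ne, 2 / (1 / NP + 1 / NM), tolerance = 1e-12)
  theta <- (NP - NM) / (NP + NM)
  expect_equal(ne, (1 + theta) * (1 - theta) * (NP + NM) / 2, tolerance = 1e-12)
})

test_that("mutational variance decomposes fitness variability and rectifies", {
  cell <- data.frame(kP = c(0.5, 0.5, 0.5), kM = c(0.2, 0.2, 0.2))
  out <- mutationalVariance(cell, c(1, 1))
  expect_equal(out$sigma2_f, 0)          # no within-cell variance
  cell2 <- data.frame(kP = rnorm(20, 0.5, 0.1), kM = rnorm(20, -0.3, 0.1))
  out2 <- mutationalVariance(cell2, c(2, 3))
  expect_equal(out2$term_M, 0)           # mean kM < 0: derivative clamps to 0
  expect_equal(out2$sigma2_f, 4 * var(cell2$kP))
  expect_error(mutationalVariance(cell2[1, ], c(1, 1)), "degenerate")
})

test_that("analytic minimal-model gradients reproduce Monte-Carlo fitness variance", {
  # a 50-replicator cell; fitness f = exp(kbar1 + kbar2 - r(k1 + k2)).
  # Oracle: empirical variance of f over mutated offspring; estimate:
  # (df/dk1)^2 s1^2 + (df/dk2)^2 s2^2 with df/dki = -r * f evaluated at the
  # cell means.
  set.seed(3)
  r <- 0.3
  p <- minimalParams(V = 100, n_total = 50, r = r)
  k1 <- runif(50, 0.4, 0.6); k2 <- runif(50, 0.2, 0.4)
  fbar <- fitnessMinimal(mean(k1), mean(k2), mean(k1), mean(k2), p)
  grad <- c(-r * fbar, -r * fbar)
  est <- mutationalVariance(data.frame(kP = k1, kM = k2), grad)
  f <- fitnessMinimal(k1, k2, mean(k1), mean(k2), p)
  mc <- var(f)
  expect_lt(abs(est$sigma2_f - mc) / mc, 0.25)
})

test_that("equilibrium summaries average after burn-in and relabel strands", {
  traj <- data.frame(step = seq(0, 1000, 100), n_cells = 10,
                     N_P = 70, N_M = 30, n_substrate = 50,
                     mean_kPP = 0.3, mean_kPM = 0.7, mean_kMP = 0, mean_kMM = 0,
                     sd_kPP = 0, sd_kPM = 0, sd_kMP = 0, sd_kMM = 0)
  s <- equilibriumSummary(traj, burn_in = 300)
  expect_equal(unname(s$means["kPP"]), 0.3)
  expect_equal(unname(s$sds["kPP"]), 0)
  expect_equal(s$n_rows, 8)
  # mirrored run (catalytic strand labelled M) reports identically
  mir <- traj
  mir[c("mean_kPP", "mean_kPM", "mean_kMP", "mean_kMM")] <-
    traj[c("mean_kMM", "mean_kMP", "mean_kPM", "mean_kPP")]
  mir[c("N_P", "N_M")] <- traj[c("N_M", "N_P")]
  s2 <- equilibriumSummary(mir, burn_in = 300)
  expect_equal(s$means, s2$means)
  expect_equal(s$N_P, s2$N_P)
  # extinct trajectory
  traj3 <- traj
  traj3[nrow(traj3), c("N_P", "N_M")] <- 0
  expect_true(equilibriumSummary(traj3, burn_in = 300)$extinct)
})

test_that("phase classification is deterministic and matches the archetypes", {
  mk <- function(kPP, kPM, kMP, kMM, NP = 60, NM = 40) {
    data.frame(step = seq(0, 2000, 100), n_cells = 10, N_P = NP, N_M = NM,
               n_substrate = 50,
               mean_kPP = kPP + seq(-0.002, 0.002, length.out = 21),
               mean_kPM = kPM, mean_kMP = kMP, mean_kMM = kMM,
               sd_kPP = 0.01, sd_kPM = 0.01, sd_kMP = 0.01, sd_kMM = 0.01)
  }
  broken <- mk(0.35, 0.75, 0.001, 0.001)
  expect_equal(classifyPhase(broken, burn_in = 500)$label, "broken")
  symmetric <- mk(0.95, 0.95, 0.95, 0.95)
  expect_equal(classifyPhase(symmetric, burn_in = 500)$label, "symmetric")
  ext <- mk(0.2, 0.2, 0.2, 0.2)
  ext[nrow(ext), c("N_P", "N_M")] <- 0
  expect_equal(classifyPhase(ext, burn_in = 500)$label, "extinct")
  # determinism
  expect_identical(classifyPhase(broken, burn_in = 500),
                   classifyPhase(broken, burn_in = 500))
  # disagreement across initial conditions flags metastability
  multi <- classifyPhase(list(broken, symmetric), burn_in = 500)
  expect_true(multi$metastable)
})

test_that("phase scans emit tidy tables and recover the boundary scaling", {
  # degenerate one-point grid runs end to end
  set.seed(4)
  tab <- phaseScan(m_values = 0.01, V_values = 30, steps = 300, stride = 30,
                   burn_in = 150,
                   params_fn = function(m, V) protocellParams(V = V, m = m,
                                                              N = 20 * V))
  expect_equal(nrow(tab), 1)
  expect_true(tab$label %in% c("symmetric", "broken", "extinct"))
  # slope fitting on a synthetic table with a known m* ~ V^-2 boundary
  Vs <- c(200, 400, 800, 1600)
  ms <- exp(seq(log(1e-5), log(1), length.out = 25))
  synth <- do.call(rbind, lapply(Vs, function(V) {
    mstar <- 5000 / V^2
    data.frame(m = ms, V = V, replicate = 1,
               label = ifelse(ms < mstar, "symmetric", "broken"),
               a_f = ifelse(ms < mstar, 0, 0.9))
  }))
  fit <- boundarySlope(synth)
  expect_equal(fit$slope, -2, tolerance = 0.25)
  expect_error(boundarySlope(synth[synth$V == 200, ]), "slope")
})
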