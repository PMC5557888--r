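# Single-lineage assays against the infinite background population.

test_that("background substrate supply is Poisson with the configured mean", {
  cfg <- lineageConfig(background_density = 0.7, initial_density = 0.725,
                       V = 100, reps = 1)
  expect_equal(sampleBackgroundSubstrates(0, cfg), 0L)
  set.seed(1)
  n_R <- 70
  draws <- sampleBackgroundSubstrates(rep(n_R, 10000), cfg)
  mu <- n_R * 0.3 / 0.7
  expect_lt(abs(mean(draws) - mu), 3.5 * sqrt(mu / 10000))
  expect_error(lineageConfig(background_density = 1, initial_density = 1,
                             V = 100), "background_density")
  expect_error(lineageConfig(background_density = 0.5, initial_density = 0.7,
                             V = 100, reps = 0), "reps")
})

test_that("a lineage without catalysis never divides and goes extinct", {
  cfg <- lineageConfig(background_density = 0.7, initial_density = 0.725,
                       V = 60, k_init = c(-1, -1, -1, -1), reps = 1,
                       max_steps = 5000)
  set.seed(2)
  out <- runLineage(cfg)
  expect_equal(out$divisions, 0)
  expect_true(out$extinct)
  expect_false(out$restored)
  expect_lte(out$min_particles, round(60 / 2))
})

test_that("division counts increase with functional asymmetry at fixed initial fitness", {
  # kinetic-symmetric profiles calibrated to the same closed-cell replicator
  # density; the functionally asymmetric lineage degrades more slowly
  # (its sigma_f^2 is smaller) and sustains more divisions before dying
  base <- lineageConfig(background_density = 0.7, initial_density = 0.725,
                        V = 600, d = 0.0632, m = 0.01,
                        symmetry_mode = "kinetic", reps = 12,
                        max_steps = 60000)
  set.seed(1)
  ksym <- calibrateInitialK(0.725, base, profile = c(1, 1, 1, 1), tol = 0.01,
                            steps = 2000, burnin = 600)
  set.seed(2)
  kasym <- calibrateInitialK(0.725, base, profile = c(1, 1, 0.3, 0.3),
                             tol = 0.01, steps = 2000, burnin = 600)
  expect_lt(abs(ksym$density - 0.725), 0.015)
  expect_lt(abs(kasym$density - 0.725), 0.015)
  run_mean <- function(k, seed) {
    cfg <- base
    cfg$k_init <- k
    set.seed(seed)
    mean(vapply(seq_len(cfg$reps),
                function(i) runLineage(cfg)$divisions, 0))
  }
  sym <- run_mean(ksym$k, 3)     # a_f = 0
  asym <- run_mean(kasym$k, 4)   # a_f = 0.54
  expect_gt(asym, sym)
  expect_gt(sym, 0)              # finite, nonzero division counts
})

test_that("lineage outcome fields are internally consistent", {
  cfg <- lineageConfig(background_density = 0.7, initial_density = 0.725,
                       V = 120, d = 0.0632, symmetry_mode = "kinetic",
                       k_init = c(0.6, 0.6, 0.6, 0.6), reps = 5,
                       max_steps = 4000)
  set.seed(5)
  for (i in 1:5) {
    out <- runLineage(cfg)
    expect_gte(out$divisions, 0)
    expect_lte(out$min_particles, round(120 / 2))
    if (out$restored) {
      expect_lt(out$min_particles, 0.3 * 120)
      expect_gte(out$restorations, 1)
    }
  }
})

test_that("restoration probability is a proper frequency and needs kappa < 1", {
  cfg <- lineageConfig(background_density = 0.85, initial_density = 0.88,
                       V = 150, d = 0.02, reps = 40,
                       k_init = c(1.2, 2.4, -1, -1), max_steps = 30000)
  set.seed(6)
  est <- estimateRestorationProbability(cfg)
  expect_gte(est$probability, 0)
  expect_lte(est$probability, 1)
  expect_equal(est$n, 40)
  expect_true(is.finite(est$se))
  if (length(est$min_replicator_distribution))
    expect_true(all(est$min_replicator_distribution >= 0))
  # kappa = 1 (kPP = 0): the plus strand is never produced (it only arises
  # from minus templates, which are never replicated), the strand pair cannot
  # sustain itself and no lineage restores
  cfg1 <- cfg
  cfg1$k_init <- c(0, 2.4, -1, -1)
  cfg1$reps <- 15
  set.seed(7)
  est1 <- estimateRestorationProbability(cfg1)
  expect_equal(est1$probability, 0)
})

test_that("initial-rate calibration matches the pilot density and is monotone", {
  cfg <- lineageConfig(background_density = 0.7, initial_density = 0.725,
                       V = 100, d = 0.0632, reps = 1)
  set.seed(8)
  lo <- calibrateInitialK(0.70, cfg, profile = c(1, 1, 1, 1), tol = 0.01,
                          steps = 2000, burnin = 600)
  set.seed(8)
  hi <- calibrateInitialK(0.78, cfg, profile = c(1, 1, 1, 1), tol = 0.01,
                          steps = 2000, burnin = 600)
  expect_gt(hi$multiplier, lo$multiplier)
  expect_lt(abs(hi$density - 0.78), 0.025)
  expect_lt(abs(lo$density - 0.70), 0.025)
  # equal-fitness start for a functionally asymmetric profile
  set.seed(9)
  asym <- calibrateInitialK(0.72, cfg, profile = c(2, 2, -1, -1), tol = 0.01,
                            steps = 2000, burnin = 600)
  expect_lt(abs(asym$density - 0.72), 0.025)
  expect_error(calibrateInitialK(0, cfg), "target_density")
  expect_error(calibrateInitialK(0.5, cfg, profile = c(-1, -1, -1, -1)),
               "catalytic")
  # densities inside the collapse gap are diagnosed as unattainable
  set.seed(10)
  expect_error(calibrateInitialK(0.3, cfg, profile = c(1, 1, 1, 1),
                                 tol = 0.01, steps = 1500, burnin = 500),
               "attainable")
})
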