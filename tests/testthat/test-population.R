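# System construction, diffusion, division and model variants.

test_that("the initial system has exactly N particles and unit rates", {
  p <- protocellParams(V = 100, N = 5000)
  s <- initializeSystem(p)
  expect_equal(totalParticles(s), 5000)
  expect_equal(length(s$substrates), ceiling(2 * 5000 / 100))
  reps <- s$replicators
  expect_true(all(reps$kPP == 1 & reps$kPM == 1 & reps$kMP == 1 & reps$kMM == 1))
  expect_lte(abs(sum(reps$strand_code == 0) - sum(reps$strand_code == 1)), 1)
  validateState(s)
  # custom starting rates for trajectory studies
  s2 <- initializeSystem(p, k_init = c(0.2, 0.8, 0.3, 0.7))
  expect_true(all(s2$replicators$kPM == 0.8))
  # awkward N that does not divide evenly
  s3 <- initializeSystem(protocellParams(V = 7, N = 53))
  expect_equal(totalParticles(s3), 53)
  expect_error(initializeSystem(protocellParams(V = 100, N = 5000,
                                                m = -1)), "m")
})

test_that("diffusion conserves substrates and respects replicator weights", {
  s <- makeFixture("two_cells_asym")
  total <- sum(s$substrates)
  set.seed(1)
  for (i in 1:50) {
    out <- diffusionStep(s)
    expect_equal(sum(out$substrates), total)
  }
  # single protocell receives everything
  s1 <- makeFixture("one_cell_three_reps")
  out <- diffusionStep(s1)
  expect_equal(out$substrates, s1$substrates)
  # a replicator-free protocell receives no substrates
  s2 <- s
  s2$replicators <- s2$replicators[s2$replicators$cell == 1, ]
  s2$substrates <- c(2L, 10L)
  s2$extinct <- FALSE
  set.seed(2)
  out2 <- diffusionStep(s2)
  expect_equal(out2$substrates[2], 0L)
  expect_equal(out2$substrates[1], 12L)
})

test_that("all-cells-empty diffusion flags extinction", {
  s <- makeFixture("two_cells_asym")
  s$replicators <- s$replicators[0, ]
  s$substrates <- c(8L, 8L)
  out <- diffusionStep(s)
  expect_true(out$extinct)
})

test_that("division splits only at the threshold and conserves daughters", {
  p <- protocellParams(V = 10, N = 19)
  mkcell <- function(n, nsub) {
    reps <- data.frame(cell = 1L, strand_code = rep_len(c(0L, 1L), n),
                       chirality_code = 0L, kPP = 1, kPM = 1, kMP = 1, kMM = 1,
                       partner = NA_integer_, is_template = FALSE)
    st <- list(replicators = reps, substrates = as.integer(nsub), params = p,
               step = 0, extinct = FALSE)
    class(st) <- "protocellState"
    st
  }
  # V - 1 particles: untouched
  s <- mkcell(5, 4)
  set.seed(3)
  out <- divisionStep(s)
  expect_equal(length(out$substrates), 1)
  # V particles: split into two daughters whose counts sum to the parent's
  s2 <- mkcell(5, 5)
  set.seed(4)
  out2 <- divisionStep(s2)
  expect_equal(length(out2$substrates) >= 1, TRUE)
  expect_equal(totalParticles(out2), 10)
  # daughter counts over many divisions fit Binomial(n, 1/2)
  set.seed(5)
  draws <- replicate(600, {
    o <- divisionStep(mkcell(10, 0))
    tabulate(o$replicators$cell, nbins = length(o$substrates))[1]
  })
  counts <- table(factor(pmin(pmax(draws, 2), 8), levels = 2:8))
  probs <- dbinom(2:8, 10, 0.5)           # pooled tails at 2 and 8
  probs[1] <- pbinom(2, 10, 0.5)
  probs[7] <- 1 - pbinom(7, 10, 0.5)
  gof <- suppressWarnings(chisq.test(counts, p = probs / sum(probs)))
  expect_gt(gof$p.value, 0.001)
})

test_that("complexes divide as a unit unless configured otherwise", {
  p <- protocellParams(V = 6, N = 6)
  reps <- data.frame(cell = 1L, strand_code = c(0L, 1L, 0L, 1L, 0L, 1L),
                     chirality_code = 0L, kPP = 1, kPM = 1, kMP = 1, kMM = 1,
                     partner = c(2L, 1L, 4L, 3L, NA, NA),
                     is_template = c(FALSE, TRUE, TRUE, FALSE, FALSE, FALSE))
  st <- list(replicators = reps, substrates = 0L, params = p,
             step = 0, extinct = FALSE)
  class(st) <- "protocellState"
  validateState(st)
  set.seed(6)
  for (i in 1:40) {
    out <- divisionStep(st)
    reps2 <- out$replicators
    comp <- which(!is.na(reps2$partner))
    expect_true(all(reps2$cell[comp] == reps2$cell[reps2$partner[comp]]))
    validateState(out)
  }
  # dissociate-at-division alternative
  st2 <- st
  st2$params$split_complex_units <- FALSE
  set.seed(7)
  out2 <- divisionStep(st2)
  expect_true(all(is.na(out2$replicators$partner)))
})

test_that("the cell count settles near 2N/V within a small factor", {
  set.seed(8)
  run <- runSimulation(protocellParams(V = 40, N = 1200), steps = 1500,
                       stride = 50)
  tr <- run$trajectory
  eq <- tr$n_cells[tr$step >= 750]
  expect_gt(mean(eq), 0.8 * 2 * 1200 / 40)
  expect_lt(mean(eq), 1.6 * 2 * 1200 / 40)
})

test_that("one-step replication forms no complexes and stays neutral within cells", {
  # structural: no complex ever persists in the one-step variant
  set.seed(9)
  p1 <- protocellParams(V = 40, N = 400, variant = "one_step", m = 0)
  s <- initializeSystem(p1)
  for (i in 1:30) {
    s <- reactionStep(s)
    expect_true(all(is.na(s$replicators$partner)))
  }
  # molecular-level neutrality: within a closed cell, high-k replicators are
  # not displaced in the one-step variant, while the two-step trade-off
  # selects against them
  freq_after <- function(variant, seed) {
    p <- protocellParams(V = 200, N = 200, variant = variant, m = 0, d = 0.02)
    reps <- data.frame(cell = 1L, strand_code = rep_len(c(0L, 1L), 100),
                       chirality_code = 0L,
                       kPP = rep(c(1, 0.05), each = 50),
                       kPM = rep(c(1, 0.05), each = 50),
                       kMP = rep(c(1, 0.05), each = 50),
                       kMM = rep(c(1, 0.05), each = 50),
                       partner = NA_integer_, is_template = FALSE)
    st <- list(replicators = reps, substrates = 100L, params = p,
               step = 0, extinct = FALSE)
    class(st) <- "protocellState"
    set.seed(seed)
    st <- reactionStep(st, nsteps = 300)
    mean(st$replicators$kPP > 0.5)
  }
  one <- vapply(1:6, function(sd) freq_after("one_step", sd), 0)
  two <- vapply(1:6, function(sd) freq_after("two_step", sd), 0)
  # two-step: catalysts are exploited, their frequency collapses
  expect_lt(mean(two), 0.35)
  # one-step: no systematic within-cell disadvantage for high-k replicators
  expect_gt(mean(one), 0.45)
})

test_that("cross-chiral catalysis only acts across stereoisomer classes", {
  p <- protocellParams(V = 30, N = 300, variant = "cross_chiral", m = 0)
  set.seed(10)
  s <- initializeSystem(p)
  expect_true(all(c(0L, 1L) %in% s$replicators$chirality_code))
  sawComplex <- FALSE
  for (i in 1:40) {
    s <- reactionStep(s)
    reps <- s$replicators
    comp <- which(!is.na(reps$partner))
    if (length(comp)) {
      sawComplex <- TRUE
      expect_true(all(reps$chirality_code[comp] !=
                        reps$chirality_code[reps$partner[comp]]))
    }
  }
  expect_true(sawComplex)
  # replication preserves chirality while complementing the strand: with all
  # L replicators being P and D being M, L_M products can only appear via
  # replication of an L_P template
  reps0 <- data.frame(cell = 1L,
                      strand_code = c(0L, 1L),
                      chirality_code = c(0L, 1L),
                      kPP = 1, kPM = 1, kMP = 1, kMM = 1,
                      partner = NA_integer_, is_template = FALSE)
  st <- list(replicators = reps0, substrates = 8L,
             params = protocellParams(V = 20, N = 10, variant = "cross_chiral",
                                      m = 0, d = 0.001),
             step = 0, extinct = FALSE)
  class(st) <- "protocellState"
  set.seed(11)
  for (i in 1:200) st <- reactionStep(st)
  reps <- st$replicators
  lm <- reps$chirality_code == 0L & reps$strand_code == 1L
  dp <- reps$chirality_code == 1L & reps$strand_code == 0L
  expect_true(any(lm) || any(dp))  # replication happened across the cycle
})
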