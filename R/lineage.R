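#' Configuration of the single-lineage assays
#'
#' A single protocell is followed along its line of descent while competing
#' against an infinite, stationary background population of protocells. The
#' background enters only through the diffusion sub-step: the cell's
#' substrate count is replaced by a Poisson draw with mean
#' `n_R * N'_S / N'_R`, where `n_R` is the cell's replicator count and
#' `N'_S / N'_R` is fixed by `background_density = N'_R / (N'_R + N'_S)`.
#' At each division one daughter is kept at random and the other discarded.
#'
#' @param background_density Replicator density of the background population,
#'   strictly inside (0, 1).
#' @param initial_density Expected initial replicator density of the followed
#'   cell; for the division-counting assay it must exceed
#'   `background_density` so the cell starts at a competitive advantage.
#' @param V,d,m,delta As in [protocellParams()]; rates are unbounded above in
#'   these assays (`k_upper = Inf`), so the probability scaling is recomputed
#'   each step from the current maximum rate.
#' @param k_init Length-4 vector of initial rates shared by all replicators
#'   of the founding cell (entries may be negative to make a strand
#'   non-catalytic).
#' @param symmetry_mode Mutation constraint, as in [protocellParams()].
#' @param reps Number of independent lineages to simulate.
#' @param restoration_threshold_fraction A lineage scores a growth
#'   restoration when it divides after its particle count has dropped below
#'   this fraction of `V` (default 0.3).
#' @param max_steps Safety cap per lineage.
#' @return A validated list of class `lineageConfig`.
#' @export
lineageConfig <- function(background_density, initial_density, V,
                          d = 0.02, m = 0.01, delta = 0.05,
                          k_init = c(1, 1, 1, 1),
                          symmetry_mode = "none",
                          reps = 100,
                          restoration_threshold_fraction = 0.3,
                          max_steps = 1e6) {
  if (background_density <= 0 || background_density >= 1)
    stop("background_density must lie strictly inside (0, 1)")
  if (initial_density <= 0 || initial_density > 1)
    stop("initial_density must lie in (0, 1]")
  if (reps < 1) stop("reps must be at least 1")
  if (length(k_init) != 4) stop("k_init must have length 4")
  cfg <- list(background_density = background_density,
              initial_density = initial_density,
              V = as.integer(V), d = d, m = m, delta = delta,
              k_init = as.numeric(k_init),
              symmetry_mode = match.arg(symmetry_mode, .symmetry_modes),
              reps = as.integer(reps),
              restoration_threshold_fraction = restoration_threshold_fraction,
              max_steps = max_steps)
  class(cfg) <- "lineageConfig"
  cfg
}

#' Background substrate supply
#'
#' Substrate count supplied to the followed protocell at a diffusion step:
#' a Poisson draw with mean `n_R * N'_S / N'_R` set by the background
#' replicator density.
#'
#' @param n_R Replicator count of the followed cell.
#' @param cfg A [lineageConfig()].
#' @return An integer draw (0 when `n_R = 0`).
#' @export
sampleBackgroundSubstrates <- function(n_R, cfg) {
  if (any(n_R < 0)) stop("n_R must be >= 0")
  ratio <- (1 - cfg$background_density) / cfg$background_density
  rpois(length(n_R), n_R * ratio)
}

# founding cell of a lineage: ~V/2 particles at the configured density,
# strand ratio taken from a closed-cell pilot of the same k profile
.lineageState <- function(cfg, p_fraction = 0.5) {
  params <- protocellParams(V = cfg$V, N = cfg$V, m = cfg$m, delta = cfg$delta,
                            d = cfg$d, k_upper = Inf,
                            symmetry_mode = cfg$symmetry_mode)
  tot <- max(4L, as.integer(round(cfg$V / 2)))
  nrep <- max(2L, as.integer(round(cfg$initial_density * tot)))
  nP <- min(nrep - 1L, max(1L, as.integer(round(p_fraction * nrep))))
  reps <- data.frame(cell = 1L,
                     strand_code = rep(c(0L, 1L), c(nP, nrep - nP)),
                     chirality_code = 0L,
                     kPP = cfg$k_init[1], kPM = cfg$k_init[2],
                     kMP = cfg$k_init[3], kMM = cfg$k_init[4],
                     partner = NA_integer_, is_template = FALSE)
  st <- list(replicators = reps, substrates = as.integer(tot - nrep),
             params = params, step = 0, extinct = FALSE)
  class(st) <- "protocellState"
  st
}

#' Follow one protocell along its line of descent
#'
#' Simulates reaction, background diffusion and division for a single
#' lineage until it dies (no replicators left) or `max_steps` is reached,
#' counting divisions and recording the minimum internal particle and
#' replicator counts and whether a division occurred after the particle count
#' fell below `restoration_threshold_fraction * V` (a bottleneck-induced
#' growth restoration).
#'
#' @param cfg A [lineageConfig()].
#' @param p_fraction Initial plus-strand fraction of the founding cell.
#' @return A list: `divisions`, `restorations`, `restored`, `min_particles`,
#'   `min_replicators`, `extinct`, `steps`.
#' @export
runLineage <- function(cfg, p_fraction = 0.5) {
  stopifnot(inherits(cfg, "lineageConfig"))
  st <- .lineageState(cfg, p_fraction)
  ratio <- (1 - cfg$background_density) / cfg$background_density
  cppRunLineage(.cppState(st), ratio, cfg$restoration_threshold_fraction,
                cfg$max_steps)
}

#' Probability of bottleneck-induced growth restoration
#'
#' Repeats the single-lineage assay and reports the fraction of lineages in
#' which the protocell divided at least once after its particle count had
#' dropped below `0.3 V`, together with the distribution of minimum
#' replicator counts among the restored lineages. In the standard use of this
#' assay the minus strand is non-catalytic (`kMP`, `kMM` negative) and the
#' kinetic asymmetry `kappa = (kPM - kPP) / (kPM + kPP)` is varied through
#' `kPP` and `kPM`; `kappa < 1` (i.e. `kPP > 0`) is required for the two
#' strands to sustain each other at all.
#'
#' @param cfg A [lineageConfig()].
#' @param p_fraction Initial plus-strand fraction of the founding cell.
#' @return A list: `probability`, `se`, `n`, `min_replicator_distribution`
#'   (minimum replicator counts of restored lineages), `outcomes` (one row
#'   per lineage).
#' @export
estimateRestorationProbability <- function(cfg, p_fraction = 0.5) {
  stopifnot(inherits(cfg, "lineageConfig"))
  out <- vector("list", cfg$reps)
  for (i in seq_len(cfg$reps)) out[[i]] <- runLineage(cfg, p_fraction)
  df <- data.frame(divisions = vapply(out, `[[`, 0, "divisions"),
                   min_particles = vapply(out, `[[`, 0, "min_particles"),
                   min_replicators = vapply(out, `[[`, 0, "min_replicators"),
                   restored = vapply(out, `[[`, TRUE, "restored"))
  p <- mean(df$restored)
  list(probability = p,
       se = sqrt(p * (1 - p) / cfg$reps),
       n = cfg$reps,
       min_replicator_distribution = df$min_replicators[df$restored],
       outcomes = df)
}

#' Steady-state replicator density of a closed protocell
#'
#' Pilot measurement used by [calibrateInitialK()]: a single cell with a
#' fixed particle budget, no diffusion and no division (mutation off), run to
#' stationarity; returns the time-averaged replicator density
#' `n_R / (n_R + n_S)`.
#'
#' @param k Length-4 rate vector shared by all replicators.
#' @param V Cell particle budget (and division threshold of the parent
#'   assay).
#' @param d Decay rate.
#' @param steps,burnin Pilot length and discarded transient.
#' @param total Particle budget of the pilot cell (defaults to `V / 2`, the
#'   size of a freshly divided cell).
#' @return The mean replicator density over the retained steps.
#' @export
closedCellDensity <- function(k, V, d = 0.02, steps = 3000, burnin = 500,
                              total = NULL) {
  if (is.null(total)) total <- max(10L, as.integer(round(V / 2)))
  params <- protocellParams(V = as.integer(total) + 1L, N = total, m = 0,
                            delta = 0.05, d = d, k_upper = Inf)
  nrep <- as.integer(round(total / 2))
  nP <- as.integer(ceiling(nrep / 2))
  reps <- data.frame(cell = 1L, strand_code = rep(c(0L, 1L), c(nP, nrep - nP)),
                     chirality_code = 0L,
                     kPP = k[1], kPM = k[2], kMP = k[3], kMM = k[4],
                     partner = NA_integer_, is_template = FALSE)
  st <- list(replicators = reps, substrates = as.integer(total - nrep),
             params = params, step = 0, extinct = FALSE)
  class(st) <- "protocellState"
  cppClosedCellDensity(.cppState(st), steps, burnin)
}

#' Calibrate initial rates to a target closed-cell replicator density
#'
#' Finds a scalar multiplier of a rate profile such that the steady-state
#' replicator density of a closed protocell matches `target_density`,
#' by bisection against the pilot simulation [closedCellDensity()]. This lets
#' lineages with different degrees of functional asymmetry start at the same
#' expected fitness (replicator density).
#'
#' @param target_density Desired replicator density in (0, 1).
#' @param cfg A [lineageConfig()] (supplies `V`, `d` and the profile via
#'   `k_init`).
#' @param profile Length-4 rate profile to scale (defaults to `cfg$k_init`);
#'   negative entries stay negative (non-catalytic) under scaling.
#' @param tol Density tolerance of the bisection.
#' @param steps,burnin Pilot length per bisection probe.
#' @param max_iter Bisection iteration cap.
#' @return A list: `k` (calibrated rates), `multiplier`, `density` (achieved
#'   pilot density).
#' @export
calibrateInitialK <- function(target_density, cfg, profile = cfg$k_init,
                              tol = 1e-3, steps = 4000, burnin = 1000,
                              max_iter = 30) {
  if (target_density <= 0 || target_density >= 1)
    stop("target_density must lie strictly inside (0, 1)")
  if (all(profile <= 0)) stop("profile has no catalytic entry; nothing to scale")
  dens <- function(s) closedCellDensity(s * profile, cfg$V, cfg$d,
                                        steps = steps, burnin = burnin)
  lo <- 0; hi <- 1
  dhi <- dens(hi)
  while (dhi < target_density && hi < 1024) {
    hi <- hi * 2
    dhi <- dens(hi)
  }
  if (dhi < target_density)
    stop(sprintf(paste0("target_density %.3f unattainable for this profile; ",
                        "achievable densities reach only about %.3f"),
                 target_density, dhi))
  mid <- hi; dmid <- dhi
  for (i in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    dmid <- dens(mid)
    if (abs(dmid - target_density) < tol) break
    if (dmid < target_density) lo <- mid else hi <- mid
  }
  if (abs(dmid - target_density) > max(5 * tol, 0.02))
    stop(sprintf(paste0("target_density %.3f is not attainable for this ",
                        "profile: below a threshold rate the closed cell ",
                        "collapses (density 0); the nearest achievable ",
                        "density found was %.3f"),
                 target_density, dmid))
  list(k = mid * profile, multiplier = mid, density = dmid)
}
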