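#' The reaction sub-step
#'
#' Runs the stochastic reaction algorithm: `N / alpha` micro-iterations, each
#' picking a particle X uniformly among all `N` particles and, when the cell
#' offers one, a second particle Y uniformly among the other particles of X's
#' protocell (excluding X's complex partner). A single uniform draw then
#' selects at most one event among complex formation (probability
#' `alpha * beta * k_xy` per orientation, `beta = 1/2`), replication of a
#' complex from a substrate (`alpha * gamma`, `gamma = 1/4`) and decay of X
#' (`alpha * d`), so realised event frequencies are exactly proportional to
#' the rate constants. Replication converts a substrate into a replicator
#' complementary to the template (rates copied, mutated with probability `m`)
#' and decay does the reverse, so the total particle number never changes.
#'
#' @param state A `protocellState`.
#' @param nsteps Number of reaction time steps to run.
#' @return The updated state.
#' @export
reactionStep <- function(state, nsteps = 1) {
  stopifnot(inherits(state, "protocellState"))
  .fromCppState(cppReactionStep(.cppState(state), as.integer(nsteps)))
}

#' The diffusion sub-step
#'
#' Pools all substrates and redistributes them among protocells with
#' probabilities proportional to each cell's replicator count (a multinomial
#' draw); a replicator-free protocell receives none. If no cell holds a
#' replicator the run is flagged extinct.
#'
#' @inheritParams reactionStep
#' @return The updated state.
#' @export
diffusionStep <- function(state) {
  stopifnot(inherits(state, "protocellState"))
  .fromCppState(cppDiffusionStep(.cppState(state)))
}

#' The cell-division sub-step
#'
#' Every protocell holding at least `V` particles is split in two, each
#' particle assigned to a daughter with probability 1/2 (catalyst-template
#' complexes as a unit unless `split_complex_units` is off). Protocells left
#' with no particles are removed.
#'
#' @inheritParams reactionStep
#' @return The updated state.
#' @export
divisionStep <- function(state) {
  stopifnot(inherits(state, "protocellState"))
  .fromCppState(cppDivisionStep(.cppState(state)))
}

#' Run the full protocell simulation
#'
#' Iterates reaction, diffusion and cell division, recording population
#' summaries every `stride` steps. The run stops early if the system goes
#' extinct (no replicators anywhere).
#'
#' @param x A `protocellState` (e.g. from [initializeSystem()]) or a
#'   [protocellParams()] object, in which case the default initial state is
#'   built first.
#' @param steps Number of time steps.
#' @param stride Recording stride (rows of the trajectory table).
#' @param ... Passed to [initializeSystem()] when `x` is a parameter object.
#' @return An object of class `protosymTrajectory`: a list with `trajectory`
#'   (data frame: step, cell count, strand copy numbers `N_P`/`N_M`,
#'   substrate count, mean and sd of each `k_xy` over all replicators),
#'   `state` (final state), `extinct` and `steps_run`.
#' @export
#' @examples
#' set.seed(1)
#' run <- runSimulation(protocellParams(V = 30, N = 300), steps = 50, stride = 10)
#' tail(run$trajectory, 2)
runSimulation <- function(x, steps, stride = 1000, ...) {
  state <- if (inherits(x, "protocellParams")) initializeSystem(x, ...) else x
  stopifnot(inherits(state, "protocellState"))
  out <- cppRunSimulation(.cppState(state), as.numeric(steps), as.numeric(stride))
  traj <- as.data.frame(out$traj)
  names(traj) <- c("step", "n_cells", "N_P", "N_M", "n_substrate",
                   paste0("mean_", .k_names), paste0("sd_", .k_names))
  res <- list(trajectory = traj, state = .fromCppState(out$state),
              extinct = out$extinct, steps_run = out$steps_run,
              params = state$params)
  class(res) <- "protosymTrajectory"
  res
}

#' @export
print.protosymTrajectory <- function(x, ...) {
  last <- x$trajectory[nrow(x$trajectory), ]
  cat(sprintf("protocell trajectory: %g steps%s, %d recorded rows\n",
              x$steps_run, if (x$extinct) " (extinct)" else "",
              nrow(x$trajectory)))
  cat(sprintf("  final: %g cells, N_P = %g, N_M = %g, mean k = (%.3f, %.3f, %.3f, %.3f)\n",
              last$n_cells, last$N_P, last$N_M,
              last$mean_kPP, last$mean_kPM, last$mean_kMP, last$mean_kMM))
  invisible(x)
}

# First-event sampler used by the Gillespie-equivalence checks: repeatedly
# runs micro-iterations from a frozen state until one event fires.
.firstEvents <- function(state, ntrials) {
  stopifnot(inherits(state, "protocellState"))
  df <- cppFirstEvents(.cppState(state), as.integer(ntrials))
  df$type <- c("complex", "replication", "decay")[df$type]
  df
}
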