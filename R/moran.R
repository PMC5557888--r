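#' Parameters of the minimal hierarchical Moran model
#'
#' The minimal model strips the protocell system down to the ingredients
#' sufficient for functional symmetry breaking: replicators carry a pair of
#' cooperativity values `(k1, k2)` and live in protocells that split when
#' they exceed `V` members; each time step one replicator replicates with
#' probability proportional to its fitness
#' `f = exp(kbar1 + kbar2 - r (k1 + k2))` (per-cell means `kbar`) and one
#' replicator is removed at random, keeping the total count constant.
#'
#' Two variance modes control how the mutational variance of `f` behaves near
#' zero. In `"rectified"` mode every `k` entering `f` is clamped below at 0,
#' so `df/dk_i = 0` for `k_i < 0` and the variance of `f` generated by
#' mutation vanishes as a cooperativity crosses zero; symmetry breaking is
#' expected at intermediate `V`. In `"invariant"` mode no clamping is done
#' and mutation acts on an unbounded additive scale, so the variance of `f`
#' is independent of the position in `(k1, k2)` space; no symmetry breaking
#' is expected.
#'
#' @param V A protocell divides when its member count exceeds `V`.
#' @param n_total Total replicator count (constant).
#' @param r Relative cost of cooperation, in (0, 1).
#' @param m,delta Mutation probability per value per replication and uniform
#'   step half-width.
#' @param variance_mode `"rectified"` or `"invariant"`.
#' @param k_upper Reflecting upper bound on `k1`, `k2` (`Inf` disables).
#' @param within_cell_death If `TRUE` the removed replicator is drawn from
#'   the cell of the birth instead of the whole population (sensitivity
#'   switch; default `FALSE`, global uniform removal).
#' @return A validated list of class `minimalParams`.
#' @export
minimalParams <- function(V, n_total, r = 0.3, m = 0.01, delta = 0.05,
                          variance_mode = c("rectified", "invariant"),
                          k_upper = 1, within_cell_death = FALSE) {
  variance_mode <- match.arg(variance_mode)
  if (r <= 0 || r >= 1) stop("r must lie strictly inside (0, 1)")
  if (V < 1) stop("V must be >= 1")
  if (n_total < 2) stop("n_total must be >= 2")
  if (m < 0 || m > 1) stop("m must lie in [0, 1]")
  if (delta <= 0) stop("delta must be > 0")
  p <- list(V = as.integer(V), n_total = as.integer(n_total), r = r, m = m,
            delta = delta, variance_mode = variance_mode, k_upper = k_upper,
            within_cell_death = isTRUE(within_cell_death))
  class(p) <- "minimalParams"
  p
}

.minimalParForCpp <- function(p) {
  list(r = p$r, m = p$m, delta = p$delta,
       k_upper = if (is.finite(p$k_upper)) p$k_upper else Inf,
       V = p$V,
       variance_mode_code = match(p$variance_mode,
                                  c("rectified", "invariant")) - 1L,
       within_cell_death = p$within_cell_death)
}

#' Fitness in the minimal hierarchical Moran model
#'
#' `f = exp(kbar1 + kbar2 - r (k1 + k2))`, with every `k` (individual and
#' per-cell mean contribution) clamped below at 0 in `"rectified"` variance
#' mode so that `df/dk_i = 0` whenever `k_i < 0`.
#'
#' @param k1,k2 Cooperativity values of the replicator.
#' @param kbar1,kbar2 Means over the replicator's protocell.
#' @param params A [minimalParams()] object.
#' @return The fitness value(s).
#' @export
#' @examples
#' p <- minimalParams(V = 10, n_total = 100, r = 0.5)
#' fitnessMinimal(1, 1, 1, 1, p)  # exp(2 - 1) = e
fitnessMinimal <- function(k1, k2, kbar1, kbar2, params) {
  stopifnot(inherits(params, "minimalParams"))
  if (params$variance_mode == "rectified") {
    k1 <- pmax(k1, 0); k2 <- pmax(k2, 0)
    kbar1 <- pmax(kbar1, 0); kbar2 <- pmax(kbar2, 0)
  }
  exp(kbar1 + kbar2 - params$r * (k1 + k2))
}

#' Initial population for the minimal model
#'
#' Replicators start at a common `(k1, k2)` and are spread over
#' `ceiling(2 n_total / V)` protocells of roughly `V / 2` members.
#'
#' @param params A [minimalParams()].
#' @param k1,k2 Common starting values.
#' @return A data frame with columns `k1`, `k2`, `cell`.
#' @export
initializeMinimal <- function(params, k1 = 0.5, k2 = 0.5) {
  stopifnot(inherits(params, "minimalParams"))
  ncells <- max(1L, as.integer(ceiling(2 * params$n_total / params$V)))
  cell <- rep_len(seq_len(ncells), params$n_total)
  data.frame(k1 = k1, k2 = k2, cell = sort(cell))
}

#' One birth-death step of the minimal Moran process
#'
#' @param pop Data frame `(k1, k2, cell)`.
#' @param params A [minimalParams()].
#' @return The updated population data frame (same number of rows).
#' @export
moranStep <- function(pop, params) {
  runMinimal(params, steps = 1, stride = 1, init = pop)$population
}

#' Run the minimal hierarchical Moran model
#'
#' @param params A [minimalParams()].
#' @param steps Number of birth-death steps.
#' @param stride Recording stride.
#' @param init Initial population (default [initializeMinimal()]).
#' @param k1,k2 Starting values passed to [initializeMinimal()] when `init`
#'   is not given.
#' @return A list with `trajectory` (data frame: step, mean `k1`, mean `k2`,
#'   asymmetry `|(k1 - k2)/(k1 + k2)|` of the clamped population means, cell
#'   count) and `population` (final state).
#' @export
#' @examples
#' set.seed(1)
#' p <- minimalParams(V = 10, n_total = 60, m = 0)
#' out <- runMinimal(p, steps = 100, stride = 50)
#' out$trajectory$mean_k1  # constant when m = 0
runMinimal <- function(params, steps, stride = 1000, init = NULL,
                       k1 = 0.5, k2 = 0.5) {
  stopifnot(inherits(params, "minimalParams"))
  if (is.null(init)) init <- initializeMinimal(params, k1, k2)
  stopifnot(nrow(init) == params$n_total)
  out <- cppRunMinimal(as.numeric(init$k1), as.numeric(init$k2),
                       as.integer(init$cell), .minimalParForCpp(params),
                       as.numeric(steps), as.numeric(stride))
  traj <- as.data.frame(out$traj)
  names(traj) <- c("step", "mean_k1", "mean_k2", "asymmetry", "n_cells")
  list(trajectory = traj,
       population = data.frame(k1 = out$k1, k2 = out$k2, cell = out$cell))
}
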