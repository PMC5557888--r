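#' Model parameters for the protocell simulation
#'
#' Collects and validates the parameters of the individual-based protocell
#' model. The defaults follow the standard parameterisation of the model:
#' mutation probability `m = 0.01` per replication, mutation step half-width
#' `delta = 0.05`, decay rate `d = 0.02` per time step, total particle number
#' `N = 50 V`, and an upper bound `k_upper = 1` on the complex-formation
#' rates.
#'
#' @param V Division threshold: a protocell divides when it holds at least
#'   `V` particles (replicators plus substrates).
#' @param N Total number of particles in the system; conserved exactly.
#' @param m Probability that a newly replicated molecule mutates its
#'   complex-formation rates.
#' @param delta Half-width of the uniform mutation step distribution.
#' @param d Per-time-step decay probability of a replicator into a substrate.
#' @param k_upper Upper (reflecting) bound on `k_xy`; use `Inf` to disable,
#'   in which case the probability scaling constant alpha is recomputed each
#'   time step from the current maximum effective rate.
#' @param mutation_method One of `"additive_free_below_zero"` (default:
#'   additive steps, reflecting at `k_upper`, no lower bound so stored rates
#'   may go negative with effective rate zero), `"additive_reflect_zero"`
#'   (additionally reflecting at zero), or `"multiplicative_log"` (random
#'   walk in log scale).
#' @param symmetry_mode Constraint tying `k_xy` values: `"none"`,
#'   `"kinetic"` (`kPP = kPM`, `kMP = kMM`), `"functional"` (`kPP = kMP`,
#'   `kPM = kMM`) or `"both"`. Tied groups are perturbed by the mean of as
#'   many independent uniform draws as the group has members, which keeps the
#'   mutational variance of `sum(k_xy)` identical to the unconstrained model.
#' @param variant `"two_step"` (complex formation then replication),
#'   `"one_step"` (instantaneous replication on a catalyst-template
#'   encounter; removes the template/catalyst trade-off) or `"cross_chiral"`
#'   (two stereoisomer classes L and D; catalysis only across chiralities).
#' @param mutate_all If `TRUE` (default) a mutation event perturbs every
#'   (tied group of) rate(s), each with its own draw; if `FALSE` one randomly
#'   chosen group is perturbed.
#' @param split_complex_units If `TRUE` (default) a catalyst-template complex
#'   is assigned to one daughter cell as a unit at division; if `FALSE`
#'   complexes are dissociated before the particles are partitioned.
#'
#' @return An object of class `protocellParams` (a validated list).
#' @export
#' @examples
#' p <- protocellParams(V = 100)
#' p$N  # 50 * V by default
protocellParams <- function(V,
                            N = 50 * V,
                            m = 0.01,
                            delta = 0.05,
                            d = 0.02,
                            k_upper = 1,
                            mutation_method = "additive_free_below_zero",
                            symmetry_mode = "none",
                            variant = "two_step",
                            mutate_all = TRUE,
                            split_complex_units = TRUE) {
  mutation_method <- match.arg(mutation_method, .mutation_methods)
  symmetry_mode <- match.arg(symmetry_mode, .symmetry_modes)
  variant <- match.arg(variant, .variants)
  if (!is.numeric(V) || length(V) != 1 || V < 2)
    stop("V must be a single number >= 2")
  if (!is.numeric(N) || length(N) != 1 || N < 2)
    stop("N must be a single number >= 2")
  if (m < 0 || m > 1) stop("m must lie in [0, 1]")
  if (delta <= 0) stop("delta must be > 0")
  if (d <= 0 || d >= 1) stop("d must lie in (0, 1)")
  if (!(is.infinite(k_upper) || k_upper > 0))
    stop("k_upper must be positive or Inf")
  p <- list(V = as.integer(V), N = as.numeric(N), m = m, delta = delta, d = d,
            k_upper = k_upper, mutation_method = mutation_method,
            symmetry_mode = symmetry_mode, variant = variant,
            mutate_all = isTRUE(mutate_all),
            split_complex_units = isTRUE(split_complex_units))
  class(p) <- "protocellParams"
  p
}

#' @export
print.protocellParams <- function(x, ...) {
  cat("protocell model parameters\n")
  cat(sprintf("  V = %d, N = %g, m = %g, delta = %g, d = %g, k_upper = %g\n",
              x$V, x$N, x$m, x$delta, x$d, x$k_upper))
  cat(sprintf("  mutation: %s (%s), symmetry: %s, variant: %s\n",
              x$mutation_method,
              if (x$mutate_all) "all rates per event" else "one rate per event",
              x$symmetry_mode, x$variant))
  invisible(x)
}

# integer-coded view of the parameters consumed by the compiled core
.paramsForCpp <- function(p) {
  list(V = p$V, N = p$N, m = p$m, delta = p$delta, d = p$d,
       k_upper = if (is.finite(p$k_upper)) p$k_upper else Inf,
       mutation_method_code = match(p$mutation_method, .mutation_methods),
       symmetry_mode_code = match(p$symmetry_mode, .symmetry_modes) - 1L,
       variant_code = match(p$variant, .variants) - 1L,
       mutate_all = p$mutate_all,
       split_complex_units = p$split_complex_units)
}

#' Probability scaling constant of the reaction algorithm
#'
#' The reaction sub-step assigns each candidate reaction a probability
#' `alpha * beta * k` (complex formation, `beta = 1/2`), `alpha * gamma`
#' (replication, `gamma = 1/4`) or `alpha * d` (decay). `alpha` is set so that
#' the sum of these probabilities can never exceed one:
#' `alpha = 1 / (2 * beta * k_max + gamma + d) = 1 / (k_max + 1/4 + d)`.
#'
#' @param k_max Largest effective complex-formation rate admissible in the
#'   run (`k_upper` when rates are bounded, otherwise the current maximum).
#' @param d Decay rate.
#' @return The scaling constant `alpha` (a positive number).
#' @export
#' @examples
#' computeAlpha(1, 0.02)  # 1 / 1.27
computeAlpha <- function(k_max, d) {
  if (!is.numeric(k_max) || any(k_max < 0)) stop("k_max must be >= 0")
  if (!is.numeric(d) || any(d < 0)) stop("d must be >= 0")
  1 / (k_max + 0.25 + d)
}
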