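# Single-event primitives. These are the reference semantics of one reaction
# event on an explicit state; the compiled reaction loop realises the same
# probabilities (checked against closed forms in the test suite).

.effRate <- function(k) pmax(k, 0)

.kRate <- function(rep_row, template_strand) {
  # catalyst's rate towards a template of the given strand code
  kmat <- matrix(unlist(rep_row[.k_names]), 2, 2, byrow = TRUE)
  .effRate(kmat[rep_row$strand_code + 1L, template_strand + 1L])
}

#' Attempt complex formation between two free replicators
#'
#' With probability `alpha * beta * k_xy^X` the pair forms a complex with X
#' as catalyst and Y as template; failing that, with probability
#' `alpha * beta * k_yx^Y` the reverse orientation forms (a single uniform
#' draw against cumulative thresholds, so the two orientations occur in
#' proportion `k_xy^X : k_yx^Y`). Negative stored rates contribute an
#' effective rate of zero. At most one complex forms per attempt.
#'
#' @param state A `protocellState`.
#' @param i,j Row indices of the two replicators; both must be free and in
#'   the same protocell.
#' @param alpha Probability scaling constant; defaults to the value implied
#'   by the run parameters ([computeAlpha()]).
#' @return A list with the updated `state` and `formed`, one of `"none"`,
#'   `"xy"` (X catalyst) or `"yx"` (Y catalyst).
#' @export
attemptComplexFormation <- function(state, i, j, alpha = NULL) {
  reps <- state$replicators
  if (i == j) stop("a replicator cannot complex with itself")
  if (!is.na(reps$partner[i]) || !is.na(reps$partner[j]))
    stop("attemptComplexFormation called on a complexed replicator")
  if (reps$cell[i] != reps$cell[j])
    stop("complex formation requires co-resident replicators")
  if (is.null(alpha)) alpha <- .alphaOf(state)
  pX <- alpha * 0.5 * .kRate(reps[i, ], reps$strand_code[j])
  pY <- alpha * 0.5 * .kRate(reps[j, ], reps$strand_code[i])
  if (state$params$variant == "cross_chiral") {
    if (reps$chirality_code[i] == reps$chirality_code[j]) pX <- pY <- 0
  }
  u <- runif(1)
  formed <- "none"
  if (u < pX) {
    formed <- "xy"
    reps$partner[c(i, j)] <- c(j, i)
    reps$is_template[c(i, j)] <- c(FALSE, TRUE)
  } else if (u < pX + pY) {
    formed <- "yx"
    reps$partner[c(i, j)] <- c(j, i)
    reps$is_template[c(i, j)] <- c(TRUE, FALSE)
  }
  state$replicators <- reps
  list(state = state, formed = formed)
}

#' Attempt replication of a complexed template from a substrate
#'
#' With probability `alpha * gamma` (`gamma = 1/4`) one substrate of the
#' complex's protocell is converted into a new replicator whose strand is the
#' complement of the template's, whose rates are copied from the template
#' (mutated with probability `m`), after which the complex dissociates.
#'
#' @param state A `protocellState`.
#' @param i Row index of either complex member.
#' @param alpha Probability scaling constant (default as in
#'   [attemptComplexFormation()]).
#' @return A list with the updated `state` and logical `replicated`.
#' @export
attemptReplication <- function(state, i, alpha = NULL) {
  reps <- state$replicators
  if (is.na(reps$partner[i])) stop("replication requires a formed complex")
  cell <- reps$cell[i]
  if (state$substrates[cell] < 1)
    stop("replication requires a substrate in the complex's protocell")
  if (is.null(alpha)) alpha <- .alphaOf(state)
  replicated <- runif(1) < alpha * 0.25
  if (replicated) {
    tidx <- if (reps$is_template[i]) i else reps$partner[i]
    tmpl <- reps[tidx, ]
    k <- unlist(tmpl[.k_names])
    if (runif(1) < state$params$m) k <- mutateK(k, state$params)
    newrow <- tmpl
    newrow$strand_code <- 1L - tmpl$strand_code
    newrow[.k_names] <- as.list(k)
    newrow$partner <- NA_integer_
    newrow$is_template <- FALSE
    j <- reps$partner[i]
    reps$partner[c(i, j)] <- NA_integer_
    reps$is_template[c(i, j)] <- FALSE
    reps <- rbind(reps, newrow)
    state$substrates[cell] <- state$substrates[cell] - 1L
    state$replicators <- reps
  }
  list(state = state, replicated = replicated)
}

#' Attempt decay of a replicator into a substrate
#'
#' With probability `alpha * d` the replicator's complex (if any) is
#' dissociated and the replicator becomes a substrate of the same protocell;
#' the partner survives as a free replicator. Total particles are unchanged.
#'
#' @inheritParams attemptReplication
#' @return A list with the updated `state` and logical `decayed`.
#' @export
attemptDecay <- function(state, i, alpha = NULL) {
  if (is.null(alpha)) alpha <- .alphaOf(state)
  decayed <- runif(1) < alpha * state$params$d
  if (decayed) {
    reps <- state$replicators
    j <- reps$partner[i]
    if (!is.na(j)) {
      reps$partner[j] <- NA_integer_
      reps$is_template[j] <- FALSE
    }
    cell <- reps$cell[i]
    state$substrates[cell] <- state$substrates[cell] + 1L
    reps <- reps[-i, ]
    # reindex partner references after the removal
    shift <- !is.na(reps$partner) & reps$partner > i
    reps$partner[shift] <- reps$partner[shift] - 1L
    state$replicators <- reps
  }
  list(state = state, decayed = decayed)
}

.alphaOf <- function(state) {
  kmax <- if (is.finite(state$params$k_upper)) state$params$k_upper
          else max(0, state$replicators[, .k_names], na.rm = TRUE)
  computeAlpha(kmax, state$params$d)
}

#' Mutate a vector of complex-formation rates
#'
#' Applies one mutation event to the four rates `(kPP, kPM, kMP, kMM)`. Under
#' the default additive method each rate receives an independent uniform step
#' on `(-delta, delta)` with a reflecting boundary at `k_upper` and no lower
#' bound (negative stored values are retained and act as rate zero); the
#' `additive_reflect_zero` method also reflects at zero; the
#' `multiplicative_log` method multiplies by a uniform factor on
#' `(1 - delta, 1 + delta)` (reflection at `k_upper` performed in log scale).
#' Symmetry constraints tie rate pairs together; each tied group of size `n`
#' is perturbed by the mean of `n` independent draws, which leaves the
#' mutational variance of `sum(k_xy)` equal to the unconstrained `4 delta^2 / 3`.
#'
#' This function applies the event unconditionally; callers draw the
#' per-replication Bernoulli(`m`) trial.
#'
#' @param k Numeric length-4 vector `(kPP, kPM, kMP, kMM)`.
#' @param params A [protocellParams()] object (uses `delta`, `k_upper`,
#'   `mutation_method`, `symmetry_mode`, `mutate_all`).
#' @return The mutated length-4 vector, ties preserved exactly.
#' @export
mutateK <- function(k, params) {
  stopifnot(length(k) == 4)
  groups <- switch(params$symmetry_mode,
                   none = list(1L, 2L, 3L, 4L),
                   kinetic = list(c(1L, 2L), c(3L, 4L)),
                   functional = list(c(1L, 3L), c(2L, 4L)),
                   both = list(1:4))
  pick <- if (params$mutate_all) seq_along(groups)
          else sample.int(length(groups), 1)
  delta <- params$delta
  up <- params$k_upper
  for (g in groups[pick]) {
    n <- length(g)
    if (params$mutation_method == "multiplicative_log") {
      f <- exp(mean(log(runif(n, 1 - delta, 1 + delta))))
      v <- k[g] * f
      if (is.finite(up)) v <- ifelse(v > up, up^2 / v, v)
    } else {
      eps <- mean(runif(n, -delta, delta))
      v <- k[g] + eps
      if (is.finite(up)) while (any(v > up)) v[v > up] <- 2 * up - v[v > up]
      if (params$mutation_method == "additive_reflect_zero") {
        while (any(v < 0)) {
          v[v < 0] <- -v[v < 0]
          if (is.finite(up)) v[v > up] <- 2 * up - v[v > up]
        }
      }
    }
    k[g] <- v
  }
  names(k) <- .k_names
  k
}
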