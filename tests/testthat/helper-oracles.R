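# Closed-form single-iteration event probabilities for a frozen state, derived
# directly from the reaction algorithm's definition. Used as the independent
# oracle for the event-frequency and Gillespie-equivalence checks; kept free
# of any call into the package's stepping code.
#
# For a single compartment with `tot` particles, nR free replicators
# r_1..r_nR (rates k), complexes and nS substrates, one micro-iteration picks
# X uniformly among the tot particles and Y uniformly among the remaining
# particles of the compartment (excluding X's partner). Event probabilities
# per micro-iteration:
#   complex (i catalyses j): 2/(tot*(tot-1)) * alpha*beta*max(k_ij, 0)
#   replication of complex c: alpha*gamma * nS * (2/(tot*(tot-2)) + 2/(tot*(tot-1)))
#     (member picked first excludes its partner from the Y draw, a substrate
#      picked first excludes only itself)
#   decay of replicator i: alpha*d/tot  (complexed or not; lone X included)
oracleEventProbs <- function(state) {
  p <- state$params
  reps <- state$replicators
  stopifnot(length(state$substrates) == 1)
  nS <- state$substrates[1]
  tot <- nrow(reps) + nS
  kmax <- if (is.finite(p$k_upper)) p$k_upper else max(0, unlist(reps[protosym:::.k_names]))
  alpha <- computeAlpha(kmax, p$d)
  ab <- alpha / 2
  ag <- alpha / 4
  free <- which(is.na(reps$partner))
  kOf <- function(i, j) { # catalyst i towards template j
    kmat <- matrix(unlist(reps[i, protosym:::.k_names]), 2, 2, byrow = TRUE)
    max(kmat[reps$strand_code[i] + 1, reps$strand_code[j] + 1], 0)
  }
  pComplex <- 0
  if (length(free) >= 2 && tot >= 2) {
    for (i in free) for (j in free) if (i != j)
      pComplex <- pComplex + 2 / (tot * (tot - 1)) * ab * kOf(i, j)
  }
  nComplex <- sum(!is.na(reps$partner)) / 2
  pRepl <- if (nComplex > 0 && nS > 0 && tot > 2)
    nComplex * ag * nS * (2 / (tot * (tot - 2)) + 2 / (tot * (tot - 1)))
  else 0
  pDecay <- nrow(reps) * alpha * p$d / tot
  c(complex = pComplex, replication = pRepl, decay = pDecay)
}

# standard-error based expectation check for a proportion
expect_prop <- function(successes, n, p_expected, n_se = 3.5) {
  se <- sqrt(p_expected * (1 - p_expected) / n)
  expect_lt(abs(successes / n - p_expected), n_se * se + 1e-12)
}

# total particle count of a state
totalParticles <- function(state) nrow(state$replicators) + sum(state$substrates)
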