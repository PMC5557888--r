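#' Construct the initial system state
#'
#' Builds a population of protocells holding replicators and substrates. By
#' default the system starts from functionally indistinguishable strands:
#' every replicator has `kPP = kPM = kMP = kMM = 1`, strands are present in
#' equal numbers, and half of the particles are replicators. Particles are
#' spread over `ceiling(2 N / V)` protocells of roughly `V / 2` particles so
#' the cell count starts near its equilibrium `~ 2 N / V`; the total particle
#' count equals `N` exactly.
#'
#' @param params A [protocellParams()] object.
#' @param frac_replicator Initial fraction of particles that are replicators.
#' @param k_init Either a single number or a length-4 vector
#'   `(kPP, kPM, kMP, kMM)` of initial rates, recycled to every replicator.
#'   Custom grids of starting points are useful for trajectory studies.
#' @return An object of class `protocellState`: a list with elements
#'   `replicators` (one row per molecule: cell, strand, chirality, the four
#'   `k_xy` rates, complex partner and role), `substrates` (per-cell counts),
#'   `params`, `step` and `extinct`.
#' @export
#' @examples
#' s <- initializeSystem(protocellParams(V = 20, N = 200))
#' sum(particleCounts(s)) # == 200
initializeSystem <- function(params, frac_replicator = 0.5, k_init = 1) {
  stopifnot(inherits(params, "protocellParams"))
  if (params$N < params$V) stop("N must be at least V")
  if (length(k_init) == 1) k_init <- rep(k_init, 4)
  if (length(k_init) != 4) stop("k_init must have length 1 or 4")
  if (frac_replicator <= 0 || frac_replicator > 1)
    stop("frac_replicator must lie in (0, 1]")
  ncells <- max(1L, as.integer(ceiling(2 * params$N / params$V)))
  tot <- rep(floor(params$N / ncells), ncells)
  extra <- as.integer(params$N - sum(tot))
  if (extra > 0) tot[seq_len(extra)] <- tot[seq_len(extra)] + 1L
  nrep <- round(frac_replicator * tot)
  cells <- rep(seq_len(ncells), nrep)
  n <- length(cells)
  strand <- integer(n)
  chir <- integer(n)
  # equal P/M within each cell (odd counts alternate the extra strand)
  off <- 0L
  for (c in seq_len(ncells)) {
    idx <- off + seq_len(nrep[c])
    # alternate the leading strand between cells so odd per-cell counts do
    # not bias the global P:M ratio
    lead <- if (c %% 2 == 1L) c(0L, 1L) else c(1L, 0L)
    strand[idx] <- rep_len(lead, nrep[c])
    if (params$variant == "cross_chiral")
      chir[idx] <- rep_len(c(0L, 0L, 1L, 1L), nrep[c])
    off <- off + nrep[c]
  }
  reps <- data.frame(cell = cells, strand_code = strand, chirality_code = chir,
                     kPP = k_init[1], kPM = k_init[2],
                     kMP = k_init[3], kMM = k_init[4],
                     partner = NA_integer_, is_template = FALSE)
  state <- list(replicators = reps,
                substrates = as.integer(tot - nrep),
                params = params, step = 0, extinct = FALSE)
  class(state) <- "protocellState"
  state
}

#' @export
print.protocellState <- function(x, ...) {
  nrep <- nrow(x$replicators)
  np <- sum(x$replicators$strand_code == 0L)
  cat(sprintf("protocell system: %d cells, %d replicators (P %d / M %d), %d substrates, step %g%s\n",
              length(x$substrates), nrep, np, nrep - np,
              sum(x$substrates), x$step,
              if (isTRUE(x$extinct)) " [extinct]" else ""))
  invisible(x)
}

#' Per-cell particle counts
#'
#' @param state A `protocellState`.
#' @return Integer vector: replicators plus substrates per protocell.
#' @export
particleCounts <- function(state) {
  as.integer(tabulate(state$replicators$cell, nbins = length(state$substrates)) +
               state$substrates)
}

#' Replicator table with readable strand labels
#'
#' @param state A `protocellState`.
#' @return The replicator data frame with `strand` and `chirality` as labels.
#' @export
replicators <- function(state) {
  df <- state$replicators
  df$strand <- .strands[df$strand_code + 1L]
  df$chirality <- .chiralities[df$chirality_code + 1L]
  df
}

# attach the integer-coded params used by the compiled core
.cppState <- function(state) {
  state$cparams <- .paramsForCpp(state$params)
  state
}

.fromCppState <- function(state) {
  state$cparams <- NULL
  class(state) <- "protocellState"
  state
}

#' Validate the structural invariants of a system state
#'
#' Checks that complex partner references are mutually consistent, that both
#' members of a complex reside in the same protocell with exactly one of them
#' flagged as template, that counts are non-negative, and (unless the state
#' has been flagged extinct) that the total particle number equals `params$N`.
#'
#' @param state A `protocellState`.
#' @return Invisibly `TRUE`; stops with a message naming the violated
#'   invariant otherwise.
#' @export
validateState <- function(state) {
  reps <- state$replicators
  if (any(state$substrates < 0)) stop("negative substrate count")
  if (nrow(reps) > 0 && (any(reps$cell < 1) || any(reps$cell > length(state$substrates))))
    stop("replicator assigned to a nonexistent cell")
  tot <- nrow(reps) + sum(state$substrates)
  if (!isTRUE(state$extinct) && tot != state$params$N)
    stop(sprintf("particle count %d differs from N = %g", tot, state$params$N))
  comp <- which(!is.na(reps$partner))
  for (i in comp) {
    j <- reps$partner[i]
    if (j < 1 || j > nrow(reps) || is.na(reps$partner[j]) || reps$partner[j] != i)
      stop("complex partner references are not mutually consistent")
    if (reps$cell[i] != reps$cell[j])
      stop("complex members reside in different protocells")
    if (i < j && sum(reps$is_template[c(i, j)]) != 1)
      stop("a complex must have exactly one template member")
  }
  if (any(reps$is_template & is.na(reps$partner)))
    stop("free replicator flagged as template")
  invisible(TRUE)
}

#' Deterministic micro-systems for tests and examples
#'
#' @param name One of `"one_cell_three_reps"` (a single compartment with
#'   three free replicators and substrates), `"two_cells_asym"` (two cells
#'   with different rate profiles), `"gillespie_compartment"` (a well-mixed
#'   single compartment used for comparisons against the exact
#'   continuous-time description) or `"broken_state"` (a symmetry-broken
#'   population: `kPy > 0`, `kMy = 0`).
#' @return A validated `protocellState`.
#' @export
makeFixture <- function(name = c("one_cell_three_reps", "two_cells_asym",
                                 "gillespie_compartment", "broken_state")) {
  name <- match.arg(name)
  mk <- function(params, cell, strand, k, nsub) {
    reps <- data.frame(cell = as.integer(cell), strand_code = as.integer(strand),
                       chirality_code = 0L,
                       kPP = k[, 1], kPM = k[, 2], kMP = k[, 3], kMM = k[, 4],
                       partner = NA_integer_, is_template = FALSE)
    st <- list(replicators = reps, substrates = as.integer(nsub),
               params = params, step = 0, extinct = FALSE)
    class(st) <- "protocellState"
    st
  }
  state <- switch(name,
    one_cell_three_reps = mk(protocellParams(V = 12, N = 8),
                             cell = c(1, 1, 1), strand = c(0, 1, 0),
                             k = matrix(c(1, 1, 1, 1,
                                          0.5, 0.5, 0.5, 0.5,
                                          0.2, 0.8, 0.3, 0.7),
                                        nrow = 3, byrow = TRUE),
                             nsub = 5),
    two_cells_asym = mk(protocellParams(V = 10, N = 16),
                        cell = c(1, 1, 2, 2), strand = c(0, 1, 0, 1),
                        k = matrix(c(1, 1, 1, 1,
                                     1, 1, 1, 1,
                                     0.1, 0.1, 0.1, 0.1,
                                     0.1, 0.1, 0.1, 0.1),
                                   nrow = 4, byrow = TRUE),
                        nsub = c(6, 6)),
    gillespie_compartment = mk(protocellParams(V = 40, N = 12),
                               cell = c(1, 1, 1), strand = c(0, 1, 1),
                               k = matrix(c(0.9, 0.4, 0.2, 0.6,
                                            0.3, 0.8, 0.5, 0.1,
                                            0.7, 0.2, 0.6, 0.4),
                                          nrow = 3, byrow = TRUE),
                               nsub = 9),
    broken_state = mk(protocellParams(V = 10, N = 20),
                      cell = rep(c(1, 2), each = 4),
                      strand = rep(c(0, 0, 0, 1), 2),
                      k = matrix(rep(c(0.3, 0.7, 0, 0), 8),
                                 nrow = 8, byrow = TRUE),
                      nsub = c(6, 6)))
  validateState(state)
  state
}
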