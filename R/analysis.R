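#' Strand asymmetry metrics of a replicator population
#'
#' Computes, from population-mean rates and strand copy numbers:
#' kinetic asymmetry `kappa = (kPM - kPP) / (kPM + kPP)`, copy-number
#' asymmetry `theta = (N_P - N_M) / (N_P + N_M)` and functional asymmetry
#' `a_f = (k_P - k_M) / (k_P + k_M)`, where `k_P`, `k_M` are the per-strand
#' catalytic aggregates (the tied values under kinetic symmetry, otherwise
#' the row means `(kPP + kPM)/2` and `(kMP + kMM)/2`). A metric whose
#' denominator is not positive is flagged undefined (`NA`).
#'
#' @param x A `protocellState`, a replicator data frame (columns
#'   `strand_code`, `kPP`..`kMM`), or a trajectory row with `mean_k*` and
#'   `N_P`/`N_M` columns.
#' @return A list with `kappa`, `theta`, `a_f` and logical flags
#'   `kappa_defined`, `theta_defined`, `a_f_defined`.
#' @export
#' @examples
#' s <- makeFixture("broken_state")
#' asymmetryMetrics(s)$kappa  # (0.7 - 0.3) / (0.7 + 0.3) = 0.4
asymmetryMetrics <- function(x) {
  if (inherits(x, "protocellState")) x <- x$replicators
  if (is.data.frame(x) && all(c("strand_code", .k_names) %in% names(x))) {
    if (nrow(x) == 0) stop("empty replicator population")
    mk <- colMeans(x[.k_names])
    nP <- sum(x$strand_code == 0L)
    nM <- nrow(x) - nP
  } else if (is.data.frame(x) || is.list(x)) {
    mk <- c(kPP = x$mean_kPP, kPM = x$mean_kPM,
            kMP = x$mean_kMP, kMM = x$mean_kMM)
    nP <- x$N_P; nM <- x$N_M
    if (nP + nM == 0) stop("empty replicator population")
  } else stop("unrecognised input")
  ratio <- function(a, b) {
    if (is.na(a + b) || a + b <= 0) list(value = NA_real_, defined = FALSE)
    else list(value = (a - b) / (a + b), defined = TRUE)
  }
  kap <- ratio(mk[["kPM"]], mk[["kPP"]])
  th <- ratio(nP, nM)
  af <- ratio((mk[["kPP"]] + mk[["kPM"]]) / 2, (mk[["kMP"]] + mk[["kMM"]]) / 2)
  list(kappa = kap$value, theta = th$value, a_f = af$value,
       kappa_defined = kap$defined, theta_defined = th$defined,
       a_f_defined = af$defined)
}

#' Variance effective population size of an alternating-strand population
#'
#' For a replicator population whose generations alternate between the two
#' complementary strands with per-strand copy numbers `N_P` and `N_M`, the
#' variance effective population size is the harmonic mean
#' `N_e = 2 / (1/N_P + 1/N_M)`, equivalently
#' `(1 + theta)(1 - theta)(N_P + N_M)/2` with the copy-number asymmetry
#' `theta`. A copy-number bias therefore always decreases `N_e` and increases
#' intracellular genetic drift.
#'
#' @param N_P,N_M Non-negative strand copy numbers (vectorised); not both 0.
#' @return `N_e`; 0 when either count is 0.
#' @export
#' @examples
#' effectivePopulationSize(70, 30)  # 42
effectivePopulationSize <- function(N_P, N_M) {
  if (any(N_P < 0) || any(N_M < 0)) stop("copy numbers must be >= 0")
  if (any(N_P + N_M == 0)) stop("at least one strand must be present")
  ifelse(N_P == 0 | N_M == 0, 0, 2 / (1 / N_P + 1 / N_M))
}

#' Mutational variance of replicator fitness within a protocell
#'
#' First-order decomposition of the within-cell fitness variance generated
#' by mutation: `sigma_f^2 ~ (df/dk_P)^2 sigma_kP^2 + (df/dk_M)^2 sigma_kM^2`
#' with the derivatives evaluated at the per-cell average values. Because the
#' effective rate of a negative `k` is zero, a term is set to exactly 0 when
#' the corresponding mean aggregate is negative (`df/dk = 0` below zero).
#' This quantity drives the rate of molecular-level evolution (Fisher's
#' fundamental theorem), and its collapse as one strand's aggregate reaches
#' zero is what stabilises the functionally broken state.
#'
#' @param cell Replicator data frame of a single protocell (at least 2 rows)
#'   with columns `kPP`..`kMM`, or a data frame with columns `kP`, `kM`.
#' @param gradient Either a numeric length-2 vector `(df/dk_P, df/dk_M)` or a
#'   function `(mean_kP, mean_kM) -> length-2 gradient` (e.g. finite
#'   differences on short-horizon growth pilots, or the analytic gradient of
#'   the minimal model's fitness).
#' @return A list: `sigma2_f`, `term_P`, `term_M`, `gradient`,
#'   `sigma2_kP`, `sigma2_kM`.
#' @export
mutationalVariance <- function(cell, gradient) {
  if (all(c("kPP", "kPM", "kMP", "kMM") %in% names(cell))) {
    kP <- (cell$kPP + cell$kPM) / 2
    kM <- (cell$kMP + cell$kMM) / 2
  } else if (all(c("kP", "kM") %in% names(cell))) {
    kP <- cell$kP; kM <- cell$kM
  } else stop("cell must provide kPP..kMM or kP/kM columns")
  if (length(kP) < 2) stop("degenerate cell: need at least 2 replicators")
  mP <- mean(kP); mM <- mean(kM)
  g <- if (is.function(gradient)) gradient(mP, mM) else gradient
  if (length(g) != 2) stop("gradient must have two components")
  gP <- if (mP < 0) 0 else g[1]
  gM <- if (mM < 0) 0 else g[2]
  termP <- gP^2 * var(kP)
  termM <- gM^2 * var(kM)
  list(sigma2_f = termP + termM, term_P = termP, term_M = termM,
       gradient = c(gP, gM), sigma2_kP = var(kP), sigma2_kM = var(kM))
}

# relabel strands so the less catalytic strand is reported as M
.relabelTraj <- function(traj) {
  kP <- mean(pmax(traj$mean_kPP, 0) + pmax(traj$mean_kPM, 0), na.rm = TRUE)
  kM <- mean(pmax(traj$mean_kMP, 0) + pmax(traj$mean_kMM, 0), na.rm = TRUE)
  if (!is.na(kP) && !is.na(kM) && kM > kP) {
    traj[c("mean_kPP", "mean_kPM", "mean_kMP", "mean_kMM")] <-
      traj[c("mean_kMM", "mean_kMP", "mean_kPM", "mean_kPP")]
    traj[c("sd_kPP", "sd_kPM", "sd_kMP", "sd_kMM")] <-
      traj[c("sd_kMM", "sd_kMP", "sd_kPM", "sd_kPP")]
    traj[c("N_P", "N_M")] <- traj[c("N_M", "N_P")]
  }
  traj
}

#' Equilibrium summary of a trajectory
#'
#' Time-averages of the population-mean rates after a burn-in, with strands
#' relabelled so that the less catalytic strand (the genome-like one, if
#' symmetry broke) is always reported as the minus strand. Exchanging the
#' strand labels P and M maps `kPP <-> kMM` and `kPM <-> kMP`.
#'
#' @param x A `protosymTrajectory` or its trajectory data frame.
#' @param burn_in Steps discarded before averaging.
#' @return A list with `means` and `sds` (named over `kPP`..`kMM`), mean
#'   strand copy numbers, mean cell count, `n_rows` retained and `extinct`.
#' @export
equilibriumSummary <- function(x, burn_in) {
  traj <- if (inherits(x, "protosymTrajectory")) x$trajectory else x
  keep <- traj[traj$step >= burn_in, , drop = FALSE]
  extinct <- nrow(traj) > 0 &&
    (traj$N_P[nrow(traj)] + traj$N_M[nrow(traj)] == 0)
  if (extinct || nrow(keep) == 0)
    return(list(means = setNames(rep(NA_real_, 4), .k_names),
                sds = setNames(rep(NA_real_, 4), .k_names),
                N_P = NA_real_, N_M = NA_real_, n_cells = NA_real_,
                n_rows = nrow(keep), extinct = extinct))
  keep <- .relabelTraj(keep)
  means <- vapply(paste0("mean_", .k_names), function(cn) mean(keep[[cn]]), 0)
  sds <- vapply(paste0("mean_", .k_names), function(cn) sd(keep[[cn]]), 0)
  names(means) <- names(sds) <- .k_names
  list(means = means, sds = sds,
       N_P = mean(keep$N_P), N_M = mean(keep$N_M),
       n_cells = mean(keep$n_cells), n_rows = nrow(keep), extinct = FALSE)
}

#' Classify the evolutionary phase of a run
#'
#' Labels a trajectory `"extinct"` (replicators reached zero), `"broken"`
#' (time-averaged functional asymmetry `|a_f|` exceeds `a_f_threshold` and
#' the minor strand's catalytic aggregate is statistically indistinguishable
#' from zero or below) or `"symmetric"`. With several trajectories from
#' different initial conditions, disagreeing labels (and no observed
#' transition) set the `metastable` flag and the label of the majority is
#' reported.
#'
#' @param x A `protosymTrajectory`, a trajectory data frame, or a list of
#'   either (replicate runs from different initial conditions).
#' @param burn_in Steps discarded before averaging.
#' @param a_f_threshold Functional-asymmetry threshold for the broken label.
#' @param minor_tol Absolute floor below which the minor-strand aggregate
#'   counts as zero regardless of its standard error.
#' @return A list: `label` (`"symmetric"`, `"broken"` or `"extinct"`),
#'   `metastable`, `a_f`, `minor_aggregate`, and per-replicate `labels`.
#' @export
classifyPhase <- function(x, burn_in, a_f_threshold = 0.5, minor_tol = 0.02) {
  single <- function(tr) {
    traj <- if (inherits(tr, "protosymTrajectory")) tr$trajectory else tr
    last <- traj[nrow(traj), ]
    if (last$N_P + last$N_M == 0)
      return(list(label = "extinct", a_f = NA_real_, minor = NA_real_))
    keep <- .relabelTraj(traj[traj$step >= burn_in, , drop = FALSE])
    if (nrow(keep) < 2)
      return(list(label = "inconclusive", a_f = NA_real_, minor = NA_real_))
    kPt <- (keep$mean_kPP + keep$mean_kPM) / 2
    kMt <- (keep$mean_kMP + keep$mean_kMM) / 2
    a_f <- (mean(kPt) - mean(kMt)) / (mean(kPt) + mean(kMt))
    minor <- mean(kMt)
    se <- sd(kMt) / sqrt(nrow(keep))
    minorZero <- minor <= max(minor_tol, 2 * se)
    lab <- if (!is.na(a_f) && abs(a_f) > a_f_threshold && minorZero) "broken"
           else "symmetric"
    list(label = lab, a_f = a_f, minor = minor)
  }
  runs <- if (is.data.frame(x) || inherits(x, "protosymTrajectory")) list(x)
          else x
  res <- lapply(runs, single)
  labels <- vapply(res, `[[`, "", "label")
  if (any(labels == "extinct")) {
    label <- if (all(labels == "extinct")) "extinct"
             else names(sort(table(labels), decreasing = TRUE))[1]
  } else {
    label <- names(sort(table(labels), decreasing = TRUE))[1]
  }
  list(label = label,
       metastable = length(unique(labels[labels != "inconclusive"])) > 1,
       a_f = mean(vapply(res, `[[`, 0, "a_f"), na.rm = TRUE),
       minor_aggregate = mean(vapply(res, `[[`, 0, "minor"), na.rm = TRUE),
       labels = labels)
}

#' Phase scan over mutation rate and cell size
#'
#' Runs replicate simulations on a grid of `(m, V)` values, classifies each
#' run, and returns a tidy table (one row per run). At the onset of symmetry
#' breaking the boundary mutation rate scales as `m* V ~ 1/V` (mutational
#' input per cell against between-cell variation), i.e. `m* ~ V^-2`; see
#' [boundarySlope()].
#'
#' @param m_values,V_values Grid margins.
#' @param steps,stride,burn_in Run length, recording stride, classification
#'   burn-in.
#' @param replicates Replicate runs per grid point.
#' @param params_fn Function `(m, V) -> protocellParams`, by default Table-1
#'   style defaults with `N = 50 V`.
#' @param ... Passed to [classifyPhase()].
#' @return Data frame: `m`, `V`, `replicate`, `label`, `a_f`.
#' @export
phaseScan <- function(m_values, V_values, steps, stride = max(1, steps / 100),
                      burn_in = steps / 2, replicates = 1,
                      params_fn = function(m, V) protocellParams(V = V, m = m),
                      ...) {
  grid <- expand.grid(m = m_values, V = V_values, replicate = seq_len(replicates))
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    run <- runSimulation(params_fn(grid$m[i], grid$V[i]), steps = steps,
                         stride = stride)
    cl <- classifyPhase(run, burn_in = burn_in, ...)
    data.frame(m = grid$m[i], V = grid$V[i], replicate = grid$replicate[i],
               label = cl$label, a_f = cl$a_f)
  })
  do.call(rbind, rows)
}

#' Boundary slope of the symmetric/broken transition
#'
#' From a phase table, estimates for each `V` the boundary mutation rate
#' `m*(V)` as the geometric midpoint between the largest `m` labelled
#' symmetric and the smallest `m` labelled broken, then fits
#' `log(m*) ~ log(V)`. Under the scaling `m* V ~ 1/V` the slope is -2.
#'
#' @param phase_table Data frame as returned by [phaseScan()].
#' @return A list: `slope`, `intercept`, `boundary` (data frame of `V`, `m_star`).
#' @export
boundarySlope <- function(phase_table) {
  bs <- lapply(split(phase_table, phase_table$V), function(d) {
    msym <- d$m[d$label == "symmetric"]
    mbrk <- d$m[d$label == "broken"]
    if (!length(msym) || !length(mbrk)) return(NULL)
    lo <- max(msym[msym < min(mbrk)], na.rm = TRUE)
    if (!is.finite(lo)) return(NULL)
    data.frame(V = d$V[1], m_star = sqrt(lo * min(mbrk)))
  })
  boundary <- do.call(rbind, bs[!vapply(bs, is.null, TRUE)])
  if (is.null(boundary) || nrow(boundary) < 2)
    stop("need boundary points at >= 2 values of V to fit a slope")
  fit <- lm(log(m_star) ~ log(V), data = boundary)
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       boundary = boundary)
}
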