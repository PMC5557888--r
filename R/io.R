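# Configuration, reproducibility plumbing and trajectory/snapshot IO.

.config_defaults <- function() {
  list(V = 1000, N = NULL, m = 0.01, delta = 0.05, d = 0.02, k_upper = 1,
       mutation_method = "additive_free_below_zero", symmetry_mode = "none",
       variant = "two_step", mutate_all = TRUE, split_complex_units = TRUE,
       frac_replicator = 0.5, k_init = 1,
       steps = 1e5, stride = 1e3, seed = 1L, output = NULL)
}

#' Parse and validate a run configuration
#'
#' Reads an optional YAML file, applies overrides (e.g. CLI flags), fills in
#' the standard defaults (`m = 0.01`, `delta = 0.05`, `d = 0.02`,
#' `N = 50 V`, `k_upper = 1`) and validates every field. Unknown keys are an
#' error naming the key.
#'
#' @param file Path to a YAML configuration file, or `NULL`.
#' @param overrides Named list overriding file values.
#' @return A list of class `runConfig`, with a `params` element holding the
#'   validated [protocellParams()].
#' @export
#' @examples
#' cfg <- parseConfig(overrides = list(V = 1000))
#' cfg$params$N  # 50000
parseConfig <- function(file = NULL, overrides = list()) {
  cfg <- .config_defaults()
  if (!is.null(file)) {
    vals <- yaml::read_yaml(file)
    unknown <- setdiff(names(vals), names(cfg))
    if (length(unknown))
      stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
    cfg <- modifyList(cfg, vals)
  }
  unknown <- setdiff(names(overrides), names(cfg))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  cfg <- modifyList(cfg, overrides)
  if (is.null(cfg$N)) cfg$N <- 50 * cfg$V
  cfg$params <- protocellParams(V = cfg$V, N = cfg$N, m = cfg$m,
                                delta = cfg$delta, d = cfg$d,
                                k_upper = cfg$k_upper,
                                mutation_method = cfg$mutation_method,
                                symmetry_mode = cfg$symmetry_mode,
                                variant = cfg$variant,
                                mutate_all = cfg$mutate_all,
                                split_complex_units = cfg$split_complex_units)
  if (cfg$steps < 0) stop("steps must be >= 0")
  if (cfg$stride < 1) stop("stride must be >= 1")
  cfg$seed <- as.integer(cfg$seed)
  class(cfg) <- "runConfig"
  cfg
}

#' Serialise a configuration to YAML
#'
#' Writes the scalar fields of a `runConfig` so that
#' `parseConfig(serialiseConfig(cfg, f))` round-trips.
#'
#' @param cfg A `runConfig`.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
serialiseConfig <- function(cfg, file) {
  keep <- intersect(names(.config_defaults()), names(cfg))
  vals <- cfg[keep]
  vals <- vals[!vapply(vals, is.null, TRUE)]
  yaml::write_yaml(vals, file)
  invisible(file)
}

#' Stable hash of a configuration
#'
#' @param cfg A `runConfig` (or any list).
#' @return A short hash string recorded in output headers.
#' @export
configHash <- function(cfg) {
  keep <- cfg[setdiff(names(cfg), c("params", "output"))]
  digest::digest(keep[order(names(keep))], algo = "md5")
}

#' Write a trajectory table as TSV
#'
#' Emits `#`-prefixed header lines naming the configuration hash and seed,
#' followed by a tab-separated table; two runs with identical config and seed
#' produce byte-identical files.
#'
#' @param traj A trajectory data frame or `protosymTrajectory`.
#' @param path Output path.
#' @param config The `runConfig` (or list) the run used.
#' @param seed The RNG seed the run used.
#' @return `path`, invisibly.
#' @export
writeTrajectory <- function(traj, path, config = list(), seed = NA) {
  if (inherits(traj, "protosymTrajectory")) traj <- traj$trajectory
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# config_hash: %s", configHash(config)), con)
  writeLines(sprintf("# seed: %s", seed), con)
  write.table(format(traj, digits = 15, trim = TRUE, scientific = FALSE),
              con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a trajectory TSV written by [writeTrajectory()]
#'
#' @param path Input path.
#' @return The trajectory data frame; header metadata in attributes
#'   `config_hash` and `seed`.
#' @export
readTrajectory <- function(path) {
  hdr <- readLines(path, n = 2)
  df <- read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  attr(df, "config_hash") <- sub("^# config_hash: ", "", hdr[1])
  attr(df, "seed") <- sub("^# seed: ", "", hdr[2])
  df
}

#' Write a full-state snapshot as JSON
#'
#' @param state A `protocellState`.
#' @param path Output path.
#' @param config,seed Recorded alongside the state.
#' @return `path`, invisibly.
#' @export
writeSnapshot <- function(state, path, config = list(), seed = NA) {
  obj <- list(config_hash = configHash(config), seed = seed,
              step = state$step, extinct = state$extinct,
              params = unclass(state$params),
              substrates = state$substrates,
              replicators = state$replicators)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' Read a snapshot written by [writeSnapshot()]
#'
#' @param path Input path.
#' @return A `protocellState`.
#' @export
readSnapshot <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  p <- obj$params
  params <- protocellParams(V = p$V, N = p$N, m = p$m, delta = p$delta,
                            d = p$d,
                            k_upper = if (is.null(p$k_upper) ||
                                          !is.numeric(p$k_upper)) Inf
                                      else p$k_upper,
                            mutation_method = p$mutation_method,
                            symmetry_mode = p$symmetry_mode,
                            variant = p$variant, mutate_all = p$mutate_all,
                            split_complex_units = p$split_complex_units)
  reps <- as.data.frame(obj$replicators)
  reps$partner <- ifelse(is.na(reps$partner), NA_integer_,
                         as.integer(reps$partner))
  state <- list(replicators = reps, substrates = as.integer(obj$substrates),
                params = params, step = obj$step, extinct = obj$extinct)
  class(state) <- "protocellState"
  state
}
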