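#' Analysis run configuration
#'
#' Bundles every tunable knob of the network pipeline: the random seed, the
#' number of null-model randomizations, the simulated-annealing schedule used
#' to maximize Barber modularity, the quantile that turns pooled null node
#' values into critical role thresholds, and the weighting scheme for the
#' reproduction GLMs.
#'
#' @param random_seed Integer seed driving every stochastic stage. Each stage
#'   draws its own sub-seed from this one, so toggling one stage does not
#'   perturb the random stream of another.
#' @param n_null Number of null-model randomizations (default 100, the
#'   conventional choice for vaznull-based significance testing). Must be
#'   at least 2.
#' @param sa_params Simulated-annealing schedule, a list with elements
#'   `t0` (initial temperature on the modularity scale), `cooling`
#'   (geometric factor applied per sweep), `moves_per_node` (proposed moves
#'   per node per sweep), `max_sweeps`, `patience` (sweeps without
#'   improvement before stopping) and `n_restarts` (independent annealing
#'   runs, best kept). See [optimize_modules()].
#' @param threshold_quantile Quantile of the pooled null node values used as
#'   the critical threshold for participation coefficient and within-module
#'   degree; 0.975 is the upper limit of a central 95% interval.
#' @param weight_scheme Either `"variance"` (prior weights equal to the
#'   per-site response variance, mirroring the field protocol this package
#'   reproduces) or `"inverse_variance"` (the conventional precision
#'   weighting). See [reproduction_models()].
#' @param fast_null If `TRUE`, null-matrix modularity searches run on a
#'   quarter of the annealing budget — a pragmatic speed-up when the 100
#'   null optimizations dominate runtime, at the cost of slightly
#'   under-optimized null partitions (and hence an upward-biased z-score).
#'   Default `FALSE`: nulls use the same schedule as the observed network.
#' @param dmax_unconstrained If `TRUE`, the d' upper bound places a node's
#'   whole marginal total on its single rarest partner instead of capping
#'   each partner at its observed availability. See [dprime()].
#'
#' @return An object of class `run_config` (a validated list).
#' @examples
#' cfg <- run_config(random_seed = 1, n_null = 10)
#' cfg$threshold_quantile
#' @export
run_config <- function(random_seed = 1L,
                       n_null = 100L,
                       sa_params = list(),
                       threshold_quantile = 0.975,
                       weight_scheme = c("variance", "inverse_variance"),
                       fast_null = FALSE,
                       dmax_unconstrained = FALSE) {
  weight_scheme <- match.arg(weight_scheme)
  defaults <- list(t0 = 0.05, cooling = 0.995, moves_per_node = 50,
                   max_sweeps = 1000, patience = 200, n_restarts = 3)
  bad <- setdiff(names(sa_params), names(defaults))
  if (length(bad) > 0) {
    stop("unknown sa_params field(s): ", paste(bad, collapse = ", "))
  }
  sa <- modifyList(defaults, sa_params)
  if (sa$t0 <= 0 || sa$cooling <= 0 || sa$cooling >= 1) {
    stop("sa_params: need t0 > 0 and 0 < cooling < 1")
  }
  n_null <- as.integer(n_null)
  if (is.na(n_null) || n_null < 2) stop("n_null must be an integer >= 2")
  if (!is.numeric(threshold_quantile) || threshold_quantile <= 0 ||
      threshold_quantile >= 1) {
    stop("threshold_quantile must lie strictly between 0 and 1")
  }
  structure(list(
    random_seed = as.integer(random_seed),
    n_null = n_null,
    sa_params = sa,
    threshold_quantile = threshold_quantile,
    weight_scheme = weight_scheme,
    fast_null = isTRUE(fast_null),
    dmax_unconstrained = isTRUE(dmax_unconstrained)
  ), class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat("pollinet run configuration\n")
  cat("  seed:", x$random_seed, " n_null:", x$n_null,
      " threshold quantile:", x$threshold_quantile, "\n")
  cat("  weights:", x$weight_scheme,
      " fast_null:", x$fast_null,
      " dmax_unconstrained:", x$dmax_unconstrained, "\n")
  sa <- x$sa_params
  cat(sprintf("  SA: t0=%g cooling=%g moves/node=%d max_sweeps=%d patience=%d\n",
              sa$t0, sa$cooling, as.integer(sa$moves_per_node),
              as.integer(sa$max_sweeps), as.integer(sa$patience)))
  invisible(x)
}

# Derive independent per-stage sub-seeds from the global seed so that
# adding or removing one stage leaves the others' streams untouched.
# Kept below 2^31 - 1 (R integers are 32-bit).
stage_seed <- function(seed, stage) {
  stopifnot(is.character(stage), length(stage) == 1)
  h <- sum(as.integer(charToRaw(stage)) * seq_along(charToRaw(stage)))
  as.integer((as.numeric(seed) * 48271 + h * 7919) %% 2147483562) + 1L
}

pollinet_log <- function(..., verbose = getOption("pollinet.verbose", TRUE)) {
  if (isTRUE(verbose)) message("[pollinet] ", ...)
  invisible(NULL)
}
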