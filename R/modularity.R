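#' Barber weighted bipartite modularity
#'
#' Evaluates the degree-corrected modularity of a joint partition of sites
#' and species into modules:
#' `Q = (1/F) * sum_ij (A_ij - K_i L_j / F) * delta(m_i, m_j)`,
#' where delta is 1 when site i and species j carry the same module label.
#' Q is 0 for the trivial one-module partition and bounded in \[-0.5, 1\].
#'
#' @param matrix An `incidence_matrix`.
#' @param assignment Named integer/character vector mapping every node id
#'   (all row and all column names) to a module label, or a
#'   `module_partition`.
#' @return Modularity Q (numeric scalar).
#' @examples
#' m <- new_incidence_matrix(rbind(c(2, 0), c(0, 2)))
#' barber_q(m, c(site1 = 1, site2 = 2, sp1 = 1, sp2 = 2))  # 0.5
#' @export
barber_q <- function(matrix, assignment) {
  if (inherits(assignment, "module_partition")) {
    assignment <- assignment$assignment
  }
  ids <- c(rownames(matrix$A), colnames(matrix$A))
  missing_nodes <- setdiff(ids, names(assignment))
  if (length(missing_nodes) > 0) {
    stop("assignment missing node(s): ",
         paste(utils::head(missing_nodes, 5), collapse = ", "))
  }
  rm_ <- as.character(assignment[rownames(matrix$A)])
  cm_ <- as.character(assignment[colnames(matrix$A)])
  B <- matrix$A - outer(matrix$K, matrix$L) / matrix$F
  same <- outer(rm_, cm_, "==")
  sum(B[same]) / matrix$F
}

#' Maximize Barber modularity by simulated annealing
#'
#' Searches the space of joint module assignments with single-node
#' reassignments (to occupied or freshly opened modules) and whole-module
#' merges, accepting uphill moves always and downhill moves with
#' probability `exp(dQ / T)` under a geometric cooling schedule. The
#' best-seen partition is returned; among equal-Q partitions the one with
#' fewer modules is kept, and labels are canonicalized by first appearance
#' over sites then species, so results are reproducible given the seed.
#'
#' This is the same objective the quantitative-bipartite-modules
#' (QuanBiMo-style) algorithm maximizes; only the proposal mechanism
#' differs, and an exhaustive-enumeration cross-check on small matrices
#' guards optimizer quality (see the package tests).
#'
#' @param matrix An `incidence_matrix` with at least 2 nodes per level
#'   (a single-node level yields the one-module partition with a warning).
#' @param config A [run_config()]; `config$sa_params` sets the schedule.
#' @param seed Integer seed; defaults to a modularity-stage seed derived
#'   from `config$random_seed`.
#' @param budget_scale Multiplier on `moves_per_node` and `patience`
#'   (used internally to shrink the budget for null-matrix searches).
#' @return A `module_partition`: list with `assignment` (named integer
#'   vector over all nodes), `level` (named, `"lower"`/`"higher"`), `Q`
#'   (modularity of the returned partition), `Q_anneal` (best-seen Q of
#'   the annealing phase before polishing; `Q >= Q_anneal` always, and
#'   `Q_anneal` never decreases when the sweep budget is extended under
#'   the same seed), `n_modules` and `seed`.
#' @export
optimize_modules <- function(matrix, config = run_config(), seed = NULL,
                             budget_scale = 1) {
  A <- matrix$A
  ids <- c(rownames(A), colnames(A))
  levels_ <- c(rep("lower", nrow(A)), rep("higher", ncol(A)))
  if (nrow(A) < 2 || ncol(A) < 2) {
    warning("degenerate matrix (fewer than 2 nodes on a level): ",
            "returning the single-module partition")
    assignment <- setNames(rep(1L, length(ids)), ids)
    return(structure(list(assignment = assignment,
                          level = setNames(levels_, ids),
                          Q = 0, n_modules = 1L, seed = NA_integer_),
                     class = "module_partition"))
  }
  if (is.null(seed)) seed <- stage_seed(config$random_seed, "modularity")
  sa <- config$sa_params
  mpn <- max(1L, as.integer(round(sa$moves_per_node * budget_scale)))
  pat <- max(5L, as.integer(round(sa$patience * budget_scale)))
  B <- A - outer(matrix$K, matrix$L) / matrix$F
  init <- seq_len(length(ids)) - 1L          # singleton start
  old_seed_state <- get0(".Random.seed", envir = globalenv())
  res <- NULL
  for (r in seq_len(max(1L, as.integer(sa$n_restarts)))) {
    set.seed(stage_seed(seed, paste0("restart", r)))
    cand <- .sa_optimize(B, matrix$F, init, sa$t0, sa$cooling, mpn,
                         as.integer(sa$max_sweeps), pat,
                         stage_seed(seed, paste0("refine", r)))
    if (is.null(res) || cand$Q > res$Q + 1e-12 ||
        (cand$Q > res$Q - 1e-12 && cand$n_modules < res$n_modules)) {
      res <- cand
    }
  }
  if (!is.null(old_seed_state)) assign(".Random.seed", old_seed_state,
                                       envir = globalenv())
  labels <- canonicalize_labels(res$assignment)
  assignment <- setNames(labels, ids)
  structure(list(assignment = assignment,
                 level = setNames(levels_, ids),
                 Q = res$Q,
                 Q_anneal = res$Q_anneal,
                 n_modules = length(unique(labels)),
                 seed = as.integer(seed)),
            class = "module_partition")
}

# Relabel modules 1..M in order of first appearance (rows first, then
# columns), compacting any empty labels.
canonicalize_labels <- function(raw) {
  first <- unique(raw)
  match(raw, first)
}

#' @export
print.module_partition <- function(x, ...) {
  cat(sprintf("module_partition: %d modules, Q = %.4f (seed %s)\n",
              x$n_modules, x$Q, x$seed))
  invisible(x)
}

#' Flatten a module partition to a data frame
#' @param partition A `module_partition`.
#' @return Data frame with `node_id`, `level`, `module`.
#' @export
partition_frame <- function(partition) {
  data.frame(node_id = names(partition$assignment),
             level = as.character(partition$level),
             module = as.integer(partition$assignment),
             stringsAsFactors = FALSE)
}

#' Modularity z-score against a null distribution
#'
#' `z = (Q_obs - mean(Q_null)) / sd(Q_null)` with the sample standard
#' deviation; a z-score above roughly 2 flags a network as significantly
#' more modular than its randomizations.
#'
#' @param q_obs Observed modularity.
#' @param q_null Numeric vector of null modularities (length >= 2 with
#'   nonzero spread).
#' @return List with `z`, `mean_null`, `sd_null`, `n`, and `significant`
#'   (`z > 2`).
#' @examples
#' modularity_zscore(0.6, c(0.2, 0.3, 0.4))$z  # 3
#' @export
modularity_zscore <- function(q_obs, q_null) {
  if (length(q_null) < 2) stop("need at least 2 null modularity values")
  s <- sd(q_null)
  if (!is.finite(s) || s == 0) stop("null modularities have zero spread")
  z <- (q_obs - mean(q_null)) / s
  list(z = z, mean_null = mean(q_null), sd_null = s,
       n = length(q_null), significant = z > 2)
}
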