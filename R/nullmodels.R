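#' One vaznull-style randomization of a weighted bipartite matrix
#'
#' Generates a random matrix with exactly the observed row totals, column
#' totals, grand total and number of nonzero cells (links). Links are first
#' placed by sampling cells with probability proportional to
#' `(K_i/F) * (L_j/F)` under the constraint that every row and column ends
#' up with at least one link: sampling is restricted to cells that cover a
#' still-uncovered row or column until all are covered, after which the
#' remaining links are drawn unconstrained (the run is restarted, up to
#' `max_attempts` times, if coverage would need more cells than there are
#' links). Each chosen link then receives one interaction unit, and the
#' remaining `F - links` units are distributed one at a time among chosen
#' links with the same cell probabilities, skipping placements that would
#' overshoot a row or column total; any units still unplaced when row and
#' column slack fall on disjoint links are settled by weight-shift moves
#' that preserve all marginals and the link set (bounded at `10 * F` moves,
#' else the draw is regenerated).
#'
#' @param matrix An `incidence_matrix`.
#' @param max_attempts Restart bound for the link-placement stage.
#' @return An `incidence_matrix` with the same dimnames as the input.
#' @export
vaznull_one <- function(matrix, max_attempts = 1000) {
  A <- matrix$A
  nr <- nrow(A); nc <- ncol(A)
  K <- matrix$K; L <- matrix$L; Ftot <- matrix$F
  n_links <- sum(A > 0)
  if (n_links < max(nr, nc)) {
    stop("infeasible: fewer links than rows or columns; ",
         "a Patefield-style (r2dtable) null would be required")
  }
  P <- outer(K / Ftot, L / Ftot)
  for (attempt in seq_len(max_attempts)) {
    links <- place_links(P, nr, nc, n_links)
    if (is.null(links)) next
    W <- fill_weights(links, P, K, L, Ftot, nr, nc)
    if (is.null(W)) next
    dimnames(W) <- dimnames(A)
    return(new_incidence_matrix(W))
  }
  stop("vaznull: no feasible randomization in ", max_attempts,
       " attempts; consider a Patefield-style (r2dtable) fallback")
}

# Choose n_links cells (as a logical matrix) covering every row and column,
# sampled proportional to P. Returns NULL when coverage fails.
place_links <- function(P, nr, nc, n_links) {
  chosen <- matrix(FALSE, nr, nc)
  row_cov <- logical(nr); col_cov <- logical(nc)
  placed <- 0L
  p_vec <- as.vector(P)
  # phase 1: cover all rows and columns
  while (!(all(row_cov) && all(col_cov))) {
    if (placed >= n_links) return(NULL)   # out of links before coverage
    cover <- outer(!row_cov, rep(TRUE, nc), "&") |
      outer(rep(TRUE, nr), !col_cov, "&")
    eligible <- which(cover & !chosen)
    if (length(eligible) == 0) return(NULL)
    cell <- if (length(eligible) == 1) eligible else
      sample(eligible, 1, prob = p_vec[eligible])
    chosen[cell] <- TRUE
    placed <- placed + 1L
    i <- (cell - 1L) %% nr + 1L
    j <- (cell - 1L) %/% nr + 1L
    row_cov[i] <- TRUE; col_cov[j] <- TRUE
  }
  # phase 2: remaining links anywhere
  remaining <- n_links - placed
  if (remaining > 0) {
    free <- which(!chosen)
    cells <- if (length(free) == 1) free else
      sample(free, remaining, prob = p_vec[free])
    chosen[cells] <- TRUE
  }
  chosen
}

# Distribute integer weights over the chosen links to match marginals.
fill_weights <- function(chosen, P, K, L, Ftot, nr, nc) {
  W <- matrix(0, nr, nc)
  W[chosen] <- 1
  row_rem <- K - rowSums(W)
  col_rem <- L - colSums(W)
  if (any(row_rem < 0) || any(col_rem < 0)) return(NULL)
  link_idx <- which(chosen)
  li <- (link_idx - 1L) %% nr + 1L
  lj <- (link_idx - 1L) %/% nr + 1L
  p_link <- P[link_idx]
  units <- Ftot - length(link_idx)
  while (units > 0) {
    open <- row_rem[li] > 0 & col_rem[lj] > 0
    if (!any(open)) break
    k <- if (sum(open) == 1) which(open) else
      sample(which(open), 1, prob = p_link[open])
    W[li[k], lj[k]] <- W[li[k], lj[k]] + 1
    row_rem[li[k]] <- row_rem[li[k]] - 1
    col_rem[lj[k]] <- col_rem[lj[k]] - 1
    units <- units - 1
  }
  if (units > 0) {
    W <- repair_marginals(W, row_rem, col_rem, units, Ftot)
    if (is.null(W)) return(NULL)
  }
  W
}

# Remaining row slack and column slack sit on disjoint links. Settle each
# leftover unit with a weight-shift: add 1 at (i, j1), remove 1 at (i2, j1)
# where W[i2, j1] >= 2, add 1 at (i2, j) — net effect +1 on row i and
# column j, all other marginals and the link set unchanged.
repair_marginals <- function(W, row_rem, col_rem, units, Ftot) {
  budget <- 10 * Ftot
  while (units > 0 && budget > 0) {
    i <- which(row_rem > 0)[1]
    j <- which(col_rem > 0)[1]
    if (W[i, j] > 0) {
      W[i, j] <- W[i, j] + 1
    } else {
      done <- FALSE
      j1s <- which(W[i, ] > 0)
      for (j1 in j1s[sample.int(length(j1s))]) {
        i2s <- which(W[, j1] >= 2 & W[, j] > 0)
        if (length(i2s) > 0) {
          i2 <- i2s[sample.int(length(i2s), 1)]
          W[i, j1] <- W[i, j1] + 1
          W[i2, j1] <- W[i2, j1] - 1
          W[i2, j] <- W[i2, j] + 1
          done <- TRUE
          break
        }
      }
      if (!done) { budget <- budget - 1; next }
    }
    row_rem[i] <- row_rem[i] - 1
    col_rem[j] <- col_rem[j] - 1
    units <- units - 1
    budget <- budget - 1
  }
  if (units > 0) NULL else W
}

#' Null distributions of modularity and node-role metrics
#'
#' Draws `config$n_null` vaznull randomizations, optimizes the module
#' partition of each (on a quarter annealing budget when
#' `config$fast_null`), and pools the per-node participation coefficients
#' and within-module degrees per level, alongside the null modularities.
#' Deterministic given `config$random_seed` (each replicate draws its own
#' sub-seed).
#'
#' @param matrix An `incidence_matrix`.
#' @param config A [run_config()].
#' @return List with `Q` (numeric, length `n_null`), `c_lower`, `z_lower`,
#'   `c_higher`, `z_higher` (pooled numeric vectors), and `replicate`
#'   (data frame of per-replicate summaries).
#' @export
null_distributions <- function(matrix, config = run_config()) {
  n_null <- config$n_null
  base_seed <- stage_seed(config$random_seed, "nullmodels")
  budget <- if (config$fast_null) 0.25 else 1
  if (config$fast_null) {
    pollinet_log("null-model modularity searches use a quarter annealing budget")
  }
  Qs <- numeric(n_null)
  c_lo <- list(); z_lo <- list(); c_hi <- list(); z_hi <- list()
  rep_rows <- vector("list", n_null)
  for (r in seq_len(n_null)) {
    rseed <- stage_seed(base_seed, paste0("rep", r))
    set.seed(rseed)
    nm <- vaznull_one(matrix)
    part <- optimize_modules(nm, config, seed = rseed + 1L,
                             budget_scale = budget)
    Qs[r] <- part$Q
    cz_l <- node_cz(nm, part, "lower")
    cz_h <- node_cz(nm, part, "higher")
    c_lo[[r]] <- cz_l$c; z_lo[[r]] <- cz_l$z_wmd
    c_hi[[r]] <- cz_h$c; z_hi[[r]] <- cz_h$z_wmd
    rep_rows[[r]] <- data.frame(
      replicate = r, Q = part$Q, n_modules = part$n_modules,
      c_lower_q = quantile(cz_l$c, config$threshold_quantile, type = 7),
      z_lower_q = quantile(cz_l$z_wmd, config$threshold_quantile, type = 7),
      c_higher_q = quantile(cz_h$c, config$threshold_quantile, type = 7),
      z_higher_q = quantile(cz_h$z_wmd, config$threshold_quantile, type = 7))
  }
  rep_df <- do.call(rbind, rep_rows)
  rownames(rep_df) <- NULL
  list(Q = Qs,
       c_lower = unlist(c_lo), z_lower = unlist(z_lo),
       c_higher = unlist(c_hi), z_higher = unlist(z_hi),
       replicate = rep_df)
}

#' Critical role thresholds from pooled null distributions
#'
#' The critical thresholds for the participation coefficient and the
#' within-module degree are empirical quantiles (type-7 interpolation) of
#' the pooled null node values at each level — by default the 0.975
#' quantile, i.e. the upper limit of a central 95% interval.
#'
#' @param c_null,z_null Pooled null values for one level.
#' @param quantile_p Quantile probability (default 0.975).
#' @param level Level tag stored in the result.
#' @return A `threshold_set`: list with `level`, `c_crit`, `z_crit`,
#'   `quantile`.
#' @export
derive_thresholds <- function(c_null, z_null, quantile_p = 0.975,
                              level = c("lower", "higher")) {
  level <- match.arg(level)
  if (length(c_null) == 0 || length(z_null) == 0) {
    stop("empty null distribution")
  }
  structure(list(level = level,
                 c_crit = unname(quantile(c_null, quantile_p, type = 7)),
                 z_crit = unname(quantile(z_null, quantile_p, type = 7)),
                 quantile = quantile_p),
            class = "threshold_set")
}

#' @export
print.threshold_set <- function(x, ...) {
  cat(sprintf("thresholds (%s level, q = %g): c > %.3f, z > %.3f\n",
              x$level, x$quantile, x$c_crit, x$z_crit))
  invisible(x)
}
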