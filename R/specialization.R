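# Kullback-Leibler contribution of an integer/real allocation `a` against
# availability `q` (both over partners); 0*log(0) := 0.
kl_d <- function(a, q) {
  k <- sum(a)
  if (k <= 0) stop("allocation with zero total")
  p <- a / k
  nz <- p > 0
  sum(p[nz] * log(p[nz] / q[nz]))
}

#' Node specialization index d'
#'
#' Computes the discrimination/specialization index for one node of a
#' weighted bipartite network: the Kullback-Leibler divergence (in nats) of
#' the node's interaction frequencies from overall partner availability,
#' standardized to \[0, 1\] between the minimum and maximum divergence
#' achievable given the node's marginal total. For a site, d' near 0 means
#' the site attracts visitors in proportion to how common they are across
#' the landscape (a generalist site); d' = 1 means its visitors occur
#' nowhere else (a specialist site). Species-level d' is the mirror image
#' (found everywhere vs. found at a single site).
#'
#' The raw divergence for a lower-level node i is
#' `d = sum_j p_ij * ln(p_ij / q_j)` with `p_ij = A_ij / K_i` and
#' `q_j = L_j / F`. The upper bound is the exact maximum of d over all
#' integer reallocations of the node's total K_i across partners, with each
#' partner capped at its observed total L_j (a node cannot be "more
#' specialized" than its partners' availability permits); it is computed by
#' a max-plus dynamic program over partners, since the objective is
#' separable. `dmax_unconstrained = TRUE` removes the cap and places all of
#' K_i on the single rarest partner. The lower bound allocates K_i
#' proportionally to q by largest-remainder integer rounding, which tends
#' to 0 divergence as counts grow.
#'
#' @param matrix An `incidence_matrix`.
#' @param node Node identifier (row or column name) or index.
#' @param level `"lower"` (site, row) or `"higher"` (species, column).
#' @param dmax_unconstrained Remove the availability cap on the upper
#'   bound (default `FALSE`).
#' @return A list of class `specialization_result`: `node_id`, `level`,
#'   `d_raw`, `d_min`, `d_max` (nats) and `d_prime` in \[0, 1\].
#' @examples
#' m <- new_incidence_matrix(rbind(c(3, 1), c(0, 2)))
#' dprime(m, 1, "lower")$d_prime
#' @export
dprime <- function(matrix, node, level = c("lower", "higher"),
                   dmax_unconstrained = FALSE) {
  level <- match.arg(level)
  A <- if (level == "lower") matrix$A else t(matrix$A)
  ids <- rownames(A)
  i <- if (is.character(node)) match(node, ids) else as.integer(node)
  if (is.na(i) || i < 1 || i > nrow(A)) stop("unknown node: ", node)
  a_obs <- A[i, ]
  K <- sum(a_obs)
  if (K <= 0) stop("node ", ids[i], " has zero marginal total")
  L <- colSums(A)
  Ftot <- sum(L)
  q <- L / Ftot
  d_raw <- kl_d(a_obs, q)
  d_min <- kl_d(alloc_proportional(K, q), q)
  d_max <- if (dmax_unconstrained) {
    a <- numeric(length(q)); a[which.min(q)] <- K
    kl_d(a, q)
  } else {
    dmax_constrained(K, q, L)
  }
  d_prime <- if (d_max - d_min > 1e-12) {
    min(1, max(0, (d_raw - d_min) / (d_max - d_min)))
  } else 0
  structure(list(node_id = ids[i], level = level, d_raw = d_raw,
                 d_min = d_min, d_max = d_max, d_prime = d_prime),
            class = "specialization_result")
}

# Largest-remainder integer allocation of total K proportional to q.
# Ties in fractional part broken by index order (deterministic).
alloc_proportional <- function(K, q) {
  target <- K * q / sum(q)
  base <- floor(target)
  rem <- as.integer(round(K - sum(base)))
  a <- base
  if (rem > 0) {
    frac <- target - base
    ord <- order(-frac, seq_along(q))
    a[ord[seq_len(rem)]] <- a[ord[seq_len(rem)]] + 1
  }
  a
}

# Exact maximum of sum_j (a_j/K) ln((a_j/K)/q_j) over integer allocations
# a of K with 0 <= a_j <= L_j, by max-plus DP over partners (the objective
# is separable in a_j; 0 units contribute 0).
dmax_constrained <- function(K, q, L) {
  K <- as.integer(round(K))
  if (sum(pmin(L, K)) < K) {
    stop("cannot allocate node total within partner availabilities")
  }
  V <- c(0, rep(-Inf, K))   # V[r + 1]: best value placing r units so far
  for (j in seq_along(q)) {
    cap <- min(floor(L[j]), K)
    if (cap < 1) next
    a <- seq_len(cap)
    g <- (a / K) * log((a / K) / q[j])
    Vnew <- V
    for (ai in a) {
      idx <- (ai + 1):(K + 1)
      Vnew[idx] <- pmax(Vnew[idx], V[idx - ai] + g[ai])
    }
    V <- Vnew
  }
  V[K + 1]
}

#' d' for every node of one level
#'
#' @inheritParams dprime
#' @return Data frame with one row per node: `node_id`, `level`, `d_raw`,
#'   `d_min`, `d_max`, `d_prime`.
#' @export
dprime_all <- function(matrix, level = c("lower", "higher"),
                       dmax_unconstrained = FALSE) {
  level <- match.arg(level)
  ids <- if (level == "lower") rownames(matrix$A) else colnames(matrix$A)
  res <- lapply(ids, function(id)
    dprime(matrix, id, level, dmax_unconstrained))
  data.frame(
    node_id = ids, level = level,
    d_raw = vapply(res, `[[`, numeric(1), "d_raw"),
    d_min = vapply(res, `[[`, numeric(1), "d_min"),
    d_max = vapply(res, `[[`, numeric(1), "d_max"),
    d_prime = vapply(res, `[[`, numeric(1), "d_prime"),
    stringsAsFactors = FALSE
  )
}

#' Node strength (sum of partner dependencies)
#'
#' The dependency of site i on species j is the fraction of site i's visits
#' contributed by species j, `A_ij / K_i`. A species' strength is the sum of
#' these dependencies over sites, so species strengths sum to the number of
#' sites; the strongest species are the ones the sites depend on most.
#' Site strengths are defined symmetrically over species dependencies.
#'
#' @param matrix An `incidence_matrix`.
#' @param level `"higher"` (species strengths, default) or `"lower"`.
#' @return Data frame with `node_id`, `level`, `strength`.
#' @examples
#' m <- new_incidence_matrix(rbind(c(3, 1), c(0, 2)))
#' node_strength(m)$strength  # 0.75, 1.25
#' @export
node_strength <- function(matrix, level = c("higher", "lower")) {
  level <- match.arg(level)
  A <- matrix$A
  if (level == "higher") {
    dep <- A / matrix$K          # rows sum to 1
    s <- colSums(dep)
    ids <- colnames(A)
  } else {
    dep <- t(t(A) / matrix$L)    # columns sum to 1
    s <- rowSums(dep)
    ids <- rownames(A)
  }
  data.frame(node_id = ids, level = level, strength = as.numeric(s),
             stringsAsFactors = FALSE)
}
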