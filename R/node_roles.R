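# Interaction weight of each node into each module of its partners.
# Returns a nodes x modules matrix for one level.
module_weights <- function(matrix, partition, level) {
  A <- if (level == "lower") matrix$A else t(matrix$A)
  partner_ids <- colnames(A)
  pm <- partition$assignment[partner_ids]
  if (anyNA(pm)) stop("partition missing partner node(s)")
  mods <- sort(unique(as.integer(partition$assignment)))
  W <- sapply(mods, function(m) rowSums(A[, pm == m, drop = FALSE]))
  if (is.null(dim(W))) W <- matrix(W, nrow = nrow(A))
  dimnames(W) <- list(rownames(A), mods)
  W
}

#' Participation coefficient of one node
#'
#' `c = 1 - sum_t (k_it / k_i)^2`, where `k_it` is the node's interaction
#' weight into module t and `k_i` its total weight. c is 0 when all of a
#' node's interactions fall in a single module and approaches `1 - 1/M`
#' when weight is spread evenly over M modules; high-c nodes knit modules
#' together. Weights (not binary degrees) are used, consistent with the
#' weighted modularity partition; `binary = TRUE` reduces to the classic
#' presence/absence form.
#'
#' @param matrix An `incidence_matrix`.
#' @param partition A `module_partition` covering all nodes.
#' @param node Node id (row/column name).
#' @param level `"lower"` (site) or `"higher"` (species).
#' @param binary Use 0/1 links instead of weights.
#' @return Participation coefficient in \[0, 1\].
#' @export
participation_coefficient <- function(matrix, partition, node,
                                      level = c("lower", "higher"),
                                      binary = FALSE) {
  level <- match.arg(level)
  m <- matrix
  if (binary) m <- new_incidence_matrix((m$A > 0) * 1)
  W <- module_weights(m, partition, level)
  if (!node %in% rownames(W)) stop("unknown node: ", node)
  k <- W[node, ]
  tot <- sum(k)
  if (tot <= 0) stop("isolated node: ", node)
  unname(1 - sum((k / tot)^2))
}

#' Within-module degree of one node
#'
#' The node's interaction weight into its own module, standardized by the
#' mean and sample standard deviation of that weight over the same-level
#' nodes sharing the module: `z = (k_is - mean_s) / sd_s`. Modules with a
#' single same-level node, or with zero spread, yield z = 0 so that role
#' classification is total.
#'
#' @inheritParams participation_coefficient
#' @return Standardized within-module degree (numeric scalar).
#' @export
within_module_degree <- function(matrix, partition, node,
                                 level = c("lower", "higher"),
                                 binary = FALSE) {
  level <- match.arg(level)
  cz <- node_cz(matrix, partition, level, binary = binary)
  if (!node %in% cz$node_id) stop("unknown node: ", node)
  cz$z_wmd[match(node, cz$node_id)]
}

# c and z for every node of one level (vectorized; the per-node exported
# functions delegate here).
node_cz <- function(matrix, partition, level, binary = FALSE) {
  m <- matrix
  if (binary) m <- new_incidence_matrix((m$A > 0) * 1)
  W <- module_weights(m, partition, level)
  ids <- rownames(W)
  own <- as.character(partition$assignment[ids])
  k_tot <- rowSums(W)
  if (any(k_tot <= 0)) stop("isolated node(s) present")
  c_val <- 1 - rowSums((W / k_tot)^2)
  k_own <- W[cbind(seq_along(ids), match(own, colnames(W)))]
  z_val <- numeric(length(ids))
  for (mlab in unique(own)) {
    members <- which(own == mlab)
    if (length(members) < 2) { z_val[members] <- 0; next }
    mu <- mean(k_own[members]); s <- sd(k_own[members])
    z_val[members] <- if (is.finite(s) && s > 0)
      (k_own[members] - mu) / s else 0
  }
  data.frame(node_id = ids, level = level, c = unname(c_val),
             z_wmd = z_val, stringsAsFactors = FALSE)
}

#' Classify node roles against critical thresholds
#'
#' Nodes are classified by comparing their participation coefficient c and
#' within-module degree z to null-derived critical thresholds (strict
#' inequalities): both exceeded = network hub; only c = between-module
#' connector; only z = within-module hub; neither = peripheral.
#'
#' @param cz Data frame with columns `node_id`, `c`, `z_wmd` (as returned
#'   by [node_roles()]'s internals or assembled by hand).
#' @param thresholds A `threshold_set` for the matching level.
#' @return `cz` with an added `role` factor column (levels
#'   `peripheral`, `connector`, `module_hub`, `network_hub`).
#' @export
classify_roles <- function(cz, thresholds) {
  high_c <- cz$c > thresholds$c_crit
  high_z <- cz$z_wmd > thresholds$z_crit
  role <- ifelse(high_c & high_z, "network_hub",
          ifelse(high_c, "connector",
          ifelse(high_z, "module_hub", "peripheral")))
  cz$role <- factor(role, levels = c("peripheral", "connector",
                                     "module_hub", "network_hub"))
  cz
}

#' c, z and role for every node of one level
#'
#' @inheritParams participation_coefficient
#' @param thresholds A `threshold_set` for this level (see
#'   [derive_thresholds()]).
#' @return Data frame with `node_id`, `level`, `c`, `z_wmd`, `role`.
#' @export
node_roles <- function(matrix, partition, thresholds,
                       level = c("lower", "higher"), binary = FALSE) {
  level <- match.arg(level)
  if (thresholds$level != level) {
    stop("thresholds were derived for the ", thresholds$level, " level")
  }
  classify_roles(node_cz(matrix, partition, level, binary = binary),
                 thresholds)
}
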