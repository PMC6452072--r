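fixed_partition <- function(m, site_mods, sp_mods) {
  ids <- c(rownames(m$A), colnames(m$A))
  structure(list(
    assignment = setNames(c(site_mods, sp_mods), ids),
    level = setNames(c(rep("lower", nrow(m$A)), rep("higher", ncol(m$A))),
                     ids),
    Q = NA_real_, n_modules = length(unique(c(site_mods, sp_mods))),
    seed = NA_integer_), class = "module_partition")
}

test_that("participation coefficient has its closed forms", {
  # all links in one module -> c = 0
  m <- new_incidence_matrix(matrix(c(2, 3, 4, 1), 2, 2))
  p <- fixed_partition(m, c(1, 1), c(1, 1))
  expect_equal(participation_coefficient(m, p, rownames(m$A)[1], "lower"), 0)

  # equal split over M modules -> 1 - 1/M
  for (M in 2:6) {
    A <- matrix(1, 1 + M, M)        # row 1 is the focal site
    A[-1, ] <- diag(M) * 5
    rownames(A) <- paste0("s", 1:(1 + M)); colnames(A) <- paste0("p", 1:M)
    m <- new_incidence_matrix(A)
    p <- fixed_partition(m, c(1, seq_len(M)), seq_len(M))
    expect_equal(participation_coefficient(m, p, "s1", "lower"), 1 - 1 / M)
  }
})

test_that("within-module degree standardizes against same-level module peers", {
  # three sites in one module with within-module weights 2, 4, 6
  A <- rbind(s1 = c(2, 0), s2 = c(4, 0), s3 = c(6, 0), s4 = c(0, 5),
             s5 = c(0, 3))
  colnames(A) <- c("p1", "p2")
  m <- new_incidence_matrix(A)
  p <- fixed_partition(m, c(1, 1, 1, 2, 2), c(1, 2))
  z <- vapply(c("s1", "s2", "s3"), function(s)
    within_module_degree(m, p, s, "lower"), numeric(1))
  expect_equal(unname(z), c(-1, 0, 1))   # sample sd = 2

  # equal weights -> all zero
  Ae <- rbind(s1 = c(3, 0), s2 = c(3, 0), s3 = c(0, 1))
  colnames(Ae) <- c("p1", "p2")
  me <- new_incidence_matrix(Ae)
  pe <- fixed_partition(me, c(1, 1, 2), c(1, 2))
  expect_equal(within_module_degree(me, pe, "s1", "lower"), 0)
  # singleton module -> defined as zero
  expect_equal(within_module_degree(me, pe, "s3", "lower"), 0)
})

test_that("role classification follows the threshold quadrants strictly", {
  thr <- structure(list(level = "lower", c_crit = 0.60, z_crit = 1.88,
                        quantile = 0.975), class = "threshold_set")
  cz <- data.frame(node_id = c("hub", "conn", "mhub", "peri", "edge"),
                   c = c(0.70, 0.62, 0.10, 0, 0.60),
                   z_wmd = c(2.0, 1.0, 2.5, 0, 1.88))
  out <- classify_roles(cz, thr)
  expect_equal(as.character(out$role),
               c("network_hub", "connector", "module_hub", "peripheral",
                 "peripheral"))  # exact threshold values do not qualify
})

test_that("every node gets exactly one role and c is bounded by 1 - 1/M", {
  set.seed(61)
  m <- random_matrix(6, 9, lambda = 2)
  part <- optimize_modules(m, test_config(seed = 2))
  nd <- null_distributions(m, run_config(
    random_seed = 3, n_null = 3,
    sa_params = list(max_sweeps = 40, patience = 10, n_restarts = 1)))
  thr <- derive_thresholds(nd$c_lower, nd$z_lower, 0.975, "lower")
  roles <- node_roles(m, part, thr, "lower")
  expect_equal(nrow(roles), nrow(m$A))
  expect_false(anyNA(roles$role))
  expect_true(all(roles$c <= 1 - 1 / part$n_modules + 1e-12))
  expect_true(all(roles$c >= 0))
  # c = 0 iff all partners in one module
  W <- sapply(sort(unique(part$assignment)), function(mm)
    rowSums(m$A[, part$assignment[colnames(m$A)] == mm, drop = FALSE]))
  one_mod <- rowSums(W > 0) == 1
  expect_equal(unname(roles$c == 0), unname(one_mod))
})

test_that("weighted c/z reduce to the binary Guimera-Amaral values on 0/1 webs", {
  set.seed(71)
  for (k in 1:5) {
    repeat {
      A <- matrix(rbinom(48, 1, 0.5), 6, 8)
      if (all(rowSums(A) > 0) && all(colSums(A) > 0)) break
    }
    m <- new_incidence_matrix(A)
    A <- m$A   # pick up the generated dimnames
    part <- optimize_modules(m, test_config(seed = k))
    cm <- part$assignment[colnames(m$A)]
    for (i in seq_len(nrow(A))) {
      # direct binary computation: degrees into modules
      deg <- tapply(A[i, ] > 0, cm, sum)
      deg <- deg[!is.na(deg)]
      c_ref <- 1 - sum((deg / sum(deg))^2)
      expect_equal(
        participation_coefficient(m, part, rownames(A)[i], "lower",
                                  binary = TRUE),
        c_ref)
    }
    # binary z: within-module degree standardized over same-level peers
    rm_ <- part$assignment[rownames(m$A)]
    k_own <- vapply(seq_len(nrow(A)), function(i)
      sum(A[i, cm == rm_[i]]), numeric(1))
    for (mm in unique(rm_)) {
      members <- which(rm_ == mm)
      if (length(members) < 2 || sd(k_own[members]) == 0) next
      for (i in members) {
        z_ref <- (k_own[i] - mean(k_own[members])) / sd(k_own[members])
        expect_equal(
          within_module_degree(m, part, rownames(A)[i], "lower",
                               binary = TRUE),
          z_ref)
      }
    }
  }
})
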