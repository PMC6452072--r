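# Shared fixtures and independent oracles used across the suite.

options(pollinet.verbose = FALSE)

# --- small fixed matrices -------------------------------------------------

toy_matrix <- function() {
  # the 2x2 running example: sites s1, s2; species p1, p2
  new_incidence_matrix(matrix(c(3, 0, 1, 2), 2, 2,
                              dimnames = list(c("s1", "s2"), c("p1", "p2"))))
}

block_matrix <- function(w = 2) {
  new_incidence_matrix(matrix(c(w, 0, 0, w), 2, 2,
                              dimnames = list(c("s1", "s2"), c("p1", "p2"))))
}

# random matrix without empty margins
random_matrix <- function(nr, nc, lambda = 1.5) {
  repeat {
    A <- matrix(rpois(nr * nc, lambda), nr, nc)
    if (all(rowSums(A) > 0) && all(colSums(A) > 0)) return(new_incidence_matrix(A))
  }
}

# --- exhaustive partition oracle (Barber Q) -------------------------------

# all set partitions of n items as restricted-growth strings
all_partitions <- function(n) {
  out <- list()
  rec <- function(a, mx) {
    if (length(a) == n) { out[[length(out) + 1]] <<- a; return() }
    for (v in 1:(mx + 1)) rec(c(a, v), max(mx, v))
  }
  rec(integer(0), 0L)
  out
}

exhaustive_best_q <- function(m) {
  ids <- c(rownames(m$A), colnames(m$A))
  max(vapply(all_partitions(length(ids)),
             function(a) barber_q(m, setNames(a, ids)), numeric(1)))
}

# --- brute-force d' allocation oracle -------------------------------------

# all integer allocations of K over columns with caps
all_allocations <- function(K, caps) {
  nc <- length(caps)
  rec <- function(left, j) {
    if (j == nc) {
      if (left <= caps[j]) return(list(left)) else return(list())
    }
    out <- list()
    for (a in 0:min(left, caps[j])) {
      for (rest in rec(left - a, j + 1)) out[[length(out) + 1]] <- c(a, rest)
    }
    out
  }
  rec(K, 1)
}

kl_oracle <- function(a, q) {
  p <- a / sum(a)
  nz <- p > 0
  sum(p[nz] * log(p[nz] / q[nz]))
}

# largest-remainder proportional allocation (restated independently)
prop_alloc_oracle <- function(K, q) {
  target <- K * q
  base <- floor(target)
  rem <- as.integer(round(K - sum(base)))
  if (rem > 0) {
    ord <- order(-(target - base), seq_along(q))
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  }
  base
}

# d' for one row, fully via brute force (exhaustive max + proportional min)
dprime_oracle <- function(m, i) {
  q <- m$L / m$F
  ds <- vapply(all_allocations(m$K[i], m$L), kl_oracle, numeric(1), q = q)
  d_raw <- kl_oracle(m$A[i, ], q)
  d_min <- kl_oracle(prop_alloc_oracle(m$K[i], q), q)
  d_max <- max(ds)
  if (d_max - d_min > 1e-12) {
    min(1, max(0, (d_raw - d_min) / (d_max - d_min)))
  } else 0
}

# --- misc ------------------------------------------------------------------

# fast-ish run configuration for small matrices
test_config <- function(seed = 1, ...) {
  run_config(random_seed = seed,
             sa_params = list(max_sweeps = 200, patience = 40,
                              n_restarts = 2), ...)
}

write_temp_csv <- function(lines) {
  f <- tempfile(fileext = ".csv")
  writeLines(lines, f)
  f
}
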