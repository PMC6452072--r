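test_that("intercept-only quasi-Poisson matches the mean on the log scale", {
  fit <- fit_quasi_glm(y ~ 1, data.frame(y = c(2, 4, 6)), "quasipoisson")
  expect_equal(unname(fit$coefficients), log(4))
  expect_equal(fit$df_resid, 2)
})

test_that("quasi-Poisson point estimates equal Poisson maximum likelihood", {
  set.seed(81)
  d <- data.frame(x = rnorm(30))
  d$y <- rpois(30, exp(0.5 + 0.8 * d$x))
  ours <- fit_quasi_glm(y ~ x, d, "quasipoisson")
  ml <- glm(y ~ x, data = d, family = poisson())
  expect_equal(ours$coefficients, coef(ml), tolerance = 1e-9)
  # dispersion scales the standard errors, not the estimates
  expect_gt(abs(ours$dispersion - 1), 0)
})

test_that("weighted gaussian fits match the closed-form WLS solution", {
  d <- data.frame(x = c(0, 1, 2, 3, 4, 5),
                  y = c(1.1, 2.9, 5.2, 6.8, 9.1, 10.9))
  w <- c(1, 2, 1, 3, 1, 2)
  fit <- fit_quasi_glm(y ~ x, d, "gaussian", weights = w)
  X <- cbind(1, d$x)
  beta <- solve(t(X) %*% (w * X), t(X) %*% (w * d$y))
  expect_equal(unname(fit$coefficients), drop(beta), tolerance = 1e-10)
})

test_that("IRLS matches direct likelihood maximization", {
  set.seed(91)
  d <- data.frame(x = rnorm(25))
  d$y <- rpois(25, exp(0.3 + 0.6 * d$x))
  ours <- fit_quasi_glm(y ~ x, d, "quasipoisson")
  nll <- function(b) sum(exp(b[1] + b[2] * d$x) - d$y * (b[1] + b[2] * d$x))
  opt <- optim(c(0, 0), nll, method = "BFGS",
               control = list(reltol = 1e-14))
  expect_equal(unname(ours$coefficients), opt$par, tolerance = 1e-6)

  db <- data.frame(x = rnorm(40))
  db$y <- rbinom(40, 1, plogis(-0.2 + 1.1 * db$x))
  ourb <- fit_quasi_glm(y ~ x, db, "quasibinomial")
  nllb <- function(b) {
    eta <- b[1] + b[2] * db$x
    -sum(db$y * eta - log1p(exp(eta)))
  }
  optb <- optim(c(0, 0), nllb, method = "BFGS",
                control = list(reltol = 1e-14))
  expect_equal(unname(ourb$coefficients), optb$par, tolerance = 1e-6)
})

test_that("reproduction_models fits the four site-level models", {
  set.seed(101)
  land <- generate_landscape(synthetic_config(seed = 14))
  tr <- land$truth
  metrics <- data.frame(node_id = tr$site_id, c = unname(tr$site_c),
                        d_prime = runif(20))
  repro <- standardize_reproduction(land$plants)
  out <- reproduction_models(metrics, repro, run_config())
  expect_named(out$fits, c("fert_c", "fert_dprime", "seeds_c",
                           "seeds_dprime"))
  expect_equal(out$fits$fert_c$family, "quasibinomial")
  expect_equal(out$fits$seeds_c$family, "quasipoisson")
  expect_equal(nrow(out$directions), 4)
  expect_error(reproduction_models(metrics[1:3, ], repro, run_config()),
               "fewer than 5")
})

test_that("land-use comparisons detect no difference when there is none", {
  d <- data.frame(land_use = rep(c("a", "b", "c"), each = 5),
                  y = rep(7, 15))
  # identical responses: deviance difference exactly 0
  res <- suppressWarnings(landuse_comparisons(d, "y", "quasipoisson"))
  expect_equal(res$F, 0, tolerance = 1e-10)
  expect_error(landuse_comparisons(data.frame(land_use = "a", y = 1), "y",
                                   "gaussian"),
               "at least 2")
})

test_that("gaussian land-use model reproduces group means", {
  set.seed(111)
  d <- data.frame(land_use = rep(c("a", "b", "c"), each = 6),
                  y = rnorm(18, rep(c(1, 3, 5), each = 6)))
  res <- landuse_comparisons(d, "y", "gaussian")
  cf <- res$fit$coefficients
  fitted_means <- c(cf[1], cf[1] + cf[2], cf[1] + cf[3])
  expect_equal(unname(fitted_means), as.numeric(res$group_means),
               tolerance = 1e-10)
  expect_lt(res$p, 0.001)
})

test_that("a suppressed land-use effect is recovered in sign", {
  set.seed(121)
  hits <- 0
  for (r in 1:10) {
    d <- data.frame(land_use = rep(c("forest", "dairy"), each = 8))
    mu <- ifelse(d$land_use == "forest", 10, 20)
    d$y <- rnbinom(16, mu = mu, size = 5)
    res <- landuse_comparisons(d, "y", "quasipoisson")
    # treatment contrast for forest relative to dairy (alphabetical base)
    hits <- hits + (res$fit$coefficients[["land_useforest"]] < 0)
  }
  expect_gte(hits, 9)
})

test_that("distance-similarity regression is exact in its degenerate cases", {
  coords <- data.frame(site_id = c("a", "b", "c"),
                       latitude = c(0, 1, 0), longitude = c(0, 0, 1))
  metrics <- data.frame(node_id = c("a", "b", "c"), c = 0.5, d_prime = 0.2)
  out <- distance_similarity(metrics, coords)
  # identical metric everywhere: slope exactly 0
  expect_equal(unname(out$c$fit$coefficients["dist_km"]), 0)
  # 1 degree of latitude at the equator is 111.19 km under the haversine
  d_ab <- out$c$pairs$dist_km[out$c$pairs$site_a == "a" &
                                out$c$pairs$site_b == "b"]
  expect_equal(d_ab, 111.19, tolerance = 0.01 / 111.19)

  same <- data.frame(site_id = c("a", "b", "c"),
                     latitude = c(5, 5, 6), longitude = c(10, 10, 10))
  out2 <- distance_similarity(metrics, same)
  expect_equal(min(out2$c$pairs$dist_km), 0)

  bad <- coords; bad$latitude[2] <- NA
  expect_error(distance_similarity(metrics, bad), "missing coordinates.*b")
})

test_that("AICc selection ranks a strong predictor first and guards on noise", {
  set.seed(131)
  n <- 20
  d <- data.frame(P1 = rnorm(n), P2 = rnorm(n), P3 = rnorm(n))
  d$y <- 2 * d$P1 + rnorm(n, sd = 0.3)
  tab <- aicc_selection(d, "y", c("P1", "P2", "P3"))
  expect_equal(tab$model[1], "P1")
  expect_false(attr(tab, "best_is_intercept_only"))
  expect_gt(tab$delta_AICc[tab$model == "(intercept only)"], 2)
  expect_true(tab$suitable[1])

  # pure noise: intercept-only must rank first in the majority of draws,
  # and when it does, no other model is suitable
  io_first <- 0
  for (r in 1:20) {
    d$y <- rnorm(n)
    tb <- aicc_selection(d, "y", c("P1", "P2", "P3"))
    if (attr(tb, "best_is_intercept_only")) {
      io_first <- io_first + 1
      expect_false(any(tb$suitable))
    }
  }
  expect_gt(io_first, 10)
})

test_that("AICc converges to AIC for large n", {
  set.seed(141)
  n <- 1e5
  d <- data.frame(x = rnorm(n))
  d$y <- 0.2 * d$x + rnorm(n)
  tab <- aicc_selection(d, "y", "x")
  fit <- glm(y ~ x, data = d, family = gaussian())
  expect_equal(tab$AICc[tab$model == "x"], stats::AIC(fit),
               tolerance = 1e-3 / abs(stats::AIC(fit)))
})
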