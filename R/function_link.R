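#' Fit a (quasi-)likelihood GLM with prior weights
#'
#' Thin, typed front end over [stats::glm()] — i.e. iteratively reweighted
#' least squares with prior weights — for the three families the pipeline
#' uses: quasi-Poisson with log link, quasi-binomial with logit link, and
#' Gaussian with identity link. The dispersion is the Pearson chi-square
#' divided by the residual degrees of freedom; standard errors are scaled
#' by its square root and Wald tests use the t distribution on residual df.
#'
#' @param formula Model formula.
#' @param data Data frame.
#' @param family `"quasipoisson"`, `"quasibinomial"` or `"gaussian"`.
#' @param weights Optional non-negative prior weights (one per row).
#' @param weight_scheme Label recording how the weights were built
#'   (stored in the result, not used in fitting).
#' @return An object of class `glm_fit`: list with `family`,
#'   `coefficients`, `se`, `t_values`, `p_values`, `dispersion`, `n`,
#'   `df_resid`, `weights_used`, and the underlying `glm` object in `fit`.
#' @examples
#' d <- data.frame(y = c(2, 4, 6))
#' fit_quasi_glm(y ~ 1, d, "quasipoisson")$coefficients  # log(4)
#' @export
fit_quasi_glm <- function(formula, data,
                          family = c("quasipoisson", "quasibinomial",
                                     "gaussian"),
                          weights = NULL, weight_scheme = "unit") {
  family <- match.arg(family)
  fam <- switch(family,
                quasipoisson = quasipoisson(link = "log"),
                quasibinomial = quasibinomial(link = "logit"),
                gaussian = gaussian())
  if (is.null(weights)) weights <- rep(1, nrow(data))
  if (any(weights < 0)) stop("negative prior weights")
  if (all(weights == 0)) stop("all prior weights are zero")
  data$.pw <- weights
  fit <- glm(formula, data = data, family = fam, weights = .pw,
             control = list(epsilon = 1e-9, maxit = 100))
  if (!fit$converged) {
    stop("IRLS did not converge in ", fit$iter, " iterations")
  }
  if (family == "quasibinomial" &&
      any(abs(coef(fit)) > 15, na.rm = TRUE)) {
    warning("possible separation: unbounded quasi-binomial coefficient(s)")
  }
  sm <- summary(fit)
  ct <- sm$coefficients
  n <- length(fit$y)
  structure(list(
    family = family,
    coefficients = setNames(ct[, 1], rownames(ct)),
    se = setNames(ct[, 2], rownames(ct)),
    t_values = setNames(ct[, 3], rownames(ct)),
    p_values = setNames(ct[, 4], rownames(ct)),
    dispersion = sm$dispersion,
    n = n,
    df_resid = fit$df.residual,
    weights_used = weight_scheme,
    fit = fit
  ), class = "glm_fit")
}

#' @export
print.glm_fit <- function(x, ...) {
  cat(sprintf("glm_fit (%s, weights: %s, dispersion %.3f)\n",
              x$family, x$weights_used, x$dispersion))
  print(round(cbind(estimate = x$coefficients, se = x$se,
                    t = x$t_values, p = x$p_values), 4))
  invisible(x)
}

glm_fit_row <- function(fit, response, predictor) {
  terms_ <- names(fit$coefficients)
  data.frame(response = response, predictor = predictor,
             family = fit$family, term = terms_,
             estimate = unname(fit$coefficients),
             se = unname(fit$se), t = unname(fit$t_values),
             p = unname(fit$p_values), dispersion = fit$dispersion,
             weight_scheme = fit$weights_used, n = fit$n,
             stringsAsFactors = FALSE)
}

#' Link site network position to sentinel-plant reproduction
#'
#' Fits four GLMs over sites: mean fertilized-pod proportion against the
#' participation coefficient and against d' (quasi-binomial), and mean
#' seeds per pod against the same two metrics (quasi-Poisson). Because the
#' responses are per-site averages, each model is weighted by the per-site
#' variance of the response — masking less of the within-site variation —
#' or by its inverse under `config$weight_scheme = "inverse_variance"`
#' (the conventional precision weighting). Zero variances get the smallest
#' positive weight observed, so no site is silently dropped.
#'
#' @param metrics Data frame of site node metrics with columns `node_id`,
#'   `c`, `d_prime`.
#' @param repro A `site_reproduction` data frame (see
#'   [standardize_reproduction()]).
#' @param config A [run_config()] (only `weight_scheme` is used).
#' @return List with `fits` (named list of `glm_fit`), `table` (one row
#'   per coefficient), and `directions` (sign and p of each slope).
#' @export
reproduction_models <- function(metrics, repro, config = run_config()) {
  d <- merge(metrics, repro, by.x = "node_id", by.y = "site_id")
  if (nrow(d) < 5) stop("fewer than 5 matched sites")
  scheme <- config$weight_scheme
  mk_w <- function(v) {
    w <- v
    if (all(w == 0)) w[] <- 1
    w[w == 0] <- min(w[w > 0])
    if (scheme == "inverse_variance") w <- 1 / w
    w
  }
  specs <- list(
    fert_c = list(f = mean_fert_prop ~ c, fam = "quasibinomial",
                  v = d$var_fert_prop, pred = "c"),
    fert_dprime = list(f = mean_fert_prop ~ d_prime, fam = "quasibinomial",
                       v = d$var_fert_prop, pred = "d_prime"),
    seeds_c = list(f = mean_seeds ~ c, fam = "quasipoisson",
                   v = d$var_seeds, pred = "c"),
    seeds_dprime = list(f = mean_seeds ~ d_prime, fam = "quasipoisson",
                        v = d$var_seeds, pred = "d_prime")
  )
  fits <- lapply(specs, function(s)
    fit_quasi_glm(s$f, d, s$fam, weights = mk_w(s$v), weight_scheme = scheme))
  tab <- do.call(rbind, Map(function(fit, nm, s)
    glm_fit_row(fit, all.vars(s$f)[1], s$pred),
    fits, names(fits), specs))
  rownames(tab) <- NULL
  dirs <- do.call(rbind, Map(function(fit, s) {
    slope <- fit$coefficients[s$pred]
    data.frame(response = all.vars(s$f)[1], predictor = s$pred,
               slope = unname(slope), sign = sign(unname(slope)),
               p = unname(fit$p_values[s$pred]), stringsAsFactors = FALSE)
  }, fits, specs))
  rownames(dirs) <- NULL
  list(fits = fits, table = tab, directions = dirs)
}

#' Compare a response across land-use types
#'
#' Fits `response ~ land_use` with the stated family and reports the
#' overall dispersion-scaled F test against the intercept-only model
#' (deviance difference over between-group df, divided by the estimated
#' dispersion).
#'
#' @param data Data frame containing the response and a `land_use` column.
#' @param response Name of the response column.
#' @param family GLM family as in [fit_quasi_glm()].
#' @param weights Optional prior weights.
#' @param weight_scheme Label for the weights.
#' @return List with `fit` (a `glm_fit`), `F`, `df`, `p`, and
#'   `group_means`.
#' @export
landuse_comparisons <- function(data, response,
                                family = c("quasipoisson", "quasibinomial",
                                           "gaussian"),
                                weights = NULL, weight_scheme = "unit") {
  family <- match.arg(family)
  if (length(unique(data$land_use)) < 2) {
    stop("need at least 2 land-use types")
  }
  data$land_use <- factor(data$land_use)
  f1 <- as.formula(paste(response, "~ land_use"))
  f0 <- as.formula(paste(response, "~ 1"))
  fit1 <- fit_quasi_glm(f1, data, family, weights, weight_scheme)
  fit0 <- fit_quasi_glm(f0, data, family, weights, weight_scheme)
  df1 <- length(levels(data$land_use)) - 1
  df2 <- fit1$df_resid
  dev_diff <- fit0$fit$deviance - fit1$fit$deviance
  if (abs(dev_diff) < 1e-10) {
    Fstat <- 0   # constant response: no between-group signal (0/0 guard)
  } else {
    Fstat <- (dev_diff / df1) / max(fit1$dispersion, 1e-12)
  }
  p <- pf(Fstat, df1, df2, lower.tail = FALSE)
  gm <- tapply(data[[response]], data$land_use, mean)
  list(fit = fit1, F = unname(Fstat), df = c(df1, df2), p = unname(p),
       group_means = gm)
}

#' Pairwise distance vs. node-metric similarity
#'
#' For every unordered pair of sites, computes the great-circle distance
#' (haversine, Earth radius 6371.0088 km) and the absolute difference of a
#' node metric, then regresses difference on distance with an ordinary
#' linear model. A negative slope means nearby sites are *less* similar.
#' Pairs built from n sites are not independent observations; the simple-LM
#' approach is retained deliberately and the result carries a
#' `note` field saying so.
#'
#' @param metrics Data frame with `node_id` and the metric columns.
#' @param coords Data frame with `site_id`, `latitude`, `longitude`.
#' @param metric_cols Character vector of metric column names.
#' @return Named list (one per metric) of lists with `fit` (a `glm_fit`),
#'   `pairs` (the pair table), and `note`.
#' @export
distance_similarity <- function(metrics, coords,
                                metric_cols = c("c", "d_prime")) {
  d <- merge(metrics, coords, by.x = "node_id", by.y = "site_id")
  if (nrow(d) < 3) stop("need at least 3 sites with coordinates")
  miss <- d$node_id[is.na(d$latitude) | is.na(d$longitude)]
  if (length(miss) > 0) {
    stop("missing coordinates for site(s): ", paste(miss, collapse = ", "))
  }
  pr <- t(combn(nrow(d), 2))
  dist_km <- geosphere::distHaversine(
    cbind(d$longitude[pr[, 1]], d$latitude[pr[, 1]]),
    cbind(d$longitude[pr[, 2]], d$latitude[pr[, 2]]),
    r = 6371008.8) / 1000
  out <- lapply(metric_cols, function(mc) {
    diff_m <- abs(d[[mc]][pr[, 1]] - d[[mc]][pr[, 2]])
    pd <- data.frame(site_a = d$node_id[pr[, 1]],
                     site_b = d$node_id[pr[, 2]],
                     dist_km = dist_km, metric_diff = diff_m,
                     stringsAsFactors = FALSE)
    fit <- fit_quasi_glm(metric_diff ~ dist_km, pd, "gaussian")
    list(fit = fit, pairs = pd,
         note = paste("site pairs are non-independent; slope is on the",
                      "absolute-difference (dissimilarity) scale"))
  })
  names(out) <- metric_cols
  out
}

#' AICc model selection over single-predictor candidates
#'
#' Fits an intercept-only Gaussian GLM plus one model per candidate
#' predictor, ranks them by the small-sample-corrected AIC,
#' `AICc = AIC + 2k(k+1)/(n - k - 1)` with k counting the variance
#' parameter, and flags models with delta-AICc below 2 as most
#' explanatory. If the intercept-only model ranks first, no predictor
#' model is considered suitable (`best_is_intercept_only = TRUE`).
#'
#' @param data Data frame.
#' @param response Response column name.
#' @param predictors Character vector of candidate predictor columns.
#' @param delta_threshold Delta-AICc cut for the "most explanatory" flag.
#' @return A `model_selection_table`: data frame with `model`, `k`,
#'   `AICc`, `delta_AICc`, `rank`, `most_explanatory`, `suitable`, and
#'   attribute `best_is_intercept_only`.
#' @export
aicc_selection <- function(data, response, predictors,
                           delta_threshold = 2) {
  n <- nrow(data)
  candidates <- c("(intercept only)" = "1", setNames(predictors, predictors))
  rows <- lapply(names(candidates), function(nm) {
    rhs <- candidates[[nm]]
    f <- as.formula(paste(response, "~", rhs))
    fit <- glm(f, data = data, family = gaussian())
    k <- length(coef(fit)) + 1  # + variance parameter
    if (n - k - 1 <= 0) stop("n - k - 1 <= 0: too few observations for AICc")
    aicc <- stats::AIC(fit) + 2 * k * (k + 1) / (n - k - 1)
    data.frame(model = nm, k = k, AICc = aicc, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$AICc, tab$k), , drop = FALSE]
  tab$delta_AICc <- tab$AICc - tab$AICc[1]
  tab$rank <- seq_len(nrow(tab))
  best_io <- tab$model[1] == "(intercept only)"
  tab$most_explanatory <- tab$delta_AICc < delta_threshold
  tab$suitable <- tab$most_explanatory & !best_io &
    tab$model != "(intercept only)"
  rownames(tab) <- NULL
  attr(tab, "best_is_intercept_only") <- best_io
  class(tab) <- c("model_selection_table", "data.frame")
  tab
}
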