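#' Simulate a landscape and write its input files
#'
#' Writes `visitation.csv`, `plants.csv` (per-pod seed counts joined with
#' semicolons) and `truth.json` to `out_dir`, in exactly the schemas
#' [read_visitation()] and [read_plants()] read back.
#'
#' @param out_dir Output directory (created if absent).
#' @param config A [synthetic_config()]; default [paper_shaped_preset()].
#' @param seed Optional integer overriding `config$seed`.
#' @return Invisibly, a named character vector of written paths.
#' @export
cmd_simulate <- function(out_dir, config = paper_shaped_preset(),
                         seed = NULL) {
  if (!is.null(seed)) config$seed <- as.integer(seed)
  land <- generate_landscape(config)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  paths <- c(visitation = file.path(out_dir, "visitation.csv"),
             plants = file.path(out_dir, "plants.csv"),
             truth = file.path(out_dir, "truth.json"))
  v <- as.data.frame(land$visitation)
  write.csv(v, paths[["visitation"]], row.names = FALSE,
            fileEncoding = "UTF-8")
  p <- as.data.frame(land$plants)
  p$seeds <- vapply(p$seeds, function(s) paste(s, collapse = ";"),
                    character(1))
  write.csv(p, paths[["plants"]], row.names = FALSE, fileEncoding = "UTF-8")
  tr <- land$truth
  tr$partition <- list(assignment = as.list(tr$partition$assignment),
                       Q = tr$partition$Q,
                       n_modules = tr$partition$n_modules)
  jsonlite::write_json(tr, paths[["truth"]], auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  pollinet_log("simulated landscape written to ", out_dir)
  invisible(paths)
}

# Per-site pollinator-community predictors from a visitation table.
community_predictors <- function(visitation) {
  agg <- function(sel) {
    v <- tapply(visitation$visits[sel], visitation$site_id[sel], sum)
    v
  }
  sites <- sort(unique(visitation$site_id))
  take <- function(v) { out <- setNames(numeric(length(sites)), sites)
    out[names(v)] <- v; out }
  rich <- tapply(visitation$species_id, visitation$site_id,
                 function(s) length(unique(s)))
  data.frame(
    site_id = sites,
    total_visits = take(agg(rep(TRUE, nrow(visitation)))),
    richness = take(rich),
    hym_visits = take(agg(visitation$order_name == "Hymenoptera")),
    syrphid_visits = take(agg(visitation$family_name %in% "Syrphidae")),
    other_dipt_visits = take(agg(visitation$order_name == "Diptera" &
                                   !visitation$family_name %in% "Syrphidae")),
    col_visits = take(agg(visitation$order_name == "Coleoptera")),
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Run the full network-to-function analysis pipeline
#'
#' Orchestrates: matrix construction, d' and node strength, modularity
#' optimization, vaznull null distributions and the modularity z-score,
#' null-derived role thresholds and node roles, reproduction GLMs,
#' land-use comparisons, pairwise distance-similarity regressions, and
#' AICc selection of pollinator-community predictors for each site node
#' metric. All outputs are written to `out_dir` (see [write_outputs()]).
#'
#' @param visitation_path,plants_path Input CSV paths (see
#'   [read_visitation()], [read_plants()]).
#' @param out_dir Output directory.
#' @param config A [run_config()].
#' @return A `pipeline_result`: list with `paths`, `summary` (seed, Q,
#'   z-score, thresholds, role counts), `matrix`, `partition`, `metrics`,
#'   `thresholds`, `models`, `aicc`, `distance`, and `null` distributions.
#' @export
cmd_analyze <- function(visitation_path, plants_path, out_dir,
                        config = run_config()) {
  stage <- function(name, expr) {
    pollinet_log("stage: ", name)
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }
  visitation <- stage("read", {
    v <- read_visitation(visitation_path)
    p <- read_plants(plants_path)
    list(v = v, p = p)
  })
  plants <- visitation$p; visitation <- visitation$v

  mat <- stage("build_matrix", build_matrix(visitation))
  spec <- stage("specialization", {
    rbind(dprime_all(mat, "lower", config$dmax_unconstrained),
          dprime_all(mat, "higher", config$dmax_unconstrained))
  })
  stren <- stage("node_strength", {
    rbind(node_strength(mat, "lower"), node_strength(mat, "higher"))
  })
  part <- stage("modularity", optimize_modules(mat, config))
  nulls <- stage("null_models", null_distributions(mat, config))
  zres <- stage("zscore", modularity_zscore(part$Q, nulls$Q))
  thr_lower <- derive_thresholds(nulls$c_lower, nulls$z_lower,
                                 config$threshold_quantile, "lower")
  thr_higher <- derive_thresholds(nulls$c_higher, nulls$z_higher,
                                  config$threshold_quantile, "higher")
  roles <- stage("node_roles", {
    rbind(node_roles(mat, part, thr_lower, "lower"),
          node_roles(mat, part, thr_higher, "higher"))
  })
  metrics <- merge(merge(spec, stren, by = c("node_id", "level")),
                   roles, by = c("node_id", "level"))
  metrics <- metrics[order(metrics$level, metrics$node_id), ]
  rownames(metrics) <- NULL

  repro <- stage("reproduction", standardize_reproduction(plants))
  site_metrics <- metrics[metrics$level == "lower", ]
  repro_mod <- stage("reproduction_models",
                     reproduction_models(site_metrics, repro, config))

  coords <- unique(as.data.frame(visitation)[, c("site_id", "land_use",
                                                 "latitude", "longitude")])
  lu_df <- merge(merge(site_metrics, repro, by.x = "node_id",
                       by.y = "site_id"),
                 merge(coords, community_predictors(visitation),
                       by = "site_id"),
                 by.x = "node_id", by.y = "site_id")
  lu <- stage("landuse_comparisons", {
    list(
      richness = landuse_comparisons(lu_df, "richness", "quasipoisson"),
      total_visits = landuse_comparisons(lu_df, "total_visits",
                                         "quasipoisson"),
      fert_prop = landuse_comparisons(lu_df, "mean_fert_prop",
                                      "quasibinomial",
                                      weights = pmax(lu_df$var_fert_prop,
                                                     1e-8),
                                      weight_scheme = "variance"),
      seeds = landuse_comparisons(lu_df, "mean_seeds", "quasipoisson",
                                  weights = pmax(lu_df$var_seeds, 1e-8),
                                  weight_scheme = "variance"),
      c = landuse_comparisons(lu_df, "c", "gaussian"),
      d_prime = landuse_comparisons(lu_df, "d_prime", "gaussian"))
  })
  dist_mod <- stage("distance_similarity",
                    distance_similarity(site_metrics, coords))
  aicc <- stage("aicc_selection", {
    preds <- c("total_visits", "richness", "hym_visits", "syrphid_visits",
               "other_dipt_visits", "col_visits")
    list(c = aicc_selection(lu_df, "c", preds),
         d_prime = aicc_selection(lu_df, "d_prime", preds))
  })

  models_tab <- rbind(
    cbind(model_type = "reproduction", repro_mod$table),
    do.call(rbind, lapply(names(lu), function(nm)
      cbind(model_type = paste0("landuse_", nm),
            glm_fit_row(lu[[nm]]$fit, nm, "land_use")))),
    do.call(rbind, lapply(names(dist_mod), function(nm)
      cbind(model_type = paste0("distance_", nm),
            glm_fit_row(dist_mod[[nm]]$fit, nm, "dist_km")))))
  rownames(models_tab) <- NULL

  role_counts <- table(metrics$level, metrics$role)
  summary_list <- list(
    seed = config$random_seed,
    n_sites = nrow(mat$A), n_species = ncol(mat$A),
    total_visits = mat$F,
    Q = part$Q, n_modules = part$n_modules,
    z_score = zres$z, null_mean_Q = zres$mean_null,
    null_sd_Q = zres$sd_null, n_null = config$n_null,
    significant_modularity = zres$significant,
    thresholds = list(
      lower = list(c_crit = thr_lower$c_crit, z_crit = thr_lower$z_crit),
      higher = list(c_crit = thr_higher$c_crit, z_crit = thr_higher$z_crit),
      quantile = config$threshold_quantile),
    role_counts = lapply(rownames(role_counts), function(l)
      as.list(role_counts[l, ])) |> setNames(rownames(role_counts)),
    weight_scheme = config$weight_scheme,
    fast_null = config$fast_null,
    landuse_F = lapply(lu, function(x) list(F = x$F, p = x$p)),
    strongest_species = stren$node_id[stren$level == "higher"][
      which.max(stren$strength[stren$level == "higher"])],
    max_species_strength = max(stren$strength[stren$level == "higher"]))

  null_summary <- nulls$replicate
  paths <- stage("write_outputs",
                 write_outputs(metrics, part, null_summary, models_tab,
                               summary_list, out_dir))
  aicc_path <- file.path(out_dir, "aicc.csv")
  aicc_tab <- rbind(cbind(metric = "c", as.data.frame(aicc$c)),
                    cbind(metric = "d_prime", as.data.frame(aicc$d_prime)))
  write.csv(aicc_tab, aicc_path, row.names = FALSE)
  paths <- c(paths, aicc = aicc_path)

  structure(list(paths = paths, summary = summary_list, matrix = mat,
                 partition = part, metrics = metrics,
                 thresholds = list(lower = thr_lower, higher = thr_higher),
                 reproduction = repro_mod, landuse = lu, distance = dist_mod,
                 aicc = aicc, null = nulls),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  s <- x$summary
  cat("pollinet pipeline result\n")
  cat(sprintf("  %d sites x %d species, %g total visits\n",
              s$n_sites, s$n_species, s$total_visits))
  cat(sprintf("  Q = %.3f (%d modules), z = %.2f vs %d nulls%s\n",
              s$Q, s$n_modules, s$z_score, s$n_null,
              if (isTRUE(s$significant_modularity)) " *" else ""))
  cat(sprintf("  thresholds: sites c > %.2f, z > %.2f; species c > %.2f, z > %.2f\n",
              s$thresholds$lower$c_crit, s$thresholds$lower$z_crit,
              s$thresholds$higher$c_crit, s$thresholds$higher$z_crit))
  cat(sprintf("  strongest species: %s (strength %.2f)\n",
              s$strongest_species, s$max_species_strength))
  invisible(x)
}
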