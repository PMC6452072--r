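#' Read a flower-visitation table
#'
#' Reads long-format visitation records: one row per site x visitor-species
#' combination with a visit count, plus the site's land-use label and
#' coordinates. Duplicate (site, species) rows — e.g. separate observation
#' rotations — are summed into a single record, since the analysis operates
#' on one aggregate landscape network.
#'
#' @param path Path to a delimited text file with a header row. Required
#'   columns: `site_id`, `land_use`, `latitude`, `longitude`, `species_id`,
#'   `order_name`, `visits`; `family_name` is optional.
#' @param dialect `"csv"` (comma, default) or `"tsv"` (tab).
#' @return A `data.frame` of class `visitation_table`, one row per
#'   (site, species) with aggregated visits.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c(
#'   "site_id,land_use,latitude,longitude,species_id,order_name,family_name,visits",
#'   "s1,forest,-17.3,145.5,spA,Diptera,Syrphidae,2",
#'   "s1,forest,-17.3,145.5,spA,Diptera,Syrphidae,3"), f)
#' read_visitation(f)$visits  # rotations summed: 5
#' @seealso [build_matrix()], [read_plants()]
#' @export
read_visitation <- function(path, dialect = c("csv", "tsv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (dialect == "csv") "," else "\t"
  df <- read.csv(path, sep = sep, stringsAsFactors = FALSE,
                 fileEncoding = "UTF-8")
  required <- c("site_id", "land_use", "latitude", "longitude",
                "species_id", "order_name", "visits")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("visitation schema error: missing column(s) ",
         paste(missing_cols, collapse = ", "))
  }
  if (!"family_name" %in% names(df)) df$family_name <- NA_character_
  as_visitation_table(df)
}

#' Validate and aggregate a visitation data frame
#'
#' @param df Data frame with the visitation schema (see [read_visitation()]).
#' @return A validated `visitation_table`.
#' @export
as_visitation_table <- function(df) {
  if (!is.numeric(df$visits)) {
    df$visits <- suppressWarnings(as.numeric(df$visits))
  }
  bad <- which(is.na(df$visits) | df$visits < 0 |
                 df$visits != round(df$visits))
  if (length(bad) > 0) {
    stop("visitation validation error: non-negative integer `visits` ",
         "required; offending row(s): ", paste(bad, collapse = ", "))
  }
  # one land use / coordinate pair per site
  meta <- unique(df[, c("site_id", "land_use", "latitude", "longitude")])
  if (anyDuplicated(meta$site_id)) {
    dup <- meta$site_id[duplicated(meta$site_id)]
    stop("site(s) with inconsistent land_use/coordinates: ",
         paste(unique(dup), collapse = ", "))
  }
  key <- interaction(df$site_id, df$species_id, drop = TRUE)
  if (anyDuplicated(key)) {
    pollinet_log("summing ", sum(duplicated(key)),
                 " duplicate (site, species) row(s)")
    visits <- tapply(df$visits, key, sum)
    first <- df[!duplicated(key), , drop = FALSE]
    first$visits <- as.numeric(visits[as.character(
      interaction(first$site_id, first$species_id, drop = TRUE))])
    df <- first
  }
  df <- df[order(df$site_id, df$species_id), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("visitation_table", "data.frame")
  df
}

#' Read per-plant reproduction records
#'
#' One row per sentinel plant: counts of inflorescences, unfertilized
#' flowers and fertilized pods, and the per-pod seed counts joined with
#' semicolons in the `seeds` column.
#'
#' @inheritParams read_visitation
#' @return A `data.frame` of class `plant_table` whose `seeds` column is a
#'   list of integer vectors (one count per pod).
#' @export
read_plants <- function(path, dialect = c("csv", "tsv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (dialect == "csv") "," else "\t"
  df <- read.csv(path, sep = sep, stringsAsFactors = FALSE,
                 fileEncoding = "UTF-8", colClasses = c(seeds = "character"))
  required <- c("site_id", "plant_id", "n_inflorescences",
                "n_unfertilized_flowers", "n_pods", "seeds")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("plant schema error: missing column(s) ",
         paste(missing_cols, collapse = ", "))
  }
  df$seeds <- lapply(df$seeds, function(s) {
    if (is.na(s) || !nzchar(s)) return(integer(0))
    as.integer(strsplit(s, ";", fixed = TRUE)[[1]])
  })
  as_plant_table(df)
}

#' Validate a plant data frame
#' @param df Data frame with the plant schema; `seeds` must be a list of
#'   integer vectors, one element per pod.
#' @return A validated `plant_table`.
#' @export
as_plant_table <- function(df) {
  counts <- c("n_inflorescences", "n_unfertilized_flowers", "n_pods")
  for (cc in counts) {
    if (any(is.na(df[[cc]]) | df[[cc]] < 0)) {
      stop("plant validation error: negative or missing ", cc)
    }
  }
  n_seed <- vapply(df$seeds, length, integer(1))
  bad <- which(n_seed != df$n_pods)
  if (length(bad) > 0) {
    stop("plant validation error: seeds list length != n_pods at row(s) ",
         paste(bad, collapse = ", "))
  }
  if (any(unlist(df$seeds) < 0)) stop("plant validation error: negative seed count")
  class(df) <- c("plant_table", "data.frame")
  df
}

#' Build the weighted site x species incidence matrix
#'
#' Constructs the weighted bipartite network: rows are sites (lower level),
#' columns are flower-visitor species (higher level), entries are total
#' visits. Rows or columns whose marginal total is zero are dropped with a
#' message — the specialization index and the null models are undefined for
#' empty margins.
#'
#' @param table A `visitation_table` (or a data frame with columns
#'   `site_id`, `species_id`, `visits`).
#' @return An object of class `incidence_matrix`: a list with the weight
#'   matrix `A` (dimnames = site/species ids), row totals `K`, column totals
#'   `L`, and grand total `F`.
#' @examples
#' tab <- data.frame(site_id = c("s1", "s1", "s2"),
#'                   species_id = c("p1", "p2", "p2"),
#'                   visits = c(3, 1, 2))
#' m <- build_matrix(tab)
#' m$A
#' m$F  # 6
#' @export
build_matrix <- function(table) {
  if (NROW(table) == 0) stop("cannot build a matrix from an empty table")
  sites <- sort(unique(as.character(table$site_id)))
  species <- sort(unique(as.character(table$species_id)))
  A <- matrix(0, length(sites), length(species),
              dimnames = list(sites, species))
  idx <- cbind(match(as.character(table$site_id), sites),
               match(as.character(table$species_id), species))
  for (r in seq_len(nrow(table))) {
    A[idx[r, 1], idx[r, 2]] <- A[idx[r, 1], idx[r, 2]] + table$visits[r]
  }
  zr <- rowSums(A) == 0
  zc <- colSums(A) == 0
  if (any(zr)) pollinet_log("dropping ", sum(zr), " all-zero site row(s): ",
                            paste(sites[zr], collapse = ", "))
  if (any(zc)) pollinet_log("dropping ", sum(zc), " all-zero species column(s): ",
                            paste(species[zc], collapse = ", "))
  A <- A[!zr, !zc, drop = FALSE]
  if (nrow(A) == 0 || ncol(A) == 0) stop("matrix empty after dropping zero margins")
  new_incidence_matrix(A)
}

#' Wrap a plain weight matrix as an incidence matrix
#'
#' @param A Non-negative numeric matrix, rows = sites, columns = species.
#'   Dimnames are used as node identifiers (defaults are generated).
#' @return An `incidence_matrix`.
#' @export
new_incidence_matrix <- function(A) {
  A <- as.matrix(A)
  if (any(A < 0)) stop("negative weights are not allowed")
  if (is.null(rownames(A))) rownames(A) <- paste0("site", seq_len(nrow(A)))
  if (is.null(colnames(A))) colnames(A) <- paste0("sp", seq_len(ncol(A)))
  K <- rowSums(A)
  L <- colSums(A)
  structure(list(A = A, K = K, L = L, F = sum(A)), class = "incidence_matrix")
}

#' @export
print.incidence_matrix <- function(x, ...) {
  cat(sprintf("incidence_matrix: %d sites x %d species, total weight %g\n",
              nrow(x$A), ncol(x$A), x$F))
  invisible(x)
}

#' @export
as.matrix.incidence_matrix <- function(x, ...) x$A

#' Standardize plant reproduction per site
#'
#' For each plant, reproductive success is standardized for the number of
#' open flowers: `fert_prop = n_pods / (n_unfertilized_flowers + n_pods)`.
#' Per site this returns the mean and sample (n-1) variance of plant-level
#' fertilized-pod proportions, and the mean and variance of seeds per pod.
#' Seed variance is computed over the pooled per-pod counts by default;
#' plant-level means are also summarized (columns `mean_seeds_plant`,
#' `var_seeds_plant`) for sensitivity checks.
#'
#' Plants with no flowers at all (`n_unfertilized_flowers + n_pods == 0`)
#' carry no information about fertilization success and are excluded with a
#' message, as are sites left with zero valid plants.
#'
#' @param plants A `plant_table` (see [read_plants()]).
#' @return A `data.frame` of class `site_reproduction` with one row per
#'   site: `site_id`, `mean_fert_prop`, `var_fert_prop`, `mean_seeds`,
#'   `var_seeds`, `mean_seeds_plant`, `var_seeds_plant`, `n_plants`.
#' @examples
#' pl <- data.frame(site_id = "s1", plant_id = c("a", "b"),
#'                  n_inflorescences = 1, n_unfertilized_flowers = c(6, 4),
#'                  n_pods = c(4, 6))
#' pl$seeds <- list(c(10, 12, 9, 11), c(8, 9, 10, 12, 11, 9))
#' standardize_reproduction(as_plant_table(pl))
#' @export
standardize_reproduction <- function(plants) {
  tot <- plants$n_unfertilized_flowers + plants$n_pods
  drop <- tot == 0
  if (any(drop)) {
    pollinet_log("excluding ", sum(drop), " plant(s) with no flowers")
    plants <- plants[!drop, , drop = FALSE]
  }
  if (nrow(plants) == 0) stop("no valid plants remain")
  plants$fert_prop <- plants$n_pods /
    (plants$n_unfertilized_flowers + plants$n_pods)
  out <- do.call(rbind, lapply(split(seq_len(nrow(plants)), plants$site_id),
    function(ix) {
      p <- plants[ix, , drop = FALSE]
      pooled <- unlist(p$seeds)
      per_plant <- vapply(p$seeds, function(s)
        if (length(s) > 0) mean(s) else NA_real_, numeric(1))
      data.frame(
        site_id = p$site_id[1],
        mean_fert_prop = mean(p$fert_prop),
        var_fert_prop = if (nrow(p) > 1) var(p$fert_prop) else 0,
        mean_seeds = if (length(pooled) > 0) mean(pooled) else 0,
        var_seeds = if (length(pooled) > 1) var(pooled) else 0,
        mean_seeds_plant = mean(per_plant, na.rm = TRUE),
        var_seeds_plant = if (sum(!is.na(per_plant)) > 1)
          var(per_plant, na.rm = TRUE) else 0,
        n_plants = nrow(p),
        stringsAsFactors = FALSE
      )
    }))
  rownames(out) <- NULL
  out$mean_seeds_plant[is.nan(out$mean_seeds_plant)] <- 0
  class(out) <- c("site_reproduction", "data.frame")
  out
}

#' Write pipeline outputs as delimited text plus a run summary
#'
#' Writes `node_metrics.csv`, `partition.csv`, `null_summary.csv`,
#' `models.csv` and a machine-readable `run_summary.json`. Numeric values
#' are written with 15 significant digits so that re-reading reproduces
#' integers bit-exactly and reals to at least 12 significant digits.
#'
#' @param metrics Node metrics data frame (see [node_metrics()]).
#' @param partition A `module_partition`.
#' @param null_summary Data frame of per-replicate null summaries.
#' @param models Data frame of fitted-model rows.
#' @param summary_list Named list written as the JSON run summary (seed, Q,
#'   z-score, thresholds, ...).
#' @param out_dir Output directory, created if absent.
#' @return Invisibly, the named character vector of written paths.
#' @export
write_outputs <- function(metrics, partition, null_summary, models,
                          summary_list, out_dir) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", out_dir)
  }
  paths <- c(
    node_metrics = file.path(out_dir, "node_metrics.csv"),
    partition = file.path(out_dir, "partition.csv"),
    null_summary = file.path(out_dir, "null_summary.csv"),
    models = file.path(out_dir, "models.csv"),
    run_summary = file.path(out_dir, "run_summary.json")
  )
  write_csv15 <- function(df, path) {
    df <- as.data.frame(df)
    for (nm in names(df)) {
      if (is.numeric(df[[nm]]) && !is.integer(df[[nm]])) {
        df[[nm]] <- vapply(df[[nm]], function(v)
          format(v, digits = 15, scientific = FALSE, trim = TRUE), character(1))
      }
    }
    write.csv(df, path, row.names = FALSE, quote = TRUE, fileEncoding = "UTF-8")
  }
  write_csv15(metrics, paths[["node_metrics"]])
  write_csv15(partition_frame(partition), paths[["partition"]])
  write_csv15(null_summary, paths[["null_summary"]])
  write_csv15(models, paths[["models"]])
  jsonlite::write_json(summary_list, paths[["run_summary"]],
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(paths)
}
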