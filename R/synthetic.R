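#' Configuration for the synthetic landscape generator
#'
#' Describes a mosaic agricultural landscape of sites in several land-use
#' types, each land use with a private pool of flower-visitor species
#' (planted modules), plus a shared generalist pool. Visitation counts are
#' negative-binomial (field visit counts are overdispersed relative to
#' Poisson), and sentinel-plant reproduction is generated causally from
#' visitation and realized network position, so parameter-recovery tests
#' exercise the full pipeline.
#'
#' @param n_sites_per_landuse Named integer vector of sites per land use;
#'   the default is the 20-site, 4-land-use layout (forest 6, avocado 5,
#'   dairy 4, potato 5).
#' @param pool_size_per_landuse Named integer vector (recycled from a
#'   scalar) of private-pool species per land use.
#' @param shared_pool_size Species visiting all land uses.
#' @param overlap Probability in \[0, 1\] that a private-pool species
#'   ranges over the whole landscape instead of its own land use: 0 gives
#'   disjoint pools (perfect planted modules), 1 a fully mixed landscape.
#' @param visit_rate Expected total visits per site.
#' @param nb_dispersion Negative-binomial size parameter for visit counts.
#' @param specialist_fraction Proportion of private-pool species restricted
#'   to a single site.
#' @param order_composition Probabilities over insect orders
#'   (Diptera, Hymenoptera, Lepidoptera, Coleoptera); must sum to 1.
#' @param syrphid_share Target share of all visits contributed by
#'   Syrphidae (hoverflies, within Diptera).
#' @param repro_effects Named numeric vector `(b0, b_syrphid, b_hym, b_c)`:
#'   intercept and effects of standardized syrphid visits, hymenopteran
#'   visits and site participation coefficient on the logit of the
#'   fertilized-pod probability.
#' @param seeds_mean_effects Named numeric vector `(g0, g_visits)`:
#'   log-scale intercept and standardized-total-visits effect on the
#'   Poisson mean of seeds per pod.
#' @param n_plants_per_site Integer range (min, max) of sentinel plants
#'   per site.
#' @param flowers_per_plant_range Integer range (min, max) of open flowers
#'   per plant.
#' @param box_km Side of the square landscape (km).
#' @param min_separation_km Minimum distance between sites (km).
#' @param seed Integer seed; the whole landscape is a deterministic
#'   function of the configuration.
#' @return An object of class `synthetic_config`.
#' @seealso [generate_landscape()], [paper_shaped_preset()]
#' @export
synthetic_config <- function(
    n_sites_per_landuse = c(forest = 6, avocado = 5, dairy = 4, potato = 5),
    pool_size_per_landuse = 12,
    shared_pool_size = 10,
    overlap = 0.1,
    visit_rate = 57,
    nb_dispersion = 1.5,
    specialist_fraction = 0.25,
    order_composition = c(Diptera = 0.785, Hymenoptera = 0.139,
                          Lepidoptera = 0.053, Coleoptera = 0.023),
    syrphid_share = 0.48,
    repro_effects = c(b0 = -0.4, b_syrphid = 0.8, b_hym = 0.4, b_c = 1),
    seeds_mean_effects = c(g0 = log(15), g_visits = 0.2),
    n_plants_per_site = c(15, 18),
    flowers_per_plant_range = c(30, 60),
    box_km = 40,
    min_separation_km = 1,
    seed = 1L) {
  if (is.null(names(n_sites_per_landuse))) {
    stop("n_sites_per_landuse must be a named vector")
  }
  if (length(pool_size_per_landuse) == 1) {
    pool_size_per_landuse <- setNames(
      rep(pool_size_per_landuse, length(n_sites_per_landuse)),
      names(n_sites_per_landuse))
  }
  if (!setequal(names(pool_size_per_landuse), names(n_sites_per_landuse))) {
    stop("pool_size_per_landuse names must match n_sites_per_landuse")
  }
  if (abs(sum(order_composition) - 1) > 1e-8) {
    stop("order_composition must sum to 1")
  }
  if (overlap < 0 || overlap > 1) stop("overlap must lie in [0, 1]")
  if (specialist_fraction < 0 || specialist_fraction > 1) {
    stop("specialist_fraction must lie in [0, 1]")
  }
  if (!all(c("b0", "b_syrphid", "b_hym", "b_c") %in% names(repro_effects))) {
    stop("repro_effects must name b0, b_syrphid, b_hym, b_c")
  }
  structure(as.list(environment()), class = "synthetic_config")
}

#' Landscape configuration mimicking the motivating field design
#'
#' A 20-site, 4-land-use configuration whose expected order-level visit
#' totals follow the strongly Diptera-dominated composition seen in
#' tropical sentinel-plant surveys (Diptera >> Hymenoptera > Lepidoptera >
#' Coleoptera), with hoverflies (Syrphidae) contributing about 48% of all
#' visits and a positive effect of site participation coefficient on
#' reproduction. This is a qualitative mimic of that study system — the
#' species pools, abundances and coordinates are synthetic.
#'
#' @param seed Integer seed.
#' @return A `synthetic_config`.
#' @export
paper_shaped_preset <- function(seed = 1L) {
  synthetic_config(
    n_sites_per_landuse = c(forest = 6, avocado = 5, dairy = 4, potato = 5),
    pool_size_per_landuse = c(forest = 14, avocado = 11, dairy = 13,
                              potato = 11),
    shared_pool_size = 12,
    overlap = 0.1,
    visit_rate = 57,            # ~1134 visits over 20 sites
    order_composition = c(Diptera = 890, Hymenoptera = 158,
                          Lepidoptera = 60, Coleoptera = 26) / 1134,
    syrphid_share = 0.48,
    seed = seed)
}

# Rejection placement of sites in a box with a minimum separation.
place_sites <- function(n, box_km, min_sep_km, max_attempts = 10000) {
  xy <- matrix(NA_real_, n, 2)
  placed <- 0
  for (attempt in seq_len(max_attempts)) {
    cand <- runif(2, 0, box_km)
    if (placed == 0 ||
        all(sqrt(colSums((t(xy[seq_len(placed), , drop = FALSE]) - cand)^2))
            >= min_sep_km)) {
      placed <- placed + 1
      xy[placed, ] <- cand
      if (placed == n) return(xy)
    }
  }
  stop("could not place ", n, " sites at >= ", min_sep_km,
       " km separation in ", max_attempts, " attempts")
}

#' Generate a synthetic landscape with full ground truth
#'
#' Three stages. (1) Species pools and visitation: each land use gets a
#' private species pool; with probability `overlap` a private species
#' ranges landscape-wide, and a `specialist_fraction` of the rest are
#' pinned to a single site. Visit counts per (site, eligible species) are
#' negative binomial with mean `visit_rate` times the species' share of
#' the site's pool weight. (2) The realized network is built and its
#' module partition optimized, giving each site a realized participation
#' coefficient. (3) Per plant, flowers are uniform in
#' `flowers_per_plant_range`; fertilized pods are binomial with a logistic
#' success probability driven by standardized syrphid visits, hymenopteran
#' visits and the site's participation coefficient; seeds per pod are
#' Poisson with log-mean driven by standardized total visits. Sites sit in
#' a `box_km` square with at least `min_separation_km` between any two.
#'
#' The same configuration (including its seed) always yields bit-identical
#' output.
#'
#' @param config A [synthetic_config()].
#' @param run_cfg A [run_config()] used for the module search in stage 2;
#'   defaults to one seeded from `config$seed`.
#' @return A list of class `synthetic_landscape`: `visitation` (a
#'   `visitation_table`), `plants` (a `plant_table`), and `truth` (planted
#'   modules, range/specialist flags, realized site metrics and the effect
#'   parameters used).
#' @export
generate_landscape <- function(config = synthetic_config(),
                               run_cfg = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  if (is.null(run_cfg)) {
    run_cfg <- run_config(
      random_seed = stage_seed(config$seed, "synthetic-modularity"))
  }
  set.seed(config$seed)
  lus <- names(config$n_sites_per_landuse)

  ## sites ------------------------------------------------------------
  site_lu <- rep(lus, times = config$n_sites_per_landuse)
  n_sites <- length(site_lu)
  site_id <- sprintf("%s_%02d", site_lu,
                     unlist(lapply(config$n_sites_per_landuse, seq_len)))
  xy <- place_sites(n_sites, config$box_km, config$min_separation_km)
  # anchor the box in the wet-tropics study region (degrees)
  lat0 <- -17.6; lon0 <- 145.3
  km_per_deg <- 111.1949
  latitude <- lat0 + xy[, 2] / km_per_deg
  longitude <- lon0 + xy[, 1] / (km_per_deg * cos(lat0 * pi / 180))

  ## species pools -----------------------------------------------------
  pool_of <- c(rep(lus, times = config$pool_size_per_landuse[lus]),
               rep("shared", config$shared_pool_size))
  n_sp <- length(pool_of)
  species_id <- sprintf("%s_sp%02d", pool_of,
                        unlist(lapply(c(config$pool_size_per_landuse[lus],
                                        shared = config$shared_pool_size),
                                      seq_len)))
  ord <- sample(names(config$order_composition), n_sp, replace = TRUE,
                prob = config$order_composition)
  syrphid_sp_frac <- 0.4   # fraction of Diptera species that are hoverflies
  is_syrphid <- ord == "Diptera" & runif(n_sp) < syrphid_sp_frac
  family <- ifelse(is_syrphid, "Syrphidae",
            ifelse(ord == "Diptera", "Muscidae",
            ifelse(ord == "Hymenoptera", "Halictidae",
            ifelse(ord == "Lepidoptera", "Hesperiidae", "Coccinellidae"))))
  # abundance weights; syrphid species up-weighted so their expected
  # visit share matches syrphid_share
  w <- rgamma(n_sp, shape = 0.7, rate = 1) + 1e-6
  p_syr <- config$order_composition[["Diptera"]] * syrphid_sp_frac
  mult <- (config$syrphid_share / (1 - config$syrphid_share)) *
    (1 - p_syr) / p_syr
  w[is_syrphid] <- w[is_syrphid] * mult

  spread <- pool_of != "shared" & runif(n_sp) < config$overlap
  specialist <- pool_of != "shared" & !spread &
    runif(n_sp) < config$specialist_fraction
  home_site <- rep(NA_character_, n_sp)
  for (s in which(specialist)) {
    home_site[s] <- sample(site_id[site_lu == pool_of[s]], 1)
  }

  eligible <- function(i) {
    lu <- site_lu[i]
    ok <- pool_of == "shared" | spread |
      (pool_of == lu & !specialist) |
      (specialist & !is.na(home_site) & home_site == site_id[i])
    which(ok)
  }

  ## visitation --------------------------------------------------------
  rows <- list()
  for (i in seq_len(n_sites)) {
    el <- eligible(i)
    mu <- config$visit_rate * w[el] / sum(w[el])
    for (try in 1:100) {
      visits <- rnbinom(length(el), mu = mu, size = config$nb_dispersion)
      if (sum(visits) > 0) break
    }
    keep <- visits > 0
    if (!any(keep)) stop("site ", site_id[i], " received no visits")
    rows[[i]] <- data.frame(
      site_id = site_id[i], land_use = site_lu[i],
      latitude = latitude[i], longitude = longitude[i],
      species_id = species_id[el][keep], order_name = ord[el][keep],
      family_name = family[el][keep], visits = visits[keep],
      stringsAsFactors = FALSE)
  }
  visitation <- as_visitation_table(do.call(rbind, rows))

  ## realized network position ----------------------------------------
  mat <- build_matrix(visitation)
  part <- optimize_modules(mat, run_cfg)
  cz <- node_cz(mat, part, "lower")
  c_site <- setNames(cz$c, cz$node_id)[site_id]

  site_tot <- function(sel) {
    v <- tapply(visitation$visits[sel], visitation$site_id[sel], sum)
    out <- setNames(numeric(n_sites), site_id)
    out[names(v)] <- v
    out
  }
  syr_visits <- site_tot(visitation$family_name == "Syrphidae")
  hym_visits <- site_tot(visitation$order_name == "Hymenoptera")
  tot_visits <- site_tot(rep(TRUE, nrow(visitation)))
  zs <- function(x) {
    s <- sd(x)
    if (!is.finite(s) || s == 0) return(x * 0)
    (x - mean(x)) / s
  }
  z_syr <- zs(syr_visits); z_hym <- zs(hym_visits)
  z_tot <- zs(tot_visits); z_c <- zs(c_site)

  ## reproduction ------------------------------------------------------
  be <- config$repro_effects
  ge <- config$seeds_mean_effects
  p_fert <- plogis(be[["b0"]] + be[["b_syrphid"]] * z_syr +
                     be[["b_hym"]] * z_hym + be[["b_c"]] * z_c)
  lambda <- exp(ge[["g0"]] + ge[["g_visits"]] * z_tot)
  plant_rows <- list()
  for (i in seq_len(n_sites)) {
    np <- sample(seq(config$n_plants_per_site[1],
                     config$n_plants_per_site[2]), 1)
    fl <- sample(seq(config$flowers_per_plant_range[1],
                     config$flowers_per_plant_range[2]), np, replace = TRUE)
    pods <- rbinom(np, fl, p_fert[i])
    seeds <- lapply(pods, function(k) rpois(k, lambda[i]))
    plant_rows[[i]] <- data.frame(
      site_id = site_id[i], plant_id = sprintf("%s_p%02d", site_id[i],
                                               seq_len(np)),
      n_inflorescences = pmax(1L, round(fl / 8)),
      n_unfertilized_flowers = fl - pods, n_pods = pods,
      stringsAsFactors = FALSE)
    plant_rows[[i]]$seeds <- seeds
  }
  plants <- as_plant_table(do.call(rbind, plant_rows))

  truth <- list(
    site_id = site_id, site_landuse = site_lu,
    species_id = species_id, species_pool = pool_of,
    species_order = ord, species_family = family,
    spread = spread, specialist = specialist, home_site = home_site,
    site_c = c_site, site_p_fert = unname(p_fert),
    site_lambda_seeds = unname(lambda),
    z_syr = unname(z_syr), z_hym = unname(z_hym),
    z_tot = unname(z_tot), z_c = unname(z_c),
    partition = part,
    repro_effects = be, seeds_mean_effects = ge,
    seed = config$seed)
  structure(list(visitation = visitation, plants = plants, truth = truth),
            class = "synthetic_landscape")
}

#' @export
print.synthetic_landscape <- function(x, ...) {
  cat(sprintf("synthetic_landscape: %d sites, %d species records, %d plants\n",
              length(unique(x$visitation$site_id)), nrow(x$visitation),
              nrow(x$plants)))
  invisible(x)
}
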