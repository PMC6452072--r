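test_that("read_visitation sums duplicate (site, species) rows", {
  f <- write_temp_csv(c(
    "site_id,land_use,latitude,longitude,species_id,order_name,family_name,visits",
    "s1,forest,-17.3,145.5,spA,Diptera,Syrphidae,2",
    "s1,forest,-17.3,145.5,spA,Diptera,Syrphidae,3",
    "s2,dairy,-17.4,145.6,spB,Hymenoptera,Halictidae,1"))
  tab <- read_visitation(f)
  expect_s3_class(tab, "visitation_table")
  expect_equal(nrow(tab), 2)
  expect_equal(tab$visits[tab$site_id == "s1"], 5)
})

test_that("schema and validation errors name the offender", {
  f <- write_temp_csv(c(
    "site_id,land_use,latitude,longitude,species_id,order_name,family_name",
    "s1,forest,-17.3,145.5,spA,Diptera,Syrphidae"))
  expect_error(read_visitation(f), "visits")

  f2 <- write_temp_csv(c(
    "site_id,land_use,latitude,longitude,species_id,order_name,family_name,visits",
    "s1,forest,-17.3,145.5,spA,Diptera,Syrphidae,-2"))
  expect_error(read_visitation(f2), "row.*1")

  # inconsistent site metadata is rejected
  f3 <- write_temp_csv(c(
    "site_id,land_use,latitude,longitude,species_id,order_name,family_name,visits",
    "s1,forest,-17.3,145.5,spA,Diptera,Syrphidae,2",
    "s1,dairy,-17.3,145.5,spB,Diptera,Syrphidae,2"))
  expect_error(read_visitation(f3), "inconsistent")
})

test_that("a generated 20-site landscape round-trips through the reader", {
  land <- generate_landscape(synthetic_config(seed = 3))
  out <- tempfile()
  cmd_simulate(out, synthetic_config(seed = 3))
  tab <- read_visitation(file.path(out, "visitation.csv"))
  expect_equal(length(unique(tab$site_id)), 20)
  lu_per_site <- tapply(tab$land_use, tab$site_id, function(x) length(unique(x)))
  expect_true(all(lu_per_site == 1))
  # reader -> writer -> reader is the identity
  f2 <- tempfile(fileext = ".csv")
  write.csv(as.data.frame(tab), f2, row.names = FALSE)
  tab2 <- read_visitation(f2)
  expect_equal(as.data.frame(tab2), as.data.frame(tab))
  # and matches the in-memory landscape
  expect_equal(tab$visits, land$visitation$visits)

  plants <- read_plants(file.path(out, "plants.csv"))
  expect_s3_class(plants, "plant_table")
  expect_equal(nrow(plants), nrow(land$plants))
  expect_equal(unlist(plants$seeds), unlist(land$plants$seeds))
})

test_that("build_matrix forms the weighted incidence matrix", {
  tab <- data.frame(site_id = c("s1", "s1", "s2"),
                    species_id = c("p1", "p2", "p2"),
                    visits = c(3, 1, 2))
  m <- build_matrix(tab)
  expect_equal(unname(m$A), rbind(c(3, 1), c(0, 2)))
  expect_equal(m$F, 6)
  expect_equal(unname(m$K), c(4, 2))
  expect_equal(unname(m$L), c(3, 3))
  expect_error(build_matrix(tab[0, ]), "empty")
})

test_that("zero-margin rows and columns are dropped with a message", {
  tab <- data.frame(site_id = c("s1", "s1", "s2"),
                    species_id = c("p1", "p2", "p1"),
                    visits = c(3, 0, 2))
  withr::local_options(pollinet.verbose = TRUE)
  expect_message(m <- build_matrix(tab), "dropping")
  expect_false("p2" %in% colnames(m$A))
})

test_that("matrix marginal identity holds on random tables", {
  set.seed(42)
  for (k in 1:20) {
    m <- random_matrix(sample(2:8, 1), sample(2:8, 1))
    expect_equal(sum(m$K), m$F)
    expect_equal(sum(m$L), m$F)
    expect_equal(unname(m$K), unname(rowSums(m$A)))
  }
})

test_that("standardize_reproduction applies the flower-standardized formula", {
  pl <- data.frame(site_id = "s1", plant_id = c("a", "b"),
                   n_inflorescences = 1,
                   n_unfertilized_flowers = c(6, 4),
                   n_pods = c(4, 6))
  pl$seeds <- list(rep(2L, 4), rep(3L, 6))
  sr <- standardize_reproduction(as_plant_table(pl))
  # fert_prop: 4/(6+4) = 0.4 and 6/(4+6) = 0.6
  expect_equal(sr$mean_fert_prop, 0.5)
  expect_equal(sr$var_fert_prop, 0.02)
  expect_equal(sr$n_plants, 2)
  # pooled seeds: 4 twos and 6 threes
  expect_equal(sr$mean_seeds, mean(c(rep(2, 4), rep(3, 6))))

  # zero pods gives fert_prop 0
  pl0 <- data.frame(site_id = "s2", plant_id = "a", n_inflorescences = 1,
                    n_unfertilized_flowers = 10, n_pods = 0)
  pl0$seeds <- list(integer(0))
  expect_equal(standardize_reproduction(as_plant_table(pl0))$mean_fert_prop, 0)
})

test_that("standardize_reproduction is invariant to plant order and drops flowerless plants", {
  pl <- data.frame(site_id = rep(c("s1", "s2"), each = 3),
                   plant_id = paste0("p", 1:6),
                   n_inflorescences = 1,
                   n_unfertilized_flowers = c(5, 2, 8, 1, 4, 6),
                   n_pods = c(2, 3, 1, 5, 0, 2))
  pl$seeds <- lapply(pl$n_pods, function(k) rep(2L, k))
  a <- standardize_reproduction(as_plant_table(pl))
  b <- standardize_reproduction(as_plant_table(pl[sample(6), ]))
  expect_equal(a, b)

  pl$n_unfertilized_flowers[1] <- 0; pl$n_pods[1] <- 0
  pl$seeds[[1]] <- integer(0)
  withr::local_options(pollinet.verbose = TRUE)
  expect_message(out <- standardize_reproduction(as_plant_table(pl)),
                 "excluding")
  expect_equal(out$n_plants[out$site_id == "s1"], 2)
})

test_that("write_outputs round-trips tables and records the seed", {
  m <- toy_matrix()
  part <- optimize_modules(m, test_config())
  metrics <- data.frame(node_id = c("s1", "s2", "p1", "p2"),
                        level = c("lower", "lower", "higher", "higher"),
                        d_prime = c(1, 0.25, 1 / 3, 0.7071067811865476),
                        strength = c(1.5, 0.5, 0.75, 1.25))
  nulls <- data.frame(replicate = 1:2, Q = c(0.11, 0.222))
  models <- data.frame(term = "x", estimate = pi)
  out <- tempfile()
  paths <- write_outputs(metrics, part, nulls, models,
                         list(seed = 77L, Q = part$Q), out)
  back <- read.csv(paths[["node_metrics"]])
  expect_equal(back$d_prime, metrics$d_prime, tolerance = 1e-12)
  expect_equal(back$strength, metrics$strength, tolerance = 1e-12)
  summ <- jsonlite::read_json(paths[["run_summary"]])
  expect_equal(summ$seed, 77)
  pf <- read.csv(paths[["partition"]])
  expect_setequal(pf$node_id, c("s1", "s2", "p1", "p2"))
  expect_equal(anyDuplicated(pf$node_id), 0L)
})
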