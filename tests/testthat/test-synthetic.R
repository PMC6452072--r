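test_that("the generator is a deterministic function of its configuration", {
  a <- generate_landscape(synthetic_config(seed = 8))
  b <- generate_landscape(synthetic_config(seed = 8))
  expect_identical(a$visitation, b$visitation)
  expect_identical(a$plants$n_pods, b$plants$n_pods)
  expect_identical(unlist(a$plants$seeds), unlist(b$plants$seeds))
  expect_identical(a$truth$site_c, b$truth$site_c)
  c2 <- generate_landscape(synthetic_config(seed = 9))
  expect_false(identical(a$visitation$visits, c2$visitation$visits))
})

test_that("disjoint two-land-use pools are recovered whenever they are optimal", {
  skip_if_not_installed("igraph")
  exact <- 0
  for (sd in 4:8) {
    cfg <- synthetic_config(
      n_sites_per_landuse = c(forest = 5, dairy = 5),
      pool_size_per_landuse = 10, shared_pool_size = 0,
      overlap = 0, specialist_fraction = 0, visit_rate = 60, seed = sd)
    land <- generate_landscape(cfg)
    tr <- land$truth
    mat <- build_matrix(land$visitation)
    ids <- c(rownames(mat$A), colnames(mat$A))
    planted_all <- setNames(
      match(sub("_(sp)?[0-9]+$", "", ids), c("forest", "dairy")), ids)
    q_planted <- barber_q(mat, planted_all)
    # the optimizer never returns anything worse than the planted blocks
    expect_gte(tr$partition$Q, q_planted - 1e-9)
    rec <- tr$partition$assignment[tr$site_id]
    nmi <- igraph::compare(as.integer(factor(tr$site_landuse)),
                           as.integer(rec), method = "nmi")
    if (tr$partition$Q <= q_planted + 1e-9) {
      # planted blocks are the optimum: recovery must be exact
      expect_equal(nmi, 1)
      exact <- exact + 1
    } else {
      # count noise created genuine sub-structure; still close to planted
      expect_gte(nmi, 0.8)
    }
  }
  expect_gte(exact, 3)   # noise rarely beats clean disjoint blocks
})

test_that("the field-shaped preset encodes the study scale", {
  cfg <- paper_shaped_preset()
  expect_equal(sum(cfg$n_sites_per_landuse), 20)
  expect_equal(unname(cfg$n_sites_per_landuse[c("forest", "avocado",
                                                "dairy", "potato")]),
               c(6, 5, 4, 5))
  # expected Diptera share of visits follows the order composition
  expect_gt(cfg$order_composition[["Diptera"]], 0.6)
  expect_equal(cfg$syrphid_share, 0.48)
  land <- generate_landscape(cfg)
  expect_equal(length(unique(land$visitation$site_id)), 20)
  # Diptera dominate realized visits as configured
  v <- land$visitation
  shares <- tapply(v$visits, v$order_name, sum) / sum(v$visits)
  expect_gt(shares[["Diptera"]], 0.6)
})

test_that("sites respect the minimum separation", {
  land <- generate_landscape(synthetic_config(seed = 12))
  v <- unique(as.data.frame(land$visitation)[, c("site_id", "latitude",
                                                 "longitude")])
  d <- geosphere::distHaversine(
    as.matrix(v[rep(1:20, each = 20), c("longitude", "latitude")]),
    as.matrix(v[rep(1:20, times = 20), c("longitude", "latitude")]),
    r = 6371008.8) / 1000
  d <- matrix(d, 20, 20)
  expect_true(all(d[upper.tri(d)] >= 0.99))   # >= 1 km up to projection error
})

test_that("truth carries enough to recompute the planted expectations", {
  cfg <- synthetic_config(seed = 19)
  land <- generate_landscape(cfg)
  tr <- land$truth
  be <- cfg$repro_effects
  p_expected <- plogis(be[["b0"]] + be[["b_syrphid"]] * tr$z_syr +
                         be[["b_hym"]] * tr$z_hym + be[["b_c"]] * tr$z_c)
  expect_equal(tr$site_p_fert, unname(p_expected))
  # realized fertilization tracks the planted probability
  repro <- standardize_reproduction(land$plants)
  ord <- match(repro$site_id, tr$site_id)
  expect_gt(cor(repro$mean_fert_prop, tr$site_p_fert[ord]), 0.8)
})

test_that("configuration validation names the broken field", {
  expect_error(synthetic_config(n_sites_per_landuse = c(3, 3)), "named")
  expect_error(synthetic_config(overlap = 1.5), "overlap")
  expect_error(synthetic_config(order_composition = c(Diptera = 0.5,
                                                      Hymenoptera = 0.4)),
               "order_composition")
  expect_error(synthetic_config(repro_effects = c(b0 = 1)), "repro_effects")
})
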