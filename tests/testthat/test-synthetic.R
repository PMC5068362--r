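test_that("identical configurations reproduce bit-identical bundles", {
  cfg <- scenario_config("filtering", n_sites = 8, n_species = 10,
                         n_axes = 2, attrs_per_axis = c(2, 2),
                         n_env = 3, effect_size = 1, seed = 7)
  sim1 <- simulate_metacommunity(cfg)
  sim2 <- simulate_metacommunity(cfg)
  expect_identical(sim1$sites, sim2$sites)
  expect_identical(sim1$traits, sim2$traits)
  expect_identical(sim1$abundance, sim2$abundance)
  expect_identical(ape::write.tree(sim1$tree), ape::write.tree(sim2$tree))

  cfg3 <- scenario_config("filtering", n_sites = 8, n_species = 10,
                          n_axes = 2, attrs_per_axis = c(2, 2),
                          n_env = 3, effect_size = 1, seed = 8)
  expect_false(identical(simulate_metacommunity(cfg3)$abundance,
                         sim1$abundance))
})

test_that("configuration invariants are enforced", {
  expect_error(scenario_config("null", n_sites = 3), "n_sites")
  expect_error(scenario_config("null", n_species = 2), "n_species")
  expect_error(scenario_config("null", n_axes = 2, attrs_per_axis = c(1)),
               "attrs_per_axis")
  expect_error(scenario_config("null", effect_size = -1), "effect_size")
  expect_error(scenario_config("frobnicate"), "arg")
})

test_that("zero spatial range gives environments uncorrelated with space", {
  cfg <- scenario_config("null", n_sites = 100, env_spatial_range = 0,
                         min_dist = 0, n_env = 3, seed = 3)
  sites <- generate_sites(cfg)
  for (k in 1:3) {
    expect_lt(abs(cor(sites[[paste0("env_", k)]], sites$x)), 0.3)
    expect_lt(abs(cor(sites[[paste0("env_", k)]], sites$y)), 0.3)
  }
})

test_that("large spatial range yields positive Moran's I for env columns", {
  # 30 sites give the Moran test enough resolution; at the study's 15 the
  # same check is positive but noisier
  hits <- vapply(1:100, function(r) {
    cfg <- scenario_config("null", n_sites = 30, min_dist = 2.5,
                           n_env = 1, env_spatial_range = 60,
                           seed = 100 + r)
    sites <- generate_sites(cfg)
    W <- build_connectivity(sites)
    m <- moran_i(sites$env_1, W, nperm = 99, seed = r,
                 alternative = "greater")
    m$I > 0 && m$p_value <= 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("species pool gives an ultrametric unit-depth tree and labelled traits", {
  cfg <- scenario_config("null", n_species = 3, n_axes = 2,
                         attrs_per_axis = c(1, 1), seed = 5)
  pool <- generate_species_pool(cfg)
  nwk <- ape::write.tree(pool$tree)
  reread <- ape::read.tree(text = nwk)
  expect_equal(ape::Ntip(reread), 3)
  depths <- ape::node.depth.edgelength(reread)[seq_len(3)]
  expect_lt(max(depths) - min(depths), 1e-9)
  expect_equal(round(max(depths), 6), 1)

  cfg27 <- scenario_config("null", n_species = 6,
                           n_axes = 7, attrs_per_axis = c(4, 4, 4, 5, 4, 3, 3),
                           seed = 5)
  pool27 <- generate_species_pool(cfg27)
  expect_equal(nrow(pool27$meta), 27)
  expect_equal(length(unique(pool27$meta$axis)), 7)
  expect_equal(sum(pool27$meta$is_mass), 1)
  validate_trait_table(pool27$traits, pool27$meta)
})

test_that("simulated traits carry phylogenetic signal", {
  hits <- vapply(1:100, function(r) {
    cfg <- scenario_config("null", n_species = 34, n_axes = 2,
                           attrs_per_axis = c(1, 1), seed = 300 + r)
    pool <- generate_species_pool(cfg)
    coph <- cophenetic_dist(pool$tree)
    mass_col <- pool$meta$attribute[pool$meta$is_mass]
    tv <- log(pool$traits[[mass_col]])
    td <- abs(outer(tv, tv, "-"))
    lower <- lower.tri(td)
    cor(td[lower], coph[lower]) > 0
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("null mechanism with zero effect has identical expected intensities", {
  cfg <- scenario_config("null", n_sites = 6, n_species = 8, n_axes = 2,
                         attrs_per_axis = c(1, 1), effect_size = 0,
                         noise_sd = 0, n_env = 2, seed = 2)
  sim <- simulate_metacommunity(cfg)
  lam <- sim$truth$intensity
  expect_lt(max(abs(sweep(lam, 2, lam[1, ]))), 1e-12)
})

test_that("counts are nonnegative integers with no empty sites", {
  for (mech in c("filtering", "dispersion_gradient", "spatial_only", "null")) {
    cfg <- scenario_config(mech, n_sites = 8, n_species = 10, n_axes = 2,
                           attrs_per_axis = c(1, 1), n_env = 2,
                           effect_size = 2, seed = 21)
    sim <- simulate_metacommunity(cfg)
    Y <- as.matrix(sim$abundance[-1])
    expect_true(all(Y >= 0))
    expect_true(all(Y == round(Y)))
    expect_true(all(rowSums(Y) > 0))
  }
})

test_that("dispersion gradient is recovered by the decomposition", {
  cors <- vapply(1:100, function(r) {
    cfg <- scenario_config("dispersion_gradient", effect_size = 2,
                           seed = 5000 + r)
    sim <- simulate_metacommunity(cfg)
    sc <- species_scores(gower_dist(sim$traits, sim$meta))
    dec <- decompose_structure(sim$abundance, sc)
    cor(sim$truth$niche_breadth, dec$dispersion)
  }, numeric(1))
  expect_gt(mean(cors), 0.7)
})

test_that("inject_missing masks exactly the requested cells, never the mass", {
  cfg <- scenario_config("null", n_species = 34, n_axes = 7,
                         attrs_per_axis = c(4, 4, 4, 5, 4, 3, 3), seed = 9)
  pool <- generate_species_pool(cfg)

  same <- inject_missing(pool$traits, pool$meta, 0, seed = 1)
  expect_equal(as.data.frame(same), as.data.frame(pool$traits),
               ignore_attr = TRUE)

  masked <- inject_missing(pool$traits, pool$meta, 38 / 918, seed = 4)
  n_na <- sum(is.na(as.matrix(masked[pool$meta$attribute])))
  expect_identical(n_na, 38L)
  mass_col <- pool$meta$attribute[pool$meta$is_mass]
  expect_false(anyNA(masked[[mass_col]]))

  masked2 <- inject_missing(pool$traits, pool$meta, 38 / 918, seed = 4)
  expect_identical(as.data.frame(masked2), as.data.frame(masked))
  expect_error(inject_missing(pool$traits, pool$meta, 1), "fraction")
})
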