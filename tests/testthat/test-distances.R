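test_that("axis-weighted Gower matches the hand-computed toy", {
  fx <- toy_traits()
  D <- gower_dist(fx$traits, fx$meta)
  # two axes, weight 1/2 each: sp1 vs sp2 differ only in the binary axis,
  # sp2 vs sp3 only at the mensural range extremes, sp1 vs sp3 in both
  expect_equal(D["sp1", "sp2"], 0.5)
  expect_equal(D["sp2", "sp3"], 0.5)
  expect_equal(D["sp1", "sp3"], 1.0)
  expect_symmetric_zero_diag(D)
  expect_true(all(D <= 1 + 1e-12))
})

test_that("Gower extremes are 0 for identical and 1 for maximally different species", {
  tr <- tibble::tibble(species = c("a", "b", "c"),
                       b1 = c(1, 1, 0), b2 = c(0, 0, 1),
                       m1 = c(5, 5, 9), m2 = c(2, 2, 7))
  meta <- tibble::tibble(attribute = c("b1", "b2", "m1", "m2"),
                         axis = c("x", "x", "y", "y"),
                         kind = c("binary", "binary", "mensural", "mensural"),
                         is_mass = c(FALSE, FALSE, TRUE, FALSE))
  D <- gower_dist(tr, meta)
  expect_equal(D["a", "b"], 0)
  expect_equal(D["a", "c"], 1)
})

test_that("Gower respects species permutation and axis restriction", {
  cfg <- scenario_config("null", n_species = 12, n_axes = 3,
                         attrs_per_axis = c(2, 2, 2), seed = 31)
  pool <- generate_species_pool(cfg)
  D <- gower_dist(pool$traits, pool$meta)

  idx <- sample(nrow(pool$traits))
  Dp <- gower_dist(pool$traits[idx, ], pool$meta)
  expect_equal(Dp[rownames(D), colnames(D)], D, ignore_attr = TRUE)

  # restricting to one axis equals unweighted Gower on that axis's attributes
  ax <- unique(pool$meta$axis)[1]
  D1 <- gower_dist(pool$traits, pool$meta, axes = ax)
  attrs <- pool$meta$attribute[pool$meta$axis == ax]
  manual <- Reduce(`+`, lapply(attrs, function(a) {
    v <- pool$traits[[a]]
    if (pool$meta$kind[pool$meta$attribute == a] == "binary") {
      1 * outer(v, v, "!=")
    } else {
      abs(outer(v, v, "-")) / diff(range(v))
    }
  })) / length(attrs)
  expect_equal(unname(D1), unname(manual), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("zero-range mensural attributes are dropped with a warning", {
  fx <- toy_traits()
  tr <- fx$traits
  tr$men1 <- c(3, 3, 3)
  expect_warning(D <- gower_dist(tr, fx$meta), "zero-range")
  # only the binary axis remains, renormalized to weight 1
  expect_equal(D["sp1", "sp2"], 1)
  expect_equal(D["sp2", "sp3"], 0)
})

test_that("Gower agrees with cluster::daisy under matching weights", {
  skip_if_not_installed("cluster")
  cfg <- scenario_config("null", n_species = 15, n_axes = 3,
                         attrs_per_axis = c(2, 1, 2), seed = 77)
  pool <- generate_species_pool(cfg)
  D <- gower_dist(pool$traits, pool$meta)

  df <- as.data.frame(pool$traits[pool$meta$attribute])
  kinds <- pool$meta$kind
  for (j in which(kinds == "binary")) df[[j]] <- factor(df[[j]])
  n_axes <- length(unique(pool$meta$axis))
  w <- 1 / (n_axes * as.numeric(table(pool$meta$axis)[pool$meta$axis]))
  ref <- as.matrix(cluster::daisy(df, metric = "gower", weights = w))
  expect_equal(unname(D), unname(ref), tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("cophenetic distances read path lengths off the tree", {
  D <- cophenetic_dist("((A:1,B:1):1,C:2);")
  expect_equal(D["A", "B"], 2)
  expect_equal(D["A", "C"], 4)
  expect_equal(D["B", "C"], 4)

  D1 <- cophenetic_dist("((A:1,B:1):1,C:2);", species = "A")
  expect_identical(dim(D1), c(1L, 1L))
  expect_identical(D1[1, 1], 0)
})

test_that("cophenetic distances equal the graph shortest-path oracle", {
  skip_if_not_installed("igraph")
  for (s in 1:5) {
    set.seed(400 + s)
    tree <- ape::rtree(10)
    D <- cophenetic_dist(tree)
    n_node <- ape::Ntip(tree) + tree$Nnode
    g <- igraph::graph_from_data_frame(
      data.frame(from = tree$edge[, 1], to = tree$edge[, 2],
                 weight = tree$edge.length),
      directed = FALSE, vertices = data.frame(name = seq_len(n_node)))
    sp <- igraph::distances(g, v = as.character(1:10),
                            to = as.character(1:10))
    dimnames(sp) <- list(tree$tip.label, tree$tip.label)
    expect_equal(D[tree$tip.label, tree$tip.label], sp, tolerance = 1e-10,
                 ignore_attr = TRUE)
  }
})

test_that("ultrametric trees satisfy the three-point condition", {
  cfg <- scenario_config("null", n_species = 12, n_axes = 2,
                         attrs_per_axis = c(1, 1), seed = 17)
  pool <- generate_species_pool(cfg)
  D <- cophenetic_dist(pool$tree)
  n <- nrow(D)
  combs <- utils::combn(n, 3)
  for (j in seq_len(ncol(combs))) {
    trip <- sort(c(D[combs[1, j], combs[2, j]],
                   D[combs[1, j], combs[3, j]],
                   D[combs[2, j], combs[3, j]]))
    expect_lt(trip[3] - trip[2], 1e-9)
  }
})

test_that("substitutions map missing species onto stand-in tips", {
  tree <- "((A:1,B:1):1,C:2);"
  expect_error(cophenetic_dist(tree, species = c("A", "Z")), "Z")
  expect_warning(
    D <- cophenetic_dist(tree, species = c("A", "B", "Znew"),
                         substitutions = c(Znew = "B")),
    "distance 0")
  expect_equal(D["Znew", "B"], 0)
  expect_equal(D["Znew", "A"], D["B", "A"])
})
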