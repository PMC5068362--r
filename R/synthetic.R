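# Synthetic metacommunities with a known assembly mechanism, so that every
# stage of the pipeline has a parameter-recovery test. The defaults mirror
# the motivating study design: 15 sites across a ~30-km landscape with a
# minimum spacing of 3.5 km, 34 species, 27 binary/mensural attributes in 7
# niche axes, spatially autocorrelated environmental gradients, and site
# totals of about a hundred captured individuals.

#' Scenario configuration for the metacommunity generator
#'
#' @param mechanism Assembly mechanism: `"filtering"` (species optima track
#'   the environmental gradient, shifting composition),
#'   `"dispersion_gradient"` (a trait-central core is abundant everywhere
#'   while trait-peripheral species track a niche-availability score driven
#'   by the gradient, shifting dispersion but not composition),
#'   `"spatial_only"` (intensities follow a broad coordinate trend,
#'   independent of the environment), or `"null"` (sites exchangeable).
#' @param n_sites,n_species Community dimensions (>= 4 sites, >= 3 species).
#' @param n_axes Number of niche axes.
#' @param attrs_per_axis Integer vector (length `n_axes`, entries >= 1) of
#'   attributes per axis; the default 4,4,4,5,4,3,3 gives 27 attributes over
#'   7 axes (four binary axes, three mensural).
#' @param env_spatial_range Length scale (same units as coordinates, km by
#'   default) of the exponential-covariance Gaussian process generating the
#'   environmental columns; `0` gives i.i.d. environments.
#' @param effect_size Strength of the assembly mechanism (>= 0; 0 collapses
#'   every mechanism to the null).
#' @param noise_sd SD of lognormal cell-level noise on intensities.
#' @param n_env Number of environmental predictor columns (the study tracked
#'   nine landscape indices).
#' @param square_side Side (km) of the square landscape.
#' @param min_dist Minimum between-site spacing (km), enforced by rejection
#'   sampling; set 0 to disable.
#' @param total_abundance Expected number of individuals per site.
#' @param overdispersion Gamma-mixing overdispersion for counts; 0 (default)
#'   gives pure Poisson draws.
#' @param seed Integer seed; identical configurations reproduce bit-identical
#'   outputs.
#' @return List of class `scenario_config`.
#' @export
scenario_config <- function(mechanism = c("null", "filtering",
                                          "dispersion_gradient",
                                          "spatial_only"),
                            n_sites = 15, n_species = 34,
                            n_axes = 7,
                            attrs_per_axis = c(4, 4, 4, 5, 4, 3, 3),
                            env_spatial_range = 15,
                            effect_size = 1, noise_sd = 0.1,
                            n_env = 9, square_side = 30, min_dist = 3.5,
                            total_abundance = 100, overdispersion = 0,
                            seed = 1) {
  mechanism <- match.arg(mechanism)
  if (n_sites < 4) stop("n_sites must be >= 4", call. = FALSE)
  if (n_species < 3) stop("n_species must be >= 3", call. = FALSE)
  if (length(attrs_per_axis) != n_axes || any(attrs_per_axis < 1)) {
    stop("attrs_per_axis must have n_axes entries, each >= 1", call. = FALSE)
  }
  if (effect_size < 0 || noise_sd < 0 || env_spatial_range < 0) {
    stop("effect_size, noise_sd and env_spatial_range must be >= 0",
         call. = FALSE)
  }
  structure(list(mechanism = mechanism, n_sites = n_sites,
                 n_species = n_species, n_axes = n_axes,
                 attrs_per_axis = as.integer(attrs_per_axis),
                 env_spatial_range = env_spatial_range,
                 effect_size = effect_size, noise_sd = noise_sd,
                 n_env = n_env, square_side = square_side,
                 min_dist = min_dist, total_abundance = total_abundance,
                 overdispersion = overdispersion,
                 seed = as.integer(seed)),
            class = "scenario_config")
}

# Rejection-sample coordinates on the square with a minimum spacing.
sample_coords <- function(n, side, min_dist) {
  xy <- matrix(NA_real_, n, 2)
  placed <- 0
  tries <- 0
  while (placed < n) {
    cand <- stats::runif(2, 0, side)
    ok <- placed == 0 ||
      min(sqrt(colSums((t(xy[seq_len(placed), , drop = FALSE]) - cand)^2))) >=
        min_dist
    if (ok) {
      placed <- placed + 1
      xy[placed, ] <- cand
    }
    tries <- tries + 1
    if (tries > 20000 * n) {
      stop("cannot place ", n, " sites with min_dist = ", min_dist,
           " in a ", side, "-unit square", call. = FALSE)
    }
  }
  xy
}

# One zero-mean GP draw on the sites with exponential covariance.
gp_draw <- function(d, range) {
  n <- nrow(d)
  if (range <= 0) return(stats::rnorm(n))
  K <- exp(-d / range) + diag(1e-8, n)
  L <- chol(K)
  as.numeric(crossprod(L, stats::rnorm(n)))
}

#' Generate site coordinates and environmental predictors
#'
#' Coordinates are uniform on the square (optionally with a rejection-sampled
#' minimum spacing). A master environmental gradient is drawn from a
#' Gaussian process with exponential covariance at the configured range;
#' each environmental column is a mixture of that gradient and an
#' independent GP draw (landscape indices are strongly intercorrelated),
#' plus i.i.d. noise.
#'
#' @param config A [scenario_config()].
#' @return Tibble `site, x, y, env_1..env_k` with attribute `gradient` (the
#'   master gradient the mechanisms respond to).
#' @export
generate_sites <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  with_seed(config$seed, {
    n <- config$n_sites
    xy <- sample_coords(n, config$square_side, config$min_dist)
    d <- as.matrix(stats::dist(xy))
    g <- gp_draw(d, config$env_spatial_range)
    # the first column IS the master gradient (the dominant landscape index
    # is measured exactly); the others are correlated companion indices
    env <- matrix(NA_real_, n, config$n_env)
    env[, 1] <- g
    rho <- stats::runif(max(0, config$n_env - 1), 0.4, 0.9)
    for (k in seq_len(config$n_env)[-1]) {
      env[, k] <- rho[k - 1] * g +
        sqrt(1 - rho[k - 1]^2) * gp_draw(d, config$env_spatial_range) +
        config$noise_sd * stats::rnorm(n)
    }
    colnames(env) <- paste0("env_", seq_len(config$n_env))
    out <- tibble::tibble(site = sprintf("site_%02d", seq_len(n)),
                          x = xy[, 1], y = xy[, 2])
    out <- dplyr::bind_cols(out, tibble::as_tibble(as.data.frame(env)))
    attr(out, "gradient") <- g
    out
  })
}

# Cut a cophenetic distance into k groups, merging singletons into the
# cluster of their nearest relative so every group has >= 2 members.
clade_labels <- function(coph, k, prefix) {
  hc <- stats::hclust(stats::as.dist(coph), method = "average")
  cl <- stats::cutree(hc, k = min(k, nrow(coph) %/% 2))
  repeat {
    sizes <- table(cl)
    singles <- names(sizes)[sizes == 1]
    if (!length(singles)) break
    i <- which(cl == as.integer(singles[1]))
    others <- setdiff(seq_along(cl), i)
    nn <- others[which.min(coph[i, others])]
    cl[i] <- cl[nn]
  }
  paste0(prefix, match(cl, unique(cl)))
}

#' Generate a species pool: phylogeny plus trait table
#'
#' Simulates a pure-birth ultrametric phylogeny with unit depth, then traits
#' on that tree so they carry phylogenetic signal: mensural attributes are
#' exponentiated Brownian motion (positive, lognormal-like across species),
#' binary attributes are threshold Brownian (Brownian liability cut at its
#' median). The first mensural attribute is flagged as body mass. Subfamily
#' and genus labels are clades cut from the tree (every genus has at least
#' two members, so congener imputation is always possible).
#'
#' @param config A [scenario_config()].
#' @return List with `traits` (tibble), `meta` (attribute metadata tibble),
#'   and `tree` (`phylo`).
#' @export
generate_species_pool <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  with_seed(config$seed + 1L, {
    n_sp <- config$n_species
    tree <- ape::rphylo(n_sp, birth = 1, death = 0)
    depth <- max(ape::node.depth.edgelength(tree))
    tree$edge.length <- tree$edge.length / depth
    tree$tip.label <- sprintf("sp_%02d", seq_len(n_sp))

    n_axes <- config$n_axes
    n_binary_axes <- min(n_axes - 1, max(1, round(4 / 7 * n_axes)))
    axis_kind <- c(rep("binary", n_binary_axes),
                   rep("mensural", n_axes - n_binary_axes))
    axis_names <- paste0("axis_", seq_len(n_axes))

    meta <- tibble::tibble(
      attribute = character(), axis = character(),
      kind = character(), is_mass = logical())
    traits <- tibble::tibble(species = tree$tip.label)
    first_mensural_seen <- FALSE
    for (ax in seq_len(n_axes)) {
      for (j in seq_len(config$attrs_per_axis[ax])) {
        nm <- paste0(axis_names[ax], "_a", j)
        z <- as.numeric(ape::rTraitCont(tree, model = "BM", sigma = 1))
        if (axis_kind[ax] == "binary") {
          val <- as.numeric(z > stats::median(z))
        } else {
          val <- exp(z)
        }
        is_mass <- axis_kind[ax] == "mensural" && !first_mensural_seen
        if (is_mass) first_mensural_seen <- TRUE
        traits[[nm]] <- val
        meta <- dplyr::bind_rows(meta, tibble::tibble(
          attribute = nm, axis = axis_names[ax], kind = axis_kind[ax],
          is_mass = is_mass))
      }
    }
    coph <- stats::cophenetic(tree)
    traits <- tibble::add_column(
      traits,
      subfamily = clade_labels(coph, max(2, n_sp %/% 7), "subfam_"),
      genus = clade_labels(coph, max(2, ceiling(n_sp / 2.5)), "gen_"),
      .after = "species")
    list(traits = traits, meta = meta, tree = tree)
  })
}

#' Generate abundance counts under the configured assembly mechanism
#'
#' Counts are Poisson draws around mechanism-determined intensities,
#' row-normalized so every site's expected total equals
#' `config$total_abundance`, with lognormal cell noise. Baseline relative
#' abundances are lognormal (rank-abundance skew). Mechanisms:
#' \describe{
#'   \item{filtering}{log-intensity penalized by
#'     `effect_size * (gradient_i - optimum_j)^2`; composition turns over
#'     along the gradient.}
#'   \item{dispersion_gradient}{species peripherality in trait space (from
#'     the axis-weighted Gower distances of the true traits) multiplies a
#'     site niche-availability score that increases along the gradient;
#'     dispersion rises with availability while composition stays centred.}
#'   \item{spatial_only}{log-intensity follows a broad `x + y` coordinate
#'     trend with species-specific signs, unrelated to the environmental
#'     columns.}
#'   \item{null}{sites exchangeable.}
#' }
#' Any all-zero site row is redrawn.
#'
#' @param sites Output of [generate_sites()].
#' @param pool Output of [generate_species_pool()].
#' @param config The shared [scenario_config()].
#' @return List with `abundance` (tibble, `site` + one column per species)
#'   and `truth` (list: `mechanism`, `gradient`, `niche_breadth` per site,
#'   `optima` per species, `intensity` matrix).
#' @export
generate_abundances <- function(sites, pool, config) {
  stopifnot(inherits(config, "scenario_config"))
  n <- nrow(sites)
  n_sp <- nrow(pool$traits)
  if (n != config$n_sites || n_sp != config$n_species) {
    stop("sites/pool dimensions do not match the config", call. = FALSE)
  }
  g <- attr(sites, "gradient")
  if (is.null(g)) stop("sites table lacks its gradient attribute", call. = FALSE)
  gs <- as.numeric(scale(g))

  with_seed(config$seed + 2L, {
    base <- exp(stats::rnorm(n_sp, 0, 1))
    p <- base / sum(base)
    eff <- config$effect_size
    optima <- NULL
    breadth <- rep(NA_real_, n)

    log_lambda <- matrix(log(p), n, n_sp, byrow = TRUE)
    if (config$mechanism == "filtering" && eff > 0) {
      optima <- sample(seq(min(gs), max(gs), length.out = n_sp))
      log_lambda <- log_lambda - eff * outer(gs, optima, function(a, b) (a - b)^2)
    } else if (config$mechanism == "dispersion_gradient" && eff > 0) {
      # Site "niche availability" stretches the trait-space footprint of the
      # locally dominant species without changing how many dominate: every
      # site boosts the same number of species, but low-availability sites
      # boost the trait-central ones and high-availability sites a set
      # spread across the trait axis. Dispersion shifts along the gradient;
      # composition and species evenness stay approximately constant.
      D <- gower_dist(pool$traits, pool$meta)
      u <- species_scores(D)$score
      ctr <- (max(u) + min(u)) / 2
      half <- (max(u) - min(u)) / 2
      avail <- 0.05 + 0.95 * (gs - min(gs)) / (max(gs) - min(gs))
      breadth <- avail
      k <- max(3, round(0.3 * n_sp))
      # effect_size sets the share of each site's individuals belonging to
      # the structured (niche-tracking) component
      phi <- 1 - exp(-1.5 * eff)
      # pass 1: the set of locally dominant species per site — target score
      # positions symmetric about the trait-space centre, stretched by the
      # site's niche availability
      heavy_sets <- vector("list", n)
      for (i in seq_len(n)) {
        targets <- ctr + avail[i] * half * seq(-1, 1, length.out = k)
        heavy <- integer(0)
        for (t in targets[-length(targets)]) {
          free <- setdiff(seq_len(n_sp), heavy)
          heavy <- c(heavy, free[which.min(abs(u[free] - t))])
        }
        # last pick balances the set's mean score back to the centre, so
        # composition stays pinned while dispersion stretches
        free <- setdiff(seq_len(n_sp), heavy)
        want <- k * ctr - sum(u[heavy])
        heavy_sets[[i]] <- c(heavy, free[which.min(abs(u[free] - want))])
      }
      # pass 2: intensities. Trait-peripheral species dominate at fewer
      # sites and so carry smaller occurrence weights downstream; scaling
      # each dominant species' intensity by the inverse of its expected
      # occupancy keeps effective (abundance x occurrence) weights even
      # across the dominant set.
      n_heavy <- tabulate(unlist(heavy_sets), nbins = n_sp)
      p_occ_light <- 1 - exp(-(1 - phi) * config$total_abundance /
                               max(1, n_sp - k))
      occ_hat <- pmax(1, n_heavy + (n - n_heavy) * p_occ_light)
      for (i in seq_len(n)) {
        heavy <- heavy_sets[[i]]
        light <- setdiff(seq_len(n_sp), heavy)
        wts <- (1 / occ_hat[heavy]) / sum(1 / occ_hat[heavy])
        log_lambda[i, heavy] <- log(phi * wts)
        log_lambda[i, light] <- log((1 - phi) * p[light] / sum(p[light]))
      }
      optima <- u
    } else if (config$mechanism == "spatial_only" && eff > 0) {
      # pure spatial structure: intensities follow the leading Moran
      # eigenvector of the site layout (a broad landscape-wide trend built
      # from coordinates alone), with species-specific responses
      W <- build_connectivity(sites[c("site", "x", "y")])
      mem1 <- mem_basis(W)$vectors$MEM1
      trend <- as.numeric(scale(mem1))
      beta <- stats::rnorm(n_sp)
      log_lambda <- log_lambda + 0.5 * eff * outer(trend, beta)
      optima <- beta
    }
    if (config$noise_sd > 0) {
      log_lambda <- log_lambda + matrix(stats::rnorm(n * n_sp, 0,
                                                     config$noise_sd), n, n_sp)
    }
    lambda <- exp(log_lambda)
    lambda <- sweep(lambda, 1, rowSums(lambda), "/") * config$total_abundance

    draw_row <- function(lam) {
      if (config$overdispersion > 0) {
        shape <- 1 / config$overdispersion
        lam <- lam * stats::rgamma(length(lam), shape = shape, rate = shape)
      }
      stats::rpois(length(lam), lam)
    }
    Y <- t(vapply(seq_len(n), function(i) draw_row(lambda[i, ]),
                  integer(n_sp)))
    for (i in seq_len(n)) {
      tries <- 0
      while (sum(Y[i, ]) == 0) {
        Y[i, ] <- draw_row(lambda[i, ])
        tries <- tries + 1
        if (tries > 1000) stop("cannot draw a nonzero row for site ", i,
                               call. = FALSE)
      }
    }
    dimnames(Y) <- list(sites$site, pool$traits$species)
    list(
      abundance = site_matrix_to_tibble(Y),
      truth = list(mechanism = config$mechanism, gradient = g,
                   niche_breadth = breadth, optima = optima,
                   intensity = lambda)
    )
  })
}

#' Mask trait cells at random
#'
#' Masks exactly `round(fraction * n_cells)` trait cells (over all attribute
#' columns) uniformly at random, never touching the body-mass attribute
#' (required as the imputation predictor) and never blanking out an entire
#' attribute column.
#'
#' @param traits Trait tibble.
#' @param meta Attribute metadata tibble.
#' @param fraction Fraction of cells to mask, in `[0, 1)`.
#' @param seed Integer seed.
#' @return Trait tibble with `NA`s, plus attribute `mask` (tibble of masked
#'   species/attribute pairs).
#' @export
inject_missing <- function(traits, meta, fraction, seed = 1) {
  if (fraction < 0 || fraction >= 1) {
    stop("fraction must lie in [0, 1)", call. = FALSE)
  }
  validate_trait_table(traits, meta)
  n_sp <- nrow(traits)
  attrs <- meta$attribute
  n_cells <- n_sp * length(attrs)
  n_mask <- round(fraction * n_cells)
  out <- traits
  if (n_mask == 0) {
    attr(out, "mask") <- tibble::tibble(species = character(),
                                        attribute = character())
    return(out)
  }
  mass_col <- mass_attribute(meta)
  eligible <- expand.grid(species = traits$species,
                          attribute = setdiff(attrs, mass_col),
                          stringsAsFactors = FALSE)
  if (n_mask > nrow(eligible)) {
    stop("fraction too large: would mask the mass attribute", call. = FALSE)
  }
  mask <- with_seed(seed, eligible[sample(nrow(eligible), n_mask), ])
  per_attr <- table(mask$attribute)
  full <- names(per_attr)[per_attr >= n_sp]
  if (length(full)) {
    stop("masking would blank out attribute(s): ",
         paste(full, collapse = ", "), call. = FALSE)
  }
  for (r in seq_len(nrow(mask))) {
    out[[mask$attribute[r]]][out$species == mask$species[r]] <- NA
  }
  attr(out, "mask") <- tibble::as_tibble(mask)
  out
}

#' Simulate a complete metacommunity bundle
#'
#' Convenience wrapper chaining [generate_sites()],
#' [generate_species_pool()] and [generate_abundances()].
#'
#' @param config A [scenario_config()].
#' @return List: `config`, `sites`, `traits`, `meta`, `tree`, `abundance`,
#'   `truth`.
#' @export
simulate_metacommunity <- function(config) {
  sites <- generate_sites(config)
  pool <- generate_species_pool(config)
  ab <- generate_abundances(sites, pool, config)
  list(config = config, sites = sites, traits = pool$traits,
       meta = pool$meta, tree = pool$tree,
       abundance = ab$abundance, truth = ab$truth)
}
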