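# Permutation tests for the unique fractions [a] and [c].
#
# Multivariate (taxonomic) responses: permutation of the response rows with
# the partial pseudo-F statistic. (Permutation of residuals under the
# reduced model, the other common scheme for partial RDA, degenerates when
# the nuisance block is large relative to n — with nine landscape
# predictors and fifteen sites the reduced-model residuals span only five
# dimensions and the scheme's size is badly off; raw-response permutation
# is exact under the exchangeable null at any n/p.) Trait-based responses:
# a double permutation — site vectors of the tested predictor block, and
# species entries of the trait eigenvector with the decomposition recomputed
# — combined conservatively by the max-p rule.

# Semipartial R2 of the full basis over the reduced basis for a centered
# response.
semipartial_r2 <- function(Mc, Q_full, Q_red) {
  tot <- sum(Mc^2)
  if (tot == 0) stop("zero-variance response", call. = FALSE)
  (sum(crossprod(Q_full, Mc)^2) - sum(crossprod(Q_red, Mc)^2)) / tot
}

# Pseudo-F of the added predictors (full over reduced) for a centered
# response: the partial-RDA test statistic. Degrees of freedom are taken
# from the basis dimensions (intercept included in each Q).
pseudo_f <- function(Mc, Q_full, Q_red, n) {
  tot <- sum(Mc^2)
  if (tot == 0) stop("zero-variance response", call. = FALSE)
  ss_full <- sum(crossprod(Q_full, Mc)^2)
  ss_red <- sum(crossprod(Q_red, Mc)^2)
  df1 <- ncol(Q_full) - ncol(Q_red)
  df2 <- n - ncol(Q_full)
  if (df1 < 1 || df2 < 1) stop("no degrees of freedom for the test",
                               call. = FALSE)
  tol <- 1e-12 * tot
  num <- ss_full - ss_red
  resid <- tot - ss_full
  if (num <= tol) return(0)
  if (resid <= tol) return(Inf)  # response fully explained by the full model
  (num / df1) / (resid / df2)
}

perm_p <- function(obs, perm) (sum(perm >= obs - 1e-12) + 1) / (length(perm) + 1)

#' Permutation tests of unique fractions for a multivariate response
#'
#' Tests the unique environmental fraction `[a]` and the unique spatial
#' fraction `[c]` of a (typically Hellinger-transformed) community matrix by
#' permuting the rows of the community matrix and recomputing the partial
#' pseudo-F of the tested block given the other each round.
#' `p = (#{permuted >= observed} + 1) / (nperm + 1)`.
#'
#' @param response Multivariate response (tibble with `site` column or
#'   matrix), e.g. [hellinger_transform()] output.
#' @param E,S Predictor tables.
#' @param nperm Number of permutations (>= 99; classic choice 999 or 1000).
#' @param seed Integer seed.
#' @return Tibble with one row per fraction: `fraction`, `statistic` (the
#'   pseudo-F), `semipartial_r2`, `p_value`, `nperm`, `code`.
#' @export
test_unique_taxonomic <- function(response, E, S, nperm = 999, seed = NULL) {
  m <- as_site_matrix(response)
  n <- nrow(m)
  if (nperm < 99) stop("nperm must be at least 99", call. = FALSE)
  sites <- rownames(m)
  Em <- as_predictor_matrix(E, sites, "environment")
  Sm <- as_predictor_matrix(S, sites, "space")
  Q_full <- predictor_basis(cbind(Em, Sm), n, warn = FALSE)$Q
  Mc <- sweep(m, 2, colMeans(m), "-")

  one_fraction <- function(reduced, label) {
    Q_red <- predictor_basis(reduced, n, warn = FALSE)$Q
    obs <- pseudo_f(Mc, Q_full, Q_red, n)
    perm <- vapply(seq_len(nperm), function(i) {
      pseudo_f(Mc[sample(n), , drop = FALSE], Q_full, Q_red, n)
    }, numeric(1))
    tibble::tibble(fraction = label, statistic = obs,
                   semipartial_r2 = semipartial_r2(Mc, Q_full, Q_red),
                   p_value = perm_p(obs, perm), nperm = nperm)
  }
  out <- with_seed(seed, dplyr::bind_rows(
    one_fraction(Sm, "a"),
    one_fraction(Em, "c")
  ))
  out$code <- significance_code(out$p_value)
  out
}

#' Double-permutation tests of unique fractions for trait-based responses
#'
#' For a composition or dispersion response derived from species scores, two
#' null distributions are generated per fraction: (i) site permutation — rows
#' of the tested predictor block are shuffled; (ii) species permutation —
#' the species score vector is shuffled across species and the
#' composition/dispersion decomposition recomputed each round. Each gives a
#' one-sided permutation p for the pseudo-F of the tested fraction; the
#' reported p-value is the maximum of the two (both must be extreme), the
#' conservative convention for trait-environment association tests.
#'
#' @param Y Site-by-species counts (tibble with `site` column or matrix).
#' @param scores [species_scores()] output.
#' @param E,S Predictor tables.
#' @param component `"dispersion"` (default) or `"composition"`.
#' @param include_env_model Also test the whole environment-bearing model
#'   (`[ab]`, the R-squared on E alone) alongside the unique fractions;
#'   useful when environmental effects are themselves spatially structured
#'   and the signal sits in `[b]`.
#' @param weighting Cell-weight scheme passed to [decompose_structure()].
#' @param weights Site weights for the weighted regressions; defaults to the
#'   decomposition's per-site total weights. Pass `FALSE` for unweighted.
#' @param nperm Number of permutations per scheme (>= 99).
#' @param seed Integer seed.
#' @return Tibble with one row per fraction: `fraction`, `statistic`,
#'   `p_site`, `p_species`, `p_value` (max of the two), `nperm`, `code`.
#' @export
test_unique_trait <- function(Y, scores, E, S,
                              component = c("dispersion", "composition"),
                              include_env_model = FALSE,
                              weighting = "abundance_occurrence",
                              weights = NULL, nperm = 999, seed = NULL) {
  component <- match.arg(component)
  if (nperm < 99) stop("nperm must be at least 99", call. = FALSE)
  m <- as_site_matrix(Y)
  check_abundance(m)
  n <- nrow(m)
  sites <- rownames(m)
  Em <- as_predictor_matrix(E, sites, "environment")
  Sm <- as_predictor_matrix(S, sites, "space")

  decomp <- decompose_structure(m, scores, weighting)
  w <- if (isFALSE(weights)) NULL else weights %||% decomp$total_weight
  resp <- decomp[[component]]
  if (stats::sd(resp) <= 1e-10 * (abs(mean(resp)) + 1)) {
    stop("zero-variance ", component, " response: statistic undefined",
         call. = FALSE)
  }

  center_vec <- function(y) {
    if (is.null(w)) matrix(y - mean(y), ncol = 1) else {
      wm <- sum(w * y) / sum(w)
      matrix(sqrt(w) * (y - wm), ncol = 1)
    }
  }
  basis <- function(X) make_basis(X, n, weights = w, warn = FALSE)$Q
  Q_full <- basis(cbind(Em, Sm))
  Q_E <- basis(Em)
  Q_S <- basis(Sm)
  yc <- center_vec(resp)
  Q0 <- basis(matrix(numeric(0), n, 0))
  stat_vec <- function(ycv, QE, QS, Qfull) {
    out <- c(a = pseudo_f(ycv, Qfull, QS, n),
             c = pseudo_f(ycv, Qfull, QE, n))
    if (include_env_model) out <- c(out, ab = pseudo_f(ycv, QE, Q0, n))
    out
  }
  obs <- stat_vec(yc, Q_E, Q_S, Q_full)
  fracs <- names(obs)

  u <- scores$score
  sp_scores <- scores
  run <- with_seed(seed, {
    site_perm <- replicate(nperm, {
      Em_p <- Em[sample(n), , drop = FALSE]
      Sm_p <- Sm[sample(n), , drop = FALSE]
      out <- c(a = pseudo_f(yc, basis(cbind(Em_p, Sm)), Q_S, n),
               c = pseudo_f(yc, basis(cbind(Em, Sm_p)), Q_E, n))
      if (include_env_model) {
        out <- c(out, ab = pseudo_f(yc, basis(Em_p), Q0, n))
      }
      out
    })
    species_perm <- replicate(nperm, {
      sp_scores$score <- sample(u)
      d_p <- decompose_structure(m, sp_scores, weighting)
      y_p <- d_p[[component]]
      if (stats::sd(y_p) <= 1e-10 * (abs(mean(y_p)) + 1)) {
        return(stats::setNames(rep(-Inf, length(fracs)), fracs))
      }
      stat_vec(center_vec(y_p), Q_E, Q_S, Q_full)
    })
    list(site = site_perm, species = species_perm)
  })
  p_site <- vapply(fracs, function(f) perm_p(obs[f], run$site[f, ]), numeric(1))
  p_species <- vapply(fracs, function(f) perm_p(obs[f], run$species[f, ]),
                      numeric(1))
  p <- pmax(p_site, p_species)
  tibble::tibble(
    fraction = fracs,
    statistic = unname(obs),
    p_site = unname(p_site),
    p_species = unname(p_species),
    p_value = unname(p),
    nperm = nperm,
    code = significance_code(unname(p))
  )
}
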