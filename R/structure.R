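# Response construction: taxonomic composition (Hellinger matrix) and the
# composition / dispersion components of functional or phylogenetic structure.

#' Hellinger transformation of a site-by-species abundance table
#'
#' Each entry becomes the square root of the species' within-site relative
#' abundance, `sqrt(y_ij / rowsum_i)`, which downweights species that are
#' rare at a site and infrequent overall and makes Euclidean-based ordination
#' appropriate for species data. Rows of the result have unit sum of squares.
#'
#' @param Y Site-by-species counts: a tibble with a `site` id column, or a
#'   numeric matrix with site rownames. Rows must be nonnegative with at
#'   least one nonzero entry.
#' @return Tibble (`site` + one column per species) of Hellinger-transformed
#'   abundances.
#' @export
hellinger_transform <- function(Y) {
  m <- as_site_matrix(Y)
  check_abundance(m)
  H <- as.matrix(vegan::decostand(m, method = "hellinger"))
  site_matrix_to_tibble(H)
}

#' Species scores from a distance matrix (first principal coordinate)
#'
#' Runs principal-coordinates analysis on the distance matrix (Gower double
#' centering of -D^2/2) and returns the eigenvector of the largest positive
#' eigenvalue scaled by the square root of that eigenvalue — the single axis
#' summarizing functional or phylogenetic variation among species. Sign is
#' fixed so the largest-magnitude score is positive.
#'
#' @param D Symmetric species distance matrix (from [gower_dist()] or
#'   [cophenetic_dist()]).
#' @param k Number of axes to return (default 1; the decomposition consumes
#'   one axis).
#' @return Tibble with columns `species`, `score` (and `score2`, ... when
#'   `k > 1`), with attributes `eigenvalues` and `provenance`.
#' @export
species_scores <- function(D, k = 1) {
  check_distance_matrix(D)
  n <- nrow(D)
  B <- -0.5 * D^2
  J <- diag(n) - matrix(1 / n, n, n)
  B <- J %*% B %*% J
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  pos <- which(e$values > max(1e-12, 1e-9 * max(abs(e$values))))
  if (!length(pos)) {
    stop("degenerate distance matrix: no positive eigenvalue", call. = FALSE)
  }
  k_use <- min(k, length(pos))
  if (k_use < k) {
    warning("only ", k_use, " positive axes available", call. = FALSE)
  }
  scores <- vapply(seq_len(k_use), function(j) {
    fix_sign(e$vectors[, pos[j]]) * sqrt(e$values[pos[j]])
  }, numeric(n))
  colnames(scores) <- if (k_use == 1) "score" else
    c("score", paste0("score", seq_len(k_use)[-1]))
  out <- tibble::as_tibble(as.data.frame(scores))
  out <- tibble::add_column(out, species = rownames(D) %||%
                              paste0("sp_", seq_len(n)), .before = 1)
  attr(out, "eigenvalues") <- e$values[pos[seq_len(k_use)]]
  attr(out, "provenance") <- attr(D, "provenance") %||% "unknown"
  out
}

#' Decompose abundance-weighted trait variation into composition and dispersion
#'
#' Links the site-by-species abundance matrix to a species score vector
#' (Hadamard element-wise weighting) and redistributes the sum of squares of
#' the resulting total-variation matrix into per-site means and variances.
#' Cell weights default to `w_ij = y_ij * o_j` where `o_j` is the number of
#' sites occupied by species j — the occurrence multiplier that minimizes the
#' influence of rare species. Per site:
#' \deqn{m_i = \sum_j w_{ij} u_j / \sum_j w_{ij}}
#' \deqn{s_i = \sqrt{\sum_j w_{ij} (u_j - m_i)^2 / \sum_j w_{ij}}}
#' so that, with normalized weights, the weighted mean of `u^2` equals
#' `m_i^2 + s_i^2` exactly.
#'
#' @param Y Site-by-species counts (tibble with `site` column, or matrix).
#' @param scores Output of [species_scores()] (or a tibble with `species`
#'   and `score`).
#' @param weighting Cell-weight scheme: `"abundance_occurrence"` (default,
#'   `y_ij * o_j`), `"presence_occurrence"` (`1[y_ij>0] * o_j`), or
#'   `"abundance"` (`y_ij`).
#' @return Tibble with one row per site: `site`, `composition` (weighted mean
#'   score), `dispersion` (weighted SD), `dispersion_var` (weighted
#'   variance), `total_weight`, plus a `weighting` attribute recording the
#'   scheme.
#' @export
decompose_structure <- function(Y, scores,
                                weighting = c("abundance_occurrence",
                                              "presence_occurrence",
                                              "abundance")) {
  weighting <- match.arg(weighting)
  m <- as_site_matrix(Y)
  check_abundance(m)
  if (!all(c("species", "score") %in% names(scores))) {
    stop("`scores` needs columns species and score", call. = FALSE)
  }
  if (!setequal(colnames(m), scores$species)) {
    stop("species sets of abundances and scores differ", call. = FALSE)
  }
  u <- scores$score[match(colnames(m), scores$species)]

  occ <- colSums(m > 0)
  W <- switch(weighting,
    abundance_occurrence = sweep(m, 2, occ, "*"),
    presence_occurrence  = sweep(1 * (m > 0), 2, occ, "*"),
    abundance            = m
  )
  tw <- rowSums(W)
  if (any(tw == 0)) {
    stop("site with zero total weight: ",
         paste(rownames(m)[tw == 0], collapse = ", "), call. = FALSE)
  }
  comp <- as.numeric(W %*% u) / tw
  dev2 <- outer(comp, u, function(a, b) (b - a)^2)
  v <- rowSums(W * dev2) / tw
  v <- pmax(v, 0)
  out <- tibble::tibble(
    site = rownames(m),
    composition = unname(comp),
    dispersion = unname(sqrt(v)),
    dispersion_var = unname(v),
    total_weight = unname(tw)
  )
  attr(out, "weighting") <- weighting
  out
}

#' Share of between-site variation due to composition vs. dispersion
#'
#' Summarizes a decomposition by how much of the between-site variance in
#' community trait structure sits in the dispersion component versus the
#' composition component (variance across sites of `s` and of `m`).
#'
#' @param decomp Output of [decompose_structure()].
#' @return One-row tibble: `var_composition`, `var_dispersion`,
#'   `composition_share`, `dispersion_share`.
#' @export
structure_variance_shares <- function(decomp) {
  vc <- stats::var(decomp$composition)
  vs <- stats::var(decomp$dispersion)
  tot <- vc + vs
  tibble::tibble(
    var_composition = vc,
    var_dispersion = vs,
    composition_share = if (tot > 0) vc / tot else NA_real_,
    dispersion_share = if (tot > 0) vs / tot else NA_real_
  )
}
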