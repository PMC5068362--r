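# Moran's eigenvector map (MEM) spatial predictors and Moran's I tests.

#' Build a site connectivity matrix from coordinates
#'
#' Computes the Euclidean distance matrix, takes the longest edge of the
#' minimum spanning tree as the threshold distance, and links every pair of
#' sites closer than or equal to that threshold. Because all MST edges are at
#' most the threshold, the resulting graph is always connected.
#'
#' @param coords Site coordinates: tibble with `site`, `x`, `y` columns, or a
#'   two-column matrix with site rownames. Projected (planar) units assumed;
#'   longitude/latitude input is accepted but treated as planar with a
#'   warning.
#' @param weighted If `TRUE`, linked pairs get weight `1 - (d/threshold)^2`
#'   instead of 1.
#' @param geographic Set `TRUE` if `x`/`y` are longitude/latitude; distances
#'   are still computed on the plane, with a warning (fine at the scale of a
#'   single landscape, wrong for continental extents).
#' @return Symmetric adjacency matrix with attributes `threshold`,
#'   `mst_edges` (two-column matrix of site indices) and `coords`.
#' @export
build_connectivity <- function(coords, weighted = FALSE, geographic = FALSE) {
  xy <- as_site_matrix(coords)
  if (!all(c("x", "y") %in% colnames(xy))) {
    if (ncol(xy) < 2) stop("coordinates need x and y columns", call. = FALSE)
    colnames(xy)[1:2] <- c("x", "y")
  }
  xy <- xy[, c("x", "y"), drop = FALSE]
  n <- nrow(xy)
  if (n < 3) stop("need at least 3 sites", call. = FALSE)
  if (geographic) {
    warning("treating longitude/latitude as planar coordinates", call. = FALSE)
  }
  d <- as.matrix(stats::dist(xy))
  if (any(d[upper.tri(d)] == 0)) {
    stop("duplicate site coordinates", call. = FALSE)
  }
  st <- vegan::spantree(stats::as.dist(d))
  threshold <- max(st$dist)
  mst_edges <- cbind(2:n, st$kid)
  W <- 1 * (d > 0 & d <= threshold)
  if (weighted) {
    Wd <- (1 - (d / threshold)^2) * W
    W <- Wd
  }
  diag(W) <- 0
  dimnames(W) <- list(rownames(xy), rownames(xy))
  attr(W, "threshold") <- threshold
  attr(W, "mst_edges") <- mst_edges
  attr(W, "coords") <- xy
  W
}

#' Moran's eigenvector map basis from a connectivity matrix
#'
#' Eigen-decomposes the doubly centered connectivity matrix
#' `(I - 11'/n) W (I - 11'/n)`. The eigenvectors are orthogonal spatial
#' patterns ordered by descending eigenvalue (equivalently by Moran's I);
#' each sums to zero. The default spatial predictor is the eigenvector of the
#' largest positive eigenvalue — a landscape-wide trend of positive spatial
#' autocorrelation.
#'
#' @param W Connectivity matrix from [build_connectivity()].
#' @param select Index (into the positive-eigenvalue eigenvectors, sorted by
#'   descending eigenvalue) of the predictor to mark selected; default 1.
#' @return List of class `mem_basis`: `vectors` (sites x k tibble including
#'   `site`), `values` (eigenvalues), `selected` (index), `n_positive`.
#' @export
mem_basis <- function(W, select = 1) {
  n <- nrow(W)
  J <- diag(n) - matrix(1 / n, n, n)
  C <- J %*% ((W + t(W)) / 2) %*% J
  e <- eigen((C + t(C)) / 2, symmetric = TRUE)
  keep <- abs(e$values) > 1e-8 * max(1, max(abs(e$values)))
  vals <- e$values[keep]
  vecs <- e$vectors[, keep, drop = FALSE]
  vecs <- apply(vecs, 2, fix_sign)
  n_pos <- sum(vals > 0)
  if (n_pos == 0) {
    stop("no positive eigenvalue: no positive spatial structure representable",
         call. = FALSE)
  }
  if (select > n_pos) {
    stop("cannot select MEM ", select, ": only ", n_pos,
         " positive eigenvectors", call. = FALSE)
  }
  tb <- tibble::as_tibble(as.data.frame(vecs))
  names(tb) <- paste0("MEM", seq_along(vals))
  tb <- tibble::add_column(tb, site = rownames(W) %||%
                             paste0("site_", seq_len(n)), .before = 1)
  structure(list(vectors = tb, values = vals, selected = select,
                 n_positive = n_pos),
            class = "mem_basis")
}

#' Extract the selected MEM spatial predictor
#' @param basis A `mem_basis` object.
#' @param k Which positive eigenvector(s) to return (default the selected
#'   one); `k` may be a vector for multi-MEM predictor sets.
#' @return Tibble with `site` and one column per requested eigenvector.
#' @export
mem_predictor <- function(basis, k = NULL) {
  k <- k %||% basis$selected
  if (any(k > basis$n_positive)) {
    stop("requested MEM beyond positive eigenvectors", call. = FALSE)
  }
  basis$vectors[, c(1, 1 + k), drop = FALSE]
}

#' Moran's I spatial autocorrelation with permutation test
#'
#' Classic Moran's I with the supplied (binary or weighted) connectivity
#' matrix; significance by random permutation of the values across sites,
#' two-sided by default via `|I|`.
#'
#' @param values Numeric per-site vector.
#' @param W Connectivity matrix (same site order).
#' @param nperm Number of permutations (>= 99).
#' @param seed Integer seed for the permutation stream.
#' @param alternative `"two.sided"` (default) or `"greater"`.
#' @return One-row tibble: `I`, `expected` (-1/(n-1)), `p_value`, `nperm`.
#' @export
moran_i <- function(values, W, nperm = 999, seed = NULL,
                    alternative = c("two.sided", "greater")) {
  alternative <- match.arg(alternative)
  n <- length(values)
  stopifnot(n == nrow(W))
  if (nperm < 99) stop("nperm must be at least 99", call. = FALSE)
  if (stats::sd(values) == 0) {
    stop("zero-variance values: Moran's I undefined", call. = FALSE)
  }
  s0 <- sum(W)
  stat <- function(z) {
    zc <- z - mean(z)
    (n / s0) * as.numeric(zc %*% W %*% zc) / sum(zc^2)
  }
  obs <- stat(values)
  perm <- with_seed(seed,
    vapply(seq_len(nperm), function(i) stat(sample(values)), numeric(1)))
  p <- if (alternative == "two.sided") {
    (sum(abs(perm) >= abs(obs)) + 1) / (nperm + 1)
  } else {
    (sum(perm >= obs) + 1) / (nperm + 1)
  }
  tibble::tibble(I = obs, expected = -1 / (n - 1), p_value = p, nperm = nperm)
}
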