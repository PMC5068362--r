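# Variation partitioning via full and partial redundancy analysis:
# fractions [a] (unique environment), [b] (spatially structured environment),
# [c] (unique space), [d] (residual), with Ezekiel-adjusted R2 and
# permutation tests of the unique fractions.

# Align a predictor table (tibble with optional `site` column, matrix, or
# NULL) against a vector of site ids; returns a plain numeric matrix
# (possibly zero-column). Zero-variance columns are rejected.
as_predictor_matrix <- function(X, sites, role = "predictor") {
  if (is.null(X)) {
    return(matrix(numeric(0), nrow = length(sites), ncol = 0,
                  dimnames = list(sites, NULL)))
  }
  m <- as_site_matrix(X)
  if (!is.null(rownames(m)) && all(sites %in% rownames(m))) {
    m <- m[sites, , drop = FALSE]
  } else if (nrow(m) != length(sites)) {
    stop(role, " rows do not match the response sites", call. = FALSE)
  }
  if (anyNA(m)) stop(role, " contains missing values", call. = FALSE)
  if (ncol(m)) {
    zv <- apply(m, 2, stats::sd) == 0
    if (any(zv)) {
      stop(role, " has zero-variance columns: ",
           paste(colnames(m)[zv], collapse = ", "), call. = FALSE)
    }
  }
  m
}

# Orthonormal basis (Q of the thin QR) of cbind(1, X) after dropping
# collinear columns; used to project responses. Returns list(Q, p) with p the
# number of retained predictor columns (intercept excluded).
predictor_basis <- function(X, n, warn = TRUE) {
  M <- cbind(`(Intercept)` = rep(1, n), X)
  qr_ <- qr(M)
  rank <- qr_$rank
  if (rank < ncol(M) && warn) {
    warning("dropping ", ncol(M) - rank, " collinear predictor column(s)",
            call. = FALSE)
  }
  Q <- qr.Q(qr_)[, seq_len(rank), drop = FALSE]
  list(Q = Q, p = rank - 1)
}

# R2 of a centered response matrix given an orthonormal predictor basis.
r2_from_basis <- function(Mc, Q) {
  tot <- sum(Mc^2)
  if (tot == 0) stop("zero-variance response", call. = FALSE)
  fit <- crossprod(Q, Mc)
  min(1, sum(fit^2) / tot)
}

# Center a response: multivariate -> column-centered matrix; univariate with
# site weights -> sqrt(w)-scaled, weighted-mean-centered column vector.
center_response <- function(response, weights = NULL) {
  m <- as_site_matrix(response)
  if (ncol(m) == 1 && !is.null(weights)) {
    y <- m[, 1]
    wm <- sum(weights * y) / sum(weights)
    matrix(sqrt(weights) * (y - wm), ncol = 1, dimnames = dimnames(m))
  } else {
    sweep(m, 2, colMeans(m), "-")
  }
}

# Row-scale a predictor matrix for weighted fits (sqrt(w) transform; the
# intercept column is scaled inside predictor_basis via cbind then qr, so we
# pre-scale X and the implicit intercept jointly).
weighted_basis <- function(X, weights, warn = TRUE) {
  n <- length(weights)
  M <- cbind(rep(1, n), X) * sqrt(weights)
  qr_ <- qr(M)
  rank <- qr_$rank
  if (rank < ncol(M) && warn) {
    warning("dropping ", ncol(M) - rank, " collinear predictor column(s)",
            call. = FALSE)
  }
  list(Q = qr.Q(qr_)[, seq_len(rank), drop = FALSE], p = rank - 1)
}

make_basis <- function(X, n, weights = NULL, warn = TRUE) {
  if (is.null(weights)) predictor_basis(X, n, warn) else
    weighted_basis(X, weights, warn)
}

#' Redundancy-analysis R-squared of a response on a predictor set
#'
#' For a multivariate response (e.g., a Hellinger-transformed abundance
#' table) this is the RDA statistic: the fitted sum of squares over the total
#' sum of squares, pooled over all column-centered response columns. For a
#' univariate response (a composition or dispersion vector) it is the
#' (optionally weighted) least-squares R-squared, computed on the weighted
#' scale. An intercept is always included; collinear predictor columns are
#' dropped with a warning.
#'
#' @param response Tibble with `site` column (one or more numeric columns) or
#'   numeric matrix/vector.
#' @param X Predictor tibble/matrix (may be `NULL` for the intercept-only
#'   model, giving R-squared 0).
#' @param weights Optional positive site weights (univariate responses only).
#' @return Object of class `rda_fit`: list with `r_squared`,
#'   `adj_r_squared`, `n`, `p` (retained predictors), `weighted`.
#' @export
fit_r2 <- function(response, X = NULL, weights = NULL) {
  m <- as_site_matrix(response)
  n <- nrow(m)
  if (!is.null(weights)) {
    stopifnot(length(weights) == n, all(weights > 0))
    if (ncol(m) > 1) stop("site weights are for univariate responses",
                          call. = FALSE)
  }
  sites <- rownames(m)
  Xm <- as_predictor_matrix(X, sites)
  if (ncol(Xm) >= n - 1) {
    stop("too many predictors (p must be < n - 1)", call. = FALSE)
  }
  b <- make_basis(Xm, n, weights)
  Mc <- center_response(m, weights)
  r2 <- r2_from_basis(Mc, b$Q)
  structure(list(r_squared = r2,
                 adj_r_squared = adjust_r2(r2, n, b$p),
                 n = n, p = b$p, weighted = !is.null(weights)),
            class = "rda_fit")
}

#' @export
print.rda_fit <- function(x, ...) {
  cat(sprintf("RDA fit: R2 = %.4f, adj R2 = %.4f (n = %d, p = %d%s)\n",
              x$r_squared, x$adj_r_squared, x$n, x$p,
              if (x$weighted) ", weighted" else ""))
  invisible(x)
}

#' Ezekiel-adjusted R-squared
#'
#' `1 - (1 - R2) * (n - 1) / (n - p - 1)` — unbiased under added noise
#' predictors; may be negative.
#'
#' @param r2 Unadjusted R-squared in `[0, 1]`.
#' @param n Number of sites.
#' @param p Number of predictors (intercept excluded).
#' @return Adjusted R-squared (scalar).
#' @export
adjust_r2 <- function(r2, n, p) {
  if (n <= p + 1) stop("adjusted R2 requires n > p + 1", call. = FALSE)
  1 - (1 - r2) * (n - 1) / (n - p - 1)
}

#' Partition response variation between environment and space
#'
#' Fits the full model (E and S), the environment-only model, and the
#' space-only model, adjusts each R-squared, and splits total variation into
#' the unique environmental fraction `[a] = [abc] - [bc]`, the spatially
#' structured environmental fraction `[b] = [ab] + [bc] - [abc]`, the unique
#' spatial fraction `[c] = [abc] - [ab]`, and the residual `[d] = 1 - [abc]`.
#' Raw fractions keep sign (negative `[b]` arises when E and S are correlated
#' with opposing effects); clamped copies floor each fraction at zero for
#' display.
#'
#' @param response Response table/vector (see [fit_r2()]).
#' @param E Environmental predictor tibble/matrix.
#' @param S Spatial predictor tibble/matrix (e.g., from [mem_predictor()]).
#' @param weights Optional site weights for univariate responses.
#' @param meta Optional named list (season, scale, response kind, ...) echoed
#'   into the result.
#' @return Object of class `commpart`; see [tidy.commpart()] and
#'   [glance.commpart()].
#' @export
partition_variation <- function(response, E, S, weights = NULL, meta = list()) {
  fit_abc <- fit_r2(response, cbind_predictors(E, S, response), weights)
  fit_ab  <- fit_r2(response, E, weights)
  fit_bc  <- fit_r2(response, S, weights)
  abc <- fit_abc$adj_r_squared
  ab  <- fit_ab$adj_r_squared
  bc  <- fit_bc$adj_r_squared
  a <- abc - bc
  c_ <- abc - ab
  b <- ab + bc - abc
  d <- 1 - abc
  raw <- c(a = a, b = b, c = c_, d = d)
  structure(list(
    raw = raw,
    clamped = pmax(raw, 0),
    totals = c(ab = ab, bc = bc, abc = abc),
    fits = list(abc = fit_abc, ab = fit_ab, bc = fit_bc),
    p_values = c(a = NA_real_, c = NA_real_),
    meta = meta
  ), class = "commpart")
}

# cbind two predictor sets aligned to the response's sites.
cbind_predictors <- function(E, S, response) {
  sites <- rownames(as_site_matrix(response))
  Em <- as_predictor_matrix(E, sites, "environment")
  Sm <- as_predictor_matrix(S, sites, "space")
  if (ncol(Em) && is.null(colnames(Em)))
    colnames(Em) <- paste0("E", seq_len(ncol(Em)))
  if (ncol(Sm) && is.null(colnames(Sm)))
    colnames(Sm) <- paste0("S", seq_len(ncol(Sm)))
  cbind(Em, Sm)
}

#' Significance codes for permutation p-values
#'
#' `"**"` for p <= 0.01, `"*"` for 0.01 < p <= 0.05, `"@"` for
#' 0.05 < p <= 0.10, empty string otherwise.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Character vector of codes.
#' @export
significance_code <- function(p) {
  if (any(is.na(p))) {
    out <- rep(NA_character_, length(p))
    ok <- !is.na(p)
    out[ok] <- significance_code(p[ok])
    return(out)
  }
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]", call. = FALSE)
  dplyr::case_when(
    p <= 0.01 ~ "**",
    p <= 0.05 ~ "*",
    p <= 0.10 ~ "@",
    TRUE ~ ""
  )
}

#' @export
print.commpart <- function(x, ...) {
  cat("Variation partition (adjusted R2 scale)\n")
  lab <- c(a = "[a] environment | space",
           b = "[b] spatially structured environment",
           c = "[c] space | environment",
           d = "[d] residual")
  for (f in names(x$raw)) {
    pv <- if (f %in% names(x$p_values)) x$p_values[[f]] else NA_real_
    cat(sprintf("  %-38s %8.4f%s\n", lab[[f]], x$raw[[f]],
                if (!is.na(pv)) sprintf("  (P = %.4g %s)", pv,
                                        significance_code(pv)) else ""))
  }
  invisible(x)
}
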