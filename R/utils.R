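# Internal coercion and validation helpers shared across modules.

# Convert a site-by-species table (tibble with `site` id column, or a plain
# matrix with rownames) to a numeric matrix with site ids as rownames.
as_site_matrix <- function(x, id_col = "site") {
  if (is.matrix(x)) {
    m <- x
    if (is.null(rownames(m))) rownames(m) <- paste0("site_", seq_len(nrow(m)))
    return(m)
  }
  x <- as.data.frame(x)
  if (id_col %in% names(x)) {
    ids <- as.character(x[[id_col]])
    x <- x[setdiff(names(x), id_col)]
  } else {
    ids <- paste0("site_", seq_len(nrow(x)))
  }
  num <- vapply(x, is.numeric, logical(1))
  if (!all(num)) {
    stop("non-numeric columns in site table: ",
         paste(names(x)[!num], collapse = ", "), call. = FALSE)
  }
  m <- as.matrix(x)
  rownames(m) <- ids
  m
}

# Matrix -> tibble with a `site` id column first.
site_matrix_to_tibble <- function(m, id_col = "site") {
  tb <- tibble::as_tibble(as.data.frame(m))
  tb <- tibble::add_column(tb, !!id_col := rownames(m), .before = 1)
  tb
}

check_abundance <- function(Y) {
  if (any(Y < 0)) stop("abundance matrix has negative entries", call. = FALSE)
  if (any(abs(Y - round(Y)) > 1e-8)) {
    stop("abundance matrix has non-integer counts", call. = FALSE)
  }
  zero <- rowSums(Y) == 0
  if (any(zero)) {
    stop("all-zero site rows: ", paste(rownames(Y)[zero], collapse = ", "),
         call. = FALSE)
  }
  invisible(Y)
}

check_distance_matrix <- function(D, tol = 1e-12) {
  if (!is.matrix(D) || nrow(D) != ncol(D)) {
    stop("distance matrix must be square", call. = FALSE)
  }
  if (max(abs(D - t(D))) > 1e-8) stop("distance matrix not symmetric", call. = FALSE)
  if (any(diag(D) != 0)) stop("distance matrix diagonal must be 0", call. = FALSE)
  if (any(D < -tol)) stop("distance matrix has negative entries", call. = FALSE)
  invisible(D)
}

# Deterministic sign convention for eigenvectors: entry of largest magnitude
# is made positive (first such entry on ties).
fix_sign <- function(v) {
  i <- which.max(abs(v))
  if (v[i] < 0) -v else v
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `code` under a temporary RNG state seeded with `seed` (NULL means
# use the ambient stream). Restores the caller's stream afterwards.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  }, add = TRUE)
  set.seed(seed)
  force(code)
}
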