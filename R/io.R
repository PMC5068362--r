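# Plain-text readers and writers for the pipeline's table formats.

#' Write / read a site-by-species abundance table
#'
#' CSV with sites as rows (`site` id column) and species as columns.
#'
#' @param abundance Tibble (`site` + species columns) or matrix.
#' @param path File path.
#' @return `read_abundance()` returns the tibble; writers return the path
#'   invisibly.
#' @export
write_abundance <- function(abundance, path) {
  m <- as_site_matrix(abundance)
  readr::write_csv(site_matrix_to_tibble(m), path)
  invisible(path)
}

#' @rdname write_abundance
#' @export
read_abundance <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}

#' Write / read a trait table with attribute metadata
#'
#' CSV with three header rows: attribute names, niche-axis labels, and
#' attribute kind (`binary`, `mensural`, or `mensural_mass` for the
#' body-mass column). Identifier columns (`species`, `subfamily`, `genus`)
#' carry the kind `id`.
#'
#' @param traits Trait tibble.
#' @param meta Attribute metadata tibble.
#' @param path File path.
#' @return `read_trait_table()` returns `list(traits, meta)`.
#' @export
write_trait_table <- function(traits, meta, path) {
  validate_trait_table(traits, meta)
  id_cols <- intersect(c("species", "subfamily", "genus"), names(traits))
  cols <- c(id_cols, meta$attribute)
  axis_row <- c(rep("id", length(id_cols)), meta$axis)
  kind <- meta$kind
  if ("is_mass" %in% names(meta)) {
    kind[meta$is_mass] <- "mensural_mass"
  }
  kind_row <- c(rep("id", length(id_cols)), kind)
  body <- traits[cols]
  writeLines(c(paste(cols, collapse = ","),
               paste(axis_row, collapse = ","),
               paste(kind_row, collapse = ",")), path)
  readr::write_csv(body, path, append = TRUE, col_names = FALSE)
  invisible(path)
}

#' @rdname write_trait_table
#' @export
read_trait_table <- function(path) {
  hdr <- readLines(path, n = 3)
  cols <- strsplit(hdr[1], ",")[[1]]
  axis <- strsplit(hdr[2], ",")[[1]]
  kind <- strsplit(hdr[3], ",")[[1]]
  body <- readr::read_csv(path, skip = 3, col_names = cols,
                          show_col_types = FALSE)
  is_attr <- kind != "id"
  kind_attr <- kind[is_attr]
  meta <- tibble::tibble(
    attribute = cols[is_attr],
    axis = axis[is_attr],
    kind = ifelse(kind_attr == "mensural_mass", "mensural", kind_attr),
    is_mass = kind_attr == "mensural_mass")
  for (a in meta$attribute) body[[a]] <- as.numeric(body[[a]])
  list(traits = body, meta = meta)
}

#' Write / read a square distance matrix as CSV
#'
#' Species ids appear both as the header row and as the first column.
#'
#' @param D Symmetric distance matrix with dimnames.
#' @param path File path.
#' @return `read_distance_matrix()` returns the matrix.
#' @export
write_distance_matrix <- function(D, path) {
  check_distance_matrix(D)
  tb <- tibble::as_tibble(as.data.frame(D))
  tb <- tibble::add_column(tb, species = rownames(D), .before = 1)
  readr::write_csv(tb, path)
  invisible(path)
}

#' @rdname write_distance_matrix
#' @export
read_distance_matrix <- function(path) {
  tb <- readr::read_csv(path, show_col_types = FALSE)
  m <- as.matrix(tb[-1])
  rownames(m) <- tb[[1]]
  storage.mode(m) <- "double"
  m
}

#' Write a simulated metacommunity bundle to a directory
#'
#' Emits `abundance.csv`, `traits.csv` (three header rows), `tree.nwk`,
#' `sites.csv`, and `truth.json`.
#'
#' @param sim Output of [simulate_metacommunity()].
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_metacommunity <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_abundance(sim$abundance, file.path(dir, "abundance.csv"))
  write_trait_table(sim$traits, sim$meta, file.path(dir, "traits.csv"))
  ape::write.tree(sim$tree, file.path(dir, "tree.nwk"))
  readr::write_csv(sim$sites, file.path(dir, "sites.csv"))
  truth <- sim$truth
  truth$intensity <- NULL
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
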