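# Species-by-species functional and phylogenetic distance matrices.

as_phylo <- function(tree) {
  if (inherits(tree, "phylo")) return(tree)
  if (is.character(tree) && length(tree) == 1) {
    if (grepl("\\(", tree)) return(ape::read.tree(text = tree))
    return(ape::read.tree(tree))
  }
  stop("tree must be a phylo object, a Newick string, or a file path",
       call. = FALSE)
}

#' Axis-weighted Gower dissimilarity between species
#'
#' Computes the Gower dissimilarity over mixed binary/mensural attributes,
#' weighting each attribute by `1 / (n_axes_used * n_attributes_in_its_axis)`
#' so that every niche axis contributes equal total weight regardless of how
#' many attributes describe it. Binary attributes contribute a 0/1 mismatch;
#' mensural attributes contribute `|x - y| / range`, the range taken over the
#' analyzed species set. Zero-range mensural attributes are dropped with a
#' warning and the remaining weights renormalized. Should missing values
#' remain (the pipeline imputes first), pairs fall back to pairwise deletion
#' with weight renormalization.
#'
#' @param traits Complete trait tibble (see [validate_trait_table()]).
#' @param meta Attribute metadata tibble.
#' @param axes Optional character vector of axis labels restricting the
#'   attribute set (single-axis analyses use `axes = "that_axis"`).
#' @return Symmetric species x species matrix in `[0, 1]`, zero diagonal,
#'   with attributes `provenance = "gower"` and `axes`.
#' @export
gower_dist <- function(traits, meta, axes = NULL) {
  validate_trait_table(traits, meta)
  if (!is.null(axes)) {
    unknown <- setdiff(axes, unique(meta$axis))
    if (length(unknown)) {
      stop("unknown axes: ", paste(unknown, collapse = ", "), call. = FALSE)
    }
    meta <- meta[meta$axis %in% axes, , drop = FALSE]
  }
  sp <- traits$species
  n <- length(sp)
  attrs <- meta$attribute
  n_axes <- length(unique(meta$axis))
  axis_size <- table(meta$axis)
  w <- 1 / (n_axes * as.numeric(axis_size[meta$axis]))
  names(w) <- attrs

  # per-attribute dissimilarity contributions (n x n each)
  keep <- rep(TRUE, length(attrs))
  contrib <- vector("list", length(attrs))
  avail <- vector("list", length(attrs))
  for (k in seq_along(attrs)) {
    v <- traits[[attrs[k]]]
    ok <- !is.na(v)
    if (meta$kind[k] == "mensural") {
      rng <- diff(range(v, na.rm = TRUE))
      if (!is.finite(rng) || rng == 0) {
        warning("zero-range mensural attribute `", attrs[k],
                "` excluded from Gower distance", call. = FALSE)
        keep[k] <- FALSE
        next
      }
      d <- abs(outer(v, v, "-")) / rng
    } else {
      d <- 1 * outer(v, v, "!=")
    }
    d[is.na(d)] <- 0
    contrib[[k]] <- d
    avail[[k]] <- 1 * outer(ok, ok, "&")
  }
  if (!any(keep)) stop("no usable attributes for Gower distance", call. = FALSE)

  num <- matrix(0, n, n)
  den <- matrix(0, n, n)
  for (k in which(keep)) {
    num <- num + w[k] * contrib[[k]] * avail[[k]]
    den <- den + w[k] * avail[[k]]
  }
  if (any(den == 0 & row(den) != col(den))) {
    stop("species pair with no shared observed attributes", call. = FALSE)
  }
  D <- num / den
  diag(D) <- 0
  D <- (D + t(D)) / 2
  dimnames(D) <- list(sp, sp)
  attr(D, "provenance") <- "gower"
  attr(D, "axes") <- sort(unique(meta$axis[keep]))
  check_distance_matrix(D)
  D
}

#' Cophenetic (patristic) distances between analysis species
#'
#' Entry (i, j) is the sum of branch lengths along the tree path between the
#' tips representing species i and j. Species absent from the tree may be
#' mapped to a stand-in tip via `substitutions` (the classic closest-congener
#' substitution); two species mapped to the same tip get distance 0 with a
#' warning.
#'
#' @param tree A `phylo`, Newick string, or Newick file path with branch
#'   lengths.
#' @param species Character vector of analysis species (defaults to all tips).
#' @param substitutions Named character vector `c(species = tip)` for species
#'   not present as tips.
#' @return Symmetric species x species matrix with attribute
#'   `provenance = "cophenetic"`.
#' @export
cophenetic_dist <- function(tree, species = NULL, substitutions = NULL) {
  tree <- as_phylo(tree)
  if (is.null(tree$edge.length)) {
    stop("tree must have branch lengths", call. = FALSE)
  }
  species <- species %||% tree$tip.label
  tip_of <- stats::setNames(species, species)
  if (!is.null(substitutions)) {
    tip_of[names(substitutions)] <- substitutions
  }
  unmapped <- species[!(tip_of[species] %in% tree$tip.label)]
  if (length(unmapped)) {
    stop("species not on the tree and without substitution: ",
         paste(unmapped, collapse = ", "), call. = FALSE)
  }
  dup <- duplicated(tip_of[species])
  if (any(dup)) {
    warning("species sharing a substituted tip get cophenetic distance 0: ",
            paste(species[dup], collapse = ", "), call. = FALSE)
  }
  if (length(species) == 1) {
    D <- matrix(0, 1, 1, dimnames = list(species, species))
  } else {
    coph <- stats::cophenetic(tree)
    D <- coph[tip_of[species], tip_of[species], drop = FALSE]
    dimnames(D) <- list(species, species)
    diag(D) <- 0
  }
  attr(D, "provenance") <- "cophenetic"
  check_distance_matrix(D)
  D
}
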