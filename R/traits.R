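#' Validate a trait table against its attribute metadata
#'
#' A trait table is a tibble with one row per species: a `species` id column,
#' optional `subfamily` and `genus` columns, and one column per attribute.
#' The companion metadata tibble has one row per attribute with columns
#' `attribute`, `axis` (niche-axis label), `kind` (`"binary"` or
#' `"mensural"`), and `is_mass` (flags the body-mass attribute used as the
#' imputation predictor).
#'
#' @param traits Trait tibble (species x attributes).
#' @param meta Attribute metadata tibble.
#' @return `traits`, invisibly, after validation.
#' @export
validate_trait_table <- function(traits, meta) {
  stopifnot(is.data.frame(traits), is.data.frame(meta))
  need <- c("attribute", "axis", "kind")
  if (!all(need %in% names(meta))) {
    stop("trait metadata needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (!"species" %in% names(traits)) {
    stop("trait table needs a `species` column", call. = FALSE)
  }
  missing_cols <- setdiff(meta$attribute, names(traits))
  if (length(missing_cols)) {
    stop("attributes in metadata but not in table: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!all(meta$kind %in% c("binary", "mensural"))) {
    stop("attribute kind must be 'binary' or 'mensural'", call. = FALSE)
  }
  if (anyDuplicated(meta$attribute)) {
    stop("each attribute must carry exactly one axis label", call. = FALSE)
  }
  for (a in meta$attribute[meta$kind == "binary"]) {
    v <- traits[[a]]
    if (!all(v %in% c(0, 1) | is.na(v))) {
      stop("binary attribute `", a, "` has values outside {0,1,NA}",
           call. = FALSE)
    }
  }
  for (a in meta$attribute[meta$kind == "mensural"]) {
    v <- traits[[a]]
    if (!is.numeric(v) || any(v < 0, na.rm = TRUE)) {
      stop("mensural attribute `", a, "` must be nonnegative numeric",
           call. = FALSE)
    }
  }
  invisible(traits)
}

mass_attribute <- function(meta) {
  if (!"is_mass" %in% names(meta) || !any(meta$is_mass)) {
    stop("no attribute flagged as mass (`is_mass`) in trait metadata",
         call. = FALSE)
  }
  meta$attribute[which(meta$is_mass)[1]]
}

#' Impute missing trait values
#'
#' Missing mensural values are predicted from body mass by ordinary least
#' squares fitted on same-subfamily species with observed values (intercept
#' included; at least two donors required). Missing binary values are copied
#' from a congener: when a phylogeny is supplied the congener at smallest
#' cophenetic distance donates, otherwise the alphabetically first congener
#' with an observed value.
#'
#' Observed cells are never altered. The completed table carries an
#' `imputation_report` attribute listing every imputed cell (species,
#' attribute, method, donor, value).
#'
#' @param traits Trait tibble (see [validate_trait_table()]).
#' @param meta Attribute metadata tibble.
#' @param tree Optional `phylo` (or Newick string) used to rank congeners.
#' @return Completed trait tibble with attribute `imputation_report`.
#' @export
impute_traits <- function(traits, meta, tree = NULL) {
  validate_trait_table(traits, meta)
  mass_col <- mass_attribute(meta)
  if (anyNA(traits[[mass_col]])) {
    stop("mass attribute `", mass_col, "` must be complete", call. = FALSE)
  }
  out <- traits
  report <- list()

  coph <- NULL
  if (!is.null(tree)) {
    tree <- as_phylo(tree)
    tips <- intersect(tree$tip.label, traits$species)
    if (length(tips) >= 2) coph <- stats::cophenetic(tree)
  }

  for (a in meta$attribute) {
    kind <- meta$kind[meta$attribute == a]
    miss <- which(is.na(out[[a]]))
    for (i in miss) {
      sp <- traits$species[i]
      if (kind == "mensural") {
        if (!"subfamily" %in% names(traits)) {
          stop("subfamily labels required to impute mensural attribute `",
               a, "` for ", sp, call. = FALSE)
        }
        donors <- which(traits$subfamily == traits$subfamily[i] &
                          !is.na(traits[[a]]) & traits$species != sp)
        if (length(donors) < 2) {
          stop("cannot impute mensural cell (", sp, ", ", a,
               "): fewer than 2 same-subfamily species with known values",
               call. = FALSE)
        }
        fit <- stats::lm(y ~ mass,
                         data = data.frame(y = traits[[a]][donors],
                                           mass = traits[[mass_col]][donors]))
        val <- unname(stats::predict(fit,
                                     newdata = data.frame(mass = traits[[mass_col]][i])))
        out[[a]][i] <- val
        report[[length(report) + 1]] <- tibble::tibble(
          species = sp, attribute = a, kind = kind,
          method = "ols_on_mass_within_subfamily",
          donor = NA_character_, value = val)
      } else {
        if (!"genus" %in% names(traits)) {
          stop("genus labels required to impute binary attribute `", a,
               "` for ", sp, call. = FALSE)
        }
        donors <- which(traits$genus == traits$genus[i] &
                          !is.na(traits[[a]]) & traits$species != sp)
        if (!length(donors)) {
          stop("cannot impute binary cell (", sp, ", ", a,
               "): no congener with a known value", call. = FALSE)
        }
        donor_sp <- traits$species[donors]
        if (!is.null(coph) && sp %in% rownames(coph) &&
            any(donor_sp %in% rownames(coph))) {
          cand <- donor_sp[donor_sp %in% rownames(coph)]
          donor <- cand[which.min(coph[sp, cand])]
        } else {
          donor <- sort(donor_sp)[1]
        }
        val <- traits[[a]][traits$species == donor]
        out[[a]][i] <- val
        report[[length(report) + 1]] <- tibble::tibble(
          species = sp, attribute = a, kind = kind,
          method = "congener_copy", donor = donor, value = val)
      }
    }
  }
  rep_tb <- if (length(report)) dplyr::bind_rows(report) else
    tibble::tibble(species = character(), attribute = character(),
                   kind = character(), method = character(),
                   donor = character(), value = numeric())
  attr(out, "imputation_report") <- rep_tb
  out
}

#' Retrieve the imputation report from a completed trait table
#' @param traits Output of [impute_traits()].
#' @return Tibble with one row per imputed cell.
#' @export
imputation_report <- function(traits) {
  attr(traits, "imputation_report") %||%
    tibble::tibble(species = character(), attribute = character(),
                   kind = character(), method = character(),
                   donor = character(), value = numeric())
}
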