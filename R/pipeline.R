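# End-to-end orchestration: one variation partition per season x focal
# scale x response, with decomposition summaries and Moran's I tables.

#' Validate consistency of a pipeline input bundle
#'
#' Report-only checks: species-set consistency across the abundance table,
#' trait table, and tree (allowing substitutions); site-set consistency
#' across abundance, coordinates and every predictor table; count
#' integrality and no all-zero site rows. A pure ordering mismatch passes
#' with a reordering note.
#'
#' @param abundance Site-by-species tibble or matrix.
#' @param traits,meta Trait table and metadata (optional).
#' @param tree Phylogeny (optional; `phylo` or Newick).
#' @param sites Site coordinate table (optional).
#' @param predictors Named list of per-scale predictor tables (optional).
#' @param substitutions Named character vector mapping species to tree tips.
#' @return Tibble with columns `check`, `status` (`"PASS"`/`"FAIL"`),
#'   `detail`.
#' @export
validate_inputs <- function(abundance, traits = NULL, meta = NULL,
                            tree = NULL, sites = NULL, predictors = NULL,
                            substitutions = NULL) {
  items <- list()
  add <- function(check, ok, detail = "") {
    items[[length(items) + 1]] <<- tibble::tibble(
      check = check, status = if (ok) "PASS" else "FAIL", detail = detail)
  }
  Y <- as_site_matrix(abundance)
  ok_counts <- all(Y >= 0) && all(abs(Y - round(Y)) < 1e-8)
  add("counts_nonnegative_integer", ok_counts,
      if (!ok_counts) "negative or non-integer entries" else "")
  zero <- rownames(Y)[rowSums(Y) == 0]
  add("no_all_zero_sites", length(zero) == 0, paste(zero, collapse = ", "))

  if (!is.null(traits)) {
    missing_tr <- setdiff(colnames(Y), traits$species)
    add("species_in_traits", length(missing_tr) == 0,
        paste(missing_tr, collapse = ", "))
  }
  if (!is.null(tree)) {
    tree <- as_phylo(tree)
    mapped <- colnames(Y) %in% tree$tip.label |
      colnames(Y) %in% names(substitutions %||% character())
    add("species_on_tree", all(mapped),
        paste(colnames(Y)[!mapped], collapse = ", "))
  }
  site_check <- function(tb, label) {
    ids <- as_site_matrix(tb)
    missing_s <- setdiff(rownames(Y), rownames(ids))
    if (length(missing_s)) {
      add(paste0("sites_in_", label), FALSE, paste(missing_s, collapse = ", "))
    } else {
      add(paste0("sites_in_", label), TRUE,
          if (!identical(rownames(ids), rownames(Y)))
            "same site set, different order: will be aligned by id" else "")
    }
  }
  if (!is.null(sites)) site_check(sites, "coordinates")
  if (!is.null(predictors)) {
    for (nm in names(predictors)) site_check(predictors[[nm]],
                                             paste0("predictors_", nm))
  }
  dplyr::bind_rows(items)
}

#' Run the full partition analysis over seasons, scales, and responses
#'
#' For every requested season x focal scale x response combination: build
#' the response (Hellinger matrix, or a composition/dispersion vector from
#' the axis-weighted Gower or cophenetic species scores), build the MEM
#' spatial predictor from the coordinates, partition variation between the
#' scale's environmental predictors and space, and test the unique
#' fractions by permutation. Also emits the composition-vs-dispersion
#' variance shares and Moran's I autocorrelation tables. A failure in one
#' combination is recorded and does not abort the others.
#'
#' @param abundance Named list of site-by-species tibbles, one per season
#'   (a single tibble is treated as one season named `"all"`).
#' @param traits,meta Trait table and attribute metadata (required for
#'   functional responses).
#' @param tree Phylogeny (required for phylogenetic responses).
#' @param sites Site coordinate table (`site`, `x`, `y`).
#' @param predictors Named list of per-scale environmental predictor tables
#'   (a single tibble is treated as one scale named `"all"`).
#' @param responses Subset of `c("taxonomic", "functional_composition",
#'   "functional_dispersion", "phylogenetic_composition",
#'   "phylogenetic_dispersion", "per_axis_dispersion")`.
#' @param substitutions Optional species-to-tip map for the tree.
#' @param weighting Cell-weight scheme for the decomposition.
#' @param nperm Permutations for every test (>= 99).
#' @param mem_select Which positive MEM eigenvector is the spatial predictor.
#' @param seed Integer seed; combination-level seeds are derived from it.
#' @return List of class `commdecomp_report`: `results` (one row per
#'   combination with raw and clamped fractions, p-values, codes),
#'   `structure_shares`, `moran`, `log`.
#' @export
run_partition_analysis <- function(abundance, traits = NULL, meta = NULL,
                                   tree = NULL, sites = NULL,
                                   predictors = NULL,
                                   responses = c("taxonomic",
                                                 "functional_dispersion",
                                                 "phylogenetic_dispersion"),
                                   substitutions = NULL,
                                   weighting = "abundance_occurrence",
                                   nperm = 999, mem_select = 1, seed = 1) {
  if (!is.list(abundance) || is.data.frame(abundance)) {
    abundance <- list(all = abundance)
  }
  if (is.null(predictors) || is.data.frame(predictors)) {
    predictors <- list(all = predictors)
  }
  choices <- c("taxonomic", "functional_composition", "functional_dispersion",
               "phylogenetic_composition", "phylogenetic_dispersion",
               "per_axis_dispersion")
  responses <- match.arg(responses, choices, several.ok = TRUE)
  if (is.null(sites)) stop("site coordinates are required", call. = FALSE)

  W <- build_connectivity(sites)
  basis <- mem_basis(W, select = mem_select)
  S <- mem_predictor(basis)

  need_fun <- any(grepl("functional|per_axis", responses))
  need_phy <- any(grepl("phylogenetic", responses))
  scores_F <- NULL
  scores_P <- NULL
  if (need_fun) {
    if (is.null(traits) || is.null(meta)) {
      stop("traits and meta required for functional responses", call. = FALSE)
    }
    traits_c <- impute_traits(traits, meta, tree)
    scores_F <- species_scores(gower_dist(traits_c, meta))
  }
  if (need_phy) {
    if (is.null(tree)) stop("tree required for phylogenetic responses",
                            call. = FALSE)
    D_P <- cophenetic_dist(tree, species = colnames(as_site_matrix(abundance[[1]])),
                           substitutions = substitutions)
    scores_P <- species_scores(D_P)
  }

  results <- list()
  shares <- list()
  moran_rows <- list()
  log <- list()
  note <- function(...) log[[length(log) + 1]] <<- paste0(...)
  note("weighting scheme: ", weighting, "; MEM selected: ", mem_select,
       "; nperm: ", nperm, "; seed: ", seed)
  note("MEM threshold distance: ",
       format(attr(W, "threshold"), digits = 6))

  combo_idx <- 0L
  for (season in names(abundance)) {
    Y <- abundance[[season]]
    Ym <- as_site_matrix(Y)
    Hel <- hellinger_transform(Ym)

    decomp_of <- function(sc) decompose_structure(Ym, sc, weighting)
    if (need_fun) {
      dF <- decomp_of(scores_F)
      shares[[length(shares) + 1]] <- dplyr::bind_cols(
        tibble::tibble(season = season, dimension = "functional"),
        structure_variance_shares(dF))
    }
    if (need_phy) {
      dP <- decomp_of(scores_P)
      shares[[length(shares) + 1]] <- dplyr::bind_cols(
        tibble::tibble(season = season, dimension = "phylogenetic"),
        structure_variance_shares(dP))
    }

    # Moran's I of the univariate responses
    moran_of <- function(v, label) {
      res <- try(moran_i(v, W, nperm = max(199, min(nperm, 999)),
                         seed = seed + 7L), silent = TRUE)
      if (inherits(res, "try-error")) return(NULL)
      dplyr::bind_cols(tibble::tibble(season = season, variable = label), res)
    }
    if (need_fun) {
      moran_rows[[length(moran_rows) + 1]] <- moran_of(dF$dispersion, "s_F")
      moran_rows[[length(moran_rows) + 1]] <- moran_of(dF$composition, "m_F")
    }
    if (need_phy) {
      moran_rows[[length(moran_rows) + 1]] <- moran_of(dP$dispersion, "s_P")
      moran_rows[[length(moran_rows) + 1]] <- moran_of(dP$composition, "m_P")
    }

    for (scale in names(predictors)) {
      E <- predictors[[scale]]
      if (season == names(abundance)[1]) {
        Em <- tryCatch(as_predictor_matrix(E, rownames(Ym), "environment"),
                       error = function(e) NULL)
        for (j in seq_len(ncol(Em %||% matrix(nrow = 0, ncol = 0)))) {
          mr <- moran_of(Em[, j], colnames(Em)[j])
          if (!is.null(mr)) {
            mr$season <- NA_character_
            moran_rows[[length(moran_rows) + 1]] <- mr
          }
        }
      }
      run_one <- function(label, fun) {
        combo_idx <<- combo_idx + 1L
        res <- tryCatch(fun(seed + combo_idx),
                        error = function(e) {
                          note("FAILED ", season, "/", scale, "/", label,
                               ": ", conditionMessage(e))
                          NULL
                        })
        if (!is.null(res)) {
          res <- dplyr::bind_cols(
            tibble::tibble(season = season, scale = scale, response = label),
            res)
          results[[length(results) + 1]] <<- res
        }
      }
      tax_row <- function(sd) {
        pt <- partition_variation(Hel, E, S)
        tests <- test_unique_taxonomic(Hel, E, S, nperm = nperm, seed = sd)
        partition_row(pt, tests)
      }
      trait_row <- function(scores, component) function(sd) {
        dcmp <- decompose_structure(Ym, scores, weighting)
        resp <- tibble::tibble(site = dcmp$site, value = dcmp[[component]])
        pt <- partition_variation(resp, E, S, weights = dcmp$total_weight)
        tests <- test_unique_trait(Ym, scores, E, S, component = component,
                                   weighting = weighting, nperm = nperm,
                                   seed = sd)
        partition_row(pt, tests)
      }
      for (resp in responses) {
        switch(resp,
          taxonomic = run_one("taxonomic", tax_row),
          functional_composition =
            run_one("functional_composition",
                    trait_row(scores_F, "composition")),
          functional_dispersion =
            run_one("functional_dispersion",
                    trait_row(scores_F, "dispersion")),
          phylogenetic_composition =
            run_one("phylogenetic_composition",
                    trait_row(scores_P, "composition")),
          phylogenetic_dispersion =
            run_one("phylogenetic_dispersion",
                    trait_row(scores_P, "dispersion")),
          per_axis_dispersion = {
            for (ax in unique(meta$axis)) {
              sc_ax <- tryCatch(
                species_scores(gower_dist(impute_traits(traits, meta, tree),
                                          meta, axes = ax)),
                error = function(e) NULL)
              if (is.null(sc_ax)) {
                note("FAILED axis scores for ", ax)
                next
              }
              run_one(paste0("functional_dispersion[", ax, "]"),
                      trait_row(sc_ax, "dispersion"))
            }
          })
      }
    }
  }
  structure(list(
    results = if (length(results)) dplyr::bind_rows(results) else
      tibble::tibble(),
    structure_shares = if (length(shares)) dplyr::bind_rows(shares) else
      tibble::tibble(),
    moran = if (length(moran_rows)) dplyr::bind_rows(moran_rows) else
      tibble::tibble(),
    log = unlist(log)
  ), class = "commdecomp_report")
}

# Flatten a partition + its tests into a one-row tibble.
partition_row <- function(pt, tests) {
  p_a <- tests$p_value[tests$fraction == "a"]
  p_c <- tests$p_value[tests$fraction == "c"]
  tibble::tibble(
    a = pt$raw[["a"]], b = pt$raw[["b"]], c = pt$raw[["c"]],
    d = pt$raw[["d"]],
    a_clamped = pt$clamped[["a"]], b_clamped = pt$clamped[["b"]],
    c_clamped = pt$clamped[["c"]], d_clamped = pt$clamped[["d"]],
    abc = pt$totals[["abc"]], ab = pt$totals[["ab"]], bc = pt$totals[["bc"]],
    p_a = p_a, p_c = p_c,
    code_a = significance_code(p_a), code_c = significance_code(p_c))
}

#' @export
print.commdecomp_report <- function(x, ...) {
  cat("commdecomp report: ", nrow(x$results), " partition(s)\n", sep = "")
  if (nrow(x$results)) {
    print(dplyr::select(x$results, dplyr::all_of(
      c("season", "scale", "response", "a", "b", "c", "d", "p_a", "p_c"))),
      n = 20)
  }
  invisible(x)
}

#' Write a report bundle to a directory
#'
#' Emits `results.csv` (3-decimal rounding), `results.json` (full
#' precision), `structure_shares.csv`, `moran.csv`, and `log.txt`.
#'
#' @param report A `commdecomp_report`.
#' @param dir Output directory.
#' @return The directory, invisibly.
#' @export
write_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  res3 <- dplyr::mutate(report$results,
                        dplyr::across(dplyr::where(is.numeric),
                                      ~ round(.x, 3)))
  readr::write_csv(res3, file.path(dir, "results.csv"))
  jsonlite::write_json(report$results, file.path(dir, "results.json"),
                       digits = NA, dataframe = "rows")
  readr::write_csv(report$structure_shares,
                   file.path(dir, "structure_shares.csv"))
  readr::write_csv(report$moran, file.path(dir, "moran.csv"))
  writeLines(report$log, file.path(dir, "log.txt"))
  invisible(dir)
}
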