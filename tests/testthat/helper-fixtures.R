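# Fixture builders shared across test files. Everything is generated in
# code; no data files.

# Three-species toy with two axes (one binary attribute, one mensural):
# the classic hand-computable weighted-Gower example.
toy_traits <- function() {
  list(
    traits = tibble::tibble(
      species = c("sp1", "sp2", "sp3"),
      bin1 = c(1, 0, 0),
      men1 = c(2, 2, 10)),
    meta = tibble::tibble(
      attribute = c("bin1", "men1"),
      axis = c("axis_b", "axis_m"),
      kind = c("binary", "mensural"),
      is_mass = c(FALSE, TRUE))
  )
}

# A mixed trait table with subfamily/genus labels for imputation tests.
imputation_traits <- function() {
  list(
    traits = tibble::tibble(
      species = c("Aus_x", "Aus_y", "Aus_z", "Bus_w", "Bus_v"),
      subfamily = c("S1", "S1", "S1", "S2", "S2"),
      genus = c("Aus", "Aus", "Aus", "Bus", "Bus"),
      mass = c(10, 20, 30, 15, 25),
      wing = c(20, 40, NA, 31, 49),   # wing = 2*mass within S1
      diet = c(1, NA, 0, 1, 1)),
    meta = tibble::tibble(
      attribute = c("mass", "wing", "diet"),
      axis = c("size", "aero", "diet"),
      kind = c("mensural", "mensural", "binary"),
      is_mass = c(TRUE, FALSE, FALSE))
  )
}

# Deterministic small abundance matrix with site rownames.
toy_abundance <- function() {
  Y <- matrix(c(4, 1, 0,
                2, 2, 1,
                0, 3, 5,
                1, 0, 7), nrow = 4, byrow = TRUE,
              dimnames = list(paste0("s", 1:4), paste0("sp", 1:3)))
  Y
}

# Small full metacommunity bundle for pipeline tests.
small_bundle <- function(mechanism = "filtering", seed = 11,
                         effect_size = 1.5, ...) {
  cfg <- scenario_config(mechanism, n_sites = 10, n_species = 12,
                         n_axes = 3, attrs_per_axis = c(2, 2, 2),
                         n_env = 3, effect_size = effect_size, seed = seed, ...)
  simulate_metacommunity(cfg)
}

expect_symmetric_zero_diag <- function(D, tol = 1e-12) {
  expect_lt(max(abs(D - t(D))), 1e-8)
  expect_identical(unname(diag(D)), rep(0, nrow(D)))
  expect_true(all(D >= -tol))
}
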