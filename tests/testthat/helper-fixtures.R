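# Shared fixtures, built once per test run and cached.

.fixture_env <- new.env(parent = emptyenv())

test_probe <- function() probe_geometry()

# Coarse reflectance database: enough resolution for structural and
# round-trip checks at a fraction of the production build cost.
tiny_grid <- function() grid_spec(mu_a_thin = 50, mu_sp_thin = 3)

tiny_db <- function() {
  if (is.null(.fixture_env$db)) {
    .fixture_env$db <- suppressWarnings(build_reflectance_database(
      tiny_grid(), test_probe(), mc_config(n_photons = 3e4, seed = 77)))
  }
  .fixture_env$db
}

tiny_model <- function() {
  if (is.null(.fixture_env$model)) {
    .fixture_env$model <- train_inverse_model(
      tiny_db(), hidden = c(16, 16), seed = 5, chunks = 60,
      iter_per_chunk = 80, patience = 10, n_restarts = 2)
  }
  .fixture_env$model
}

# water reference restricted to a band grid
band_values <- function(bd, ref = water_reference()) {
  sel <- ref$wavelength >= bd$range[1] & ref$wavelength <= bd$range[2]
  ref[sel, ]
}
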