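# Shared fixtures, built once per test run and cached.
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, builder(), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

# small noisy scene + segmentation-based prep (12 plots, 40 bands)
small_scene <- function() cached("small_scene", function() {
  simulate_field(n_plots = 12, plots_per_block = 6, n_bands = 40, seed = 3)
})

small_prep <- function() cached("small_prep", function() {
  prep_plots(small_scene(), margin = 5, seed = 3)
})

small_features <- function() cached("small_features", function() {
  plot_features(small_prep())
})

# noiseless renderer spec for exactness checks
noiseless_spec <- function(n_bands = 20, ...) {
  default_render_spec(n_bands = n_bands, refl_noise_sd = 0, band_noise_sd = 0,
                      height_noise_sd = 0, ...)
}

# deterministic synthetic band-mean matrix (plots x bands), positive entries
random_band_matrix <- function(n_plots, wavelengths, seed = 1) {
  set.seed(seed)
  matrix(runif(n_plots * length(wavelengths), 0.05, 0.8), n_plots,
         length(wavelengths))
}
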