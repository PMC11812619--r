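# Shared fixtures: the no-biochar kinetic condition and a default BMP design.
fo_params <- function() kinetic_params("first_order", b0 = 0.204, k = 0.57)
gz_params <- function() {
  kinetic_params("gompertz", b0 = 0.204, rm = 76.12, lam = 0)
}

noiseless_bmp <- function(params = fo_params(), seed = 1) {
  gen_bmp_dataset(params, bottle_spec("no_biochar", noise_sd = 0),
                  measurement_schedule(), seed = seed)
}

# Dense grid-search oracle for the first-order least-squares minimum.
grid_fit_first_order <- function(t, b, b0_grid, k_grid) {
  best <- list(sse = Inf)
  for (b0 in b0_grid) {
    for (k in k_grid) {
      sse <- sum((b - b0 * (1 - exp(-k * t)))^2)
      if (sse < best$sse) best <- list(b0 = b0, k = k, sse = sse)
    }
  }
  best
}
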