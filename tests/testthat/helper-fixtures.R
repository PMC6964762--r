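# small, fast fixtures shared across test files

# compact halo spot (grid 121 x 121 at 0.5 mm pitch)
small_halo_model <- function(center = c(0, 0)) {
  spot_model(sigma_core = 2, halo_weight = 0.1, sigma_halo = 6, center = center)
}

# noiseless film device: clipping without stochastic effects
film_quiet <- function() device_model("film", noise_fraction = 0)

lynx_quiet <- function() device_model("lynx", noise_fraction = 0)

# closed-form full width of a pure Gaussian at a fractional level
gauss_width <- function(sigma, fraction) 2 * sigma * sqrt(2 * log(1 / fraction))
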