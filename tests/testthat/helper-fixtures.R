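# shared fixtures, all built in code

erf <- function(x) 2 * pnorm(x * sqrt(2)) - 1

# a small ground truth with every term active (spacings/exponents from the
# pulse-series world)
gt_disk <- function() {
  pulse_series_scenario(seed = 1)$samples[[2]]  # UW-CMF-1
}

# tiny frame with a known constant or radial expected intensity
constant_frame <- function(value = 100, n = 32, monitor = 1,
                           config = instrument_config(
                             sdd = 1.7, detector_shape = c(n, n),
                             beam_center = c((n - 1) / 2, (n - 1) / 2),
                             q_range = c(0.005, 0.3))) {
  detector_frame(matrix(value, n, n), config, monitor = monitor)
}

# frame whose counts follow I(phi) = base * (1 + depth * cos(2 (phi -
# phi0))) exactly (no noise); used by anisotropy tests
modulated_frame <- function(depth, phi0 = 30, base = 1000, n = 64) {
  config <- instrument_config(sdd = 1.7, detector_shape = c(n, n),
                              beam_center = c((n - 1) / 2, (n - 1) / 2),
                              q_range = c(0.005, 0.3))
  geo <- fibrilsans:::pixel_geometry(config)
  counts <- round(base * (1 + depth * cos(2 * (geo$phi - phi0) * pi / 180)))
  detector_frame(counts, config)
}

# default merged-range q grid for direct 1D generation
qgrid_full <- function(n = 120) {
  exp(seq(log(0.003), log(0.27), length.out = n))
}
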