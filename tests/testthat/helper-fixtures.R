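# Shared fixtures: all synthetic, built in code at test time.

default_cfg <- default_config()
default_beam <- config_beam(default_cfg)

# a small synthesis configuration for fast imaging tests
small_config <- function(box_px = 64, defoci = seq(-3500, 3500, 500)) {
  cfg <- default_cfg
  cfg$synthesis$box_px <- as.integer(box_px)
  cfg$synthesis$defocus_min_angstrom <- min(defoci)
  cfg$synthesis$defocus_max_angstrom <- max(defoci)
  cfg$synthesis$defocus_step_angstrom <- diff(defoci)[1]
  cfg
}

# hand-built electron history (depths in Angstrom from beam entry)
make_history <- function(kinds, depths, layers, losses, particle_layer) {
  o <- order(depths)
  structure(list(events = data.frame(kind = kinds[o], depth = depths[o],
                                     layer = layers[o], loss = losses[o]),
                 total_loss = sum(losses),
                 particle_layer = particle_layer),
            class = "electron_history")
}

# image that IS 1 + a cos(2 pi k x / N) along columns (cosine amplitude a,
# exactly k cycles across the box): analytic peak power (a N^2 / 2)^2
cosine_image <- function(n, a, k, phase = 0) {
  x <- outer(rep(1, n), 0:(n - 1))
  1 + a * cos(2 * pi * k * x / n + phase)
}

# broad-spectrum smooth test image for alignment tests
smooth_test_image <- function(n, seed = 3) {
  set.seed(seed)
  base <- matrix(stats::rpois(n * n, 50), n, n)
  f <- iphase:::fftfreq(n)
  filt <- exp(-200 * outer(f^2, f^2, `+`))
  Re(stats::fft(stats::fft(base) * filt, inverse = TRUE)) / (n * n)
}

# single-layer stack from one material (no particle unless flagged)
one_layer_stack <- function(material, thickness, is_particle = FALSE) {
  structure(list(layers = list(list(material = material,
                                    thickness = thickness,
                                    is_particle = is_particle)),
                 orientation = "top"),
            class = "specimen_stack")
}

lossfree_config <- function() {
  cfg <- default_cfg
  for (m in names(cfg$materials))
    cfg$materials[[m]]$lambda_inel_angstrom <- Inf
  cfg
}
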