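## Synthetic energy-filtered defocus series of lattice-fringe particles.
##
## Image model: a uniform expected count per pixel (fluence x pixel area)
## modulated by cosine lattice fringes whose contrast follows a defocus-only
## phase-contrast transfer function; optional Poisson shot noise. This is a
## test-bench emulation of the experimental data, not a wave-optical image
## simulation.

#' Relativistic electron wavelength
#'
#' @param energy_kev Accelerating energy in keV.
#' @return de Broglie wavelength in Angstrom
#'   (\eqn{\lambda = hc/\sqrt{E(E + 2 m_0 c^2)}}).
#' @export
#' @examples
#' electron_wavelength(300)  # ~0.0197 A
electron_wavelength <- function(energy_kev) {
  stopifnot(energy_kev > 0)
  e_ev <- energy_kev * 1000
  12398.41984 / sqrt(e_ev * (e_ev + 2 * 510998.95))
}

#' Defocus-only contrast transfer function
#'
#' \code{sin(pi * wavelength * defocus * q^2)}: zero at zero defocus for all
#' spatial frequencies (the minimum-contrast crossing), odd in defocus.
#' Positive defocus denotes underfocus.
#'
#' @param q Spatial frequency, 1/Angstrom (>= 0).
#' @param defocus Defocus in Angstrom.
#' @param wavelength Electron wavelength in Angstrom.
#' @return Contrast factor in [-1, 1].
#' @export
ctf <- function(q, defocus, wavelength) {
  stopifnot(all(q >= 0))
  sin(pi * wavelength * defocus * q^2)
}

#' Specify a lattice fringe
#'
#' @param d_spacing Lattice spacing in Angstrom.
#' @param amplitude Contrast fraction in [0, 0.5].
#' @param angle Fringe normal orientation, radians.
#' @param footprint \code{NULL} for full-field, or
#'   \code{list(center = c(x, y), diameter = d)} in Angstrom relative to the
#'   box centre for a hard-edged disc.
#' @param phase Phase offset, radians.
#' @return A \code{fringe_spec}.
#' @export
fringe_spec <- function(d_spacing, amplitude, angle = 0, footprint = NULL,
                        phase = 0) {
  stopifnot(d_spacing > 0)
  if (amplitude < 0 || amplitude > 0.5)
    stop("fringe amplitude must be in [0, 0.5]")
  if (!is.null(footprint))
    stopifnot(is.list(footprint), length(footprint$center) == 2,
              footprint$diameter > 0)
  structure(list(d_spacing = d_spacing, amplitude = amplitude,
                 angle = angle, footprint = footprint, phase = phase),
            class = "fringe_spec")
}

## pixel-centre coordinates (Angstrom) relative to the box centre
box_coords <- function(size_px, pixel_size) {
  (seq_len(size_px) - 1 - (size_px - 1) / 2) * pixel_size
}

#' Render one micrograph box
#'
#' Expected counts per pixel are
#' \code{F_px * (1 + sum_r 2 a_r |ctf(1/d_r)| cos(2 pi q_r . x + phase_r)
#' footprint_r(x))} with \code{F_px = fluence * pixel_size^2}
#' (about 6.94 e-/px at the 60 e-/A^2, 0.34 A defaults); with
#' \code{noise = TRUE} each pixel is Poisson-realized.
#'
#' @param fringes List of \code{fringe_spec} objects (possibly empty).
#' @param defocus Defocus in Angstrom.
#' @param beam A \code{beam_parameters}.
#' @param pixel_size Pixel size in Angstrom.
#' @param size_px Box side in pixels.
#' @param seed Optional integer seed for the noise realization.
#' @param noise Poisson-realize the expectation?
#' @return A \code{micrograph}: numeric matrix with pixel_size, defocus,
#'   fluence and seed attributes.
#' @export
render_box <- function(fringes, defocus, beam = beam_parameters(),
                       pixel_size = 0.34, size_px = 250L, seed = NULL,
                       noise = TRUE) {
  lam <- electron_wavelength(beam$energy_kev)
  f_px <- beam_fluence(beam) * pixel_size^2
  xs <- box_coords(size_px, pixel_size)
  expo <- matrix(1, size_px, size_px)
  for (fr in fringes) {
    stopifnot(inherits(fr, "fringe_spec"))
    if (fr$d_spacing <= 2 * pixel_size)
      stop("fringe spacing ", fr$d_spacing, " A is at or below Nyquist")
    q <- 1 / fr$d_spacing
    qx <- q * cos(fr$angle); qy <- q * sin(fr$angle)
    ph <- outer(xs * qy, xs * qx, `+`) * 2 * pi + fr$phase
    pat <- 2 * fr$amplitude * abs(ctf(q, defocus, lam)) * cos(ph)
    if (!is.null(fr$footprint)) {
      cx <- fr$footprint$center[1]; cy <- fr$footprint$center[2]
      mask <- outer((xs - cy)^2, (xs - cx)^2, `+`) <=
        (fr$footprint$diameter / 2)^2
      pat <- pat * mask
    }
    expo <- expo + pat
  }
  if (any(expo < 0))
    stop("negative expected counts: combined fringe amplitudes too high")
  expo <- expo * f_px
  if (noise) {
    if (!is.null(seed)) set.seed(as.integer(seed))
    expo <- matrix(stats::rpois(length(expo), expo), size_px, size_px)
  }
  structure(expo, class = c("micrograph", "matrix"),
            pixel_size = pixel_size, defocus = defocus,
            fluence = beam_fluence(beam),
            seed = if (is.null(seed)) NA_integer_ else as.integer(seed))
}

#' Default defocus grid
#' @param config An \code{iphase_config}.
#' @return Strictly increasing defocus values in Angstrom (29 at defaults:
#'   -3500 to +3500 in 250 A steps).
#' @export
default_defocus_grid <- function(config = default_config()) {
  s <- config$synthesis
  seq(s$defocus_min_angstrom, s$defocus_max_angstrom,
      by = s$defocus_step_angstrom)
}

#' Render a defocus series
#'
#' One micrograph per defocus with shared fringe geometry and independent
#' Poisson noise per frame.
#'
#' @inheritParams render_box
#' @param defocus_list Strictly increasing defocus values in Angstrom.
#' @param seed Integer seed; frame i uses \code{seed + i}.
#' @return A \code{defocus_series}: list of frames plus metadata.
#' @export
render_series <- function(fringes, beam = beam_parameters(),
                          defocus_list = default_defocus_grid(),
                          pixel_size = 0.34, size_px = 250L, seed = 1L,
                          noise = TRUE) {
  stopifnot(length(defocus_list) >= 1, !is.unsorted(defocus_list,
                                                    strictly = TRUE))
  frames <- lapply(seq_along(defocus_list), function(i)
    render_box(fringes, defocus_list[i], beam, pixel_size, size_px,
               seed = if (noise) seed + i else NULL, noise = noise))
  structure(list(frames = frames, defocus_list = defocus_list,
                 pixel_size = pixel_size, fluence = beam_fluence(beam)),
            class = "defocus_series")
}

#' @export
print.defocus_series <- function(x, ...) {
  cat(sprintf("<defocus_series: %d frames, %d px, %.2f A/px, %g e-/A^2, defocus %g..%g A>\n",
              length(x$frames), nrow(x$frames[[1]]), x$pixel_size,
              x$fluence, min(x$defocus_list), max(x$defocus_list)))
  invisible(x)
}

## ---- ensembles -----------------------------------------------------------

## draw an orientation avoiding the support-grain angle by min_sep (mod pi)
draw_particle_angle <- function(al_angle, min_sep) {
  repeat {
    a <- stats::runif(1, 0, pi)
    d <- abs(a - al_angle) %% pi
    if (min(d, pi - d) >= min_sep) return(a)
  }
}

#' Plan a synthetic particle ensemble
#'
#' Draws the per-particle ground truth for a two-sided ensemble: side,
#' fringe orientation (avoiding the support-grain angle), and a lognormal
#' fringe amplitude whose side medians are set so that the expected
#' reflection POWER ratio top/bottom equals \code{true_ratio}.
#'
#' @param n_top,n_bottom Particles per side (>= 2 each).
#' @param true_ratio Target expected power ratio, > 0.
#' @param config An \code{iphase_config}.
#' @param seed Integer seed.
#' @return Truth table data frame: particle_id, side, true_amplitude,
#'   angle_rad, al_angle_rad, seed.
#' @export
plan_ensemble <- function(n_top, n_bottom, true_ratio,
                          config = default_config(), seed = 1L) {
  stopifnot(true_ratio > 0, n_top >= 2, n_bottom >= 2)
  syn <- config$synthesis
  set.seed(as.integer(seed))
  n <- n_top + n_bottom
  side <- c(rep("top", n_top), rep("bottom", n_bottom))
  a0 <- syn$pt_amplitude_median
  sc <- sqrt(true_ratio) / max(1, sqrt(true_ratio))
  med <- ifelse(side == "top", a0 * sc, a0 * sc / sqrt(true_ratio))
  amp <- stats::rlnorm(n, meanlog = log(med), sdlog = syn$dispersion_sdlog)
  amp <- pmin(amp, 0.45)  # keep the image model valid; negligible at defaults
  al_angle <- stats::runif(n, 0, pi)
  min_sep <- syn$min_angle_sep_deg * pi / 180
  angle <- vapply(al_angle, draw_particle_angle, numeric(1),
                  min_sep = min_sep)
  data.frame(particle_id = sprintf("p%03d", seq_len(n)), side = side,
             true_amplitude = amp, angle_rad = angle,
             al_angle_rad = al_angle,
             seed = as.integer(seed) + 1000L + seq_len(n) * 100L)
}

#' Render the defocus series of one planned particle
#'
#' Pt fringes inside the particle-footprint disc plus a full-field Al
#' support fringe, over the configured defocus grid.
#'
#' @param truth_row One row of a \code{\link{plan_ensemble}} truth table.
#' @param config An \code{iphase_config}.
#' @param noise Poisson-realize the frames?
#' @return A \code{defocus_series}.
#' @export
render_particle_series <- function(truth_row, config = default_config(),
                                   noise = TRUE) {
  syn <- config$synthesis
  beam <- config_beam(config)
  fr <- list(
    fringe_spec(syn$pt_d_spacing_angstrom, truth_row$true_amplitude,
                truth_row$angle_rad,
                footprint = list(center = c(0, 0),
                                 diameter =
                                   config$geometry$particle_diameter_angstrom)),
    fringe_spec(syn$al_d_spacing_angstrom, syn$al_amplitude,
                truth_row$al_angle_rad))
  render_series(fr, beam, default_defocus_grid(config),
                pixel_size = syn$pixel_size_angstrom,
                size_px = syn$box_px, seed = truth_row$seed, noise = noise)
}

#' Render a full synthetic ensemble
#'
#' Generates a two-sided particle ensemble as per-particle defocus series.
#' With \code{out_dir} set, each series is written as an MRC 2014 stack
#' (mode 2) with the pixel size in the header, alongside a
#' \code{truth.csv} sidecar, and only file paths are returned; otherwise
#' all series are returned in memory (intended for small ensembles).
#'
#' @inheritParams plan_ensemble
#' @param out_dir Optional output directory.
#' @param noise Poisson-realize the frames?
#' @return List with \code{truth} and either \code{series} (in-memory) or
#'   \code{paths}.
#' @export
render_ensemble <- function(n_top, n_bottom, true_ratio,
                            config = default_config(), seed = 1L,
                            out_dir = NULL, noise = TRUE) {
  truth <- plan_ensemble(n_top, n_bottom, true_ratio, config, seed)
  if (is.null(out_dir)) {
    series <- lapply(seq_len(nrow(truth)), function(i)
      render_particle_series(truth[i, ], config, noise = noise))
    return(list(truth = truth, series = series))
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(nrow(truth))
  for (i in seq_len(nrow(truth))) {
    s <- render_particle_series(truth[i, ], config, noise = noise)
    paths[i] <- file.path(out_dir, paste0(truth$particle_id[i], ".mrc"))
    write_mrc(s, paths[i])
  }
  utils::write.csv(truth, file.path(out_dir, "truth.csv"),
                   row.names = FALSE)
  list(truth = truth, paths = paths)
}
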