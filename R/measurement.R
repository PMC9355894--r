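## Reflection-power measurement pipeline: alignment, boxing, Fourier peak
## power in a resolution annulus, squared-fluence normalization, series
## maxima, ensemble statistics and the top/bottom comparison.

fftfreq <- function(n) {
  k <- 0:(n - 1)
  k[k >= ceiling(n / 2)] <- k[k >= ceiling(n / 2)] - n
  k / n
}

## phase cross-correlation of img against ref; returns the (row, col)
## displacement of img relative to ref, with 1/upsample subpixel precision
phase_corr_shift <- function(ref, img, upsample = 1) {
  n <- nrow(ref); m <- ncol(ref)
  R <- stats::fft(ref) * Conj(stats::fft(img))
  Rn <- R / pmax(Mod(R), .Machine$double.eps)
  cc <- Re(stats::fft(Rn, inverse = TRUE))
  pk <- arrayInd(which.max(cc), dim(cc)) - 1L
  sh <- c(pk[1], pk[2])
  if (sh[1] > n / 2) sh[1] <- sh[1] - n
  if (sh[2] > m / 2) sh[2] <- sh[2] - m
  if (upsample > 1) {
    # refine by explicit DFT of the cross-power spectrum on a fine local grid
    fy <- fftfreq(n); fx <- fftfreq(m)
    gy <- sh[1] + seq(-1, 1, by = 1 / upsample)
    gx <- sh[2] + seq(-1, 1, by = 1 / upsample)
    Ey <- exp(2i * pi * outer(gy, fy))        # |gy| x n
    Ex <- exp(2i * pi * outer(fx, gx))        # m x |gx|
    ccu <- Re(Ey %*% Rn %*% Ex)
    pk <- arrayInd(which.max(ccu), dim(ccu))
    sh <- c(gy[pk[1]], gx[pk[2]])
  }
  -sh
}

## shift an image by (dy, dx) pixels via the Fourier shift theorem
fourier_shift <- function(img, dy, dx) {
  n <- nrow(img); m <- ncol(img)
  ph <- exp(-2i * pi * (outer(fftfreq(n) * dy, rep(1, m)) +
                        outer(rep(1, n), fftfreq(m) * dx)))
  Re(stats::fft(stats::fft(img) * ph, inverse = TRUE)) / (n * m)
}

#' Align a defocus series by phase cross-correlation
#'
#' Per-frame translational drift is estimated against the series average by
#' phase cross-correlation with upsampled-DFT subpixel refinement, applied
#' by Fourier shift, and re-estimated once against the re-averaged series
#' (two passes).
#'
#' @param series A \code{defocus_series} (>= 2 frames).
#' @param upsample Subpixel precision is 1/upsample pixels.
#' @return List with \code{shifts} (frames x 2 matrix of (row, col)
#'   displacements) and \code{series} (the aligned \code{defocus_series}).
#' @export
align_series <- function(series, upsample = 10) {
  frames <- series$frames
  stopifnot(length(frames) >= 2)
  est <- function(ref, frs) t(vapply(frs, function(f)
    phase_corr_shift(ref, f, upsample), numeric(2)))
  apply_sh <- function(frs, sh) lapply(seq_along(frs), function(i)
    if (all(sh[i, ] == 0)) frs[[i]]
    else fourier_shift(frs[[i]], sh[i, 1], sh[i, 2]))
  ref <- Reduce(`+`, frames) / length(frames)
  sh1 <- est(ref, frames)
  pass1 <- apply_sh(frames, -sh1)
  ref2 <- Reduce(`+`, pass1) / length(pass1)
  sh2 <- est(ref2, pass1)
  shifts <- sh1 + sh2
  aligned <- apply_sh(frames, -shifts)
  aligned <- lapply(seq_along(aligned), function(i) {
    a <- aligned[[i]]
    attributes(a) <- attributes(frames[[i]])
    a
  })
  out <- series
  out$frames <- aligned
  list(shifts = shifts, series = out)
}

#' Crop a square box from an image
#'
#' 0-based pixel indexing; fractional centres round half-up. No padding:
#' a box touching the image edge is an error.
#'
#' @param image Numeric matrix.
#' @param center Length-2 (row, col), 0-based.
#' @param size Box side in pixels.
#' @return The size-by-size crop.
#' @export
box_out <- function(image, center, size) {
  stopifnot(length(center) == 2, size >= 1)
  c0 <- floor(center + 0.5)            # round half-up
  start <- c0 - floor(size / 2)
  end <- start + size - 1
  if (any(start < 0) || end[1] > nrow(image) - 1 || end[2] > ncol(image) - 1)
    stop("box [", start[1], "..", end[1], ", ", start[2], "..", end[2],
         "] out of image bounds")
  image[(start[1]:end[1]) + 1, (start[2]:end[2]) + 1]
}

#' Lattice-reflection peak power in a resolution annulus
#'
#' Maximum of \code{|FFT(box)|^2} (unnormalized forward FFT) over Fourier
#' pixels whose spatial-frequency modulus lies in
#' \code{[1/(d_target + d_tol), 1/(d_target - d_tol)]}. The DC term is
#' excluded by construction; exact ties are broken by the lowest
#' (row, col) index.
#'
#' @param box Numeric matrix (real image).
#' @param d_target Target lattice spacing, Angstrom.
#' @param d_tol Annulus half-width in spacing, Angstrom.
#' @param pixel_size Pixel size, Angstrom.
#' @return Peak power (numeric), with attributes \code{peak_index}
#'   (1-based (row, col)) and \code{radius} (1/Angstrom).
#' @export
reflection_power <- function(box, d_target, d_tol = 0.05,
                             pixel_size = 0.34) {
  stopifnot(d_tol > 0, d_target > d_tol)
  if (1 / (d_target - d_tol) > 1 / (2 * pixel_size))
    stop("annulus extends beyond Nyquist")
  fy <- fftfreq(nrow(box)) / pixel_size
  fx <- fftfreq(ncol(box)) / pixel_size
  r <- sqrt(outer(fy^2, fx^2, `+`))
  mask <- r >= 1 / (d_target + d_tol) & r <= 1 / (d_target - d_tol)
  if (!any(mask)) stop("empty resolution annulus at this box size")
  pw <- Mod(stats::fft(box))^2
  vmax <- max(pw[mask])
  idx <- which(mask & pw == vmax, arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE][1, ]
  structure(vmax, peak_index = unname(idx), radius = r[idx[1], idx[2]])
}

#' Squared-fluence normalization
#'
#' Divides a reflection power by the square of the mean counts per pixel of
#' the measured box, making it invariant to the number of electrons
#' reaching the detector.
#'
#' @param power Raw peak power.
#' @param mean_counts_per_pixel Mean counts of the same box.
#' @return Normalized power.
#' @export
normalize_power <- function(power, mean_counts_per_pixel) {
  if (mean_counts_per_pixel <= 0)
    stop("mean counts per pixel must be positive")
  power / mean_counts_per_pixel^2
}

#' Measure a defocus series
#'
#' Per-frame normalized Pt-reflection power; the series maximum is the
#' representative value (the frame of maximal reflection intensity), ties
#' resolved towards the lowest defocus.
#'
#' @param series A \code{defocus_series} (aligned).
#' @param center Optional 0-based (row, col) box centre; default the frame
#'   centre.
#' @param box_size Optional box side in px; default the full frame.
#' @param d_target,d_tol Annulus parameters, Angstrom.
#' @return A \code{reflection_measurement}.
#' @export
measure_series <- function(series, center = NULL, box_size = NULL,
                           d_target = 2.26, d_tol = 0.05) {
  frames <- series$frames
  px <- series$pixel_size
  n <- nrow(frames[[1]])
  if (is.null(box_size)) box_size <- n
  if (is.null(center)) center <- c((n - 1) / 2, (n - 1) / 2)
  pows <- vapply(frames, function(f) {
    b <- box_out(f, center, box_size)
    normalize_power(as.numeric(reflection_power(b, d_target, d_tol, px)),
                    mean(b))
  }, numeric(1))
  imax <- which.max(pows)   # first maximum = lowest defocus on the grid
  structure(list(per_defocus_power = pows,
                 representative = pows[imax],
                 defocus_at_max = series$defocus_list[imax],
                 defocus_list = series$defocus_list),
            class = "reflection_measurement")
}

#' @export
print.reflection_measurement <- function(x, ...) {
  cat(sprintf(
    "<reflection_measurement: representative %.6g at defocus %g A (%d frames)>\n",
    x$representative, x$defocus_at_max, length(x$per_defocus_power)))
  invisible(x)
}

## ---- ensemble statistics -------------------------------------------------

#' Ensemble mean, SD and SEM
#'
#' Sample SD (n-1 denominator); SEM = SD/sqrt(n).
#'
#' @param values Numeric vector, length >= 2.
#' @return An \code{ensemble_stats} list: n, mean, sd, sem.
#' @export
ensemble_stats <- function(values) {
  n <- length(values)
  if (n < 2) stop("ensemble_stats needs at least two values")
  s <- stats::sd(values)
  structure(list(n = n, mean = mean(values), sd = s, sem = s / sqrt(n)),
            class = "ensemble_stats")
}

#' @export
print.ensemble_stats <- function(x, ...) {
  cat(sprintf("n = %d, mean = %.6g +/- %.3g (SEM), SD = %.3g\n",
              x$n, x$mean, x$sem, x$sd))
  invisible(x)
}

#' Pooled two-sample Student's t-test
#'
#' Pooled-variance t with n1+n2-2 degrees of freedom, two-sided
#' (\code{welch = TRUE} switches to the Welch form). Two identical
#' zero-variance samples give t = 0, p = 1 by convention.
#'
#' @param top,bottom Numeric vectors, each of length >= 2.
#' @param welch Use the Welch unequal-variance form instead.
#' @return List with \code{t} and two-sided \code{p}.
#' @export
two_sample_t <- function(top, bottom, welch = FALSE) {
  stopifnot(length(top) >= 2, length(bottom) >= 2)
  if (stats::sd(top) == 0 && stats::sd(bottom) == 0) {
    if (mean(top) == mean(bottom)) return(list(t = 0, p = 1))
    return(list(t = Inf * sign(mean(top) - mean(bottom)), p = 0))
  }
  tt <- stats::t.test(top, bottom, var.equal = !welch)
  list(t = unname(tt$statistic), p = unname(tt$p.value))
}

#' Ratio of side means with propagated uncertainty
#'
#' \code{R = mean_top/mean_bottom};
#' \code{sigma_R = R sqrt((sem_top/mean_top)^2 + (sem_bottom/mean_bottom)^2)}
#' (first-order propagation).
#'
#' @param stats_top,stats_bottom \code{ensemble_stats} objects (or lists
#'   with \code{mean} and \code{sem}).
#' @return List with \code{ratio} and \code{sd}.
#' @export
ratio_with_error <- function(stats_top, stats_bottom) {
  if (stats_bottom$mean <= 0)
    stop("ratio undefined: bottom mean must be positive")
  r <- stats_top$mean / stats_bottom$mean
  s <- r * sqrt((stats_top$sem / stats_top$mean)^2 +
                (stats_bottom$sem / stats_bottom$mean)^2)
  list(ratio = r, sd = s)
}

#' Sigma-exclusion statistic
#'
#' Distance between an experimental and a simulated ratio in units of their
#' combined standard error:
#' \code{|R_exp - R_sim| / sqrt(sigma_exp^2 + sigma_sim^2)}.
#'
#' @param r_exp,sigma_exp Experimental ratio and uncertainty.
#' @param r_sim,sigma_sim Simulated ratio and uncertainty.
#' @return Exclusion distance in sigma.
#' @export
sigma_exclusion <- function(r_exp, sigma_exp, r_sim, sigma_sim) {
  stopifnot(sigma_exp >= 0, sigma_sim >= 0)
  if (sigma_exp == 0 && sigma_sim == 0)
    stop("sigma_exclusion undefined when both uncertainties are zero")
  abs(r_exp - r_sim) / sqrt(sigma_exp^2 + sigma_sim^2)
}

#' Compare the two particle ensembles
#'
#' Per-side mean/SD/SEM, pooled two-sample t-test, ratio of means with
#' propagated uncertainty, and (optionally) sigma-exclusion statistics
#' against supplied simulated scenario ratios.
#'
#' @param top_values,bottom_values Per-particle representative normalized
#'   powers.
#' @param simulated Optional named list of \code{list(ratio, sd)} simulated
#'   references.
#' @param welch Use the Welch t-test form.
#' @return A \code{side_comparison} object.
#' @export
compare_sides <- function(top_values, bottom_values, simulated = NULL,
                          welch = FALSE) {
  st <- ensemble_stats(top_values)
  sb <- ensemble_stats(bottom_values)
  tt <- two_sample_t(top_values, bottom_values, welch = welch)
  rr <- ratio_with_error(st, sb)
  excl <- NULL
  if (!is.null(simulated))
    excl <- vapply(simulated, function(s)
      sigma_exclusion(rr$ratio, rr$sd, s$ratio, s$sd), numeric(1))
  structure(list(stats_top = st, stats_bottom = sb,
                 t_statistic = tt$t, p_value = tt$p,
                 ratio = rr$ratio, ratio_sd = rr$sd, exclusions = excl),
            class = "side_comparison")
}

#' @export
print.side_comparison <- function(x, ...) {
  cat("Top/bottom ensemble comparison\n")
  cat("  top:    "); print(x$stats_top)
  cat("  bottom: "); print(x$stats_bottom)
  cat(sprintf("  pooled t = %.4g, two-sided p = %.4g\n",
              x$t_statistic, x$p_value))
  cat(sprintf("  ratio = %.4g +/- %.4g\n", x$ratio, x$ratio_sd))
  if (!is.null(x$exclusions))
    for (nm in names(x$exclusions))
      cat(sprintf("  exclusion vs %s: %.3g sigma\n", nm, x$exclusions[nm]))
  invisible(x)
}

#' @export
summary.side_comparison <- function(object, ...) {
  c(ratio = object$ratio, ratio_sd = object$ratio_sd,
    t = object$t_statistic, p = object$p_value,
    mean_top = object$stats_top$mean, mean_bottom = object$stats_bottom$mean)
}

#' Render-and-measure a synthetic ensemble (streaming)
#'
#' Generates each planned particle's defocus series, measures it
#' immediately, and discards the frames, so arbitrarily large ensembles fit
#' in memory. Frames carry no injected drift, so alignment is the identity
#' and is skipped here; see \code{\link{align_series}} for drifted data.
#'
#' @inheritParams plan_ensemble
#' @param noise Poisson-realize the frames?
#' @return Data frame: truth columns plus defocus_at_max and
#'   representative_power.
#' @export
ensemble_measurements <- function(n_top, n_bottom, true_ratio,
                                  config = default_config(), seed = 1L,
                                  noise = TRUE) {
  truth <- plan_ensemble(n_top, n_bottom, true_ratio, config, seed)
  mp <- config$measurement
  res <- lapply(seq_len(nrow(truth)), function(i) {
    s <- render_particle_series(truth[i, ], config, noise = noise)
    m <- measure_series(s, d_target = mp$d_target_angstrom,
                        d_tol = mp$d_tol_angstrom)
    c(defocus_at_max = m$defocus_at_max,
      representative_power = m$representative)
  })
  cbind(truth, do.call(rbind, res))
}
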