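test_that("box_out follows the 0-based, round-half-up convention", {
  img <- matrix(seq_len(512 * 512), 512, 512)
  b <- box_out(img, c(256, 256), 250)
  # rows/cols 131..380, 0-based
  expect_equal(dim(b), c(250, 250))
  expect_equal(b[1, 1], img[132, 132])
  expect_equal(b[250, 250], img[381, 381])

  small <- matrix(1:16, 4, 4)
  expect_equal(box_out(small, c(1.5, 1.5), 4), small)  # identity crop
  expect_error(box_out(small, c(0, 0), 4), "out of image bounds")
})

test_that("reflection power matches the analytic cosine value", {
  n <- 128; px <- 0.34
  a <- 0.17; k <- 20
  d <- n * px / k
  img <- cosine_image(n, a, k)
  pw <- reflection_power(img, d, 0.05, px)
  expect_equal(as.numeric(pw), (a * n^2 / 2)^2, tolerance = 1e-6)
  expect_equal(attr(pw, "radius"), 1 / d, tolerance = 1e-9)

  # uniform image: all power at DC, annulus maximum is 0
  expect_equal(as.numeric(reflection_power(matrix(5, n, n), d, 0.05, px)), 0)
  expect_error(reflection_power(img, 0.6, 0.05, px), "Nyquist")
})

test_that("Pt and Al fringes resolve into disjoint annuli", {
  n <- 250; px <- 0.34
  img <- cosine_image(n, 0.1, round(n * px / 2.26)) +
         t(cosine_image(n, 0.2, round(n * px / 2.34))) - 2
  # Al fringe has twice the contrast, but the 2.26 A annulus must pick Pt
  pw <- reflection_power(img + 1, 2.26, 0.05, px)
  expect_equal(attr(pw, "radius"), round(n * px / 2.26) / (n * px),
               tolerance = 1e-9)
  pw_al <- reflection_power(img + 1, 2.34, 0.05, px)
  expect_gt(as.numeric(pw_al), as.numeric(pw))
})

test_that("squared-fluence normalization is scale-invariant", {
  expect_equal(normalize_power(100, 2), 25)
  n <- 64; px <- 0.34; d <- n * px / 9
  img <- cosine_image(n, 0.2, 9) * 7
  p1 <- normalize_power(as.numeric(reflection_power(img, d, 0.05, px)),
                        mean(img))
  p2 <- normalize_power(as.numeric(reflection_power(img * 3, d, 0.05, px)),
                        mean(img * 3))
  expect_equal(p1, p2, tolerance = 1e-12)
  expect_error(normalize_power(10, 0), "positive")
})

test_that("series measurement takes the maximum and is order-free", {
  cfg <- small_config()
  truth <- plan_ensemble(2, 2, 1, cfg, seed = 6)
  s <- render_particle_series(truth[1, ], cfg, noise = FALSE)
  m <- measure_series(s, d_target = 2.26)
  expect_equal(m$representative, max(m$per_defocus_power))
  # noise-free: argmax of measured power agrees with argmax of |ctf|
  lam <- electron_wavelength(300)
  expect_equal(m$defocus_at_max,
               s$defocus_list[which.max(abs(ctf(1 / 2.26, s$defocus_list,
                                               lam)))])
  # permuting frames does not change the representative value
  perm <- sample(seq_along(s$frames))
  s2 <- s; s2$frames <- s$frames[perm]; s2$defocus_list <- s$defocus_list[perm]
  m2 <- measure_series(s2, d_target = 2.26)
  expect_equal(m2$representative, m$representative)

  # all-zero fringes give a zero representative
  s0 <- render_series(list(), default_beam, c(-500, 0, 500), 0.34, 64L,
                      noise = FALSE)
  expect_equal(measure_series(s0, d_target = 2.26)$representative, 0)
})

test_that("alignment recovers known shifts", {
  n <- 64
  base <- smooth_test_image(n)
  mk <- function(dy, dx) iphase:::fourier_shift(base, dy, dx)

  # unshifted noiseless series: all shifts zero
  ser0 <- structure(list(frames = list(base, base, base),
                         defocus_list = 1:3, pixel_size = 0.34,
                         fluence = 60), class = "defocus_series")
  expect_equal(align_series(ser0, upsample = 1)$shifts,
               matrix(0, 3, 2))

  # integer offsets: relative shifts recovered exactly at upsample 1
  sh <- rbind(c(0, 0), c(3, -2), c(-5, 4), c(2, 2))
  ser <- structure(list(frames = lapply(1:4, function(i)
    mk(sh[i, 1], sh[i, 2])), defocus_list = 1:4, pixel_size = 0.34,
    fluence = 60), class = "defocus_series")
  got <- align_series(ser, upsample = 1)$shifts
  rel <- sweep(got, 2, got[1, ])
  expect_equal(rel, sweep(sh, 2, sh[1, ]), ignore_attr = TRUE)
  al <- align_series(ser, upsample = 10)$series$frames
  expect_lt(max(abs(al[[2]] - al[[1]])), 1e-8)

  # subpixel shifts recovered within 0.1 px at upsample 10
  shs <- rbind(c(0, 0), c(0.25, -0.25), c(-0.25, 0.5))
  ser2 <- structure(list(frames = lapply(1:3, function(i)
    mk(shs[i, 1], shs[i, 2])), defocus_list = 1:3, pixel_size = 0.34,
    fluence = 60), class = "defocus_series")
  got2 <- align_series(ser2, upsample = 10)$shifts
  rel2 <- sweep(got2, 2, got2[1, ])
  expect_lt(max(abs(rel2 - sweep(shs, 2, shs[1, ]))), 0.1)
})

test_that("ensemble statistics: mean, sample SD, SEM", {
  s <- ensemble_stats(c(1, 1, 1))
  expect_equal(c(s$mean, s$sd, s$sem), c(1, 0, 0))
  s2 <- ensemble_stats(c(1, 3))
  expect_equal(c(s2$mean, s2$sd, s2$sem), c(2, sqrt(2), 1))
  set.seed(8)
  x <- stats::rlnorm(91)
  s3 <- ensemble_stats(x)
  expect_equal(s3$sem, s3$sd / sqrt(91))
  expect_error(ensemble_stats(5), "at least two")
})

test_that("pooled t-test agrees with the closed form", {
  top <- c(1, 2, 3); bottom <- c(2, 3, 4)
  got <- two_sample_t(top, bottom)
  sp2 <- (2 * stats::var(top) + 2 * stats::var(bottom)) / 4
  t_manual <- (mean(top) - mean(bottom)) / sqrt(sp2 * (1 / 3 + 1 / 3))
  p_manual <- 2 * stats::pt(-abs(t_manual), df = 4)
  expect_equal(got$t, t_manual, tolerance = 1e-12)
  expect_equal(got$p, p_manual, tolerance = 1e-12)

  same <- two_sample_t(c(2, 2, 2), c(2, 2, 2))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  set.seed(12)
  a <- stats::rnorm(50, 5); b <- stats::rnorm(50, 5)
  r <- two_sample_t(a, b)
  expect_lt(abs(r$t), 3)
  expect_gt(r$p, 0.003)
})

test_that("ratio error propagation reproduces the experimental 1.00 +/- 0.10", {
  st <- list(mean = 1.37e6, sem = 9e4)
  sb <- list(mean = 1.37e6, sem = 1.1e5)
  r <- ratio_with_error(st, sb)
  expect_equal(r$ratio, 1.00, tolerance = 1e-12)
  expect_equal(r$sd, 0.10, tolerance = 0.05)

  same <- ratio_with_error(list(mean = 3, sem = 1), list(mean = 3, sem = 1))
  expect_equal(same$ratio, 1)
  dbl <- ratio_with_error(list(mean = 2.74e6, sem = 1.8e5),
                          list(mean = 2.74e6, sem = 2.2e5))
  expect_equal(dbl$ratio, r$ratio, tolerance = 1e-12)
  expect_equal(dbl$sd, r$sd, tolerance = 1e-12)
  expect_error(ratio_with_error(st, list(mean = 0, sem = 1)), "positive")
})

test_that("sigma exclusion is the combined-error distance", {
  expect_equal(sigma_exclusion(1.00, 0.10, 0.00650, 0.00009), 9.9,
               tolerance = 0.01)
  expect_equal(sigma_exclusion(1.00, 0.10, 99.3, 1.3), 75.4,
               tolerance = 0.01)
  expect_equal(sigma_exclusion(5, 1, 5, 2), 0)
  expect_error(sigma_exclusion(1, 0, 2, 0), "undefined")
})

test_that("compare_sides assembles the full comparison", {
  set.seed(77)
  top <- stats::rlnorm(30, log(10), 0.5)
  bottom <- stats::rlnorm(30, log(10), 0.5)
  cmp <- compare_sides(top, bottom,
                       simulated = list(s2 = list(ratio = 0.0065,
                                                  sd = 9e-5)))
  expect_s3_class(cmp, "side_comparison")
  expect_true(cmp$p_value >= 0 && cmp$p_value <= 1)
  expect_equal(cmp$ratio, mean(top) / mean(bottom))
  expect_gt(cmp$exclusions[["s2"]], 5)
  expect_output(print(cmp), "ratio")
})
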