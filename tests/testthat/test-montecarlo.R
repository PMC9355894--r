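test_that("loss-free materials give zero total loss and no signal", {
  cfg <- lossfree_config()
  beam <- config_beam(cfg)
  stack <- build_stack("top", cfg)
  set.seed(5)
  for (i in 1:20) expect_equal(sample_history(stack, beam)$total_loss, 0)
  for (s in 1:3)
    expect_equal(run_scenario(stack, beam, s, 1e4, seed = 7)$n_signal, 0)
  expect_equal(window_fraction(stack, beam, 1e4, seed = 7), 0)
})

test_that("per-layer event counts follow Poisson closed forms", {
  set.seed(31)
  al <- config_materials(default_cfg)$Al
  stack <- one_layer_stack(al, 1100)
  n <- 1e4
  k <- replicate(n, sum(sample_history(stack, default_beam)$events$kind ==
                          "inelastic"))
  mu <- 1100 / al$lambda_inel
  p1 <- mu * exp(-mu)                       # P(exactly one event)
  emp <- mean(k == 1)
  expect_lt(abs(emp - p1), 4 * sqrt(p1 * (1 - p1) / n))

  # mean elastic count in the Pt sublayer
  top <- build_stack("top", default_cfg)
  ke <- replicate(n, sum(sample_history(top, default_beam)$events$kind ==
                           "elastic"))
  mu_el <- 33.5 / config_materials(default_cfg)$Pt$lambda_el
  expect_lt(abs(mean(ke) - mu_el), 4 * sqrt(mu_el / n))
})

test_that("histories are depth-sorted with consistent total loss", {
  set.seed(41)
  top <- build_stack("top", default_cfg)
  for (i in 1:50) {
    h <- sample_history(top, default_beam)
    expect_false(is.unsorted(h$events$depth))
    expect_equal(h$total_loss, sum(h$events$loss))
    expect_true(all(h$events$loss[h$events$kind == "elastic"] == 0))
    expect_true(all(h$events$depth >= 0 &
                    h$events$depth < total_thickness(top)))
  }
})

test_that("the energy window is a closed 13-17 eV interval on total loss", {
  mk <- function(total) structure(list(total_loss = total),
                                  class = "electron_history")
  expect_true(passes_window(mk(15), default_beam))
  expect_true(passes_window(mk(13), default_beam))
  expect_true(passes_window(mk(17), default_beam))
  expect_false(passes_window(mk(0), default_beam))
  expect_false(passes_window(mk(30), default_beam))  # two Al plasmons
})

test_that("scenario predicates encode the event-sequence conditions", {
  # top stack: elastic in Pt at 10 A, inelastic (15 eV) in Al at 500 A
  h1 <- make_history(c("elastic", "inelastic"), c(10, 500), c(1L, 2L),
                     c(0, 15), particle_layer = 1L)
  expect_true(scenario_accepts(h1, 1))
  expect_false(scenario_accepts(h1, 2))
  expect_true(scenario_accepts(h1, 3))

  # bottom stack: inelastic in Al at 800 A, elastic in Pt at 1710 A
  h2 <- make_history(c("inelastic", "elastic"), c(800, 1710), c(2L, 3L),
                     c(15, 0), particle_layer = 3L)
  expect_true(scenario_accepts(h2, 1))
  expect_true(scenario_accepts(h2, 2))
  expect_false(scenario_accepts(h2, 3))

  # two elastic events in the particle fail every scenario
  h3 <- make_history(c("elastic", "elastic"), c(5, 20), c(1L, 1L),
                     c(0, 0), particle_layer = 1L)
  for (s in 1:3) expect_false(scenario_accepts(h3, s))
})

test_that("runs are bit-reproducible from the seed", {
  top <- build_stack("top", default_cfg)
  a <- run_scenario(top, default_beam, 2, 1e5, seed = 123)
  b <- run_scenario(top, default_beam, 2, 1e5, seed = 123)
  c <- run_scenario(top, default_beam, 2, 1e5, seed = 124)
  expect_identical(a$n_signal, b$n_signal)
  expect_false(isTRUE(all.equal(a$n_signal, c$n_signal)))
  expect_identical(window_fraction(top, default_beam, 1e5, 9),
                   window_fraction(top, default_beam, 1e5, 9))
})

test_that("Monte Carlo matches the closed-form oracle to 4 sigma binomial", {
  n <- 1e6
  for (orient in c("top", "bottom")) {
    stack <- build_stack(orient, default_cfg)
    for (s in 1:3) {
      p <- oracle_probability(stack, default_beam, s)
      got <- run_scenario(stack, default_beam, s, n,
                          seed = 1000 + s)$n_signal
      expect_lt(abs(got - n * p), 4 * sqrt(n * p * (1 - p)),
                label = sprintf("scenario %d %s count |%d - %.1f|",
                                s, orient, got, n * p))
    }
  }
})

test_that("window fraction matches its Poisson product closed form", {
  sup <- support_stack(default_cfg)
  n <- 2e5
  p <- oracle_window_fraction(sup, default_beam)
  # delta losses: exactly one Al plasmon, no C loss
  mats <- config_materials(default_cfg)
  p_manual <- stats::dpois(1, 1100 / mats$Al$lambda_inel) *
    stats::dpois(0, 600 / mats$C$lambda_inel)
  expect_equal(p, p_manual, tolerance = 1e-12)
  got <- window_fraction(sup, default_beam, n, seed = 77)
  expect_lt(abs(got - p), 4 * sqrt(p * (1 - p) / n))
})

test_that("scenario-1 ratio is symmetric under orientation", {
  est <- top_bottom_ratio(default_cfg, scenario = 1, n_electrons = 2e5,
                          n_repeats = 5, seed = 3001)
  expect_lt(abs(est$ratio - 1), 4 * est$sd)
})

test_that("ratio estimation propagates repeat spread and guards zero counts", {
  est <- top_bottom_ratio(default_cfg, scenario = 2, n_electrons = 2e5,
                          n_repeats = 3, seed = 881)
  expect_gt(est$sd, 0)
  expect_equal(est$ratio, est$mean_top / est$mean_bottom)
  expect_length(est$seeds, 6)
  expect_identical(length(intersect(est$seeds[1:3], est$seeds[4:6])), 0L)

  cfg0 <- lossfree_config()
  expect_error(top_bottom_ratio(cfg0, 1, 1e3, 2, seed = 5),
               "undefined ratio")
})
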