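## Closed-form oracle for the Monte Carlo acceptance probabilities.
##
## The probability that an electron is counted as signal factorizes into
## (i) exactly one elastic event in the particle layer, Poisson;
## (ii) over the elastic depth d* (uniform in the particle layer, integrated
##      on a midpoint grid), a sum over inelastic event-count configurations
##      in the regions the scenario allows, each weighted by Poisson
##      probabilities, times the probability that the total loss of those
##      events falls in the filter window;
## (iii) zero inelastic events in the regions the scenario forbids.
## Event counts per region are enumerated up to `kmax` (default 4); with the
## shipped mean free paths every region mean is <= 0.72, so the neglected
## Poisson tail is below 1e-6 per region.

## -- small discrete-distribution algebra ----------------------------------

dist_point <- function(v) list(val = v, p = 1)

dist_collapse <- function(d, digits = 9) {
  key <- round(d$val, digits)
  p <- rowsum(d$p, key)
  list(val = as.numeric(rownames(p)), p = p[, 1])
}

dist_convolve <- function(a, b) {
  val <- outer(a$val, b$val, `+`)
  p <- outer(a$p, b$p)
  dist_collapse(list(val = as.numeric(val), p = as.numeric(p)))
}

## distribution of the sum of k iid draws from a discrete loss model
kfold_loss_dist <- function(material, k) {
  loss <- material$loss
  if (k == 0) return(dist_point(0))
  switch(loss$kind,
    delta = dist_point(k * loss$center),
    tabulated = {
      d <- list(val = loss$table$ev, p = loss$table$weight)
      out <- d
      if (k > 1) for (i in seq_len(k - 1)) out <- dist_convolve(out, d)
      out
    },
    stop("kfold_loss_dist is only defined for discrete loss models"))
}

## P(total loss in closed [lo, hi]) for a set of (material, count) parts.
## Gaussian losses contribute exact normal moments; discrete parts are
## convolved exactly.
window_prob_total <- function(parts, lo, hi, cache) {
  disc <- dist_point(0)
  gmean <- 0; gvar <- 0
  for (pt in parts) {
    if (pt$k == 0) next
    loss <- pt$material$loss
    if (loss$kind == "gaussian") {
      gmean <- gmean + pt$k * loss$center
      gvar <- gvar + pt$k * loss$width^2
    } else {
      key <- paste0(pt$material$name, ":", pt$k)
      d <- cache[[key]]
      if (is.null(d)) {
        d <- kfold_loss_dist(pt$material, pt$k)
        cache[[key]] <- d
      }
      disc <- dist_convolve(disc, d)
    }
  }
  if (gvar > 0) {
    sum(disc$p * (stats::pnorm(hi, disc$val + gmean, sqrt(gvar)) -
                  stats::pnorm(lo, disc$val + gmean, sqrt(gvar))))
  } else {
    sum(disc$p[disc$val + gmean >= lo & disc$val + gmean <= hi])
  }
}

## regions of inelastic activity allowed by a scenario at elastic depth
## fraction f within the particle layer
scenario_regions <- function(stack, scenario, f) {
  p <- particle_index(stack)
  layers <- stack$layers
  mus <- vapply(layers, function(l) l$thickness / l$material$lambda_inel,
                numeric(1))
  allowed <- list(); forbidden <- 0
  for (i in seq_along(layers)) {
    m <- layers[[i]]$material
    if (i == p) {
      if (scenario == 1) {
        allowed[[length(allowed) + 1]] <- list(material = m, mu = mus[i])
      } else if (scenario == 2) {
        allowed[[length(allowed) + 1]] <- list(material = m, mu = mus[i] * f)
        forbidden <- forbidden + mus[i] * (1 - f)
      } else {
        allowed[[length(allowed) + 1]] <-
          list(material = m, mu = mus[i] * (1 - f))
        forbidden <- forbidden + mus[i] * f
      }
    } else if (scenario == 1 ||
               (scenario == 2 && i < p) || (scenario == 3 && i > p)) {
      allowed[[length(allowed) + 1]] <- list(material = m, mu = mus[i])
    } else {
      forbidden <- forbidden + mus[i]
    }
  }
  list(allowed = allowed, forbidden_mu = forbidden)
}

#' Deterministic signal probability (closed-form oracle)
#'
#' Computes, without sampling, the probability that an incident electron is
#' counted as signal under a scenario: exactly one elastic event in the
#' particle layer, total loss inside the filter window, and the scenario's
#' sequence condition. Independent of the Monte Carlo path; used to verify
#' it. Scenario 1's acceptance probability is a product of per-layer,
#' order-independent terms, so its top/bottom oracle ratio is exactly 1.
#'
#' @param stack A \code{specimen_stack} with exactly one particle layer.
#' @param beam A \code{beam_parameters}.
#' @param scenario Integer 1, 2 or 3.
#' @param grid_step Midpoint-grid step (Angstrom, <= 5) for the elastic
#'   depth integral within the particle layer.
#' @param kmax Per-region truncation of the inelastic event-count
#'   enumeration.
#' @return Probability (numeric scalar).
#' @export
oracle_probability <- function(stack, beam, scenario, grid_step = 1,
                               kmax = 4) {
  stopifnot(scenario %in% 1:3, grid_step <= 5, grid_step > 0)
  validate_stack(stack)
  p <- particle_index(stack)
  t_p <- stack$layers[[p]]$thickness
  mu_el <- t_p / stack$layers[[p]]$material$lambda_el
  p1_el <- stats::dpois(1, mu_el)
  lo <- beam$window_lo_ev; hi <- beam$window_hi_ev
  cache <- new.env(parent = emptyenv())

  n_grid <- max(1L, ceiling(t_p / grid_step))
  fgrid <- (seq_len(n_grid) - 0.5) / n_grid

  inner <- vapply(fgrid, function(f) {
    reg <- scenario_regions(stack, scenario, f)
    nr <- length(reg$allowed)
    counts <- as.matrix(expand.grid(rep(list(0:kmax), nr)))
    tot <- 0
    for (r in seq_len(nrow(counts))) {
      kk <- counts[r, ]
      pp <- 1
      parts <- vector("list", nr)
      for (j in seq_len(nr)) {
        pp <- pp * stats::dpois(kk[j], reg$allowed[[j]]$mu)
        parts[[j]] <- list(material = reg$allowed[[j]]$material, k = kk[j])
      }
      if (pp > 0)
        tot <- tot + pp * window_prob_total(parts, lo, hi, cache)
    }
    exp(-reg$forbidden_mu) * tot
  }, numeric(1))

  unname(p1_el * mean(inner))
}

#' Closed-form window fraction of a stack
#'
#' Probability that the total energy loss through all layers lies in the
#' filter window, with inelastic counts enumerated to \code{kmax} per layer.
#' Companion oracle for \code{\link{window_fraction}}.
#'
#' @inheritParams oracle_probability
#' @return Probability.
#' @export
oracle_window_fraction <- function(stack, beam, kmax = 4) {
  lo <- beam$window_lo_ev; hi <- beam$window_hi_ev
  cache <- new.env(parent = emptyenv())
  layers <- stack$layers
  nr <- length(layers)
  counts <- as.matrix(expand.grid(rep(list(0:kmax), nr)))
  tot <- 0
  for (r in seq_len(nrow(counts))) {
    kk <- counts[r, ]
    pp <- 1
    parts <- vector("list", nr)
    for (j in seq_len(nr)) {
      mu <- layers[[j]]$thickness / layers[[j]]$material$lambda_inel
      pp <- pp * stats::dpois(kk[j], mu)
      parts[[j]] <- list(material = layers[[j]]$material, k = kk[j])
    }
    if (pp > 0) tot <- tot + pp * window_prob_total(parts, lo, hi, cache)
  }
  unname(tot)
}

#' Oracle top/bottom ratio
#'
#' @inheritParams oracle_probability
#' @param config An \code{iphase_config}.
#' @return Ratio of oracle signal probabilities, top over bottom.
#' @export
oracle_ratio <- function(config, scenario, grid_step = 1, kmax = 4) {
  beam <- config_beam(config)
  oracle_probability(build_stack("top", config), beam, scenario,
                     grid_step, kmax) /
    oracle_probability(build_stack("bottom", config), beam, scenario,
                       grid_step, kmax)
}
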