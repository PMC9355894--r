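## Monte Carlo of electron scattering histories through a layer stack.
##
## Event statistics: within a layer of thickness t, elastic and inelastic
## event counts are independent Poisson with means t/lambda_el and
## t/lambda_inel; event depths are uniform within the layer. Elastic events
## are generated only in the particle layer: lattice signal in the Pt 111
## reflection requires elastic scattering by Pt, and elastic events in the
## support affect only reflections and backgrounds common to both
## orientations, which cancel in the top/bottom ratio.

#' Sample one electron scattering history
#'
#' Reference (per-electron) sampler used by the unit tests and small runs;
#' \code{\link{run_scenario}} uses an equivalent vectorized path.
#'
#' @param stack A \code{specimen_stack}.
#' @param beam A \code{beam_parameters} object.
#' @return An \code{electron_history}: a list with \code{events} (data frame
#'   of kind, depth, layer, loss, sorted by depth) and \code{total_loss} (eV).
#' @export
sample_history <- function(stack, beam) {
  validate_stack(stack)
  th <- layer_thicknesses(stack)
  off <- c(0, cumsum(th))
  kind <- character(0); depth <- numeric(0)
  layer <- integer(0); lossv <- numeric(0)
  for (i in seq_along(stack$layers)) {
    l <- stack$layers[[i]]
    if (l$is_particle) {
      ne <- stats::rpois(1, l$thickness / l$material$lambda_el)
      if (ne > 0) {
        kind <- c(kind, rep("elastic", ne))
        depth <- c(depth, off[i] + stats::runif(ne, 0, l$thickness))
        layer <- c(layer, rep(i, ne)); lossv <- c(lossv, rep(0, ne))
      }
    }
    ni <- stats::rpois(1, l$thickness / l$material$lambda_inel)
    if (ni > 0) {
      kind <- c(kind, rep("inelastic", ni))
      depth <- c(depth, off[i] + stats::runif(ni, 0, l$thickness))
      layer <- c(layer, rep(i, ni))
      lossv <- c(lossv, sample_loss(l$material, ni))
    }
  }
  o <- order(depth)
  ev <- data.frame(kind = kind[o], depth = depth[o], layer = layer[o],
                   loss = lossv[o])
  structure(list(events = ev, total_loss = sum(lossv),
                 particle_layer = tryCatch(particle_index(stack),
                                           error = function(e) NA_integer_)),
            class = "electron_history")
}

#' Does a history pass the energy filter?
#'
#' True iff the total energy loss lies in the closed filter window.
#'
#' @param history An \code{electron_history}.
#' @param beam A \code{beam_parameters}.
#' @return Logical.
#' @export
passes_window <- function(history, beam) {
  history$total_loss >= beam$window_lo_ev &&
    history$total_loss <= beam$window_hi_ev
}

#' Scenario sequence predicate
#'
#' All three scenarios require exactly one elastic event inside the particle
#' layer, at depth d*. Scenario 1 imposes no further condition (inelastic
#' events may happen anywhere); scenario 2 additionally forbids inelastic
#' events after d*; scenario 3 forbids them before d*. Callers apply the
#' energy window separately (\code{\link{passes_window}}).
#'
#' @param history An \code{electron_history} (from a stack with a particle).
#' @param scenario Integer 1, 2 or 3.
#' @return Logical.
#' @export
scenario_accepts <- function(history, scenario) {
  stopifnot(scenario %in% 1:3)
  ev <- history$events
  p <- history$particle_layer
  if (is.na(p)) stop("history was sampled from a stack without a particle")
  el <- ev$kind == "elastic" & ev$layer == p
  if (sum(el) != 1) return(FALSE)
  dstar <- ev$depth[el]
  inel <- ev$depth[ev$kind == "inelastic"]
  switch(scenario,
         TRUE,
         !any(inel > dstar),
         !any(inel < dstar))
}

## vectorized loss sums: total loss of `counts[i]` iid single-event draws
sample_loss_sums <- function(material, counts) {
  loss <- material$loss
  n <- length(counts)
  switch(loss$kind,
    delta = counts * loss$center,
    gaussian = {
      out <- counts * loss$center
      pos <- counts > 0
      if (any(pos))
        out[pos] <- stats::rnorm(sum(pos), out[pos],
                                 loss$width * sqrt(counts[pos]))
      out
    },
    tabulated = {
      out <- numeric(n)
      tot <- sum(counts)
      if (tot > 0) {
        draws <- sample(loss$table$ev, tot, replace = TRUE,
                        prob = loss$table$weight)
        idx <- rep.int(seq_len(n), counts)
        s <- rowsum(draws, idx)
        out[as.integer(rownames(s))] <- s[, 1]
      }
      out
    })
}

#' Run one Monte Carlo scenario
#'
#' Counts electrons "contributing to signal": exactly one elastic event in
#' the particle, total loss inside the filter window, and the scenario's
#' event-sequence condition. Fully reproducible from \code{seed} at fixed
#' \code{n_electrons} and block size.
#'
#' @param stack A \code{specimen_stack} with exactly one particle layer.
#' @param beam A \code{beam_parameters}.
#' @param scenario Integer 1, 2 or 3.
#' @param n_electrons Number of incident electrons.
#' @param seed Integer RNG seed for this run.
#' @param block_size Internal vectorization block (fixed default keeps runs
#'   bit-reproducible).
#' @return A \code{scenario_counts} list: scenario, orientation,
#'   n_electrons, n_signal, seed.
#' @export
run_scenario <- function(stack, beam, scenario, n_electrons, seed,
                         block_size = 2e6) {
  stopifnot(scenario %in% 1:3, n_electrons >= 1)
  validate_stack(stack)
  p <- particle_index(stack)
  layers <- stack$layers
  t_p <- layers[[p]]$thickness
  mu_el <- t_p / layers[[p]]$material$lambda_el
  lo <- beam$window_lo_ev; hi <- beam$window_hi_ev
  set.seed(as.integer(seed))
  n_signal <- 0
  remaining <- n_electrons
  while (remaining > 0) {
    m <- min(remaining, block_size)
    remaining <- remaining - m
    k_el <- stats::rpois(m, mu_el)
    cand <- which(k_el == 1L)
    nc <- length(cand)
    if (nc == 0) next
    u <- stats::runif(nc)           # d* as a fraction of the particle layer
    total <- numeric(nc)
    ok <- rep(TRUE, nc)
    for (i in seq_along(layers)) {
      l <- layers[[i]]
      mu <- l$thickness / l$material$lambda_inel
      k <- if (mu > 0) stats::rpois(nc, mu) else integer(nc)
      total <- total + sample_loss_sums(l$material, k)
      if (i == p) {
        n_before <- stats::rbinom(nc, k, u)
        if (scenario == 2) ok <- ok & (k - n_before) == 0L
        if (scenario == 3) ok <- ok & n_before == 0L
      } else if (scenario == 2 && i > p) {
        ok <- ok & k == 0L
      } else if (scenario == 3 && i < p) {
        ok <- ok & k == 0L
      }
    }
    n_signal <- n_signal + sum(ok & total >= lo & total <= hi)
  }
  structure(list(scenario = scenario, orientation = stack$orientation,
                 n_electrons = n_electrons, n_signal = n_signal,
                 seed = as.integer(seed)),
            class = "scenario_counts")
}

#' Fraction of the beam transmitted by the energy filter
#'
#' Fraction of all incident electrons whose total energy loss lies in the
#' filter window — no elastic or scenario condition. The stack may lack a
#' particle layer (bare support foil).
#'
#' @inheritParams run_scenario
#' @return Fraction in [0, 1].
#' @export
window_fraction <- function(stack, beam, n_electrons, seed,
                            block_size = 2e6) {
  stopifnot(n_electrons >= 1)
  lo <- beam$window_lo_ev; hi <- beam$window_hi_ev
  set.seed(as.integer(seed))
  n_in <- 0
  remaining <- n_electrons
  while (remaining > 0) {
    m <- min(remaining, block_size)
    remaining <- remaining - m
    total <- numeric(m)
    for (l in stack$layers) {
      mu <- l$thickness / l$material$lambda_inel
      k <- if (mu > 0) stats::rpois(m, mu) else integer(m)
      total <- total + sample_loss_sums(l$material, k)
    }
    n_in <- n_in + sum(total >= lo & total <= hi)
  }
  n_in / n_electrons
}

#' Top/bottom signal ratio for one scenario
#'
#' Runs the Monte Carlo \code{n_repeats} times per orientation with disjoint
#' seed ranges (top: seed, ..., seed+n_repeats-1; bottom: the next
#' n_repeats) and forms the ratio of mean signal counts, with a first-order
#' propagated uncertainty from the per-orientation standard errors over
#' repeats.
#'
#' @param config An \code{iphase_config}.
#' @param scenario Integer 1, 2 or 3.
#' @param n_electrons Electrons per run.
#' @param n_repeats Repeats per orientation (>= 2).
#' @param seed Base integer seed.
#' @return A \code{ratio_estimate} object.
#' @export
top_bottom_ratio <- function(config, scenario, n_electrons = 1e6,
                             n_repeats = 10, seed = 1) {
  stopifnot(n_repeats >= 2)
  beam <- config_beam(config)
  top <- build_stack("top", config)
  bottom <- build_stack("bottom", config)
  seeds_top <- seed + seq_len(n_repeats) - 1L
  seeds_bot <- seed + n_repeats + seq_len(n_repeats) - 1L
  ct <- vapply(seeds_top, function(s)
    run_scenario(top, beam, scenario, n_electrons, s)$n_signal, numeric(1))
  cb <- vapply(seeds_bot, function(s)
    run_scenario(bottom, beam, scenario, n_electrons, s)$n_signal, numeric(1))
  mt <- mean(ct); mb <- mean(cb)
  if (mb == 0) stop("undefined ratio: mean bottom signal count is zero")
  sem_t <- stats::sd(ct) / sqrt(n_repeats)
  sem_b <- stats::sd(cb) / sqrt(n_repeats)
  ratio <- mt / mb
  sdv <- ratio * sqrt((sem_t / mt)^2 + (sem_b / mb)^2)
  structure(list(scenario = scenario, ratio = ratio, sd = sdv,
                 n_repeats = n_repeats, n_electrons = n_electrons,
                 seeds = c(seeds_top, seeds_bot),
                 counts_top = ct, counts_bottom = cb,
                 mean_top = mt, mean_bottom = mb),
            class = "ratio_estimate")
}

#' @export
print.ratio_estimate <- function(x, ...) {
  cat(sprintf(
    "Top/bottom signal ratio, scenario %d\n  ratio = %.5g +/- %.3g  (%d repeats x %g electrons per orientation)\n  mean counts: top %.6g, bottom %.6g\n",
    x$scenario, x$ratio, x$sd, x$n_repeats, x$n_electrons,
    x$mean_top, x$mean_bottom))
  invisible(x)
}

#' @export
summary.ratio_estimate <- function(object, ...) {
  out <- c(scenario = object$scenario, ratio = object$ratio, sd = object$sd,
           rel_sd = object$sd / object$ratio,
           n_repeats = object$n_repeats, n_electrons = object$n_electrons)
  class(out) <- "summary.ratio_estimate"
  out
}

#' @export
print.summary.ratio_estimate <- function(x, ...) {
  print(unclass(x)); invisible(x)
}
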