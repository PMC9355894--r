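#' Beam parameters
#'
#' Bundle of illumination and energy-filter settings. Defaults correspond to
#' 300 keV imaging with a 4 eV filter slit centred on the 15 eV aluminium
#' plasmon, 15 e-/A^2/s for 4 s (60 e-/A^2 per image).
#'
#' @param energy_kev Primary beam energy in keV.
#' @param window_lo_ev,window_hi_ev Energy-loss filter window edges in eV
#'   (closed interval).
#' @param fluence_rate Electron flux on the specimen, e-/A^2/s.
#' @param exposure Exposure time per image, s.
#' @return An object of class \code{beam_parameters}.
#' @export
beam_parameters <- function(energy_kev = 300, window_lo_ev = 13,
                            window_hi_ev = 17, fluence_rate = 15,
                            exposure = 4) {
  if (!is.numeric(energy_kev) || energy_kev <= 0)
    stop("beam energy must be positive")
  if (window_lo_ev >= window_hi_ev)
    stop("window_lo_ev must be less than window_hi_ev")
  if (fluence_rate <= 0 || exposure <= 0)
    stop("fluence_rate and exposure must be positive")
  structure(list(energy_kev = energy_kev,
                 window_lo_ev = window_lo_ev,
                 window_hi_ev = window_hi_ev,
                 fluence_rate = fluence_rate,
                 exposure = exposure),
            class = "beam_parameters")
}

#' Per-image fluence
#'
#' @param beam A \code{beam_parameters} object.
#' @return Fluence in e-/A^2 delivered per image (rate times exposure).
#' @export
beam_fluence <- function(beam) beam$fluence_rate * beam$exposure

## ---- single-event energy-loss models ------------------------------------

#' Energy-loss models for a single inelastic event
#'
#' A material's single-event loss spectrum. Multiple losses along one
#' trajectory add: a 30 eV total loss in aluminium arises from two 15 eV
#' plasmon events, never from a single 30 eV event.
#'
#' @param center_ev Loss of the delta model / mean of the gaussian model, eV.
#' @param width_ev Standard deviation of the gaussian model, eV.
#' @param ev,weight Support points (eV) and probabilities of the tabulated
#'   model. Weights must be non-negative and sum to 1 (within 1e-6) unless
#'   \code{normalize = TRUE}.
#' @param normalize If \code{TRUE}, rescale tabulated weights to sum to 1.
#' @return An object of class \code{loss_model}.
#' @export
loss_delta <- function(center_ev) {
  stopifnot(is.numeric(center_ev), length(center_ev) == 1, center_ev >= 0)
  structure(list(kind = "delta", center = center_ev, width = 0),
            class = "loss_model")
}

#' @rdname loss_delta
#' @export
loss_gaussian <- function(center_ev, width_ev) {
  stopifnot(is.numeric(center_ev), center_ev >= 0,
            is.numeric(width_ev), width_ev > 0)
  structure(list(kind = "gaussian", center = center_ev, width = width_ev),
            class = "loss_model")
}

#' @rdname loss_delta
#' @export
loss_tabulated <- function(ev, weight, normalize = FALSE) {
  if (length(ev) != length(weight) || length(ev) == 0)
    stop("ev and weight must be non-empty vectors of equal length")
  if (any(weight < 0)) stop("loss-table weights must be non-negative")
  if (any(ev < 0)) stop("loss-table energies must be non-negative")
  s <- sum(weight)
  if (normalize) {
    if (s <= 0) stop("loss-table weights sum to zero")
    weight <- weight / s
  } else if (abs(s - 1) > 1e-6) {
    stop("loss-table weights must sum to 1 (got ", format(s), ")")
  }
  o <- order(ev)
  structure(list(kind = "tabulated", table = data.frame(ev = ev[o],
                                                        weight = weight[o])),
            class = "loss_model")
}

validate_loss <- function(loss) {
  if (!inherits(loss, "loss_model")) stop("loss must be a loss_model")
  switch(loss$kind,
    delta = stopifnot(loss$width == 0),
    gaussian = stopifnot(loss$width > 0),
    tabulated = {
      if (abs(sum(loss$table$weight) - 1) > 1e-6)
        stop("tabulated loss weights must sum to 1")
    },
    stop("unknown loss model kind: ", loss$kind))
  invisible(loss)
}

## ---- materials ----------------------------------------------------------

#' Define a scattering material
#'
#' A material is summarised, at fixed beam energy, by its elastic and
#' inelastic mean free paths and a single-event energy-loss model. Mean free
#' paths are treated as independent of depth and of prior losses (a 15 eV
#' loss at 300 keV changes them by a relative 1e-4 or less).
#'
#' @param name Identifier, e.g. \code{"Al"}.
#' @param lambda_el Elastic mean free path, Angstrom.
#' @param lambda_inel Inelastic mean free path, Angstrom. \code{Inf} is
#'   allowed and describes a loss-free material.
#' @param loss A \code{loss_model}.
#' @return An object of class \code{material}.
#' @export
#' @examples
#' al <- make_material("Al", 420, 2220, loss_delta(15))
make_material <- function(name, lambda_el, lambda_inel, loss) {
  stopifnot(is.character(name), length(name) == 1, nzchar(name))
  if (!is.numeric(lambda_el) || length(lambda_el) != 1 || lambda_el <= 0)
    stop("lambda_el must be a positive length, got ", format(lambda_el))
  if (!is.numeric(lambda_inel) || length(lambda_inel) != 1 || lambda_inel <= 0)
    stop("lambda_inel must be a positive length, got ", format(lambda_inel))
  validate_loss(loss)
  structure(list(name = name, lambda_el = lambda_el,
                 lambda_inel = lambda_inel, loss = loss),
            class = "material")
}

#' @export
print.material <- function(x, ...) {
  cat(sprintf("<material %s>  lambda_el %g A, lambda_inel %g A, loss %s\n",
              x$name, x$lambda_el, x$lambda_inel, x$loss$kind))
  invisible(x)
}

#' Draw single-event energy losses
#'
#' @param material A \code{material}.
#' @param n Number of independent draws.
#' @return Numeric vector of losses in eV. For a delta model every draw
#'   equals the model's centre exactly.
#' @export
sample_loss <- function(material, n = 1) {
  loss <- material$loss
  switch(loss$kind,
    delta = rep(loss$center, n),
    gaussian = stats::rnorm(n, loss$center, loss$width),
    tabulated = sample(loss$table$ev, n, replace = TRUE,
                       prob = loss$table$weight))
}

#' Probability that a single loss event lands in an energy window
#'
#' Evaluated analytically from the loss model (no sampling); closed window.
#'
#' @param material A \code{material}.
#' @param window Numeric length-2, \code{c(lo, hi)} in eV.
#' @return Probability in [0, 1].
#' @export
window_probability <- function(material, window) {
  stopifnot(length(window) == 2, window[1] < window[2])
  loss <- material$loss
  switch(loss$kind,
    delta = as.numeric(loss$center >= window[1] & loss$center <= window[2]),
    gaussian = stats::pnorm(window[2], loss$center, loss$width) -
               stats::pnorm(window[1], loss$center, loss$width),
    tabulated = sum(loss$table$weight[loss$table$ev >= window[1] &
                                      loss$table$ev <= window[2]]))
}
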