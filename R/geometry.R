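## Specimen geometry: ordered layer stacks along the beam axis.
## The geometry is one-dimensional: the ray passes through the particle
## centre, the 50 A cylinder becomes a 33.5 A sublayer, and lateral extent
## is not modelled (it cancels in every top/bottom ratio).

new_layer <- function(material, thickness, is_particle = FALSE) {
  stopifnot(inherits(material, "material"))
  if (!is.numeric(thickness) || thickness <= 0)
    stop("layer thickness must be positive")
  list(material = material, thickness = thickness,
       is_particle = isTRUE(is_particle))
}

validate_stack <- function(stack) {
  if (!inherits(stack, "specimen_stack")) stop("not a specimen_stack")
  np <- sum(vapply(stack$layers, `[[`, logical(1), "is_particle"))
  if (np > 1) stop("at most one particle layer allowed, found ", np)
  invisible(stack)
}

new_stack <- function(layers, orientation) {
  structure(list(layers = layers, orientation = orientation),
            class = "specimen_stack")
}

#' Build the layered specimen for one orientation
#'
#' Layers are listed beam-entry side first. With the shipped defaults,
#' \code{"top"} gives [Pt 33.5 A (particle), Al 1100 A, C 600 A] and
#' \code{"bottom"} the mirror image; total thickness 1733.5 A either way.
#'
#' @param orientation \code{"top"} (particle on the beam-entry surface of the
#'   foil) or \code{"bottom"}.
#' @param config A run configuration, see \code{\link{default_config}}.
#' @return A \code{specimen_stack}.
#' @export
build_stack <- function(orientation = c("top", "bottom"),
                        config = default_config()) {
  orientation <- match.arg(orientation)
  mats <- config_materials(config)
  geo <- config$geometry
  layers <- list(
    new_layer(mats$Pt, geo$particle_height_angstrom, is_particle = TRUE),
    new_layer(mats$Al, geo$al_thickness_angstrom),
    new_layer(mats$C, geo$c_thickness_angstrom))
  if (orientation == "bottom") layers <- rev(layers)
  validate_stack(new_stack(layers, orientation))
}

#' Support-only stack (no particle)
#'
#' The Al + C foil traversed by the beam, without the Pt particle; used for
#' the transmitted window-fraction measurement.
#'
#' @inheritParams build_stack
#' @return A \code{specimen_stack} with no particle layer.
#' @export
support_stack <- function(config = default_config()) {
  mats <- config_materials(config)
  geo <- config$geometry
  new_stack(list(new_layer(mats$Al, geo$al_thickness_angstrom),
                 new_layer(mats$C, geo$c_thickness_angstrom)),
            orientation = "top")
}

#' Reverse a stack along the beam axis
#'
#' Layer order is reversed and the orientation label toggled; flipping twice
#' restores the original stack.
#'
#' @param stack A \code{specimen_stack}.
#' @return The flipped \code{specimen_stack}.
#' @export
flip <- function(stack) {
  validate_stack(stack)
  new_stack(rev(stack$layers),
            if (stack$orientation == "top") "bottom" else "top")
}

#' Total stack thickness
#' @param stack A \code{specimen_stack}.
#' @return Thickness in Angstrom.
#' @export
total_thickness <- function(stack)
  sum(vapply(stack$layers, `[[`, numeric(1), "thickness"))

layer_thicknesses <- function(stack)
  vapply(stack$layers, `[[`, numeric(1), "thickness")

particle_index <- function(stack) {
  idx <- which(vapply(stack$layers, `[[`, logical(1), "is_particle"))
  if (length(idx) != 1) stop("stack has no unique particle layer")
  idx
}

#' Axial depth of a point inside a stack
#'
#' Depth from the beam-entry plane of the point a given fraction of the way
#' through layer \code{layer} (1-based, beam-entry first). Strictly
#' increasing in (layer, fraction).
#'
#' @param stack A \code{specimen_stack}.
#' @param layer Layer index, 1-based.
#' @param fraction Position within the layer, in [0, 1].
#' @return Depth in Angstrom.
#' @export
cumulative_depth <- function(stack, layer, fraction) {
  validate_stack(stack)
  if (layer < 1 || layer > length(stack$layers))
    stop("layer index out of range")
  if (fraction < 0 || fraction > 1) stop("fraction must be in [0, 1]")
  th <- layer_thicknesses(stack)
  sum(th[seq_len(layer - 1)]) + fraction * th[layer]
}

#' @export
print.specimen_stack <- function(x, ...) {
  cat(sprintf("<specimen_stack, orientation %s, %g A total>\n",
              x$orientation, total_thickness(x)))
  for (l in x$layers)
    cat(sprintf("  %-3s %7.1f A%s\n", l$material$name, l$thickness,
                if (l$is_particle) "  [particle]" else ""))
  invisible(x)
}
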