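## Run configuration: one nested list, YAML on disk, units embedded in key
## names (…_angstrom, …_ev, …_kev) so a mis-scaled value is visible at the
## point of use. The shipped default lives in inst/extdata/default_config.yaml
## with a provenance comment per pinned number.

config_schema <- function() {
  list(
    config_version = NULL,
    beam = c("energy_kev", "window_lo_ev", "window_hi_ev",
             "fluence_rate_e_per_a2_s", "exposure_s"),
    materials = NA,  # free material names; per-material keys checked below
    geometry = c("particle_diameter_angstrom", "particle_height_angstrom",
                 "al_thickness_angstrom", "c_thickness_angstrom"),
    simulation = c("n_electrons", "n_repeats", "seed"),
    synthesis = c("box_px", "pixel_size_angstrom", "defocus_min_angstrom",
                  "defocus_max_angstrom", "defocus_step_angstrom",
                  "pt_d_spacing_angstrom", "al_d_spacing_angstrom",
                  "pt_amplitude_median", "al_amplitude", "dispersion_sdlog",
                  "min_angle_sep_deg"),
    measurement = c("d_target_angstrom", "d_tol_angstrom", "box_px"))
}

material_keys <- c("lambda_el_angstrom", "lambda_inel_angstrom", "loss")
loss_keys <- c("kind", "center_ev", "width_ev", "table_ev", "table_weight")

#' Default run configuration
#'
#' All physical constants of the experiment and simulation in one nested
#' list: beam and filter settings, material mean free paths and loss models,
#' layer thicknesses, simulation sizes, synthetic-micrograph parameters and
#' measurement parameters. The inelastic mean free paths are pinned from the
#' free-electron plasmon formula with relativistic kinematics at 300 keV;
#' elastic mean free paths from tabulated elastic cross sections at bulk
#' density. See the package vignette for the derivations.
#'
#' @return A named nested list of class \code{iphase_config}.
#' @export
default_config <- function() {
  pt_ev <- seq(4, 30, by = 2)
  pt_w <- c(0.05, 0.10, 0.13, 0.12, 0.10, 0.08, 0.07,
            0.065, 0.06, 0.055, 0.05, 0.045, 0.04, 0.035)
  cfg <- list(
    config_version = 1L,
    beam = list(energy_kev = 300, window_lo_ev = 13, window_hi_ev = 17,
                fluence_rate_e_per_a2_s = 15, exposure_s = 4),
    materials = list(
      Pt = list(lambda_el_angstrom = 75, lambda_inel_angstrom = 800,
                loss = list(kind = "tabulated", table_ev = pt_ev,
                            table_weight = pt_w)),
      Al = list(lambda_el_angstrom = 420, lambda_inel_angstrom = 2220,
                loss = list(kind = "delta", center_ev = 15)),
      C = list(lambda_el_angstrom = 1080, lambda_inel_angstrom = 1540,
               loss = list(kind = "delta", center_ev = 23))),
    geometry = list(particle_diameter_angstrom = 50,
                    particle_height_angstrom = 33.5,
                    al_thickness_angstrom = 1100,
                    c_thickness_angstrom = 600),
    simulation = list(n_electrons = 1e7, n_repeats = 10, seed = 1L),
    synthesis = list(box_px = 250L, pixel_size_angstrom = 0.34,
                     defocus_min_angstrom = -3500,
                     defocus_max_angstrom = 3500,
                     defocus_step_angstrom = 250,
                     pt_d_spacing_angstrom = 2.26,
                     al_d_spacing_angstrom = 2.34,
                     pt_amplitude_median = 0.12,
                     al_amplitude = 0.10,
                     dispersion_sdlog = 0.32,
                     min_angle_sep_deg = 10),
    measurement = list(d_target_angstrom = 2.26, d_tol_angstrom = 0.05,
                       box_px = 250L))
  structure(cfg, class = "iphase_config")
}

validate_config <- function(cfg) {
  schema <- config_schema()
  unknown <- setdiff(names(cfg), names(schema))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  for (sec in names(schema)) {
    keys <- schema[[sec]]
    if (is.null(keys) || anyNA(keys)) next
    bad <- setdiff(names(cfg[[sec]]), keys)
    if (length(bad))
      stop("unknown key(s) in config section '", sec, "': ",
           paste(bad, collapse = ", "))
  }
  for (m in c("Pt", "Al", "C"))
    if (is.null(cfg$materials[[m]]))
      stop("config is missing material '", m, "'")
  for (nm in names(cfg$materials)) {
    mt <- cfg$materials[[nm]]
    bad <- setdiff(names(mt), material_keys)
    if (length(bad))
      stop("unknown key(s) in material '", nm, "': ",
           paste(bad, collapse = ", "))
    badl <- setdiff(names(mt$loss), loss_keys)
    if (length(badl))
      stop("unknown key(s) in loss model of '", nm, "': ",
           paste(badl, collapse = ", "))
  }
  # constructing the objects runs the numeric validation
  config_materials(cfg)
  config_beam(cfg)
  if (cfg$geometry$al_thickness_angstrom <= 0 ||
      cfg$geometry$c_thickness_angstrom <= 0 ||
      cfg$geometry$particle_height_angstrom <= 0)
    stop("layer thicknesses must be positive")
  invisible(cfg)
}

loss_from_config <- function(spec) {
  switch(spec$kind,
    delta = loss_delta(spec$center_ev),
    gaussian = loss_gaussian(spec$center_ev, spec$width_ev),
    tabulated = loss_tabulated(unlist(spec$table_ev),
                               unlist(spec$table_weight)),
    stop("unknown loss kind in config: ", spec$kind))
}

#' Materialize the configured materials
#' @param config An \code{iphase_config}.
#' @return Named list of \code{material} objects.
#' @export
config_materials <- function(config) {
  out <- lapply(names(config$materials), function(nm) {
    m <- config$materials[[nm]]
    make_material(nm, m$lambda_el_angstrom, m$lambda_inel_angstrom,
                  loss_from_config(m$loss))
  })
  names(out) <- names(config$materials)
  out
}

#' Beam parameters from a configuration
#' @param config An \code{iphase_config}.
#' @return A \code{beam_parameters} object.
#' @export
config_beam <- function(config) {
  b <- config$beam
  beam_parameters(b$energy_kev, b$window_lo_ev, b$window_hi_ev,
                  b$fluence_rate_e_per_a2_s, b$exposure_s)
}

#' Load and validate a run configuration
#'
#' Reads YAML, fills any missing keys with the shipped defaults, rejects
#' unknown keys, and validates materials, beam and geometry.
#'
#' @param path Path to a YAML configuration file.
#' @return A validated \code{iphase_config}.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  cfg <- unclass(default_config())
  # merge one level down so partial configs are usable
  for (sec in names(raw)) {
    if (!is.list(raw[[sec]]) || !sec %in% names(cfg)) {
      cfg[[sec]] <- raw[[sec]]
    } else if (sec == "materials") {
      cfg$materials <- raw$materials
    } else {
      for (k in names(raw[[sec]])) cfg[[sec]][[k]] <- raw[[sec]][[k]]
    }
  }
  cfg <- structure(cfg, class = "iphase_config")
  validate_config(cfg)
  cfg
}

#' Write a configuration to YAML
#' @param config An \code{iphase_config}.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Stable hash of a configuration
#'
#' MD5 of a canonical YAML serialization; echoed into every output artifact
#' so results can be traced to the exact parameter set.
#'
#' @param config An \code{iphase_config}.
#' @return Hex digest string.
#' @export
config_hash <- function(config) {
  tf <- tempfile(fileext = ".yaml")
  on.exit(unlink(tf))
  yaml::write_yaml(unclass(config), tf)
  unname(tools::md5sum(tf))
}
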