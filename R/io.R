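.event_columns <- c("id", "time_s", "label", "area_um2", "deformation",
                    "area_ratio", "brightness_au", "diameter_um")

#' Read and write event tables as CSV
#'
#' The interchange dialect is a UTF-8 CSV with '.' decimal separator and
#' the canonical columns `id, time_s, label, area_um2, deformation,
#' area_ratio, brightness_au, diameter_um` (extra columns are preserved
#' with a warning). Values survive a write/read round trip to 12
#' significant digits. Basic physical invariants are enforced on load:
#' deformation in `[0, 1)`, positive areas, area ratio `>= 1`.
#'
#' @param path CSV file path.
#' @param events event tibble.
#' @return `read_events`: a validated tibble with canonical column order.
#' @export
read_events <- function(path) {
  ev <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(setdiff(.event_columns, "diameter_um"), names(ev))
  if (length(missing) > 0) {
    rlang::abort(paste0("event file lacks mandatory column(s): ",
                        paste(missing, collapse = ", ")),
                 class = "acoustosort_schema_error")
  }
  extra <- setdiff(names(ev), .event_columns)
  if (length(extra) > 0) {
    rlang::warn(paste0("event file carries unknown column(s), preserved: ",
                       paste(extra, collapse = ", ")))
  }
  validate_events(ev)
  dplyr::relocate(ev, dplyr::any_of(.event_columns))
}

#' @rdname read_events
#' @export
write_events <- function(events, path) {
  events <- dplyr::relocate(events, dplyr::any_of(.event_columns))
  readr::write_csv(events, path, progress = FALSE)
  invisible(path)
}

validate_events <- function(ev) {
  if (any(ev$deformation < 0 | ev$deformation >= 1, na.rm = TRUE)) {
    rlang::abort("event validation: deformation must lie in [0, 1)",
                 class = "acoustosort_schema_error")
  }
  if (any(ev$area_um2 <= 0, na.rm = TRUE)) {
    rlang::abort("event validation: area_um2 must be > 0",
                 class = "acoustosort_schema_error")
  }
  if (any(ev$area_ratio < 1 - 1e-9, na.rm = TRUE)) {
    rlang::abort("event validation: area_ratio must be >= 1",
                 class = "acoustosort_schema_error")
  }
  invisible(ev)
}

.config_sections <- c("geometry", "flow", "particle", "fluid", "field", "idt",
                      "gates", "simulation", "io")

.config_keys <- list(
  geometry = c("deformation_channel", "sorting_width", "sorting_length",
               "height", "bifurcation_offset", "focal_zone", "roi_to_sr",
               "volume"),
  flow = c("sample", "sheath"),
  particle = c("diameter", "density", "compressibility", "Y_T"),
  fluid = c("density", "compressibility", "sound_speed", "viscosity"),
  field = c("mode", "frequency", "wavelength", "pressure_amplitude",
            "energy_density", "pulse_duration"),
  idt = c("finger_periodicity", "substrate_sound_speed", "aperture",
          "focal_length", "design"),
  simulation = c("duration", "concentration", "mixture", "seed",
                 "coincidence_policy", "delay", "success_prob", "asf"),
  io = c("events", "frames", "report", "outcome")
)

#' Read and validate a YAML run configuration
#'
#' Every physical quantity in the file is a string with an explicit unit
#' (`"0.08 ul/s"`, `"135 MHz"`) parsed to SI by [parse_quantity()]. The
#' schema is closed: unknown sections or keys are rejected before any
#' computation, with a message naming the offender.
#'
#' @param path YAML file path.
#' @return nested list of class `run_config` with SI numeric values; gates
#'   are returned as [gate()] objects.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  unknown <- setdiff(names(raw), .config_sections)
  if (length(unknown) > 0) {
    rlang::abort(paste0("config: unknown section(s): ",
                        paste(unknown, collapse = ", ")),
                 class = "acoustosort_config_error")
  }
  for (sec in intersect(names(raw), names(.config_keys))) {
    bad <- setdiff(names(raw[[sec]]), .config_keys[[sec]])
    if (length(bad) > 0) {
      rlang::abort(sprintf("config: unknown key(s) in section '%s': %s",
                           sec, paste(bad, collapse = ", ")),
                   class = "acoustosort_config_error")
    }
  }
  cfg <- raw
  pq <- function(x, expect = NULL) {
    if (is.null(x)) NULL else parse_quantity(x, expect = expect)
  }
  if (!is.null(raw$geometry)) {
    gsec <- raw$geometry
    cfg$geometry <- channel_geometry(
      deformation_channel_um = si_to_unit(pq(gsec$deformation_channel, "length") %||% 30e-6, "um"),
      sorting_width_um = si_to_unit(pq(gsec$sorting_width, "length") %||% 50e-6, "um"),
      sorting_length_um = si_to_unit(pq(gsec$sorting_length, "length") %||% 130e-6, "um"),
      height_um = si_to_unit(pq(gsec$height, "length") %||% pq(gsec$deformation_channel, "length") %||% 30e-6, "um"),
      bifurcation_offset_um = si_to_unit(pq(gsec$bifurcation_offset, "length") %||% 5e-6, "um"),
      volume_nl = if (is.null(gsec$volume)) NULL else si_to_unit(pq(gsec$volume, "volume"), "nl"))
  }
  if (!is.null(raw$flow)) {
    cfg$flow <- flow_config(
      sample_ul_s = si_to_unit(pq(raw$flow$sample, "flow") %||% 1e-11, "ul/s"),
      sheath_ul_s = si_to_unit(pq(raw$flow$sheath, "flow") %||% 7e-11, "ul/s"))
  }
  if (!is.null(raw$fluid)) {
    cfg$fluid <- fluid_spec(
      density = pq(raw$fluid$density, "density") %||% 998,
      compressibility = pq(raw$fluid$compressibility, "compressibility") %||% 4.58e-10,
      sound_speed = pq(raw$fluid$sound_speed, "speed") %||% 1487,
      viscosity = pq(raw$fluid$viscosity, "viscosity") %||% 0.01)
  }
  if (!is.null(raw$particle)) {
    cfg$particle <- particle_spec(
      diameter = pq(raw$particle$diameter, "length"),
      density = pq(raw$particle$density, "density") %||% 1050,
      compressibility = pq(raw$particle$compressibility, "compressibility") %||% 4.0e-10,
      Y_T = raw$particle$Y_T %||% 1)
  }
  if (!is.null(raw$field)) {
    fsec <- raw$field
    cfg$field <- acoustic_field(
      mode = fsec$mode %||% "TSAW",
      frequency = pq(fsec$frequency, "frequency"),
      wavelength = pq(fsec$wavelength, "length"),
      pressure_amplitude = pq(fsec$pressure_amplitude, "pressure"),
      energy_density = pq(fsec$energy_density, "energy_density"),
      pulse_duration = pq(fsec$pulse_duration, "time") %||% 1e-3)
  }
  if (!is.null(raw$idt)) {
    cfg$idt <- idt_spec(
      finger_periodicity = pq(raw$idt$finger_periodicity, "length"),
      substrate_sound_speed = pq(raw$idt$substrate_sound_speed, "speed") %||% 3978,
      aperture = pq(raw$idt$aperture, "length") %||% 100e-6,
      focal_length = pq(raw$idt$focal_length, "length") %||% 170e-6,
      design = raw$idt$design %||% "focused")
  }
  if (!is.null(raw$gates)) {
    cfg$gates <- lapply(names(raw$gates), function(nm) {
      gg <- raw$gates[[nm]]
      known <- c("area_range", "deformation_max", "brightness_range",
                 "area_ratio_max", "polygon")
      bad <- setdiff(names(gg), known)
      if (length(bad) > 0) {
        rlang::abort(sprintf("config: unknown key(s) in gate '%s': %s",
                             nm, paste(bad, collapse = ", ")),
                     class = "acoustosort_config_error")
      }
      gate(nm,
           area_range = unlist(gg$area_range),
           deformation_max = gg$deformation_max,
           brightness_range = unlist(gg$brightness_range),
           area_ratio_max = gg$area_ratio_max %||% 1.08,
           polygon = if (is.null(gg$polygon)) NULL else
             do.call(rbind, lapply(gg$polygon, as.data.frame)))
    })
    names(cfg$gates) <- names(raw$gates)
  }
  if (!is.null(raw$simulation)) {
    s <- raw$simulation
    cfg$simulation <- list(
      duration_s = if (is.null(s$duration)) NULL else pq(s$duration, "time"),
      concentration_per_ml = if (is.null(s$concentration)) NULL else
        si_to_unit(pq(s$concentration, "concentration"), "cells/ml"),
      mixture = if (is.null(s$mixture)) NULL else unlist(s$mixture),
      seed = s$seed, coincidence_policy = s$coincidence_policy %||% "co-sort",
      delay_s = if (is.null(s$delay)) 1e-3 else pq(s$delay, "time"),
      success_prob = s$success_prob %||% 1,
      asf_um = if (is.null(s$asf)) 0 else si_to_unit(pq(s$asf, "length"), "um"))
  }
  structure(cfg, class = "run_config")
}

#' Serialize a sort report to JSON with provenance
#'
#' The JSON embeds the package version, the RNG seed and a hash of the
#' configuration, enough to regenerate the run exactly.
#'
#' @param report a `sort_report`.
#' @param path output JSON path.
#' @param seed the seed used for the run.
#' @param config the `run_config` (hashed into the report), or NULL.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, seed = NA_integer_, config = NULL) {
  payload <- c(unclass(report),
               list(tool_version = as.character(utils::packageVersion("acoustosort")),
                    seed = seed,
                    config_hash = if (is.null(config)) NA_character_ else rlang::hash(config)))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
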