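#' Acoustic material and field specifications
#'
#' Constructors for the objects entering the acoustofluidic force laws.
#' All values are SI: use [parse_quantity()] to convert config strings.
#'
#' @param diameter particle diameter (m).
#' @param density density (kg m^-3).
#' @param compressibility adiabatic compressibility (Pa^-1).
#' @param Y_T acoustic radiation factor (dimensionless, >= 0, default 1):
#'   the scattering-theory coefficient of the travelling-wave radiation
#'   force, dependent on particle mechanics and size; supplied by the user
#'   rather than computed.
#' @return `particle_spec`: list with the fields above plus derived
#'   `volume` (m^3, `pi d^3 / 6`).
#' @export
particle_spec <- function(diameter, density = 1050, compressibility = 4.0e-10,
                          Y_T = 1) {
  if (diameter <= 0 || density <= 0 || compressibility <= 0 || Y_T < 0) {
    rlang::abort("particle_spec: diameter, density, compressibility must be > 0 and Y_T >= 0",
                 class = "acoustosort_config_error")
  }
  structure(list(diameter = diameter, density = density,
                 compressibility = compressibility, Y_T = Y_T,
                 volume = pi * diameter^3 / 6),
            class = "particle_spec")
}

#' @rdname particle_spec
#' @param sound_speed speed of sound in the fluid (m s^-1); the default
#'   1487 is the measured value for the viscous methylcellulose-PBS
#'   measurement buffer.
#' @param viscosity dynamic viscosity (Pa s); default 0.01 is the effective
#'   in-channel value of the shear-thinning measurement buffer.
#' @return `fluid_spec`: density, compressibility, sound_speed, viscosity.
#' @export
fluid_spec <- function(density = 998, compressibility = 4.58e-10,
                       sound_speed = 1487, viscosity = 0.01) {
  vals <- c(density, compressibility, sound_speed, viscosity)
  if (any(vals <= 0)) {
    rlang::abort("fluid_spec: all parameters must be > 0",
                 class = "acoustosort_config_error")
  }
  structure(list(density = density, compressibility = compressibility,
                 sound_speed = sound_speed, viscosity = viscosity),
            class = "fluid_spec")
}

#' @rdname particle_spec
#' @param mode `"SSAW"` (standing wave) or `"TSAW"` (travelling wave).
#' @param frequency excitation frequency (Hz).
#' @param wavelength acoustic wavelength (m); required for SSAW.
#' @param pressure_amplitude acoustic pressure amplitude P0 (Pa); SSAW only.
#' @param energy_density time-averaged acoustic energy density <E>
#'   (J m^-3); TSAW only.
#' @param pulse_duration actuation pulse length (s), default 1 ms.
#' @return `acoustic_field` with derived wavenumber `k = 2 pi / lambda`.
#' @export
acoustic_field <- function(mode = c("TSAW", "SSAW"), frequency,
                           wavelength = NULL, pressure_amplitude = NULL,
                           energy_density = NULL, pulse_duration = 1e-3) {
  mode <- match.arg(mode)
  if (frequency <= 0 || pulse_duration <= 0) {
    rlang::abort("acoustic_field: frequency and pulse_duration must be > 0",
                 class = "acoustosort_config_error")
  }
  if (mode == "SSAW") {
    if (is.null(wavelength) || is.null(pressure_amplitude)) {
      rlang::abort("SSAW field requires wavelength and pressure_amplitude",
                   class = "acoustosort_config_error")
    }
    if (!is.null(energy_density)) {
      rlang::abort("energy_density is a TSAW parameter", class = "acoustosort_config_error")
    }
  } else {
    if (is.null(energy_density)) {
      rlang::abort("TSAW field requires energy_density",
                   class = "acoustosort_config_error")
    }
    if (!is.null(pressure_amplitude)) {
      rlang::abort("pressure_amplitude is a SSAW parameter", class = "acoustosort_config_error")
    }
  }
  structure(list(mode = mode, frequency = frequency, wavelength = wavelength,
                 pressure_amplitude = pressure_amplitude,
                 energy_density = energy_density,
                 pulse_duration = pulse_duration,
                 k = if (!is.null(wavelength)) 2 * pi / wavelength else NULL),
            class = "acoustic_field")
}

#' @rdname particle_spec
#' @param finger_periodicity IDT finger periodicity = acoustic wavelength
#'   on the substrate (m).
#' @param substrate_sound_speed SAW velocity on the piezoelectric substrate
#'   (m s^-1); default 3978 (128-degree Y-cut lithium niobate).
#' @param aperture acoustic aperture (m).
#' @param focal_length focal length for focused designs (m).
#' @param design `"straight"` or `"focused"`.
#' @return `idt_spec`.
#' @export
idt_spec <- function(finger_periodicity, substrate_sound_speed = 3978,
                     aperture = 100e-6, focal_length = 170e-6,
                     design = c("focused", "straight")) {
  design <- match.arg(design)
  if (finger_periodicity <= 0 || substrate_sound_speed <= 0 ||
      aperture <= 0 || focal_length <= 0) {
    rlang::abort("idt_spec: all dimensions must be > 0",
                 class = "acoustosort_config_error")
  }
  structure(list(finger_periodicity = finger_periodicity,
                 substrate_sound_speed = substrate_sound_speed,
                 aperture = aperture, focal_length = focal_length,
                 design = design),
            class = "idt_spec")
}

#' IDT design resonance frequency
#'
#' `f = v / lambda` with `v` the substrate SAW velocity and `lambda` the
#' finger periodicity. Fabricated devices typically resonate a few percent
#' below the design value; measured resonances should be configured as
#' overrides on the [acoustic_field()].
#'
#' @param idt an [idt_spec()].
#' @return frequency in Hz.
#' @examples
#' resonance_frequency(idt_spec(28e-6)) / 1e6  # 142.07 MHz design value
#' @export
resonance_frequency <- function(idt) {
  stopifnot(inherits(idt, "idt_spec"))
  idt$substrate_sound_speed / idt$finger_periodicity
}

#' Dimensionless kappa factor of travelling-wave scattering
#'
#' `kappa = 2 pi d_p f / C_f` — the ratio of particle circumference to the
#' acoustic wavelength in the fluid. It separates the radiation-force (ARF)
#' dominated regime of large particles from the streaming-drag (ASF)
#' dominated regime of small ones.
#'
#' @param diameter particle diameter (m); 0 allowed as a limit.
#' @param frequency excitation frequency (Hz).
#' @param sound_speed speed of sound in the fluid (m s^-1).
#' @return kappa, vectorized over `diameter`.
#' @examples
#' kappa_factor(2.25e-6, 135e6, 1487)  # ~1.28, the regime boundary
#' @export
kappa_factor <- function(diameter, frequency, sound_speed) {
  if (any(diameter < 0) || frequency <= 0 || sound_speed <= 0) {
    rlang::abort("kappa_factor: inputs must be positive (diameter may be 0)",
                 class = "acoustosort_domain_error")
  }
  2 * pi * diameter * frequency / sound_speed
}

#' Classify the dominant lateral transport mechanism
#'
#' Returns `"ARF"` (acoustic radiation force) when `kappa` strictly exceeds
#' the threshold, `"ASF"` (acoustic streaming flow drag) otherwise. The
#' default threshold 1.28 is the empirically suggested boundary; the
#' theoretical value 1 may be selected instead.
#'
#' @param kappa dimensionless kappa factor (>= 0), vectorized.
#' @param threshold regime boundary, default 1.28.
#' @return character vector of `"ARF"` / `"ASF"`.
#' @export
dominant_regime <- function(kappa, threshold = 1.28) {
  if (any(kappa < 0)) {
    rlang::abort("dominant_regime: kappa must be >= 0", class = "acoustosort_domain_error")
  }
  ifelse(kappa > threshold, "ARF", "ASF")
}

#' Acoustic contrast factor
#'
#' `phi = (5 rho_p - 2 rho_f) / (2 rho_p + rho_f) - beta_p / beta_f`.
#' Particles with `phi > 0` migrate to the standing-wave pressure node,
#' `phi < 0` to the antinode.
#'
#' @param particle a [particle_spec()].
#' @param fluid a [fluid_spec()].
#' @return signed dimensionless contrast factor.
#' @export
contrast_factor <- function(particle, fluid) {
  stopifnot(inherits(particle, "particle_spec"), inherits(fluid, "fluid_spec"))
  rp <- particle$density; rf <- fluid$density
  (5 * rp - 2 * rf) / (2 * rp + rf) - particle$compressibility / fluid$compressibility
}

#' Standing-wave acoustic radiation force
#'
#' One-dimensional SSAW radiation force on a small particle at distance `x`
#' from the pressure node:
#' `F = -(pi P0^2 V_p beta_f / (2 lambda)) * phi * sin(2 k x)`.
#' Zero at nodes and antinodes; restoring toward the node for `phi > 0`.
#'
#' @param field an [acoustic_field()] with `mode = "SSAW"`.
#' @param particle a [particle_spec()].
#' @param fluid a [fluid_spec()].
#' @param x distance from the pressure node (m), vectorized.
#' @return force in N (signed along x).
#' @export
ssaw_radiation_force <- function(field, particle, fluid, x) {
  stopifnot(inherits(field, "acoustic_field"))
  if (field$mode != "SSAW") {
    rlang::abort("ssaw_radiation_force requires an SSAW field",
                 class = "acoustosort_usage_error")
  }
  phi <- contrast_factor(particle, fluid)
  amp <- pi * field$pressure_amplitude^2 * particle$volume * fluid$compressibility /
    (2 * field$wavelength)
  -amp * phi * sin(2 * field$k * x)
}

#' Time-averaged travelling-wave radiation force
#'
#' `<F_ARF> = Y_T pi d_p^2 <E> / 4`, directed away from the transducer
#' (toward the target outlet). Scales with the particle cross-section.
#'
#' @param field an [acoustic_field()] with `mode = "TSAW"`.
#' @param particle a [particle_spec()], or a numeric vector of diameters (m)
#'   with `Y_T` taken from `Y_T`.
#' @param Y_T radiation factor used when `particle` is a plain diameter
#'   vector (default 1).
#' @return force in N (>= 0), vectorized over diameters.
#' @export
tsaw_radiation_force <- function(field, particle, Y_T = 1) {
  stopifnot(inherits(field, "acoustic_field"))
  if (field$mode != "TSAW") {
    rlang::abort("tsaw_radiation_force requires a TSAW field",
                 class = "acoustosort_usage_error")
  }
  if (is.null(field$energy_density)) {
    rlang::abort("TSAW field has no energy_density configured",
                 class = "acoustosort_config_error")
  }
  if (inherits(particle, "particle_spec")) {
    d <- particle$diameter
    Y_T <- particle$Y_T
  } else {
    d <- particle
  }
  Y_T * pi * d^2 * field$energy_density / 4
}

#' Stokes drag on a sphere
#'
#' `F_D = 3 pi eta d v`, opposing relative motion.
#'
#' @param fluid a [fluid_spec()].
#' @param diameter particle diameter (m).
#' @param v_rel relative velocity (m s^-1), vectorized.
#' @return drag force in N (same sign as `v_rel`).
#' @export
stokes_drag <- function(fluid, diameter, v_rel) {
  stopifnot(inherits(fluid, "fluid_spec"))
  if (any(diameter <= 0)) {
    rlang::abort("stokes_drag: diameter must be > 0", class = "acoustosort_domain_error")
  }
  3 * pi * fluid$viscosity * diameter * v_rel
}

#' Quasi-steady lateral displacement under a force pulse
#'
#' At the micrometre scale inertia is negligible (Re << 1): a constant
#' force balances Stokes drag immediately, so the particle moves at
#' terminal velocity for the pulse duration:
#' `dy = F tau / (3 pi eta d)`.
#'
#' @param force applied force (N), vectorized.
#' @param fluid a [fluid_spec()].
#' @param diameter particle diameter (m).
#' @param tau pulse duration (s).
#' @return displacement in m.
#' @export
lateral_displacement <- function(force, fluid, diameter, tau) {
  stopifnot(inherits(fluid, "fluid_spec"))
  if (any(diameter <= 0) || any(tau < 0)) {
    rlang::abort("lateral_displacement: diameter must be > 0 and tau >= 0",
                 class = "acoustosort_domain_error")
  }
  force * tau / (3 * pi * fluid$viscosity * diameter)
}

#' Map electrical drive power to an acoustic energy density
#'
#' Simple calibration helper: `<E> = efficiency * P / (focal_area * C_f)`
#' is deliberately not modelled; instead the user supplies a single
#' empirical conversion (J m^-3 per W) and this helper multiplies.
#'
#' @param power_w electrical power (W).
#' @param conversion energy density per watt (J m^-3 W^-1).
#' @return energy density in J m^-3.
#' @export
power_to_energy_density <- function(power_w, conversion) {
  if (power_w < 0 || conversion < 0) {
    rlang::abort("power_to_energy_density: inputs must be >= 0",
                 class = "acoustosort_config_error")
  }
  power_w * conversion
}
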