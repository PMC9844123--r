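#' Describe a univariate feature distribution
#'
#' A small distribution spec used by [population_spec()]: a family plus a
#' mean and coefficient of variation. `"normal"` samples are Gaussian;
#' `"lognormal"` samples have the requested arithmetic mean and CV.
#'
#' @param mean arithmetic mean of the feature.
#' @param cv coefficient of variation (sd/mean), `>= 0`.
#' @param family `"normal"` or `"lognormal"`.
#' @return a `dist_spec` list.
#' @export
dist_spec <- function(mean, cv = 0, family = c("normal", "lognormal")) {
  family <- match.arg(family)
  if (!is.finite(mean)) rlang::abort("dist_spec: mean must be finite", class = "acoustosort_config_error")
  if (!is.finite(cv) || cv < 0) {
    rlang::abort("dist_spec: cv must be >= 0", class = "acoustosort_config_error")
  }
  if (family == "lognormal" && mean <= 0) {
    rlang::abort("dist_spec: lognormal mean must be > 0", class = "acoustosort_config_error")
  }
  structure(list(mean = mean, cv = cv, family = family), class = "dist_spec")
}

sample_dist <- function(spec, n) {
  if (n == 0) return(numeric(0))
  sd <- spec$mean * spec$cv
  if (spec$family == "normal") {
    stats::rnorm(n, spec$mean, sd)
  } else {
    sigma2 <- log(1 + spec$cv^2)
    mu <- log(spec$mean) - sigma2 / 2
    stats::rlnorm(n, mu, sqrt(sigma2))
  }
}

#' Specify a particle or cell population
#'
#' Defines the feature distributions of one synthetic population of the kind
#' seen in deformability-cytometry scatter plots: projected area (um^2) or
#' physical diameter (um), deformation on `[0, 1)`, convex-hull area ratio
#' `>= 1`, and mean brightness (arbitrary grayscale units). If
#' `diameter_dist` is given the projected area is derived per event as
#' `pi d^2 / 4` (a sphere's cross-section) and `size_dist` is ignored;
#' otherwise the diameter is back-computed from the sampled area.
#'
#' @param label population label carried as ground truth on every event.
#' @param n number of events to draw by default.
#' @param size_dist [dist_spec()] for projected area in um^2.
#' @param deformation_dist [dist_spec()] for deformation; samples are
#'   truncated into `[0, 1)` by resampling.
#' @param brightness_dist [dist_spec()] for mean brightness (a.u.).
#' @param area_ratio_dist [dist_spec()] for the hull/raw area ratio; samples
#'   are reflected to stay `>= 1`.
#' @param diameter_dist optional [dist_spec()] for physical diameter in um.
#' @return a `population_spec` list.
#' @export
population_spec <- function(label, n,
                            size_dist = dist_spec(100, 0.1),
                            deformation_dist = dist_spec(0.05, 0.4),
                            brightness_dist = dist_spec(100, 0.05),
                            area_ratio_dist = dist_spec(1.02, 0.01),
                            diameter_dist = NULL) {
  if (!is.numeric(n) || n < 0 || n != round(n)) {
    rlang::abort("population_spec: n must be a non-negative integer",
                 class = "acoustosort_config_error")
  }
  for (d in list(size_dist, deformation_dist, brightness_dist, area_ratio_dist)) {
    stopifnot(inherits(d, "dist_spec"))
  }
  if (!is.null(diameter_dist)) stopifnot(inherits(diameter_dist, "dist_spec"))
  structure(list(label = as.character(label), n = as.integer(n),
                 size_dist = size_dist, deformation_dist = deformation_dist,
                 brightness_dist = brightness_dist,
                 area_ratio_dist = area_ratio_dist,
                 diameter_dist = diameter_dist),
            class = "population_spec")
}

#' Draw a ground-truth-labelled event table from one population
#'
#' @param spec a [population_spec()].
#' @param n override for `spec$n`.
#' @param seed optional integer seed for reproducibility.
#' @return tibble with columns `id`, `time_s` (NA; filled by arrival
#'   streams), `label`, `area_um2`, `deformation`, `area_ratio`,
#'   `brightness_au`, `diameter_um`.
#' @examples
#' generate_population(population_spec("beads", 5), seed = 1)
#' @export
generate_population <- function(spec, n = spec$n, seed = NULL) {
  stopifnot(inherits(spec, "population_spec"))
  if (!is.null(seed)) set.seed(seed)
  if (n == 0) return(empty_event_table())
  if (!is.null(spec$diameter_dist)) {
    diameter <- resample_positive(spec$diameter_dist, n)
    area <- pi * diameter^2 / 4
  } else {
    area <- resample_positive(spec$size_dist, n)
    diameter <- 2 * sqrt(area / pi)
  }
  deformation <- resample_interval(spec$deformation_dist, n, 0, 1 - 1e-9)
  brightness <- sample_dist(spec$brightness_dist, n)
  area_ratio <- 1 + abs(sample_dist(spec$area_ratio_dist, n) - 1)
  tibble::tibble(
    id = seq_len(n),
    time_s = NA_real_,
    label = spec$label,
    area_um2 = area,
    deformation = deformation,
    area_ratio = area_ratio,
    brightness_au = brightness,
    diameter_um = diameter
  )
}

empty_event_table <- function() {
  tibble::tibble(
    id = integer(0), time_s = numeric(0), label = character(0),
    area_um2 = numeric(0), deformation = numeric(0), area_ratio = numeric(0),
    brightness_au = numeric(0), diameter_um = numeric(0)
  )
}

# rejection sampling helpers keeping invariants (> 0, or inside [lo, hi])
resample_positive <- function(dist, n) {
  x <- sample_dist(dist, n)
  bad <- which(x <= 0)
  tries <- 0
  while (length(bad) > 0 && tries < 100) {
    x[bad] <- sample_dist(dist, length(bad))
    bad <- bad[x[bad] <= 0]
    tries <- tries + 1
  }
  if (length(bad) > 0) x[bad] <- dist$mean
  x
}

resample_interval <- function(dist, n, lo, hi) {
  x <- sample_dist(dist, n)
  bad <- which(x < lo | x >= hi)
  tries <- 0
  while (length(bad) > 0 && tries < 100) {
    x[bad] <- sample_dist(dist, length(bad))
    bad <- bad[x[bad] < lo | x[bad] >= hi]
    tries <- tries + 1
  }
  if (length(bad) > 0) x[bad] <- pmin(pmax(dist$mean, lo), hi - 1e-12)
  x
}

#' Default bead mixture emulating two closely sized microgel populations
#'
#' Two polyacrylamide-like bead populations whose modal diameters differ by
#' 1.7 um, each with a 3.2% diameter CV — the canonical hard test for
#' size-based sorting sensitivity. The smaller population's modal projected
#' area sits near 125 um^2 (diameter 12.62 um).
#'
#' @param n_small,n_large events per population.
#' @param delta_d_um modal diameter gap in um (default 1.7).
#' @param cv diameter coefficient of variation (default 0.032).
#' @return list of two [population_spec()]s.
#' @export
bead_mixture_spec <- function(n_small = 5000, n_large = 5000,
                              delta_d_um = 1.7, cv = 0.032) {
  d_small <- 12.62
  list(
    bead_small = population_spec("bead_small", n_small,
                            diameter_dist = dist_spec(d_small, cv),
                            deformation_dist = dist_spec(0.02, 0.3),
                            brightness_dist = dist_spec(100, 0.03),
                            area_ratio_dist = dist_spec(1.01, 0.005)),
    bead_large = population_spec("bead_large", n_large,
                            diameter_dist = dist_spec(d_small + delta_d_um, cv),
                            deformation_dist = dist_spec(0.02, 0.3),
                            brightness_dist = dist_spec(100, 0.03),
                            area_ratio_dist = dist_spec(1.01, 0.005))
  )
}

#' Default blood sub-population mixture
#'
#' Three populations separable in the deformation-size plane (lymphocytes,
#' myeloid cells, red blood cells) plus platelets and neutrophils separable
#' in the brightness-size plane. Feature modes sit at the centres of the
#' published gating windows; widths are chosen so the populations overlap
#' mildly, as in real scatter plots.
#'
#' @param n_per events per population.
#' @return named list of [population_spec()]s.
#' @export
blood_mixture_spec <- function(n_per = 2000) {
  list(
    rbc = population_spec("rbc", n_per,
                          size_dist = dist_spec(35, 0.15),
                          deformation_dist = dist_spec(0.25, 0.2),
                          brightness_dist = dist_spec(125, 0.04)),
    lymphocyte = population_spec("lymphocyte", n_per,
                                 size_dist = dist_spec(34, 0.12),
                                 deformation_dist = dist_spec(0.05, 0.4),
                                 brightness_dist = dist_spec(112, 0.04)),
    myeloid = population_spec("myeloid", n_per,
                              size_dist = dist_spec(75, 0.12),
                              deformation_dist = dist_spec(0.07, 0.4),
                              brightness_dist = dist_spec(107, 0.04)),
    neutrophil = population_spec("neutrophil", n_per,
                                 size_dist = dist_spec(78, 0.1),
                                 deformation_dist = dist_spec(0.07, 0.4),
                                 brightness_dist = dist_spec(107.5, 0.02)),
    platelet = population_spec("platelet", n_per,
                               size_dist = dist_spec(8, 0.3),
                               deformation_dist = dist_spec(0.03, 0.5),
                               brightness_dist = dist_spec(95, 0.04))
  )
}

#' Generate a Poisson arrival stream
#'
#' Homogeneous Poisson arrivals at rate `concentration x flow_rate`
#' (unit-consistent: cells ml^-1 times ul s^-1 gives cells s^-1 after the
#' ml/ul conversion), with population labels drawn i.i.d. from `mixture`.
#'
#' @param concentration_per_ml in-channel cell concentration (cells ml^-1).
#' @param flow_rate_ul_s total flow rate (ul s^-1).
#' @param duration_s simulated time (s).
#' @param mixture named numeric weights summing to 1 (default one population
#'   `"target"`).
#' @param seed optional integer seed.
#' @return tibble of class `arrival_stream` with columns `time_s`, `label`;
#'   attributes `duration`, `rate` (nominal events s^-1).
#' @examples
#' s <- generate_arrival_stream(5e6, 0.08, 1, seed = 1)
#' attr(s, "rate")   # 400
#' @export
generate_arrival_stream <- function(concentration_per_ml, flow_rate_ul_s,
                                    duration_s,
                                    mixture = c(target = 1), seed = NULL) {
  if (concentration_per_ml < 0 || flow_rate_ul_s < 0 || duration_s < 0) {
    rlang::abort("arrival stream: concentration, flow rate and duration must be >= 0",
                 class = "acoustosort_config_error")
  }
  if (abs(sum(mixture) - 1) > 1e-9) {
    rlang::abort("arrival stream: mixture weights must sum to 1",
                 class = "acoustosort_config_error")
  }
  if (!is.null(seed)) set.seed(seed)
  rate <- concentration_per_ml * flow_rate_ul_s * 1e-3   # ul -> ml
  times <- numeric(0)
  if (rate > 0 && duration_s > 0) {
    n_draw <- stats::rpois(1, rate * duration_s)
    times <- sort(stats::runif(n_draw, 0, duration_s))
  }
  labels <- if (length(times) > 0) {
    sample(names(mixture), length(times), replace = TRUE, prob = mixture)
  } else character(0)
  out <- tibble::tibble(time_s = times, label = labels)
  attr(out, "duration") <- duration_s
  attr(out, "rate") <- rate
  class(out) <- c("arrival_stream", class(out))
  out
}

#' Attach per-event features to an arrival stream
#'
#' Draws one event record per arrival from the [population_spec()] matching
#' its label, preserving arrival order and times.
#'
#' @param stream an [generate_arrival_stream()] result.
#' @param populations named list of [population_spec()]s covering every
#'   label in the stream.
#' @param seed optional integer seed.
#' @return event tibble aligned row-for-row with `stream`.
#' @export
sample_events_for_stream <- function(stream, populations, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  labs <- stream$label
  missing <- setdiff(unique(labs), names(populations))
  if (length(missing) > 0) {
    rlang::abort(paste0("no population spec for label(s): ",
                        paste(missing, collapse = ", ")),
                 class = "acoustosort_usage_error")
  }
  if (nrow(stream) == 0) return(empty_event_table())
  events <- empty_event_table()[rep(1L, nrow(stream))[0], ]
  parts <- lapply(unique(labs), function(lab) {
    idx <- which(labs == lab)
    ev <- generate_population(populations[[lab]], n = length(idx))
    ev$time_s <- stream$time_s[idx]
    ev$.row <- idx
    ev
  })
  out <- dplyr::arrange(dplyr::bind_rows(parts), .data$.row)
  out$id <- seq_len(nrow(out))
  out$.row <- NULL
  out
}
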