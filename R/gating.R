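#' Define a multi-parameter sorting gate
#'
#' A gate combines optional axis criteria and an optional polygon in the
#' deformation-size plane. Interval criteria are half-open `[lo, hi)` and
#' upper bounds are strict, matching the mixed "lo-hi" and "< x" notations
#' of published gating tables under one convention. The area-ratio bound is
#' a data-quality pre-filter: [purity()] removes events failing it from both
#' numerator and denominator.
#'
#' @param label gate name.
#' @param area_range optional `c(lo, hi)` in um^2.
#' @param deformation_max optional strict upper bound on deformation.
#' @param brightness_range optional `c(lo, hi)` in a.u.
#' @param area_ratio_max strict upper bound on hull/raw area ratio
#'   (default 1.08).
#' @param polygon optional matrix/data frame with columns `area_um2`,
#'   `deformation`: a simple polygon selecting events in that plane.
#' @return a `gate` object.
#' @examples
#' gate("myeloid", area_range = c(50, 100), deformation_max = 0.12)
#' @export
gate <- function(label, area_range = NULL, deformation_max = NULL,
                 brightness_range = NULL, area_ratio_max = 1.08,
                 polygon = NULL) {
  for (rng in list(area_range, brightness_range)) {
    if (!is.null(rng) && (length(rng) != 2 || rng[1] >= rng[2])) {
      rlang::abort("gate: ranges must be c(lo, hi) with lo < hi",
                   class = "acoustosort_config_error")
    }
  }
  if (!is.null(polygon)) {
    polygon <- as.data.frame(polygon)
    if (!all(c("area_um2", "deformation") %in% names(polygon)) || nrow(polygon) < 3) {
      rlang::abort("gate: polygon needs >= 3 vertices with columns area_um2, deformation",
                   class = "acoustosort_config_error")
    }
  }
  if (is.null(area_range) && is.null(deformation_max) &&
      is.null(brightness_range) && is.null(polygon)) {
    rlang::abort("gate: at least one selection criterion must be set",
                 class = "acoustosort_config_error")
  }
  structure(list(label = label, area_range = area_range,
                 deformation_max = deformation_max,
                 brightness_range = brightness_range,
                 area_ratio_max = area_ratio_max, polygon = polygon),
            class = "gate")
}

#' Evaluate a gate on an event table
#'
#' An event passes iff ALL set criteria hold (including the area-ratio
#' quality bound when the column is present).
#'
#' @param events event tibble.
#' @param g a [gate()].
#' @return logical vector, one element per event.
#' @export
apply_gate <- function(events, g) {
  stopifnot(inherits(g, "gate"))
  needed <- c(
    if (!is.null(g$area_range) || !is.null(g$polygon)) "area_um2",
    if (!is.null(g$deformation_max) || !is.null(g$polygon)) "deformation",
    if (!is.null(g$brightness_range)) "brightness_au"
  )
  miss <- setdiff(needed, names(events))
  if (length(miss) > 0) {
    rlang::abort(paste0("apply_gate: events table lacks column(s): ",
                        paste(miss, collapse = ", ")),
                 class = "acoustosort_usage_error")
  }
  ok <- rep(TRUE, nrow(events))
  if (!is.null(g$area_range)) {
    ok <- ok & events$area_um2 >= g$area_range[1] & events$area_um2 < g$area_range[2]
  }
  if (!is.null(g$deformation_max)) ok <- ok & events$deformation < g$deformation_max
  if (!is.null(g$brightness_range)) {
    ok <- ok & events$brightness_au >= g$brightness_range[1] &
      events$brightness_au < g$brightness_range[2]
  }
  if (!is.null(g$polygon)) {
    ok <- ok & pracma::inpolygon(events$area_um2, events$deformation,
                                 g$polygon$area_um2, g$polygon$deformation,
                                 boundary = TRUE)
  }
  if (!is.null(g$area_ratio_max) && "area_ratio" %in% names(events)) {
    ok <- ok & events$area_ratio < g$area_ratio_max
  }
  ok
}

quality_mask <- function(events, g) {
  if (!is.null(g$area_ratio_max) && "area_ratio" %in% names(events)) {
    events$area_ratio < g$area_ratio_max
  } else {
    rep(TRUE, nrow(events))
  }
}

#' Gate purity of an event table
#'
#' `100 * n_in_gate / n_total`, where events failing the area-ratio quality
#' pre-filter are excluded from both counts.
#'
#' @param events event tibble (non-empty after the quality filter).
#' @param g a [gate()].
#' @return purity in percent.
#' @export
purity <- function(events, g) {
  qm <- quality_mask(events, g)
  ev <- events[qm, , drop = FALSE]
  if (nrow(ev) == 0) {
    rlang::abort("purity: no events after the quality filter",
                 class = "acoustosort_domain_error")
  }
  100 * sum(apply_gate(ev, g)) / nrow(ev)
}

#' Enrichment fold
#'
#' Ratio of target purity (after sorting) to initial purity (before).
#' `IP = 0` yields `Inf` with a warning — finite folds as large as several
#' hundred arise for sub-percent initial purities.
#'
#' @param ip initial purity (percent, > 0 for a finite fold).
#' @param tp target purity (percent).
#' @return enrichment fold.
#' @examples
#' enrichment(52.6, 86.3)  # 1.64
#' @export
enrichment <- function(ip, tp) {
  if (any(ip < 0) || any(tp < 0)) {
    rlang::abort("enrichment: purities must be >= 0", class = "acoustosort_domain_error")
  }
  if (any(ip == 0)) rlang::warn("enrichment: IP = 0 gives an infinite fold")
  tp / ip
}

#' Recovery percentage
#'
#' `100 * n_collected / n_reported_sorted`: the fraction of cells the
#' instrument reports as sorted that actually arrive in the target tube.
#'
#' @param n_collected cells collected in the target tube.
#' @param n_reported_sorted cells the feedback system reports sorted (> 0).
#' @return recovery in percent.
#' @export
recovery <- function(n_collected, n_reported_sorted) {
  if (any(n_reported_sorted <= 0)) {
    rlang::abort("recovery: n_reported_sorted must be > 0",
                 class = "acoustosort_domain_error")
  }
  100 * n_collected / n_reported_sorted
}

#' Coefficient of variation
#'
#' `100 * sd(x) / mean(x)` with the sample (n-1) standard deviation.
#'
#' @param values numeric vector, `n >= 2`, nonzero mean.
#' @return CV in percent.
#' @export
coefficient_of_variation <- function(values) {
  if (length(values) < 2) {
    rlang::abort("coefficient_of_variation: need at least 2 values",
                 class = "acoustosort_domain_error")
  }
  m <- mean(values)
  if (m == 0) {
    rlang::abort("coefficient_of_variation: mean is zero",
                 class = "acoustosort_domain_error")
  }
  100 * stats::sd(values) / m
}

#' Gaussian kernel density estimate as a tidy curve
#'
#' Thin wrapper over [stats::density()] returning an evaluation grid wide
#' enough that the trapezoidal integral is 1 to within 1e-3.
#'
#' @param values numeric sample, `n >= 2`.
#' @param bandwidth kernel bandwidth; default `stats::bw.nrd0`.
#' @param n grid size (default 512).
#' @return tibble with columns `value`, `density`.
#' @export
kde_density <- function(values, bandwidth = NULL, n = 512) {
  if (length(values) < 2) {
    rlang::abort("kde_density: need at least 2 values", class = "acoustosort_domain_error")
  }
  bw <- bandwidth %||% stats::bw.nrd0(values)
  d <- stats::density(values, bw = bw, n = n, cut = 4)
  tibble::tibble(value = d$x, density = d$y)
}

#' Local maxima of a density curve
#'
#' Interior grid points higher than both neighbours, tallest first. Used to
#' measure modal gaps of bimodal mixtures.
#'
#' @param curve tibble from [kde_density()].
#' @param min_rel_height discard modes below this fraction of the tallest
#'   (default 0.1).
#' @return tibble with columns `value`, `density`.
#' @export
density_modes <- function(curve, min_rel_height = 0.1) {
  y <- curve$density
  n <- length(y)
  i <- which(y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n]) + 1
  out <- curve[i, ]
  out <- out[out$density >= min_rel_height * max(y), ]
  dplyr::arrange(out, dplyr::desc(.data$density))
}

#' Published gating strategies fixture
#'
#' The ten gating strategies and sorting performances of the device's
#' characterisation runs (bead mixtures, blood sub-populations, cell
#' lines), transcribed with their printed initial/target purities and
#' enrichment folds. Where the running text and the table disagree
#' (platelet brightness bound, myeloid size range) both variants are kept
#' and `source` marks which. The `discrepant` flag marks the one row whose
#' printed fold is inconsistent with its own printed purities.
#'
#' @return tibble with columns `sample`, `source`, `size_lo`, `size_hi`,
#'   `deformation_max`, `brightness_lo`, `brightness_hi`,
#'   `area_ratio_max`, `ip`, `tp`, `enrichment_printed`, `discrepant`.
#' @export
table1_gates <- function() {
  path <- system.file("extdata", "table1_gates.tsv", package = "acoustosort",
                      mustWork = TRUE)
  readr::read_tsv(path, show_col_types = FALSE)
}
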