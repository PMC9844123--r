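#' Sorting-channel geometry
#'
#' Geometry of the widened sorting region downstream of the deformation
#' channel. The sorting-region volume, which sets the single-occupancy
#' concentration limit, is derived as `width x length x height` unless
#' explicitly configured; an explicit value inconsistent with the
#' dimensions by more than 5% is rejected.
#'
#' @param deformation_channel_um side of the square deformation channel
#'   (20 or 30 um; default 30).
#' @param sorting_width_um sorting-region width (default 50).
#' @param sorting_length_um sorting-region length (default 130).
#' @param height_um channel height (defaults to the deformation channel
#'   side).
#' @param bifurcation_offset_um offset of the default outlet from the
#'   channel centre (default 5): the lateral displacement a cell needs to
#'   exit through the target outlet.
#' @param focal_zone_um length of the acoustically active zone (default 50).
#' @param roi_to_sr_um distance from measurement region to sorting region
#'   (default 60).
#' @param volume_nl optional explicit sorting-region volume (nl).
#' @return a `channel_geometry` with `volume_nl` filled in.
#' @examples
#' channel_geometry(volume_nl = 0.2)$volume_nl
#' @export
channel_geometry <- function(deformation_channel_um = 30,
                             sorting_width_um = 50, sorting_length_um = 130,
                             height_um = deformation_channel_um,
                             bifurcation_offset_um = 5, focal_zone_um = 50,
                             roi_to_sr_um = 60, volume_nl = NULL) {
  dims <- c(deformation_channel_um, sorting_width_um, sorting_length_um,
            height_um, bifurcation_offset_um, focal_zone_um, roi_to_sr_um)
  if (any(dims <= 0)) {
    rlang::abort("channel_geometry: all dimensions must be > 0",
                 class = "acoustosort_config_error")
  }
  derived_nl <- sorting_width_um * sorting_length_um * height_um * 1e-6
  if (is.null(volume_nl)) {
    volume_nl <- derived_nl
  } else if (abs(volume_nl - derived_nl) / derived_nl > 0.05) {
    rlang::abort(sprintf(
      "channel_geometry: configured volume %.3g nl differs from the %.3g nl implied by the dimensions by more than 5%%",
      volume_nl, derived_nl), class = "acoustosort_config_error")
  }
  structure(list(deformation_channel_um = deformation_channel_um,
                 sorting_width_um = sorting_width_um,
                 sorting_length_um = sorting_length_um, height_um = height_um,
                 bifurcation_offset_um = bifurcation_offset_um,
                 focal_zone_um = focal_zone_um, roi_to_sr_um = roi_to_sr_um,
                 volume_nl = volume_nl),
            class = "channel_geometry")
}

#' @rdname channel_geometry
#' @param sample_ul_s,sheath_ul_s sample and sheath flow rates (ul s^-1).
#' @return `flow_config` with derived `total_ul_s` and `sheath_to_sample`.
#' @export
flow_config <- function(sample_ul_s = 0.01, sheath_ul_s = 0.07) {
  if (sample_ul_s <= 0 || sheath_ul_s < 0) {
    rlang::abort("flow_config: sample flow must be > 0 and sheath flow >= 0",
                 class = "acoustosort_config_error")
  }
  structure(list(sample_ul_s = sample_ul_s, sheath_ul_s = sheath_ul_s,
                 total_ul_s = sample_ul_s + sheath_ul_s,
                 sheath_to_sample = sheath_ul_s / sample_ul_s),
            class = "flow_config")
}

#' Throughput arithmetic of a single-occupancy sorter
#'
#' `residence_time()` is the mean time a cell spends in the sorting region,
#' `V_SR / Q`; it must exceed the pulse duration.
#' `max_in_channel_concentration()` is the one-cell-per-sorting-region
#' limit `1 / V_SR`; `max_sorting_rate()` multiplies it by the flow rate;
#' and `max_sample_concentration()` rescales by the sheath dilution
#' `(ratio + 1)`.
#'
#' @param geom a [channel_geometry()].
#' @param flow a [flow_config()], or a flow rate in ul s^-1.
#' @return `residence_time`: seconds.
#' @examples
#' g <- channel_geometry(volume_nl = 0.2)
#' residence_time(g, 0.08) * 1e3              # 2.5 ms
#' max_in_channel_concentration(g)            # 5e6 per ml
#' max_sorting_rate(5e6, 0.08)                # 400 per s
#' max_sample_concentration(5e6, 7)           # 4e7 per ml
#' @export
residence_time <- function(geom, flow) {
  q <- if (inherits(flow, "flow_config")) flow$total_ul_s else flow
  if (q <= 0) {
    rlang::abort("residence_time: flow rate must be > 0",
                 class = "acoustosort_domain_error")
  }
  # nl / (ul/s) = 1e-3 s
  geom$volume_nl / q * 1e-3
}

#' @rdname residence_time
#' @return `max_in_channel_concentration`: cells ml^-1.
#' @export
max_in_channel_concentration <- function(geom) {
  1 / (geom$volume_nl * 1e-6)  # nl -> ml
}

#' @rdname residence_time
#' @param c_max_per_ml maximum in-channel concentration (cells ml^-1).
#' @param flow_ul_s total flow rate (ul s^-1).
#' @return `max_sorting_rate`: events s^-1.
#' @export
max_sorting_rate <- function(c_max_per_ml, flow_ul_s) {
  c_max_per_ml * flow_ul_s * 1e-3  # ul -> ml
}

#' @rdname residence_time
#' @param sheath_to_sample sheath:sample flow ratio (>= 0).
#' @return `max_sample_concentration`: cells ml^-1.
#' @export
max_sample_concentration <- function(c_max_per_ml, sheath_to_sample) {
  if (sheath_to_sample < 0) {
    rlang::abort("max_sample_concentration: ratio must be >= 0",
                 class = "acoustosort_config_error")
  }
  c_max_per_ml * (sheath_to_sample + 1)
}

#' Poisson occupancy statistics of the sorting region
#'
#' Under Poisson arrivals the number of cells in the sorting region is
#' Poisson with mean `lambda = concentration x V_SR`.
#'
#' @param concentration_per_ml in-channel concentration (cells ml^-1).
#' @param geom a [channel_geometry()].
#' @return tibble with `lambda`, `p_ge1 = 1 - exp(-lambda)`,
#'   `p_ge2 = 1 - exp(-lambda) (1 + lambda)`.
#' @export
occupancy_statistics <- function(concentration_per_ml, geom) {
  if (any(concentration_per_ml < 0)) {
    rlang::abort("occupancy_statistics: concentration must be >= 0",
                 class = "acoustosort_config_error")
  }
  lam <- concentration_per_ml * geom$volume_nl * 1e-6
  tibble::tibble(lambda = lam,
                 p_ge1 = 1 - exp(-lam),
                 p_ge2 = 1 - exp(-lam) * (1 + lam))
}

#' Simulate an end-to-end sorting run
#'
#' Walks a Poisson arrival stream through the sorting region: each event's
#' features are gated at detection; a gated event (with probability
#' `success_prob`) triggers an acoustic pulse `delay_s` after detection;
#' the pulse displaces the cell by the quasi-steady travelling-wave
#' displacement (using the event's own diameter), and the cell exits
#' through the target outlet iff that displacement reaches the bifurcation
#' offset. Any other cell resident in the sorting region at the instant a
#' pulse fires is *coincident*: under the `"co-sort"` policy it is pushed
#' too (and lands in the target tube if its own displacement suffices,
#' degrading purity); under `"abort"` the pulse is suppressed (degrading
#' recovery, preserving purity).
#'
#' @param stream an [generate_arrival_stream()] result.
#' @param events event tibble aligned row-for-row with `stream` (needs
#'   `diameter_um` plus the columns the gate references).
#' @param g a [gate()] selecting target events.
#' @param field a TSAW [acoustic_field()].
#' @param fluid a [fluid_spec()].
#' @param geom a [channel_geometry()].
#' @param flow a [flow_config()] or total flow rate (ul s^-1).
#' @param delay_s detection-to-pulse delay (default 1 ms).
#' @param coincidence `"co-sort"` (default) or `"abort"`.
#' @param success_prob per-event actuation success probability (default 1);
#'   a phenomenological stand-in for unmodelled failure modes such as
#'   z-velocity dispersion of very small particles.
#' @param asf_um additive streaming-flow displacement (um, default 0).
#' @param Y_T acoustic radiation factor (default 1).
#' @param seed optional integer seed (actuation-success draws).
#' @return a `sort_run`: list with `outcome` (per-event tibble: `gated`,
#'   `actuated`, `aborted`, `coincident`, `n_coresident`,
#'   `displacement_um`, `outlet`) and `report` (a `sort_report`, see
#'   [sort_report()]).
#' @export
simulate_sort <- function(stream, events, g, field, fluid = fluid_spec(),
                          geom = channel_geometry(), flow = flow_config(),
                          delay_s = 1e-3, coincidence = c("co-sort", "abort"),
                          success_prob = 1, asf_um = 0, Y_T = 1, seed = NULL) {
  coincidence <- match.arg(coincidence)
  if (nrow(stream) != nrow(events)) {
    rlang::abort("simulate_sort: stream and events must have the same number of rows",
                 class = "acoustosort_usage_error")
  }
  if (!is.null(seed)) set.seed(seed)
  t_res <- residence_time(geom, flow)
  tau <- field$pulse_duration
  if (tau > t_res) {
    rlang::warn(sprintf("pulse duration (%.3g ms) exceeds residence time (%.3g ms)",
                        tau * 1e3, t_res * 1e3))
  }
  n <- nrow(events)
  t_arr <- stream$time_s
  gated <- apply_gate(events, g)
  success <- stats::runif(n) < success_prob
  # effective push time cannot exceed the remaining residence after the delay
  eff_tau <- max(0, min(tau, t_res - delay_s))
  disp_um <- lateral_displacement(
    tsaw_radiation_force(field, events$diameter_um * 1e-6, Y_T = Y_T),
    fluid, events$diameter_um * 1e-6, eff_tau) * 1e6 + asf_um

  # occupancy at each event's own arrival: earlier arrivals still resident
  n_coresident <- count_in_window(t_arr, t_arr, t_res) # excludes self by strictness

  want_fire <- gated & success
  t_fire <- t_arr + delay_s
  # bystanders at each candidate pulse onset: arrivals in (t_fire - t_res, t_fire]
  # minus the triggering cell itself (still resident since delay < t_res)
  bystanders <- count_arrivals_interval(t_arr, t_fire - t_res, t_fire) -
    as.integer(t_arr > t_fire - t_res & t_arr <= t_fire)
  # bystanders that are outside the gate: the contamination risk
  t_off <- t_arr[!gated]
  bystanders_offgate <- count_arrivals_interval(t_off, t_fire - t_res, t_fire) -
    as.integer(!gated & t_arr > t_fire - t_res & t_arr <= t_fire)
  aborted <- want_fire & coincidence == "abort" & bystanders > 0
  fired <- want_fire & !aborted

  # coincident flag: event was resident at some OTHER event's pulse onset
  ft <- sort(t_fire[fired])
  cnt_pulses <- count_arrivals_interval(ft, t_arr, t_arr + t_res) # pulses in residence
  own_pulse <- fired & (delay_s < t_res)
  coincident <- (cnt_pulses - as.integer(own_pulse)) > 0

  pushed <- fired | (coincidence == "co-sort" & coincident)
  to_target <- pushed & disp_um >= geom$bifurcation_offset_um
  outlet <- ifelse(to_target, "target", "default")

  outcome <- tibble::tibble(
    id = seq_len(n), time_s = t_arr, label = events$label %||% NA_character_,
    gated = gated, requested = want_fire, actuated = fired, aborted = aborted,
    coincident = coincident, n_coresident = n_coresident,
    n_bystanders = ifelse(want_fire, bystanders, NA_integer_),
    n_bystanders_offgate = ifelse(want_fire, bystanders_offgate, NA_integer_),
    displacement_um = ifelse(pushed, disp_um, 0), outlet = outlet
  )
  duration <- attr(stream, "duration") %||% max(t_arr, 0)
  rep <- sort_report(events, outcome, g, duration,
                     flow = if (inherits(flow, "flow_config")) flow$total_ul_s else flow,
                     policy = coincidence)
  structure(list(outcome = outcome, report = rep), class = "sort_run")
}

# for each arrival time t (an element of `times`), the number of OTHER
# points of `times` in (t - w, t]; assumes times are distinct, so the
# self-count is exactly one
count_in_window <- function(times, at, w) {
  st <- sort(times)
  hi <- findInterval(at, st)               # points <= t (includes self)
  lo <- findInterval(at - w, st)           # points <= t - w
  hi - lo - 1L
}

# number of points of sorted-or-not `times` in (lo_i, hi_i] per interval
count_arrivals_interval <- function(times, lo, hi) {
  st <- sort(times)
  findInterval(hi, st) - findInterval(lo, st)
}

#' Aggregate a sorting outcome into a run report
#'
#' Initial purity (IP) is the gate purity of the full pre-sort event table;
#' target purity (TP) is the gate purity of the events that exited through
#' the target outlet (both with the area-ratio quality pre-filter);
#' enrichment is `TP / IP`; recovery is collected-over-reported-sorted; and
#' throughput is total events over run duration.
#'
#' @param events pre-sort event tibble.
#' @param outcome per-event outcome tibble from [simulate_sort()].
#' @param g the [gate()] used.
#' @param duration_s run duration (s).
#' @param flow total flow rate (ul s^-1), for the record.
#' @param policy coincidence policy used.
#' @return a `sort_report` list.
#' @export
sort_report <- function(events, outcome, g, duration_s, flow = NA_real_,
                        policy = NA_character_) {
  sorted_idx <- which(outcome$outlet == "target")
  n_total <- nrow(events)
  n_fired <- sum(outcome$actuated)
  # the feedback system reports every pulse it requested as a sort, whether
  # or not coincidence handling suppressed it — that is what recovery is
  # measured against
  n_requested <- if ("requested" %in% names(outcome)) sum(outcome$requested) else n_fired
  ip <- purity(events, g)
  tp <- if (length(sorted_idx) > 0) purity(events[sorted_idx, ], g) else NA_real_
  rec <- if (n_requested > 0) recovery(length(sorted_idx), n_requested) else NA_real_
  enr <- if (!is.na(tp) && ip > 0) tp / ip else NA_real_
  cvb <- if ("diameter_um" %in% names(events) && n_total >= 2) {
    coefficient_of_variation(events$diameter_um)
  } else NA_real_
  cva <- if ("diameter_um" %in% names(events) && length(sorted_idx) >= 2) {
    coefficient_of_variation(events$diameter_um[sorted_idx])
  } else NA_real_
  structure(list(
    n_total = n_total, n_gated = sum(outcome$gated), n_actuated = n_fired,
    n_aborted = sum(outcome$aborted), n_collected = length(sorted_idx),
    initial_purity = ip, target_purity = tp, enrichment = enr,
    recovery = rec,
    throughput = if (duration_s > 0) n_total / duration_s else NA_real_,
    cv_before = cvb, cv_after = cva,
    duration_s = duration_s, flow_ul_s = flow, coincidence_policy = policy,
    gate_label = g$label
  ), class = "sort_report")
}

#' @export
print.sort_report <- function(x, ...) {
  cat(sprintf("Sorting run report (gate '%s', %s policy)\n", x$gate_label,
              x$coincidence_policy))
  cat(sprintf("  events: %d total | %d gated | %d pulses | %d aborted | %d collected\n",
              x$n_total, x$n_gated, x$n_actuated, x$n_aborted, x$n_collected))
  cat(sprintf("  IP %.2f%% -> TP %.2f%%  (%.3g-fold enrichment)\n",
              x$initial_purity, x$target_purity, x$enrichment))
  cat(sprintf("  recovery %.1f%% | throughput %.1f events/s\n",
              x$recovery, x$throughput))
  invisible(x)
}

#' Chi-square goodness of fit of occupancy counts to a Poisson law
#'
#' Pools the upper tail so every expected bin count is at least 5, then
#' applies Pearson's chi-square test against `dpois(., lambda)`. Counts
#' sampled at nearby instants share arrivals and are therefore correlated;
#' use `thin_by_time()` (or any spacing rule longer than the residence
#' time) to obtain approximately independent samples first.
#'
#' @param counts non-negative integer occupancy samples.
#' @param lambda Poisson mean under the null.
#' @return the chi-square p-value.
#' @export
poisson_gof <- function(counts, lambda) {
  n <- length(counts)
  kmax <- max(counts, stats::qpois(0.9999, lambda))
  p <- stats::dpois(0:kmax, lambda)
  k <- max(1, max(which(p * n >= 5)))
  obs <- tabulate(factor(counts, levels = 0:kmax), nbins = kmax + 1)
  obs_pooled <- c(obs[seq_len(k)], sum(obs[-seq_len(k)]))
  p_pooled <- c(p[seq_len(k)], 1 - sum(p[seq_len(k)]))
  suppressWarnings(stats::chisq.test(obs_pooled, p = p_pooled)$p.value)
}

#' @rdname poisson_gof
#' @param stream an [generate_arrival_stream()] result.
#' @param geom a [channel_geometry()].
#' @param flow a [flow_config()] or total flow rate (ul s^-1).
#' @return `occupancy_counts`: integer vector of sorting-region occupancies
#'   sampled at probe times spaced one residence time apart (disjoint
#'   windows, hence i.i.d. Poisson under the arrival model).
#' @export
occupancy_counts <- function(stream, geom, flow) {
  t_res <- residence_time(geom, flow)
  duration <- attr(stream, "duration") %||% max(stream$time_s, 0)
  probes <- seq(t_res, duration, by = t_res)
  count_arrivals_interval(stream$time_s, probes - t_res, probes)
}

#' Purity and recovery across sample concentrations
#'
#' Repeats [simulate_sort()] over a grid of *sample* concentrations
#' (diluted in-channel by the sheath ratio), a scaled-down analogue of a
#' concentration-robustness experiment.
#'
#' @param concentrations_per_ml sample concentrations (cells ml^-1).
#' @param populations named list of [population_spec()]s.
#' @param mixture named arrival weights over the populations.
#' @param g target [gate()].
#' @param field,fluid,geom,flow,delay_s,coincidence,success_prob,asf_um,Y_T
#'   passed to [simulate_sort()].
#' @param n_events target number of events per run (sets the duration).
#' @param reps replicate runs per concentration (default 3).
#' @param seed integer seed controlling all randomness.
#' @return tibble of class `concentration_sweep`: one row per
#'   (concentration, rep) with `tp`, `recovery`, `ip`, `lambda_occ`,
#'   `n_events`.
#' @export
purity_vs_concentration <- function(concentrations_per_ml, populations,
                                    mixture, g, field,
                                    fluid = fluid_spec(),
                                    geom = channel_geometry(),
                                    flow = flow_config(),
                                    delay_s = 1e-3,
                                    coincidence = "abort",
                                    success_prob = 1, asf_um = 0, Y_T = 1,
                                    n_events = 1e4, reps = 3, seed = 1) {
  set.seed(seed)
  q <- if (inherits(flow, "flow_config")) flow$total_ul_s else flow
  dilution <- if (inherits(flow, "flow_config")) flow$sheath_to_sample + 1 else 8
  c_limit <- max_in_channel_concentration(geom)
  grid <- tidyr::expand_grid(concentration = concentrations_per_ml,
                             rep = seq_len(reps))
  res <- purrr::pmap_dfr(grid, function(concentration, rep) {
    c_chan <- concentration / dilution
    if (c_chan > c_limit) {
      rlang::warn(sprintf(
        "in-channel concentration %.3g/ml exceeds the single-occupancy limit %.3g/ml",
        c_chan, c_limit))
    }
    rate <- c_chan * q * 1e-3
    duration <- n_events / rate
    stream <- generate_arrival_stream(c_chan, q, duration, mixture)
    events <- sample_events_for_stream(stream, populations)
    run <- simulate_sort(stream, events, g, field, fluid, geom, flow,
                         delay_s = delay_s, coincidence = coincidence,
                         success_prob = success_prob, asf_um = asf_um, Y_T = Y_T)
    tibble::tibble(concentration = concentration, rep = rep,
                   lambda_occ = c_chan * geom$volume_nl * 1e-6,
                   n_events = run$report$n_total,
                   ip = run$report$initial_purity,
                   tp = run$report$target_purity,
                   recovery = run$report$recovery)
  })
  class(res) <- c("concentration_sweep", class(res))
  res
}
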