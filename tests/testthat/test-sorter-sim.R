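geom02 <- channel_geometry(volume_nl = 0.2)
flow08 <- flow_config(0.01, 0.07)
tsaw100 <- acoustic_field("TSAW", 135e6, energy_density = 100,
                          pulse_duration = 1e-3)

test_that("throughput arithmetic follows the single-occupancy rule", {
  expect_equal(residence_time(geom02, 0.08) * 1e3, 2.5)
  expect_equal(residence_time(geom02, 0.16) * 1e3, 1.25)
  g195 <- channel_geometry()  # 50 x 130 x 30 um
  expect_equal(g195$volume_nl, 0.195)
  expect_equal(residence_time(g195, 0.08) * 1e3, 2.4375)
  expect_equal(max_in_channel_concentration(geom02), 5e6)
  expect_equal(max_in_channel_concentration(channel_geometry(volume_nl = 0.4,
                                                             height_um = 60)), 2.5e6)
  expect_equal(max_in_channel_concentration(g195), 5.128205e6, tolerance = 1e-6)
  expect_equal(max_sorting_rate(5e6, 0.08), 400)
  expect_equal(max_sorting_rate(5e6, 0), 0)
  expect_equal(max_sorting_rate(5e6, 0.04), 200)
  expect_equal(max_sample_concentration(5e6, 7), 40e6)
  expect_equal(max_sample_concentration(5e6, 0), 5e6)
  expect_equal(max_sample_concentration(5e6, 3), 20e6)
  expect_error(residence_time(geom02, 0), class = "acoustosort_domain_error")
})

test_that("geometry constructor checks volume consistency", {
  expect_error(channel_geometry(volume_nl = 0.3),
               class = "acoustosort_config_error")
  expect_silent(channel_geometry(volume_nl = 0.2))  # within 5% of 0.195
})

test_that("occupancy statistics match the Poisson closed forms", {
  st <- occupancy_statistics(5e6, geom02)
  expect_equal(st$lambda, 1.0)
  expect_equal(st$p_ge2, 1 - exp(-1) * 2, tolerance = 1e-12)
  expect_equal(st$p_ge2, 0.264, tolerance = 0.001)
  expect_equal(occupancy_statistics(0, geom02)$p_ge1, 0)
})

test_that("an all-target dilute stream is sorted perfectly", {
  pops <- list(target = population_spec("target", 1,
                                        diameter_dist = dist_spec(14, 0.02)))
  set.seed(31)
  stream <- generate_arrival_stream(1e4, 0.08, 2000, c(target = 1))
  ev <- sample_events_for_stream(stream, pops)
  g <- gate("all", area_range = c(100, 220), area_ratio_max = 2)
  run <- simulate_sort(stream, ev, g, tsaw100, geom = geom02, flow = flow08)
  expect_equal(run$report$target_purity, 100)
  expect_equal(run$report$recovery, 100, tolerance = 0.5)
  # conservation: every event exits through exactly one outlet
  expect_equal(sum(run$outcome$outlet == "target") +
                 sum(run$outcome$outlet == "default"), nrow(ev))
  # throughput identity
  expect_equal(run$report$throughput, nrow(ev) / attr(stream, "duration"),
               tolerance = 0.01)
})

test_that("zero force sends every event to the default outlet", {
  pops <- list(target = population_spec("target", 1,
                                        diameter_dist = dist_spec(14, 0.02)))
  set.seed(32)
  stream <- generate_arrival_stream(1e5, 0.08, 100, c(target = 1))
  ev <- sample_events_for_stream(stream, pops)
  g <- gate("all", area_range = c(100, 220), area_ratio_max = 2)
  f0 <- acoustic_field("TSAW", 135e6, energy_density = 0.001,
                       pulse_duration = 1e-3)
  run <- simulate_sort(stream, ev, g, f0, geom = geom02, flow = flow08)
  expect_true(all(run$outcome$outlet == "default"))
  expect_equal(run$report$recovery, 0)
})

test_that("co-sorted contamination matches the co-residence closed form", {
  pops <- list(
    target = population_spec("target", 1, diameter_dist = dist_spec(14, 0.03)),
    other = population_spec("other", 1, diameter_dist = dist_spec(10, 0.03)))
  g <- gate("size", area_range = c(120, 200), area_ratio_max = 1.5)
  lam <- 0.1
  conc <- lam / 0.2e-6
  rate <- conc * 0.08e-3
  set.seed(7)
  stream <- generate_arrival_stream(conc, 0.08, 3e4 / rate,
                                    c(target = .5, other = .5))
  ev <- sample_events_for_stream(stream, pops)
  run <- simulate_sort(stream, ev, g, tsaw100, geom = geom02, flow = flow08,
                       coincidence = "co-sort")
  oc <- run$outcome
  frac <- mean(oc$n_bystanders_offgate[oc$actuated] > 0)
  cf <- 1 - exp(-rate * 0.5 * residence_time(geom02, flow08))
  se <- sqrt(cf * (1 - cf) / sum(oc$actuated))
  expect_lt(abs(frac - cf), 3 * se)
  # occupancy seen at arrivals has the nominal mean
  expect_lt(abs(mean(oc$n_coresident) - lam), 3 * sqrt(lam / nrow(oc)))
})

test_that("abort policy preserves purity and degrades recovery", {
  beads <- bead_mixture_spec()
  g <- gate("small", area_range = c(115, 135), area_ratio_max = 1.05)
  lam <- 0.5
  conc <- lam / 0.2e-6
  set.seed(9)
  stream <- generate_arrival_stream(conc, 0.08, 100,
                                    c(bead_small = .5, bead_large = .5))
  ev <- sample_events_for_stream(stream, beads)
  run <- simulate_sort(stream, ev, g, tsaw100, geom = geom02, flow = flow08,
                       coincidence = "abort")
  expect_equal(run$report$target_purity, 100)
  expect_lt(run$report$recovery, 75)  # ~ exp(-0.5)
  expect_gt(run$report$recovery, 45)
  expect_gt(run$report$n_aborted, 0)
})

test_that("contamination per sorted cell is non-decreasing in concentration", {
  beads <- bead_mixture_spec()
  g <- gate("small", area_range = c(115, 135), area_ratio_max = 1.05)
  concs <- c(2e6, 8e6, 16e6, 26e6, 36e6)
  sw <- purity_vs_concentration(concs, beads,
                                c(bead_small = .4, bead_large = .6), g,
                                tsaw100, geom = geom02, flow = flow08,
                                coincidence = "co-sort", n_events = 2000,
                                reps = 20, seed = 17)
  contam <- sw |>
    dplyr::group_by(concentration) |>
    dplyr::summarise(contam = mean(100 - tp))
  expect_true(all(diff(contam$contam) > -1e-9))
})

test_that("a pulse longer than the residence time warns", {
  pops <- list(target = population_spec("target", 1,
                                        diameter_dist = dist_spec(14, 0.02)))
  set.seed(2)
  stream <- generate_arrival_stream(1e4, 0.08, 10, c(target = 1))
  ev <- sample_events_for_stream(stream, pops)
  g <- gate("all", area_range = c(100, 220))
  fslow <- acoustic_field("TSAW", 135e6, energy_density = 100,
                          pulse_duration = 5e-3)
  expect_warning(simulate_sort(stream, ev, g, fslow, geom = geom02,
                               flow = flow08),
                 "residence time")
  expect_error(simulate_sort(stream, ev[-1, ], g, tsaw100, geom = geom02,
                             flow = flow08),
               class = "acoustosort_usage_error")
})

test_that("sweep at one concentration and one rep mirrors simulate_sort", {
  beads <- bead_mixture_spec()
  g <- gate("small", area_range = c(115, 135), area_ratio_max = 1.05)
  sw <- purity_vs_concentration(8e6, beads, c(bead_small = .4, bead_large = .6),
                                g, tsaw100, geom = geom02, flow = flow08,
                                coincidence = "abort", n_events = 2000,
                                reps = 1, seed = 5)
  expect_equal(nrow(sw), 1)
  expect_equal(sw$tp, 100)
  # beyond the single-occupancy limit a warning is emitted
  expect_warning(purity_vs_concentration(50e6, beads,
                                         c(bead_small = .4, bead_large = .6),
                                         g, tsaw100, geom = geom02,
                                         flow = flow08, n_events = 500,
                                         reps = 1, seed = 5),
                 "single-occupancy")
})

test_that("sort reports tidy into metric tables", {
  pops <- list(target = population_spec("target", 1,
                                        diameter_dist = dist_spec(14, 0.02)))
  set.seed(3)
  stream <- generate_arrival_stream(1e5, 0.08, 50, c(target = 1))
  ev <- sample_events_for_stream(stream, pops)
  g <- gate("all", area_range = c(100, 220), area_ratio_max = 2)
  run <- simulate_sort(stream, ev, g, tsaw100, geom = geom02, flow = flow08)
  td <- tidy(run)
  expect_true(all(c("metric", "value", "unit") %in% names(td)))
  expect_equal(td$value[td$metric == "n_total"], nrow(ev))
  gl <- glance(run)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$enrichment, gl$target_purity / gl$initial_purity,
               tolerance = 1e-9)
})
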