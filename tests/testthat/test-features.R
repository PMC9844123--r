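test_that("temporal-median background recovers the true level", {
  # identical frames -> exactly that frame
  f <- matrix(runif(64 * 64, 40, 60), 64, 64)
  expect_equal(estimate_background(list(f, f, f)), f)
  # noisy empty channel: median concentrates within 1 unit everywhere
  set.seed(3)
  frames <- lapply(1:100, function(i) matrix(rnorm(32 * 32, 50, 2), 32, 32))
  bg <- estimate_background(frames)
  expect_lt(max(abs(bg - 50)), 1)
  # robust to a single frame containing a cell
  cellframe <- frames[[1]]
  cellframe[10:20, 10:20] <- 200
  bg2 <- estimate_background(c(frames[-1], list(cellframe)))
  expect_lt(max(abs(bg2 - bg)), 1 + 1e-9)
  expect_error(estimate_background(frames[1]), class = "acoustosort_usage_error")
})

test_that("contour detection finds objects with accurate enclosed area", {
  blank <- matrix(50, 96, 96)
  expect_length(detect_contour(blank, blank), 0)
  disk <- render_frames(tibble::tibble(frame = 1, cx_px = 48, cy_px = 48,
                                       a_px = 20, b_px = 20, theta = 0,
                                       intensity = 50, asymmetry = 0),
                        96, 96, noise_sd = 0)$frames[[1]]
  cts <- detect_contour(disk, blank, threshold = 10)
  expect_length(cts, 1)
  expect_equal(cts[[1]]$area_px, pi * 20^2, tolerance = 0.02)
  # two disjoint disks, ordered by area descending
  two <- render_frames(tibble::tibble(frame = 1, cx_px = c(26, 70),
                                      cy_px = c(26, 70), a_px = c(8, 14),
                                      b_px = c(8, 14), theta = 0,
                                      intensity = 50, asymmetry = 0),
                       96, 96, noise_sd = 0)$frames[[1]]
  cts2 <- detect_contour(two, blank, threshold = 10)
  expect_length(cts2, 2)
  expect_gt(cts2[[1]]$area_px, cts2[[2]]$area_px)
  expect_error(detect_contour(disk, matrix(50, 10, 10)),
               class = "acoustosort_usage_error")
  expect_error(detect_contour(disk, blank, threshold = 0),
               class = "acoustosort_config_error")
})

test_that("deformation is the circularity complement", {
  r <- 7.3
  expect_equal(deformation(pi * r^2, 2 * pi * r), 0, tolerance = 1e-12)
  # ellipse semi-axes 10 and 5: quadrature perimeter 48.4422411027
  expect_equal(deformation(50 * pi, 48.4422411027), 0.0828494229,
               tolerance = 1e-6)
  # perimeter slightly below the circular bound gives a negative value
  A <- 100
  expect_lt(deformation(A, 2 * sqrt(pi * A) - 1e-6), 0)
  expect_error(deformation(0, 10), class = "acoustosort_domain_error")
  expect_error(deformation(10, -1), class = "acoustosort_domain_error")
})

test_that("area ratio compares hull and raw polygon areas", {
  square <- cbind(x = c(0, 2, 2, 0), y = c(0, 0, 2, 2))
  expect_equal(area_ratio(square, square), 1.0)
  # square with its bottom edge dented inward by a triangle of area 0.5
  dented <- cbind(x = c(0, 1, 2, 2, 0), y = c(0, 0.5, 0, 2, 2))
  expect_equal(area_ratio(square, dented), 4 / 3.5, tolerance = 1e-12)
  expect_error(area_ratio(square, cbind(x = c(0, 1, 2), y = c(0, 0, 0))),
               class = "acoustosort_domain_error")
})

test_that("brightness is the mean original intensity inside the raw contour", {
  uni <- matrix(100, 64, 64)
  circle <- cbind(x = 32 + 10 * cos(seq(0, 2 * pi, length.out = 60)),
                  y = 32 + 10 * sin(seq(0, 2 * pi, length.out = 60)))
  expect_equal(brightness(uni, circle), 100)
  # disk of 120 on background 50
  st <- render_frames(tibble::tibble(frame = 1, cx_px = 32, cy_px = 32,
                                     a_px = 10, b_px = 10, theta = 0,
                                     intensity = 70, asymmetry = 0),
                      64, 64, noise_sd = 0)
  cts <- detect_contour(st$frames[[1]], matrix(50, 64, 64))
  expect_equal(brightness(st$frames[[1]], cts[[1]]), 120, tolerance = 1)
  # half 120 / half 60 disk -> mean 90
  half <- matrix(60, 64, 64)
  half[, 33:64] <- 120
  mask_frame <- half
  expect_equal(brightness(mask_frame, circle), 90, tolerance = 1)
  tiny <- cbind(x = c(10.4, 10.6, 10.5), y = c(10.4, 10.4, 10.6))
  expect_error(brightness(uni, tiny), class = "acoustosort_domain_error")
})

test_that("feature recovery on rendered ellipses is accurate and unbiased", {
  n <- 24
  set.seed(14)
  area <- runif(n, 20, 200)
  D <- runif(n, 0, 0.2)
  st <- make_ellipse_stack(n, area, D, noise_sd = 2, seed = 14)
  ev <- extract_events(st, background = flat_background(st), track = FALSE)
  expect_equal(nrow(ev), n)
  ev <- ev[order(ev$frame_index), ]
  gt <- st$ground_truth[order(st$ground_truth$frame), ]
  expect_lt(mean(abs(ev$area_um2 - gt$area_um2) / gt$area_um2), 0.02)
  expect_lt(mean(abs(ev$deformation_unclamped - gt$deformation)), 0.01)
  expect_true(all(ev$area_ratio >= 1))
  # brightness bounded by the pixel range inside the contour
  expect_true(all(ev$brightness_au >= 0 & ev$brightness_au <= 255))
})

test_that("deformation is scale-equivariant within discretization tolerance", {
  for (s in c(1, 2)) {
    obj <- tibble::tibble(frame = 1, cx_px = 48 * s, cy_px = 48 * s,
                          a_px = 12 * s, b_px = 8 * s, theta = 0.5,
                          intensity = 60, asymmetry = 0)
    st <- render_frames(obj, 96 * s, 96 * s, noise_sd = 0)
    ev <- extract_events(st, background = flat_background(st), track = FALSE)
    if (s == 1) d1 <- ev$deformation else d2 <- ev$deformation
  }
  expect_lt(abs(d1 - d2), 0.01)
})

test_that("a cell crossing several frames is deduplicated to one event", {
  dx <- 6
  objs <- purrr::map_dfr(1:5, function(f) {
    tibble::tibble(frame = f, cx_px = 20 + dx * (f - 1), cy_px = 48,
                   a_px = 10, b_px = 8, theta = 0, intensity = 60,
                   asymmetry = 0)
  })
  st <- render_frames(objs, 96, 96, noise_sd = 0)
  ev_all <- extract_events(st, background = flat_background(st), track = FALSE)
  expect_equal(nrow(ev_all), 5)
  ev <- extract_events(st, background = flat_background(st), track = TRUE,
                       expected_dx_px = dx)
  expect_equal(nrow(ev), 1)
  # the representative detection is the one nearest the ROI centre
  expect_equal(ev$frame_index, 5)  # centres 20,26,32,38,44; ROI centre 47.5
})

test_that("extract_events on an empty stack yields an empty table", {
  st <- render_frames(NULL, 48, 48, n_frames = 3, noise_sd = 0)
  ev <- extract_events(st, background = flat_background(st))
  expect_equal(nrow(ev), 0)
})
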