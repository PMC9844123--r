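test_that("gate intervals are half-open with strict upper bounds", {
  g <- gate("g", area_range = c(50, 100), deformation_max = 0.12,
            area_ratio_max = 1.08)
  ev <- tibble::tibble(area_um2 = c(50, 99.999, 100, 49.999, 70),
                       deformation = c(0.05, 0.05, 0.05, 0.05, 0.12),
                       area_ratio = 1.0)
  expect_equal(apply_gate(ev, g), c(TRUE, TRUE, FALSE, FALSE, FALSE))
  # area-ratio bound is part of the ALL-criteria conjunction
  ev$area_ratio[1] <- 1.08
  expect_false(apply_gate(ev, g)[1])
  expect_error(apply_gate(tibble::tibble(deformation = 0.1), g),
               class = "acoustosort_usage_error")
  expect_error(gate("bad", area_range = c(100, 50)),
               class = "acoustosort_config_error")
})

test_that("gates select the population generated inside them", {
  blood <- blood_mixture_spec(n_per = 2000)
  ev <- dplyr::bind_rows(
    generate_population(blood$rbc, seed = 1),
    generate_population(blood$lymphocyte, seed = 2),
    generate_population(blood$myeloid, seed = 3))
  g_my <- gate("myeloid", area_range = c(50, 100), deformation_max = 0.12)
  sel <- ev[apply_gate(ev, g_my), ]
  expect_gt(mean(sel$label == "myeloid"), 0.9)
  expect_gt(sum(sel$label == "myeloid"), 1000)
})

test_that("a rectangular polygon gate equals the interval gate", {
  g_rect <- gate("r", area_range = c(50, 100), deformation_max = 0.12,
                 area_ratio_max = NULL)
  g_poly <- gate("p", polygon = data.frame(
    area_um2 = c(50, 100, 100, 50),
    deformation = c(0, 0, 0.12, 0.12)), area_ratio_max = NULL)
  set.seed(4)
  ev <- tibble::tibble(area_um2 = runif(2000, 20, 130),
                       deformation = runif(2000, 0, 0.3),
                       area_ratio = 1)
  m_rect <- apply_gate(ev, g_rect)
  m_poly <- apply_gate(ev, g_poly)
  # identical up to events exactly on the boundary (measure zero here)
  expect_equal(m_rect, m_poly)
})

test_that("gating is idempotent and composition can only lower purity", {
  set.seed(5)
  ev <- generate_population(population_spec("x", 5000))
  g1 <- gate("a", area_range = c(80, 120))
  once <- ev[apply_gate(ev, g1), ]
  twice <- once[apply_gate(once, g1), ]
  expect_identical(once, twice)
  g2 <- gate("b", deformation_max = 0.05)
  g12 <- gate("ab", area_range = c(80, 120), deformation_max = 0.05)
  expect_lte(purity(ev, g12), min(purity(ev, g1), purity(ev, g2)) + 1e-12)
})

test_that("purity is the gated percentage after the quality pre-filter", {
  ev <- tibble::tibble(area_um2 = c(60, 60, 200, 60),
                       deformation = 0.01, area_ratio = c(1, 1, 1, 1.2))
  g <- gate("g", area_range = c(50, 100), area_ratio_max = 1.08)
  # the 1.2-area-ratio event is excluded from numerator AND denominator
  expect_equal(purity(ev, g), 100 * 2 / 3)
  expect_error(purity(ev[ev$area_ratio > 2, ], g),
               class = "acoustosort_domain_error")
})

test_that("a constructed mixture reproduces its design purity", {
  set.seed(6)
  n <- 1e4
  inside <- stats::rbinom(1, n, 0.526)
  ev <- tibble::tibble(
    area_um2 = c(runif(inside, 115, 135), runif(n - inside, 140, 180)),
    deformation = 0.01, area_ratio = 1)
  g <- gate("beads", area_range = c(115, 135), area_ratio_max = 1.05)
  expect_lt(abs(purity(ev, g) - 52.6), 1.5)
})

test_that("enrichment reproduces published worked folds", {
  expect_equal(enrichment(52.6, 86.3), 1.64, tolerance = 0.005)
  expect_equal(enrichment(0.09, 60.0), 667, tolerance = 0.001)
  expect_equal(enrichment(30, 30), 1.0)
  expect_warning(e0 <- enrichment(0, 50), "infinite")
  expect_true(is.infinite(e0))
})

test_that("printed gating-table folds are consistent with their purities", {
  tab <- table1_gates()
  tab <- tab[tab$source == "table" & !tab$discrepant, ]
  expect_gte(nrow(tab), 9)
  folds <- enrichment(tab$ip, tab$tp)
  expect_true(all(abs(folds - tab$enrichment_printed) /
                    tab$enrichment_printed <= 0.03))
  # the flagged row is genuinely inconsistent with its own purities
  bad <- table1_gates()
  bad <- bad[bad$discrepant, ]
  expect_gt(abs(enrichment(bad$ip, bad$tp) - bad$enrichment_printed) /
              bad$enrichment_printed, 0.03)
})

test_that("recovery is the collected fraction of reported sorts", {
  expect_equal(recovery(100, 100), 100)
  expect_equal(recovery(72, 100), 72)
  expect_equal(recovery(0, 50), 0)
  expect_error(recovery(1, 0), class = "acoustosort_domain_error")
})

test_that("coefficient of variation uses the sample standard deviation", {
  expect_equal(coefficient_of_variation(c(9, 10, 11)), 10.0)
  expect_equal(coefficient_of_variation(rep(4, 10)), 0)
  set.seed(12)
  x <- stats::rnorm(1e4, 10, 0.32)
  expect_equal(coefficient_of_variation(x), 3.2, tolerance = 0.1 / 3.2)
  expect_error(coefficient_of_variation(5), class = "acoustosort_domain_error")
})

test_that("kernel density estimates integrate to one and find modes", {
  set.seed(13)
  x <- stats::rnorm(5000, 10, 1)
  curve <- kde_density(x)
  integral <- sum(diff(curve$value) *
                    (utils::head(curve$density, -1) + utils::tail(curve$density, -1)) / 2)
  expect_equal(integral, 1, tolerance = 1e-3)
  # narrow kernel on a repeated value peaks there
  curve2 <- kde_density(c(rep(5, 50), 5.0001), bandwidth = 0.01)
  expect_lt(abs(curve2$value[which.max(curve2$density)] - 5), 0.01)
  # bimodal bead mixture: modal gap in diameter units
  beads <- bead_mixture_spec()
  ev <- dplyr::bind_rows(generate_population(beads$bead_small, seed = 3),
                         generate_population(beads$bead_large, seed = 4))
  modes <- density_modes(kde_density(ev$diameter_um, bandwidth = 0.2))
  expect_lt(abs(abs(modes$value[1] - modes$value[2]) - 1.7), 0.15)
})
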