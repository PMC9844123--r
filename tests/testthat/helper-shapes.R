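# Shared fixture builders: rendered ellipse stacks with analytic ground
# truth. The axis-ratio solver inverts the quadrature-based boundary
# oracle, which is independent of the image pipeline under test.

# perimeter of an axis-aligned ellipse by arc-length quadrature
ellipse_perimeter <- function(a, b) {
  stats::integrate(function(t) sqrt((a * sin(t))^2 + (b * cos(t))^2),
                   0, 2 * pi, subdivisions = 1000, rel.tol = 1e-10)$value
}

# axis ratio a/b giving a prescribed deformation D
axis_ratio_for_deformation <- function(D) {
  if (D < 1e-4) return(1)
  f <- function(r) {
    A <- pi * r
    P <- ellipse_perimeter(r, 1)
    (1 - 2 * sqrt(pi * A) / P) - D
  }
  stats::uniroot(f, c(1 + 1e-6, 30), tol = 1e-10)$root
}

# one frame per object; centres jittered inside a margin that keeps every
# object fully inside the field
make_ellipse_stack <- function(n, area_um2, D, pixel_size_um = 0.34,
                               width_px = 128, intensity = 60, noise_sd = 2,
                               seed = 1, theta = NULL) {
  set.seed(seed)
  if (is.null(theta)) theta <- stats::runif(n, 0, pi)
  objs <- purrr::pmap_dfr(list(seq_len(n), area_um2, D, theta),
    function(i, A, d, th) {
      r <- axis_ratio_for_deformation(d)
      A_px <- A / pixel_size_um^2
      b <- sqrt(A_px / (pi * r))
      a <- r * b
      tibble::tibble(frame = i, cx_px = width_px / 2 + stats::runif(1, -8, 8),
                     cy_px = width_px / 2 + stats::runif(1, -8, 8),
                     a_px = a, b_px = b, theta = th,
                     intensity = intensity, asymmetry = 0)
    })
  render_frames(objs, width_px, width_px, n_frames = n,
                pixel_size_um = pixel_size_um, noise_sd = noise_sd, seed = seed)
}

flat_background <- function(stack) {
  matrix(stack$background_level, nrow(stack$frames[[1]]), ncol(stack$frames[[1]]))
}
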