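#' Render synthetic microfluidic frames with ground truth
#'
#' Rasterizes filled elliptical objects (optionally bullet-shaped via a
#' front-rear asymmetry term) over a uniform background with additive
#' Gaussian noise, emulating the bright-field frames a deformability
#' cytometer records. Pixel coverage is computed by 4x4 supersampling so
#' object edges are a one-pixel linear ramp, which is what lets the
#' sub-pixel contour detector localise boundaries accurately. Ground truth
#' (analytic area, perimeter, deformation of each rendered outline) is
#' retained alongside the frames.
#'
#' Object descriptors (`objects` tibble, one row per object):
#' `frame` (1-based frame index), `cx_px`, `cy_px` (centre, 0-based pixel
#' coordinates), `a_px`, `b_px` (semi-axes along/across flow), `theta`
#' (rotation, radians, default 0), `intensity` (signed contrast added to the
#' background), `asymmetry` (default 0; positive fattens the rear).
#'
#' @param objects tibble of object descriptors (see Details); may be empty.
#' @param width_px,height_px frame size in pixels.
#' @param n_frames number of frames (defaults to `max(objects$frame)`).
#' @param pixel_size_um physical pixel pitch, um per pixel (default 0.34).
#' @param frame_rate_fps acquisition rate (default 2700).
#' @param background_level background gray value (default 50, 8-bit scale).
#' @param noise_sd additive Gaussian noise sd in gray values (default 0).
#' @param seed optional integer seed for the noise.
#' @return a `frame_stack`: list with `frames` (list of numeric matrices,
#'   row = y, column = x), `pixel_size_um`, `frame_rate_fps`,
#'   `background_level`, and `ground_truth` (objects plus analytic
#'   `area_px2`, `perimeter_px`, `area_um2`, `perimeter_um`,
#'   `deformation`).
#' @export
render_frames <- function(objects = NULL, width_px = 96, height_px = 96,
                          n_frames = NULL, pixel_size_um = 0.34,
                          frame_rate_fps = 2700, background_level = 50,
                          noise_sd = 0, seed = NULL) {
  if (noise_sd < 0) {
    rlang::abort("render_frames: noise_sd must be >= 0", class = "acoustosort_config_error")
  }
  if (is.null(objects) || nrow(objects) == 0) {
    objects <- tibble::tibble(frame = integer(0), cx_px = numeric(0),
                              cy_px = numeric(0), a_px = numeric(0),
                              b_px = numeric(0), theta = numeric(0),
                              intensity = numeric(0), asymmetry = numeric(0))
  }
  if (!"theta" %in% names(objects)) objects$theta <- 0
  if (!"asymmetry" %in% names(objects)) objects$asymmetry <- 0
  if (is.null(n_frames)) n_frames <- max(1L, if (nrow(objects)) max(objects$frame) else 1L)

  # reject objects whose bounding extent leaves the imaged field
  if (nrow(objects) > 0) {
    ext <- pmax(objects$a_px, objects$b_px * (1 + abs(objects$asymmetry)))
    inside <- objects$cx_px - ext >= 0 & objects$cx_px + ext <= width_px - 1 &
      objects$cy_px - ext >= 0 & objects$cy_px + ext <= height_px - 1
    if (any(!inside)) {
      rlang::warn(sprintf("render_frames: %d object(s) outside the imaged field were rejected",
                          sum(!inside)))
      objects <- objects[inside, ]
    }
  }

  if (!is.null(seed)) set.seed(seed)
  frames <- vector("list", n_frames)
  for (f in seq_len(n_frames)) {
    img <- matrix(background_level, nrow = height_px, ncol = width_px)
    obj_f <- objects[objects$frame == f, , drop = FALSE]
    for (i in seq_len(nrow(obj_f))) {
      o <- obj_f[i, ]
      img <- add_object(img, o$cx_px, o$cy_px, o$a_px, o$b_px, o$theta,
                        o$intensity, o$asymmetry)
    }
    if (noise_sd > 0) {
      img <- img + matrix(stats::rnorm(length(img), 0, noise_sd), nrow = height_px)
    }
    frames[[f]] <- round(pmin(pmax(img, 0), 255))
  }

  gt <- ground_truth_shapes(objects, pixel_size_um)
  structure(list(frames = frames, pixel_size_um = pixel_size_um,
                 frame_rate_fps = frame_rate_fps,
                 background_level = background_level,
                 ground_truth = gt),
            class = "frame_stack")
}

# signed inside test for the (possibly asymmetric) ellipse, supersampled
add_object <- function(img, cx, cy, a, b, theta, intensity, asym, ss = 4) {
  h <- nrow(img); w <- ncol(img)
  ext <- ceiling(max(a, b * (1 + abs(asym))) + 2)
  rows <- max(1, floor(cy - ext) + 1):min(h, ceiling(cy + ext) + 1)
  cols <- max(1, floor(cx - ext) + 1):min(w, ceiling(cx + ext) + 1)
  off <- (seq_len(ss) - 0.5) / ss - 0.5
  cover <- matrix(0, nrow = length(rows), ncol = length(cols))
  for (dy in off) for (dx in off) {
    xs <- (cols - 1) + dx - cx
    ys <- (rows - 1) + dy - cy
    X <- matrix(xs, nrow = length(rows), ncol = length(cols), byrow = TRUE)
    Y <- matrix(ys, nrow = length(rows), ncol = length(cols))
    xp <- X * cos(theta) + Y * sin(theta)
    yp <- -X * sin(theta) + Y * cos(theta)
    u <- xp / a
    bb <- b * (1 + asym * pmin(pmax(u, -1), 1) / 2)
    cover <- cover + (u^2 + (yp / bb)^2 <= 1)
  }
  img[rows, cols] <- img[rows, cols] + intensity * cover / (ss * ss)
  img
}

# dense boundary polygon of the rendered shape; analytic-by-quadrature
# area/perimeter oracle shared by the tests
shape_boundary <- function(a, b, theta = 0, asym = 0, n = 2048) {
  t <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  xp <- a * cos(t)
  yp <- b * (1 + asym * cos(t) / 2) * sin(t)
  x <- xp * cos(theta) - yp * sin(theta)
  y <- xp * sin(theta) + yp * cos(theta)
  cbind(x = x, y = y)
}

ground_truth_shapes <- function(objects, pixel_size_um) {
  if (nrow(objects) == 0) {
    return(dplyr::mutate(objects, area_px2 = numeric(0), perimeter_px = numeric(0),
                         area_um2 = numeric(0), perimeter_um = numeric(0),
                         deformation = numeric(0)))
  }
  geo <- purrr::pmap_dfr(objects[c("a_px", "b_px", "theta", "asymmetry")],
    function(a_px, b_px, theta, asymmetry) {
      poly <- shape_boundary(a_px, b_px, theta, asymmetry)
      A <- polygon_area(poly)
      P <- polygon_perimeter(poly)
      tibble::tibble(area_px2 = A, perimeter_px = P)
    })
  dplyr::mutate(dplyr::bind_cols(objects, geo),
                area_um2 = .data$area_px2 * pixel_size_um^2,
                perimeter_um = .data$perimeter_px * pixel_size_um,
                deformation = deformation(.data$area_um2, .data$perimeter_um))
}

#' Write / read a frame stack as multi-page TIFF with a JSON sidecar
#'
#' Frames are stored as 8-bit grayscale TIFF pages; the stack metadata and
#' per-object ground truth go to `<path>.json`.
#'
#' @param stack a `frame_stack`.
#' @param path TIFF file path.
#' @return `write_frame_stack` returns `path` invisibly; `read_frame_stack`
#'   returns a `frame_stack`.
#' @export
write_frame_stack <- function(stack, path) {
  stopifnot(inherits(stack, "frame_stack"))
  pages <- lapply(stack$frames, function(m) m / 255)
  tiff::writeTIFF(pages, path, bits.per.sample = 8)
  meta <- list(pixel_size_um = stack$pixel_size_um,
               frame_rate_fps = stack$frame_rate_fps,
               background_level = stack$background_level,
               ground_truth = stack$ground_truth)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_frame_stack
#' @export
read_frame_stack <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  frames <- lapply(pages, function(m) round(m * 255))
  sidecar <- paste0(path, ".json")
  meta <- if (file.exists(sidecar)) jsonlite::read_json(sidecar, simplifyVector = TRUE) else list()
  gt <- if (!is.null(meta$ground_truth)) tibble::as_tibble(meta$ground_truth) else NULL
  structure(list(frames = frames,
                 pixel_size_um = meta$pixel_size_um %||% 0.34,
                 frame_rate_fps = meta$frame_rate_fps %||% 2700,
                 background_level = meta$background_level %||% 50,
                 ground_truth = gt),
            class = "frame_stack")
}
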