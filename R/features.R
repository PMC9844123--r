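#' @importFrom rlang .data %||%
NULL

#' Shoelace area and arc length of a closed polygon
#'
#' @param poly two-column matrix of vertices (closed implicitly).
#' @return area (absolute value) or perimeter.
#' @keywords internal
polygon_area <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  n <- length(x)
  j <- c(n, seq_len(n - 1))
  abs(sum(x[j] * y - x * y[j])) / 2
}

#' @rdname polygon_area
#' @keywords internal
polygon_perimeter <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  n <- length(x)
  j <- c(seq_len(n)[-1], 1)
  sum(sqrt((x[j] - x)^2 + (y[j] - y)^2))
}

polygon_centroid <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  n <- length(x)
  j <- c(seq_len(n)[-1], 1)
  cr <- x * y[j] - x[j] * y
  a <- sum(cr) / 2
  if (abs(a) < 1e-12) return(c(mean(x), mean(y)))
  c(sum((x + x[j]) * cr) / (6 * a), sum((y + y[j]) * cr) / (6 * a))
}

#' Deformation from area and perimeter
#'
#' The deformability-cytometry shape descriptor `D = 1 - 2*sqrt(pi*A)/l`
#' (one minus circularity): 0 for a circle, approaching 1 for increasingly
#' non-circular outlines. Perimeter underestimation can produce slightly
#' negative values for near-circular shapes; they are returned as-is so
#' callers can decide whether to clamp (see [extract_events()]).
#'
#' @param area projected area (any unit; must match `perimeter` squared).
#' @param perimeter contour perimeter.
#' @return dimensionless deformation, vectorized.
#' @examples
#' deformation(pi * 5^2, 2 * pi * 5)  # circle -> 0
#' @export
deformation <- function(area, perimeter) {
  if (any(area <= 0) || any(perimeter <= 0)) {
    rlang::abort("deformation: area and perimeter must be > 0",
                 class = "acoustosort_domain_error")
  }
  1 - 2 * sqrt(pi * area) / perimeter
}

#' Convex-hull to raw contour area ratio
#'
#' Quality metric `>= 1`; irregular or clumped detections have concave raw
#' contours and hence ratios well above 1, which is why gating strategies
#' bound it (typically `< 1.05` or `< 1.08`).
#'
#' @param hull,raw contour objects from [detect_contour()], or plain
#'   two-column vertex matrices (hull must be the convex hull of raw).
#' @return `hull_area / raw_area`.
#' @export
area_ratio <- function(hull, raw) {
  ha <- if (is.matrix(hull)) polygon_area(hull) else hull$hull_area_px
  ra <- if (is.matrix(raw)) polygon_area(raw) else raw$area_px
  if (ra <= 0) {
    rlang::abort("area_ratio: raw contour area must be > 0",
                 class = "acoustosort_domain_error")
  }
  ha / ra
}

#' Temporal-median background estimate
#'
#' Per-pixel median over the stack (optionally a sliding window ending at
#' each frame), robust to the occasional frame containing a cell.
#'
#' @param frames a `frame_stack` or list of matrices (at least 2).
#' @param window optional window length; default uses the full stack.
#' @return background matrix of the same shape as the frames.
#' @export
estimate_background <- function(frames, window = NULL) {
  fr <- if (inherits(frames, "frame_stack")) frames$frames else frames
  if (length(fr) < 2) {
    rlang::abort("estimate_background needs >= 2 frames; supply an explicit background for single frames",
                 class = "acoustosort_usage_error")
  }
  if (!is.null(window)) fr <- utils::tail(fr, window)
  arr <- array(unlist(fr), dim = c(nrow(fr[[1]]), ncol(fr[[1]]), length(fr)))
  apply(arr, c(1, 2), stats::median)
}

#' Detect sub-pixel object contours in a frame
#'
#' The absolute background-subtracted image is contoured at `threshold`
#' using marching squares with linear interpolation
#' ([grDevices::contourLines()]), yielding sub-pixel boundary polygons.
#' Components whose enclosed area is below `min_area_px` are discarded.
#' For each component the raw polygon and its convex hull are returned,
#' largest first.
#'
#' Coordinates are 0-based pixels: `x` along the flow direction (matrix
#' columns), `y` lateral (matrix rows).
#'
#' @param frame,background numeric matrices of identical shape.
#' @param threshold binarization level in intensity units above background
#'   (default 10, must be > 0).
#' @param min_area_px minimum enclosed area in px^2 (default 10).
#' @param smooth_sigma Gaussian pre-smoothing sd in px applied to the
#'   difference image before contouring (default 0.7; 0 disables). Smoothing
#'   suppresses noise-induced jaggedness that would otherwise inflate
#'   perimeters and hence deformation.
#' @param refine_edges re-localize each detected boundary at half the
#'   component's peak contrast (default TRUE). The detection threshold sits
#'   low on the intensity edge ramp, so the raw iso-contour lies outside
#'   the true object boundary; the half-contrast level is where the edge
#'   ramp crosses 50% and is the unbiased sub-pixel edge estimate.
#' @return list of contours, each a list with `raw` and `hull` vertex
#'   matrices (columns `x`, `y`), `area_px`, `hull_area_px`,
#'   `perimeter_px`, `hull_perimeter_px`, `centroid` (x, y).
#' @export
detect_contour <- function(frame, background, threshold = 10, min_area_px = 10,
                           smooth_sigma = 0.7, refine_edges = TRUE) {
  if (!all(dim(frame) == dim(background))) {
    rlang::abort("detect_contour: frame and background shapes differ",
                 class = "acoustosort_usage_error")
  }
  if (threshold <= 0) {
    rlang::abort("detect_contour: threshold must be > 0",
                 class = "acoustosort_config_error")
  }
  diff <- abs(frame - background)
  if (smooth_sigma > 0) diff <- gaussian_smooth(diff, smooth_sigma)
  polys <- closed_contours(diff, threshold, min_area_px)
  out <- list()
  for (poly in polys) {
    if (refine_edges) {
      ref <- refine_contour(diff, poly, threshold, min_area_px)
      if (!is.null(ref)) poly <- ref
    }
    a <- polygon_area(poly)
    if (a < min_area_px) next
    hidx <- grDevices::chull(poly)
    hull <- poly[hidx, , drop = FALSE]
    out[[length(out) + 1]] <- list(
      raw = poly, hull = hull,
      area_px = a, hull_area_px = polygon_area(hull),
      perimeter_px = polygon_perimeter(poly),
      hull_perimeter_px = polygon_perimeter(hull),
      centroid = polygon_centroid(poly)
    )
  }
  out[order(vapply(out, function(o) o$area_px, numeric(1)), decreasing = TRUE)]
}

# marching-squares iso-contours of z at `level`, closed, area >= min_area
closed_contours <- function(z, level, min_area) {
  cl <- grDevices::contourLines(x = 0:(ncol(z) - 1), y = 0:(nrow(z) - 1),
                                z = t(z), levels = level)
  polys <- list()
  for (cc in cl) {
    poly <- cbind(x = cc$x, y = cc$y)
    if (nrow(poly) < 3) next
    closed <- all(abs(poly[1, ] - poly[nrow(poly), ]) < 1e-9)
    if (closed) poly <- poly[-nrow(poly), , drop = FALSE]
    if (polygon_area(poly) < min_area) next
    polys[[length(polys) + 1]] <- poly
  }
  polys
}

# re-contour one component at half its peak contrast, on a padded crop
refine_contour <- function(diff, poly, threshold, min_area) {
  pad <- 3L
  cols <- max(1L, floor(min(poly[, 1])) + 1L - pad):min(ncol(diff), ceiling(max(poly[, 1])) + 1L + pad)
  rows <- max(1L, floor(min(poly[, 2])) + 1L - pad):min(nrow(diff), ceiling(max(poly[, 2])) + 1L + pad)
  crop <- diff[rows, cols, drop = FALSE]
  peak <- stats::quantile(crop, 0.995, names = FALSE)
  level <- peak / 2
  if (level <= threshold) return(NULL)   # faint object: keep detection contour
  cen <- polygon_centroid(poly)
  cands <- closed_contours(crop, level, min_area)
  for (cp in cands) {
    cp[, 1] <- cp[, 1] + (cols[1] - 1)
    cp[, 2] <- cp[, 2] + (rows[1] - 1)
    if (pracma::inpolygon(cen[1], cen[2], cp[, 1], cp[, 2], boundary = TRUE)) {
      return(cp)
    }
  }
  NULL
}

# separable Gaussian smoothing with reflected borders
gaussian_smooth <- function(m, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-r:r, 0, sigma)
  k <- k / sum(k)
  pad_conv <- function(v) {
    n <- length(v)
    vp <- c(rev(v[seq_len(r)]), v, rev(v[n - seq_len(r) + 1]))
    as.numeric(stats::filter(vp, k, sides = 2))[(r + 1):(r + n)]
  }
  m2 <- apply(m, 2, pad_conv)
  t(apply(m2, 1, pad_conv))
}

#' Mean brightness inside a contour
#'
#' Arithmetic mean of the *original* (not background-subtracted) grayscale
#' values of pixels strictly inside the raw contour.
#'
#' @param frame numeric matrix.
#' @param contour a contour from [detect_contour()] or a vertex matrix.
#' @return mean gray value (a.u.).
#' @export
brightness <- function(frame, contour) {
  poly <- if (is.matrix(contour)) contour else contour$raw
  xr <- range(poly[, 1]); yr <- range(poly[, 2])
  cols <- max(1, floor(xr[1]) + 1):min(ncol(frame), ceiling(xr[2]) + 1)
  rows <- max(1, floor(yr[1]) + 1):min(nrow(frame), ceiling(yr[2]) + 1)
  px <- expand.grid(x = cols - 1, y = rows - 1)
  inside <- pracma::inpolygon(px$x, px$y, poly[, 1], poly[, 2], boundary = FALSE)
  if (!any(inside)) {
    rlang::abort("brightness: contour encloses no pixel centres",
                 class = "acoustosort_domain_error")
  }
  mean(frame[cbind(px$y[inside] + 1, px$x[inside] + 1)])
}

#' Extract per-event morphometric features from a frame stack
#'
#' Runs the full real-time pipeline: temporal-median background,
#' sub-pixel contour detection, convex hull, and the four gating features.
#' Gating features (area, perimeter, hence deformation) are computed on the
#' convex-hull contour; the raw-contour values are stored alongside, and the
#' hull/raw area ratio is the data-quality feature. Negative deformations
#' (possible from perimeter underestimation on near-circles) are clamped to
#' 0 in `deformation` and kept raw in `deformation_unclamped`.
#'
#' The same physical cell seen in consecutive frames is deduplicated by
#' centroid tracking: detections one frame apart whose centroid moved by
#' `expected_dx_px` (+/- `track_tol_px`) along the flow are merged, keeping
#' the detection nearest `roi_center_x_px`.
#'
#' @param stack a `frame_stack`.
#' @param threshold,min_area_px,smooth_sigma see [detect_contour()].
#' @param background optional explicit background matrix; default is the
#'   temporal median of the stack.
#' @param track deduplicate across frames (default TRUE).
#' @param expected_dx_px expected per-frame centroid advance along x
#'   (default 0: static test stacks).
#' @param track_tol_px matching tolerance in px (default 3).
#' @param roi_center_x_px representative-frame criterion (default image
#'   centre).
#' @return event tibble: `id`, `frame_index`, `time_s`, `area_um2`,
#'   `perimeter_um`, `deformation`, `deformation_unclamped`,
#'   `area_raw_um2`, `area_ratio`, `brightness_au`, `diameter_um`,
#'   `centroid_x_um`, `centroid_y_um`.
#' @export
extract_events <- function(stack, threshold = 10, min_area_px = 10,
                           smooth_sigma = 0.7, background = NULL,
                           track = TRUE, expected_dx_px = 0,
                           track_tol_px = 3, roi_center_x_px = NULL) {
  stopifnot(inherits(stack, "frame_stack"))
  if (length(stack$frames) == 0) return(empty_feature_table())
  if (is.null(background)) {
    background <- if (length(stack$frames) >= 2) estimate_background(stack)
    else matrix(stack$background_level, nrow(stack$frames[[1]]), ncol(stack$frames[[1]]))
  }
  if (is.null(roi_center_x_px)) roi_center_x_px <- (ncol(stack$frames[[1]]) - 1) / 2
  px <- stack$pixel_size_um
  rows <- list()
  for (f in seq_along(stack$frames)) {
    frame <- stack$frames[[f]]
    for (ct in detect_contour(frame, background, threshold, min_area_px, smooth_sigma)) {
      d_un <- deformation(ct$hull_area_px, ct$hull_perimeter_px)
      rows[[length(rows) + 1]] <- tibble::tibble(
        frame_index = f,
        time_s = (f - 1) / stack$frame_rate_fps,
        area_um2 = ct$hull_area_px * px^2,
        perimeter_um = ct$hull_perimeter_px * px,
        deformation = max(0, d_un),
        deformation_unclamped = d_un,
        area_raw_um2 = ct$area_px * px^2,
        area_ratio = ct$hull_area_px / ct$area_px,
        brightness_au = brightness(frame, ct),
        centroid_x_px = ct$centroid[1],
        centroid_y_px = ct$centroid[2]
      )
    }
  }
  if (length(rows) == 0) return(empty_feature_table())
  ev <- dplyr::bind_rows(rows)
  if (track && nrow(ev) > 1) ev <- dedup_tracks(ev, expected_dx_px, track_tol_px, roi_center_x_px)
  ev <- dplyr::mutate(ev,
                      id = dplyr::row_number(),
                      diameter_um = 2 * sqrt(.data$area_um2 / pi),
                      centroid_x_um = .data$centroid_x_px * px,
                      centroid_y_um = .data$centroid_y_px * px)
  dplyr::select(ev, "id", "frame_index", "time_s", "area_um2", "perimeter_um",
                "deformation", "deformation_unclamped", "area_raw_um2",
                "area_ratio", "brightness_au", "diameter_um",
                "centroid_x_um", "centroid_y_um")
}

empty_feature_table <- function() {
  tibble::tibble(id = integer(0), frame_index = integer(0), time_s = numeric(0),
                 area_um2 = numeric(0), perimeter_um = numeric(0),
                 deformation = numeric(0), deformation_unclamped = numeric(0),
                 area_raw_um2 = numeric(0), area_ratio = numeric(0),
                 brightness_au = numeric(0), diameter_um = numeric(0),
                 centroid_x_um = numeric(0), centroid_y_um = numeric(0))
}

# greedy frame-to-frame linking; one representative detection per track
dedup_tracks <- function(ev, expected_dx_px, tol, roi_center) {
  ev <- dplyr::arrange(ev, .data$frame_index, dplyr::desc(.data$area_um2))
  track_id <- integer(nrow(ev))
  next_id <- 0L
  open <- list()  # track id -> list(frame, cx, cy)
  for (i in seq_len(nrow(ev))) {
    f <- ev$frame_index[i]; cx <- ev$centroid_x_px[i]; cy <- ev$centroid_y_px[i]
    matched <- 0L
    for (tid in names(open)) {
      tr <- open[[tid]]
      if (f - tr$frame == 1 &&
          abs(cx - (tr$cx + expected_dx_px)) <= tol && abs(cy - tr$cy) <= tol) {
        matched <- as.integer(tid)
        break
      }
    }
    if (matched == 0L) {
      next_id <- next_id + 1L
      matched <- next_id
    }
    track_id[i] <- matched
    open[[as.character(matched)]] <- list(frame = f, cx = cx, cy = cy)
    open <- open[vapply(open, function(tr) f - tr$frame <= 1, logical(1))]
  }
  ev$track_id <- track_id
  ev |>
    dplyr::group_by(.data$track_id) |>
    dplyr::slice_min(abs(.data$centroid_x_px - roi_center), n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::select(-"track_id") |>
    dplyr::arrange(.data$frame_index)
}
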