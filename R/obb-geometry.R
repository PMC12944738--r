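#' Principal-axis endpoints of oriented boxes
#'
#' For each detection, finds the midpoints of the two opposing longer sides
#' of the rotated rectangle. The longer side defines the bar's principal
#' axis, so the two midpoints approximate the bar's two ends. With corners
#' P1..P4 listed consecutively and side lengths `L1 = |P1 - P2|`,
#' `L2 = |P2 - P3|`: if `L1 > L2` the endpoints are `(P1 + P4) / 2` and
#' `(P2 + P3) / 2`, otherwise (including the square tie) `(P1 + P2) / 2`
#' and `(P3 + P4) / 2`.
#'
#' @param detections Detection tibble as returned by
#'   [read_obb_detections()] (columns `frame`, `class`, `x1`..`y4`).
#' @return The input with columns `L1`, `L2` (pixel side lengths) and the
#'   endpoint coordinates `m1x`, `m1y`, `m2x`, `m2y` appended.
#' @export
axis_midpoints <- function(detections) {
  d <- detections
  d$L1 <- sqrt((d$x1 - d$x2)^2 + (d$y1 - d$y2)^2)
  d$L2 <- sqrt((d$x2 - d$x3)^2 + (d$y2 - d$y3)^2)
  if (any(d$L1 <= 0 & d$L2 <= 0)) {
    abort("Degenerate box: both side lengths are zero.",
          class = "lp_degenerate_geometry")
  }
  long1 <- d$L1 > d$L2
  d$m1x <- ifelse(long1, (d$x1 + d$x4) / 2, (d$x1 + d$x2) / 2)
  d$m1y <- ifelse(long1, (d$y1 + d$y4) / 2, (d$y1 + d$y2) / 2)
  d$m2x <- ifelse(long1, (d$x2 + d$x3) / 2, (d$x3 + d$x4) / 2)
  d$m2y <- ifelse(long1, (d$y2 + d$y3) / 2, (d$y3 + d$y4) / 2)
  if (any(d$m1x == d$m2x & d$m1y == d$m2y)) {
    abort("Degenerate box: axis endpoints coincide.",
          class = "lp_degenerate_geometry")
  }
  tibble::as_tibble(d)
}

#' Classify axis endpoints as moving vs fixed end
#'
#' In image coordinates (origin top-left, y increasing downward) the
#' landmine's anchored end sits lower in the frame than the pressed end, so
#' the endpoint with the smaller image-y is the moving end. On an exact tie
#' the second endpoint is taken as moving.
#'
#' @param midpoints Output of [axis_midpoints()].
#' @return The input with `moving_x`, `moving_y`, `fixed_x`, `fixed_y`
#'   appended (pixel coordinates).
#' @export
classify_ends <- function(midpoints) {
  d <- midpoints
  m1_moving <- d$m1y < d$m2y
  d$moving_x <- ifelse(m1_moving, d$m1x, d$m2x)
  d$moving_y <- ifelse(m1_moving, d$m1y, d$m2y)
  d$fixed_x <- ifelse(m1_moving, d$m2x, d$m1x)
  d$fixed_y <- ifelse(m1_moving, d$m2y, d$m1y)
  tibble::as_tibble(d)
}

best_per_class <- function(rows) {
  rows |>
    dplyr::group_by(.data$class) |>
    dplyr::arrange(dplyr::desc(dplyr::coalesce(.data$conf, 1))) |>
    dplyr::slice(1L) |>
    dplyr::ungroup()
}

frame_endpoints <- function(rows) {
  has_markers <- all(c("moving_marker", "fixed_marker") %in% rows$class)
  if (has_markers) {
    mv <- rows[rows$class == "moving_marker", ]
    fx <- rows[rows$class == "fixed_marker", ]
    p <- c(mv = (mv$x1 + mv$x2 + mv$x3 + mv$x4) / 4,
           mvy = (mv$y1 + mv$y2 + mv$y3 + mv$y4) / 4,
           fx = (fx$x1 + fx$x2 + fx$x3 + fx$x4) / 4,
           fxy = (fx$y1 + fx$y2 + fx$y3 + fx$y4) / 4)
    # vertical-position rule as a consistency check on the class labels
    if (p[["mvy"]] >= p[["fxy"]]) {
      warn(sprintf(
        "Frame %d: class labels disagree with the vertical-position rule; trusting geometry.",
        rows$frame[1]), class = "lp_class_disagreement")
      p <- p[c(3, 4, 1, 2)]
    }
    return(tibble::tibble(frame = rows$frame[1],
                          moving_x = p[[1]], moving_y = p[[2]],
                          fixed_x = p[[3]], fixed_y = p[[4]]))
  }
  if ("bar" %in% rows$class) {
    bar <- classify_ends(axis_midpoints(rows[rows$class == "bar", ][1, ]))
    return(bar[, c("frame", "moving_x", "moving_y", "fixed_x", "fixed_y")])
  }
  NULL
}

#' Build a per-frame end-point track from detections
#'
#' Reduces each frame's detections to one moving-end and one fixed-end pixel
#' point. Frames carrying both marker-class boxes use the box centres;
#' frames carrying a `bar` box use its principal-axis endpoints
#' ([axis_midpoints()] + [classify_ends()]). Missing frames up to `max_gap`
#' long are filled by linear interpolation and flagged in `interpolated`;
#' longer gaps split the track into separate `block`s, which downstream
#' analysis treats as independent contiguous recordings. Blocks with fewer
#' than two frames are dropped.
#'
#' @param detections Detection tibble from [read_obb_detections()].
#' @param fps Frame rate in Hz.
#' @param image_height Image height in pixels (kept for the later y-up flip).
#' @param max_gap Longest run of missing frames to bridge by interpolation.
#' @return A tibble of class `lp_end_track` with columns `frame`, `t`
#'   (seconds from the first tracked frame), `moving_x`, `moving_y`,
#'   `fixed_x`, `fixed_y` (pixels), `interpolated`, `block`; attributes
#'   `fps` and `image_height`.
#' @export
build_end_track <- function(detections, fps, image_height = 1080,
                            max_gap = 5L) {
  if (!nrow(detections)) {
    abort("No detections supplied.", class = "lp_insufficient_data")
  }
  pts <- detections |>
    dplyr::group_by(.data$frame) |>
    dplyr::group_split() |>
    purrr::map(\(rows) frame_endpoints(best_per_class(rows))) |>
    purrr::compact() |>
    purrr::list_rbind() |>
    dplyr::arrange(.data$frame)
  if (nrow(pts) < 2L) {
    abort("Fewer than 2 frames with a usable end-point pair.",
          class = "lp_insufficient_data")
  }
  gaps <- diff(pts$frame) - 1L
  block <- cumsum(c(0L, gaps > max_gap)) + 1L
  out <- vector("list", max(block))
  for (b in seq_len(max(block))) {
    seg <- pts[block == b, ]
    if (nrow(seg) < 2L) next
    frames <- seq(min(seg$frame), max(seg$frame))
    interp <- function(col) stats::approx(seg$frame, seg[[col]], xout = frames)$y
    out[[b]] <- tibble::tibble(
      frame = frames,
      moving_x = interp("moving_x"), moving_y = interp("moving_y"),
      fixed_x = interp("fixed_x"), fixed_y = interp("fixed_y"),
      interpolated = !(frames %in% seg$frame),
      block = b)
  }
  out <- purrr::list_rbind(purrr::compact(out))
  if (!nrow(out) || !any(table(out$block) >= 2)) {
    abort("No contiguous block with at least 2 usable frames.",
          class = "lp_insufficient_data")
  }
  out$block <- as.integer(factor(out$block))
  out$t <- (out$frame - out$frame[1]) / fps
  out <- out[, c("frame", "t", "moving_x", "moving_y", "fixed_x", "fixed_y",
                 "interpolated", "block")]
  structure(out, fps = as.numeric(fps),
            image_height = as.numeric(image_height),
            class = c("lp_end_track", class(out)))
}

#' Calibrate a pixel track to metres
#'
#' Converts the pixel-space end-point track to a physical, y-up coordinate
#' frame with the origin at the pivot. The scale factor is
#' `s = L_real / L_pixel`, where `L_pixel` is the mean over frames of the
#' pixel distance between the two ends and `L_real` is the true bar length
#' in metres, so the mean metre-space bar length equals `L_real` exactly.
#' The pivot is taken as the per-axis median of the fixed-end detections
#' (robust to frame-to-frame jitter of the anchored end), and the image
#' y-axis is flipped so upward pressing gives increasing y.
#'
#' @param track An `lp_end_track` from [build_end_track()].
#' @param bar_length Real bar length `L_real` in metres (2.20 m for a full
#'   Olympic bar).
#' @return A tibble of class `lp_trajectory` with columns `frame`, `t`,
#'   `x`, `y` (moving end, metres, pivot at the origin), `fixed_x`,
#'   `fixed_y` (per-frame fixed end in the same frame), `interpolated`,
#'   `block`; attributes `scale_s` (m/px), `L_pixel_mean`, `L_real`, `fps`,
#'   `pivot_px`.
#' @export
calibrate <- function(track, bar_length = 2.20) {
  stopifnot(inherits(track, "lp_end_track"))
  if (bar_length <= 0) {
    abort("`bar_length` must be positive (metres).", class = "lp_config_error")
  }
  d_px <- sqrt((track$moving_x - track$fixed_x)^2 +
                 (track$moving_y - track$fixed_y)^2)
  L_pixel <- mean(d_px)
  if (!is.finite(L_pixel) || L_pixel <= 0) {
    abort("Mean pixel bar length is zero; cannot calibrate.",
          class = "lp_degenerate_geometry")
  }
  s <- bar_length / L_pixel
  pivot <- c(x = median(track$fixed_x), y = median(track$fixed_y))
  out <- tibble::tibble(
    frame = track$frame, t = track$t,
    x = s * (track$moving_x - pivot[["x"]]),
    y = s * (pivot[["y"]] - track$moving_y),
    fixed_x = s * (track$fixed_x - pivot[["x"]]),
    fixed_y = s * (pivot[["y"]] - track$fixed_y),
    interpolated = track$interpolated, block = track$block)
  structure(out, scale_s = s, L_pixel_mean = L_pixel, L_real = bar_length,
            fps = attr(track, "fps"), pivot_px = pivot,
            class = c("lp_trajectory", class(out)))
}

#' @export
print.lp_trajectory <- function(x, ...) {
  cat(sprintf(
    "<lp_trajectory> %d frames @ %g fps | scale %.6g m/px | L_real %.3g m\n",
    nrow(x), attr(x, "fps"), attr(x, "scale_s"), attr(x, "L_real")))
  NextMethod()
}
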