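#' Read oriented-bounding-box detections
#'
#' Ingests per-frame OBB detections of the barbell (and/or its two ends) in
#' either of two dialects:
#'
#' * `"yolo_obb_txt"`: a directory of label files, one per frame, each line
#'   `class x1 y1 x2 y2 x3 y3 x4 y4 [conf]` with corner coordinates
#'   normalised to the image size. The frame index is parsed from the
#'   trailing digits of each file name.
#' * `"long_csv"`: a single CSV with header columns
#'   `frame,class,x1,y1,x2,y2,x3,y3,x4,y4,conf`, corners already in pixels.
#'
#' Class labels may be given as names (`bar`, `moving_marker`,
#' `fixed_marker`) or as the integer codes 0/1/2 in that order. Corners are
#' validated (four per box, positive polygon area) and re-ordered by winding
#' around the centroid if the listed order produces crossing edges.
#'
#' @param source Directory of label files (`yolo_obb_txt`) or a CSV path
#'   (`long_csv`).
#' @param dialect One of `"yolo_obb_txt"`, `"long_csv"`.
#' @param image_width,image_height Image size in pixels, used to de-normalise
#'   `yolo_obb_txt` coordinates (and by downstream y-axis flipping).
#' @return A tibble with one row per detected box: `frame`, `class`,
#'   `x1`..`y4` (pixels), `conf` (`NA` when absent). Frames with no
#'   detections are simply absent.
#' @seealso [build_end_track()] to reduce detections to per-frame end points.
#' @export
read_obb_detections <- function(source,
                                dialect = c("yolo_obb_txt", "long_csv"),
                                image_width = 1920, image_height = 1080) {
  dialect <- match.arg(dialect)
  det <- switch(dialect,
    yolo_obb_txt = read_yolo_obb_dir(source, image_width, image_height),
    long_csv = read_obb_long_csv(source)
  )
  validate_detections(det)
}

class_levels <- c("bar", "moving_marker", "fixed_marker")

decode_class <- function(x) {
  if (is.numeric(x) || all(grepl("^[0-9]+$", x))) {
    idx <- as.integer(as.numeric(x)) + 1L
    if (any(idx < 1L | idx > 3L)) {
      abort("Class codes must be 0 (bar), 1 (moving_marker) or 2 (fixed_marker).",
            class = "lp_parse_error")
    }
    return(class_levels[idx])
  }
  x <- as.character(x)
  bad <- setdiff(unique(x), class_levels)
  if (length(bad)) {
    abort(paste0("Unknown class label(s): ", paste(bad, collapse = ", ")),
          class = "lp_parse_error")
  }
  x
}

read_yolo_obb_dir <- function(dir, image_width, image_height) {
  if (!dir.exists(dir)) {
    abort(paste0("Label directory not found: ", dir), class = "lp_parse_error")
  }
  files <- sort(list.files(dir, pattern = "\\.txt$", full.names = TRUE))
  rows <- purrr::map(files, function(f) {
    stem <- sub("\\.txt$", "", basename(f))
    m <- regmatches(stem, regexpr("[0-9]+$", stem))
    if (!length(m)) {
      abort(paste0("Cannot parse a frame index from file name: ", basename(f)),
            class = "lp_parse_error")
    }
    frame <- as.integer(m)
    lines <- readLines(f, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (!length(lines)) return(NULL)
    purrr::imap(lines, function(line, i) {
      tok <- strsplit(trimws(line), "[[:space:]]+")[[1]]
      if (!length(tok) %in% c(9L, 10L)) {
        abort(sprintf("%s line %d: expected 9 or 10 fields, found %d.",
                      basename(f), i, length(tok)), class = "lp_parse_error")
      }
      val <- suppressWarnings(as.numeric(tok[-1L]))
      if (anyNA(val)) {
        abort(sprintf("%s line %d: non-numeric coordinate.", basename(f), i),
              class = "lp_parse_error")
      }
      xs <- val[c(1, 3, 5, 7)]
      ys <- val[c(2, 4, 6, 8)]
      if (any(xs < 0 | xs > 1 | ys < 0 | ys > 1)) {
        abort(sprintf("%s line %d: normalised coordinates must lie in [0, 1].",
                      basename(f), i), class = "lp_parse_error")
      }
      tibble::tibble(
        frame = frame, class = decode_class(tok[1L]),
        x1 = xs[1] * image_width, y1 = ys[1] * image_height,
        x2 = xs[2] * image_width, y2 = ys[2] * image_height,
        x3 = xs[3] * image_width, y3 = ys[3] * image_height,
        x4 = xs[4] * image_width, y4 = ys[4] * image_height,
        conf = if (length(val) == 9L) val[9L] else NA_real_
      )
    }) |> purrr::list_rbind()
  })
  out <- purrr::list_rbind(purrr::compact(rows))
  if (!nrow(out)) {
    return(tibble::tibble(frame = integer(), class = character(),
                          x1 = double(), y1 = double(), x2 = double(),
                          y2 = double(), x3 = double(), y3 = double(),
                          x4 = double(), y4 = double(), conf = double()))
  }
  dplyr::arrange(out, .data$frame)
}

read_obb_long_csv <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("CSV not found: ", path), class = "lp_parse_error")
  }
  det <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("frame", "class", paste0(rep(c("x", "y"), 4), rep(1:4, each = 2)))
  missing_cols <- setdiff(need, names(det))
  if (length(missing_cols)) {
    abort(paste0("CSV is missing required column(s): ",
                 paste(missing_cols, collapse = ", ")), class = "lp_parse_error")
  }
  if (!"conf" %in% names(det)) det$conf <- NA_real_
  det$class <- decode_class(det$class)
  det$frame <- as.integer(det$frame)
  dplyr::arrange(tibble::as_tibble(det[c(need, "conf")]), .data$frame)
}

segments_cross <- function(p1, p2, p3, p4) {
  side <- function(a, b, c) {
    sign((b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1]))
  }
  side(p1, p2, p3) * side(p1, p2, p4) < 0 &&
    side(p3, p4, p1) * side(p3, p4, p2) < 0
}

# Re-order a box's corners consecutively around the rectangle when the
# listed order has crossing edges (non-simple polygon).
fix_corner_order <- function(xs, ys) {
  P <- lapply(1:4, function(i) c(xs[i], ys[i]))
  crossing <- segments_cross(P[[1]], P[[2]], P[[3]], P[[4]]) ||
    segments_cross(P[[2]], P[[3]], P[[4]], P[[1]])
  if (!crossing) return(list(x = xs, y = ys))
  cx <- mean(xs); cy <- mean(ys)
  ord <- order(atan2(ys - cy, xs - cx))
  # keep the original first corner first to preserve labelling intent
  k <- which(ord == 1L)
  ord <- c(ord[k:4], ord[seq_len(k - 1L)])
  list(x = xs[ord], y = ys[ord])
}

polygon_area <- function(xs, ys) {
  abs(sum(xs * c(ys[-1], ys[1]) - c(xs[-1], xs[1]) * ys)) / 2
}

validate_detections <- function(det) {
  if (!nrow(det)) return(det)
  for (i in seq_len(nrow(det))) {
    xs <- as.numeric(det[i, c("x1", "x2", "x3", "x4")])
    ys <- as.numeric(det[i, c("y1", "y2", "y3", "y4")])
    fixed <- fix_corner_order(xs, ys)
    if (polygon_area(fixed$x, fixed$y) <= 0) {
      abort(sprintf("Degenerate zero-area box at frame %d.", det$frame[i]),
            class = "lp_degenerate_geometry")
    }
    det[i, c("x1", "x2", "x3", "x4")] <- as.list(fixed$x)
    det[i, c("y1", "y2", "y3", "y4")] <- as.list(fixed$y)
  }
  det
}

#' Write detections as YOLO-OBB label files
#'
#' Inverse of [read_obb_detections()] for the `yolo_obb_txt` dialect: writes
#' one `frame_%06d.txt` per frame with normalised corner coordinates, e.g.
#' to materialise synthetic fixtures on disk.
#'
#' @param detections Detection tibble (`frame`, `class`, `x1`..`y4`, `conf`).
#' @param dir Output directory (created if needed).
#' @inheritParams read_obb_detections
#' @return Invisibly, the paths written.
#' @export
write_obb_labels <- function(detections, dir,
                             image_width = 1920, image_height = 1080) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (fr in sort(unique(detections$frame))) {
    rows <- detections[detections$frame == fr, ]
    lines <- vapply(seq_len(nrow(rows)), function(i) {
      r <- rows[i, ]
      cls <- match(r$class, class_levels) - 1L
      coords <- sprintf("%.8f", c(
        r$x1 / image_width, r$y1 / image_height, r$x2 / image_width,
        r$y2 / image_height, r$x3 / image_width, r$y3 / image_height,
        r$x4 / image_width, r$y4 / image_height))
      line <- paste(c(cls, coords), collapse = " ")
      if (!is.na(r$conf)) line <- paste(line, sprintf("%.4f", r$conf))
      line
    }, character(1))
    path <- file.path(dir, sprintf("frame_%06d.txt", fr))
    writeLines(lines, path)
    paths <- c(paths, path)
  }
  invisible(paths)
}
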