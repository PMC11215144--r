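#' Build a tibble of bounding boxes
#'
#' Boxes live in continuous pixel coordinates with the origin at the top-left
#' corner, x rightward and y downward, and are stored in centre form: centre
#' `(cx, cy)`, width `w`, height `h`, optional detection confidence `conf`.
#' Every function in the package that takes boxes accepts any data frame with
#' these columns; `bbox()` is a convenience constructor that validates them.
#'
#' @param cx,cy Box centre, pixels.
#' @param w,h Box width and height, pixels; must be strictly positive.
#' @param conf Detection confidence in \[0, 1\]; recycled, default 1.
#' @return A tibble with columns `cx`, `cy`, `w`, `h`, `conf`.
#' @examples
#' bbox(cx = c(5, 10), cy = c(5, 10), w = 4, h = 4)
#' @export
bbox <- function(cx, cy, w, h, conf = 1) {
  out <- tibble::tibble(cx = as.numeric(cx), cy = as.numeric(cy),
                        w = as.numeric(w), h = as.numeric(h),
                        conf = as.numeric(conf))
  validate_boxes(out)
  out
}

#' Validate a data frame of boxes
#'
#' Checks that `cx`, `cy`, `w`, `h` are present, finite, and that all widths
#' and heights are strictly positive. Degenerate (zero-area) boxes are
#' rejected rather than clamped: they signal upstream bugs.
#'
#' @param boxes A data frame of boxes (see [bbox()]).
#' @return `boxes`, invisibly.
#' @export
validate_boxes <- function(boxes) {
  need <- c("cx", "cy", "w", "h")
  missing_cols <- setdiff(need, names(boxes))
  if (length(missing_cols)) {
    abort(paste0("boxes must have columns ", paste(need, collapse = ", "),
                 "; missing: ", paste(missing_cols, collapse = ", ")),
          class = "earcount_invalid_box")
  }
  if (!(all(is.finite(boxes$cx)) && all(is.finite(boxes$cy)) &&
        all(is.finite(boxes$w)) && all(is.finite(boxes$h)))) {
    abort("boxes contain non-finite coordinates", class = "earcount_invalid_box")
  }
  if (any(boxes$w <= 0) || any(boxes$h <= 0)) {
    abort("boxes must have strictly positive width and height",
          class = "earcount_invalid_box")
  }
  if ("conf" %in% names(boxes) &&
      (any(boxes$conf < 0) || any(boxes$conf > 1))) {
    abort("box confidence must lie in [0, 1]", class = "earcount_invalid_box")
  }
  invisible(boxes)
}

# fast tibble-of-boxes constructor for hot paths; inputs already validated
new_boxes <- function(cx, cy, w, h, conf = NULL) {
  cols <- list(cx = cx, cy = cy, w = w, h = h)
  if (!is.null(conf)) cols$conf <- conf
  tibble::new_tibble(cols, nrow = length(cx))
}

#' Convert between centre form and corner form
#'
#' Corner form is `(x1, y1, x2, y2)` = top-left and bottom-right corners, the
#' convention of MOT-style files (which store `x1, y1, w, h`).
#'
#' @param boxes Data frame with `cx`, `cy`, `w`, `h` (for `box_corners()`) or
#'   `x1`, `y1`, `x2`, `y2` (for `corners_to_center()`).
#' @return A tibble in the other representation, extra columns carried along.
#' @export
box_corners <- function(boxes) {
  validate_boxes(boxes)
  dplyr::mutate(tibble::as_tibble(boxes),
                x1 = .data$cx - .data$w / 2, y1 = .data$cy - .data$h / 2,
                x2 = .data$cx + .data$w / 2, y2 = .data$cy + .data$h / 2)
}

#' @rdname box_corners
#' @export
corners_to_center <- function(boxes) {
  boxes <- tibble::as_tibble(boxes)
  out <- dplyr::mutate(boxes,
                       cx = (.data$x1 + .data$x2) / 2,
                       cy = (.data$y1 + .data$y2) / 2,
                       w = .data$x2 - .data$x1,
                       h = .data$y2 - .data$y1)
  validate_boxes(out)
  dplyr::select(out, -dplyr::any_of(c("x1", "y1", "x2", "y2")))
}

#' Intersection over union of box pairs
#'
#' `box_iou()` is vectorised elementwise over two equal-length (or length-1
#' recycled) sets of boxes; `iou_matrix()` returns the full pairwise matrix
#' used for track-to-detection matching. Disjoint boxes score 0; identical
#' boxes score 1; the measure is symmetric.
#'
#' @param a,b Data frames of boxes.
#' @return `box_iou()`: a numeric vector in \[0, 1\]. `iou_matrix()`: a
#'   `nrow(a)` by `nrow(b)` matrix.
#' @examples
#' box_iou(bbox(1, 1, 2, 2), bbox(2, 1, 2, 2)) # 1/3
#' @export
box_iou <- function(a, b) {
  validate_boxes(a); validate_boxes(b)
  n <- max(nrow(a), nrow(b))
  if (nrow(a) == 1L && n > 1L) a <- a[rep(1L, n), ]
  if (nrow(b) == 1L && n > 1L) b <- b[rep(1L, n), ]
  if (nrow(a) != nrow(b)) abort("box sets must have equal length or length 1")
  ix <- pmax(0, pmin(a$cx + a$w / 2, b$cx + b$w / 2) -
                pmax(a$cx - a$w / 2, b$cx - b$w / 2))
  iy <- pmax(0, pmin(a$cy + a$h / 2, b$cy + b$h / 2) -
                pmax(a$cy - a$h / 2, b$cy - b$h / 2))
  inter <- ix * iy
  inter / (a$w * a$h + b$w * b$h - inter)
}

#' @rdname box_iou
#' @export
iou_matrix <- function(a, b) {
  validate_boxes(a); validate_boxes(b)
  na <- nrow(a); nb <- nrow(b)
  if (na == 0L || nb == 0L) return(matrix(numeric(0), nrow = na, ncol = nb))
  ax1 <- a$cx - a$w / 2; ax2 <- a$cx + a$w / 2
  ay1 <- a$cy - a$h / 2; ay2 <- a$cy + a$h / 2
  bx1 <- b$cx - b$w / 2; bx2 <- b$cx + b$w / 2
  by1 <- b$cy - b$h / 2; by2 <- b$cy + b$h / 2
  ix <- pmax(0, outer(ax2, bx2, pmin) - outer(ax1, bx1, pmax))
  iy <- pmax(0, outer(ay2, by2, pmin) - outer(ay1, by1, pmax))
  inter <- ix * iy
  inter / (outer(a$w * a$h, b$w * b$h, `+`) - inter)
}
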