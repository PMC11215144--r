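#' Read and write MOT-dialect detection/track CSV
#'
#' The on-disk dialect is the MOT-challenge one: headerless CSV rows
#' `frame, id, x, y, w, h, conf` with `x, y` the box top-left corner and
#' `id = -1` for raw (untracked) detections. A leading comment line starting
#' with `#` is tolerated on read. Internally boxes are centre-form, so the
#' corner/centre conversion happens here and only here.
#'
#' @param path File path.
#' @return `read_detections()`: a tibble `frame`, `id`, `cx`, `cy`, `w`,
#'   `h`, `conf` sorted by frame. An empty file yields a 0-row tibble.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' write_detections(tibble::tibble(frame = 1, cx = 5, cy = 5, w = 4, h = 4,
#'                                 conf = 1), f)
#' read_detections(f)
#' @export
read_detections <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || all(grepl("^\\s*(#|$)", lines))) {
    return(tibble::tibble(frame = integer(), id = numeric(), cx = numeric(),
                          cy = numeric(), w = numeric(), h = numeric(),
                          conf = numeric()))
  }
  raw <- readr::read_csv(path,
                         col_names = c("frame", "id", "x", "y", "w", "h", "conf"),
                         col_types = "innnnnn", comment = "#",
                         progress = FALSE)
  if (nrow(raw) == 0) {
    return(tibble::tibble(frame = integer(), id = numeric(), cx = numeric(),
                          cy = numeric(), w = numeric(), h = numeric(),
                          conf = numeric()))
  }
  bad <- which(!is.finite(raw$x) | !is.finite(raw$y) |
               !is.finite(raw$w) | !is.finite(raw$h) | is.na(raw$frame))
  if (length(bad)) {
    abort(sprintf("malformed detection row at line %d of %s", bad[1], path),
          class = "earcount_parse_error")
  }
  if (any(raw$w <= 0 | raw$h <= 0)) {
    bad <- which(raw$w <= 0 | raw$h <= 0)[1]
    abort(sprintf("non-positive box size at line %d of %s", bad, path),
          class = "earcount_invalid_box")
  }
  if (any(raw$frame < 1)) abort("frame indices must be >= 1")
  raw |>
    dplyr::transmute(frame = .data$frame, id = .data$id,
                     cx = .data$x + .data$w / 2, cy = .data$y + .data$h / 2,
                     w = .data$w, h = .data$h,
                     conf = dplyr::coalesce(.data$conf, 1)) |>
    dplyr::arrange(.data$frame)
}

#' @rdname read_detections
#' @param detections Tibble with `frame`, `cx`, `cy`, `w`, `h` and
#'   optionally `id`, `conf`.
#' @export
write_detections <- function(detections, path) {
  detections <- tibble::as_tibble(detections)
  if (nrow(detections) > 0) validate_boxes(detections)
  out <- tibble::tibble(
    frame = detections$frame,
    id = if ("id" %in% names(detections)) detections$id else -1,
    x = detections$cx - detections$w / 2,
    y = detections$cy - detections$h / 2,
    w = detections$w, h = detections$h,
    conf = if ("conf" %in% names(detections)) detections$conf else 1)
  readr::write_csv(out, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read LabelMe rectangle annotations
#'
#' Parses a LabelMe JSON file and returns its rectangle shapes as
#' centre-form boxes. Non-rectangle shapes (polygons, points, ...) are
#' skipped with a warning; a file without the `shapes` field is a schema
#' error.
#'
#' @param path LabelMe JSON file.
#' @return A box tibble with a `label` column.
#' @export
read_labelme <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  doc <- jsonlite::read_json(path)
  if (is.null(doc$shapes)) {
    abort(paste0("not a LabelMe file (no 'shapes' field): ", path),
          class = "earcount_schema_error")
  }
  shapes <- doc$shapes
  types <- vapply(shapes, function(s) s$shape_type %||% "", character(1))
  skipped <- sum(types != "rectangle")
  if (skipped > 0) {
    warn(sprintf("skipping %d non-rectangle shape(s) in %s", skipped, path))
  }
  rects <- shapes[types == "rectangle"]
  if (!length(rects)) {
    return(dplyr::mutate(empty_detections(), label = character()))
  }
  purrr::map_dfr(rects, function(s) {
    pts <- s$points
    if (length(pts) < 2) {
      abort("rectangle shape with fewer than 2 points",
            class = "earcount_schema_error")
    }
    xs <- vapply(pts, function(p) as.numeric(p[[1]]), numeric(1))
    ys <- vapply(pts, function(p) as.numeric(p[[2]]), numeric(1))
    tibble::tibble(cx = (min(xs) + max(xs)) / 2, cy = (min(ys) + max(ys)) / 2,
                   w = max(xs) - min(xs), h = max(ys) - min(ys),
                   conf = 1, label = s$label %||% "object")
  })
}

#' @rdname read_labelme
#' @param boxes Box tibble (optionally with `label`).
#' @param image_size `(width, height)` recorded in the file.
#' @export
write_labelme <- function(boxes, path, image_size = c(0, 0)) {
  validate_boxes(boxes)
  shapes <- purrr::pmap(boxes, function(cx, cy, w, h, ...) {
    dots <- list(...)
    list(label = dots$label %||% "object",
         shape_type = "rectangle",
         points = list(list(cx - w / 2, cy - h / 2),
                       list(cx + w / 2, cy + h / 2)))
  })
  jsonlite::write_json(
    list(shapes = shapes, imageWidth = image_size[1],
         imageHeight = image_size[2]),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a counter/simulator configuration file
#'
#' YAML with optional top-level blocks `scene`, `counter` and `kalman`, whose
#' entries override the corresponding constructor defaults. `overrides` (for
#' example from CLI flags) win over the file.
#'
#' @param path YAML file, or `NULL` for all defaults.
#' @param overrides Named list of `scene`/`counter`/`kalman` override lists.
#' @return List with elements `scene` ([scene_config()]), `counter`
#'   ([counter_config()]) and `kalman` ([kf_model()]).
#' @export
read_config <- function(path = NULL, overrides = list()) {
  raw <- if (!is.null(path)) {
    if (!file.exists(path)) abort(paste0("no such file: ", path))
    yaml::read_yaml(path) %||% list()
  } else list()
  merged <- modifyList(raw, overrides)
  pick <- function(block, fn) {
    args <- merged[[block]] %||% list()
    do.call(fn, args)
  }
  list(scene = pick("scene", scene_config),
       counter = pick("counter", counter_config),
       kalman = pick("kalman", kf_model))
}

#' Serialize a count result to JSON
#'
#' @param result An `ear_count` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_count_result <- function(result, path) {
  jsonlite::write_json(
    list(total = result$total,
         counted_ids = as.integer(result$counted_ids),
         per_frame = result$per_frame,
         tracks = result$tracks),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
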