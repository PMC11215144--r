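#' Configuration for the baseline-crossing counter
#'
#' The counter registers each tracked object exactly once, at the moment its
#' estimated centre passes a fixed horizontal baseline near the bottom of the
#' frame. Counting at a line (rather than on first detection) avoids both
#' double counts and counts of partially visible objects entering at the
#' frame edge, where detection boxes are unstable.
#'
#' @param iou_gate Matching gate: a predicted box and a detection are the
#'   same object only if their similarity strictly exceeds this. Default 0.7.
#' @param frame_size Frame `(width, height)` in pixels.
#' @param baseline_y Baseline height in pixels; default 90% of frame height.
#' @param crossing_direction `"downward"` (default: objects drift down the
#'   frame as the camera sweeps forward), `"upward"`, or `"either"`.
#' @param max_age Frames a track may remain unmatched (coasting on its
#'   prediction) before deletion. Default 3. With per-frame miss rate `m`,
#'   deleting after a single miss loses a fraction of about `m^2/(1-m)^2` of
#'   baseline crossings to track deaths spanning the line (18% at `m = 0.3`);
#'   tolerating three misses reduces that to about `m^4/(1-m)^2`.
#' @param min_hits Matches required before a track may be counted. Default 1.
#' @param method,gate_mode,nwd_C,nwd_use_sqrt Matching options passed to
#'   [match_tracks()].
#' @return A list of class `counter_config`.
#' @export
counter_config <- function(iou_gate = 0.7, frame_size = c(1280, 720),
                           baseline_y = NULL,
                           crossing_direction = c("downward", "upward", "either"),
                           max_age = 3, min_hits = 1,
                           method = "iou", gate_mode = "post",
                           nwd_C = 12.8, nwd_use_sqrt = TRUE) {
  crossing_direction <- match.arg(crossing_direction)
  baseline_y <- baseline_y %||% (0.9 * frame_size[2])
  if (baseline_y < 0 || baseline_y > frame_size[2]) {
    abort("baseline_y must lie within the frame height")
  }
  if (max_age < 1) abort("max_age must be >= 1")
  structure(list(iou_gate = iou_gate, frame_size = frame_size,
                 baseline_y = baseline_y,
                 crossing_direction = crossing_direction,
                 max_age = max_age, min_hits = min_hits,
                 method = method, gate_mode = gate_mode,
                 nwd_C = nwd_C, nwd_use_sqrt = nwd_use_sqrt),
            class = "counter_config")
}

#' Create a fresh counter state
#'
#' The opaque state threaded through [step_tracks()]; [count_ears()] creates
#' one internally. Use this directly when feeding frames incrementally (for
#' example from a live detector).
#'
#' @param cfg A [counter_config()].
#' @param model A [kf_model()]; defaults to the standard constant-velocity
#'   model.
#' @return A counter state (opaque list) at frame 0 with no tracks.
#' @export
new_counter_state <- function(cfg, model = kf_model()) {
  list(tracks = list(), next_id = 1L, counted_ids = integer(),
       frame = 0L, cfg = cfg, model = model)
}

crossed_baseline <- function(prev_y, cur_y, baseline, direction) {
  switch(direction,
         downward = prev_y <= baseline && cur_y > baseline,
         upward   = prev_y >= baseline && cur_y < baseline,
         either   = (prev_y <= baseline && cur_y > baseline) ||
                    (prev_y >= baseline && cur_y < baseline))
}

#' Advance the counter by one frame
#'
#' One cycle of detect-match-count-update: every live track is advanced by
#' [kf_predict()]; predictions are matched one-to-one to the frame's
#' detections ([match_tracks()]); matched tracks are measurement-updated and,
#' if their estimated centre crossed the baseline since their last recorded
#' estimate, counted (once per track); unmatched detections spawn new tracks
#' with fresh sequential ids; tracks unmatched for more than `max_age` frames
#' are deleted. On the first frame there are no predictions, so every
#' detection starts a track.
#'
#' @param state Counter state from [new_counter_state()] or a previous
#'   `step_tracks()` call (opaque list).
#' @param detections Data frame of this frame's detected boxes (possibly
#'   0-row).
#' @param frame Frame index; must exceed the state's current frame.
#' @param validate Validate `detections` (default). [count_ears()] validates
#'   the whole table once and passes `FALSE`.
#' @return The updated state; `state$new_counts` holds the ids counted at
#'   this frame.
#' @export
step_tracks <- function(state, detections, frame, validate = TRUE) {
  cfg <- state$cfg; model <- state$model
  if (frame <= state$frame) {
    abort(sprintf("frame index regression: %d after %d", frame, state$frame),
          class = "earcount_order_error")
  }
  if (is.null(detections)) detections <- empty_detections()
  if (validate && nrow(detections) > 0) validate_boxes(detections)

  tracks <- state$tracks
  n <- length(tracks)
  # predict
  for (k in seq_len(n)) tracks[[k]]$state <- kf_predict(tracks[[k]]$state, model)
  # predicted boxes; states with non-positive size are invalid for matching
  valid <- logical(n)
  if (n > 0) {
    xs <- vapply(tracks, function(tr) tr$state$x[1:4], numeric(4))
    valid <- xs[3, ] > 0 & xs[4, ] > 0
  }
  vidx <- which(valid)
  pred <- if (length(vidx)) {
    new_boxes(cx = xs[1, vidx], cy = xs[2, vidx],
              w = xs[3, vidx], h = xs[4, vidx],
              conf = rep(1, length(vidx)))
  } else empty_detections()

  m <- match_tracks(pred, detections, gate = cfg$iou_gate,
                    method = cfg$method, gate_mode = cfg$gate_mode,
                    C = cfg$nwd_C, use_sqrt = cfg$nwd_use_sqrt)

  matched_tracks <- vidx[m$matches$track]
  new_counts <- integer()
  dcx <- detections$cx; dcy <- detections$cy
  dw <- detections$w; dh <- detections$h
  if (length(matched_tracks)) {
    for (i in seq_along(matched_tracks)) {
      k <- matched_tracks[i]
      j <- m$matches$detection[i]
      tr <- tracks[[k]]
      tr$state <- kf_update_(tr$state, c(dcx[j], dcy[j], dw[j], dh[j]), model)
      tr$hits <- tr$hits + 1L
      tr$time_since_update <- 0L
      cur_y <- tr$state$x[2]
      if (!tr$counted && tr$hits >= cfg$min_hits &&
          crossed_baseline(tr$prev_cy, cur_y, cfg$baseline_y,
                           cfg$crossing_direction)) {
        tr$counted <- TRUE
        new_counts <- c(new_counts, tr$id)
      }
      tr$prev_cy <- cur_y
      tr$history[[length(tr$history) + 1L]] <-
        c(frame, tr$state$x[1:4])
      tracks[[k]] <- tr
    }
  }
  unmatched <- setdiff(seq_len(n), matched_tracks)
  for (k in unmatched) {
    tracks[[k]]$time_since_update <- tracks[[k]]$time_since_update + 1L
  }
  # delete stale tracks
  if (n > 0) {
    ages <- vapply(tracks, function(tr) tr$time_since_update, integer(1))
    dead <- which(ages > cfg$max_age)
    if (length(dead)) {
      state$dead_tracks <- c(state$dead_tracks, lapply(tracks[dead], finish_track))
      tracks[dead] <- NULL
    }
  }
  # spawn new tracks from unmatched detections
  for (j in m$unmatched_detections) {
    st <- kf_init_(c(dcx[j], dcy[j], dw[j], dh[j]), model)
    tracks[[length(tracks) + 1L]] <- list(
      id = state$next_id, state = st, hits = 1L, time_since_update = 0L,
      counted = FALSE, prev_cy = st$x[2],
      history = list(c(frame, st$x[1:4])))
    state$next_id <- state$next_id + 1L
  }

  state$tracks <- tracks
  state$counted_ids <- c(state$counted_ids, new_counts)
  state$new_counts <- new_counts
  state$frame <- frame
  state
}

finish_track <- function(tr) {
  tr$state <- NULL
  tr
}

empty_detections <- function() {
  tibble::tibble(cx = numeric(), cy = numeric(), w = numeric(),
                 h = numeric(), conf = numeric())
}

#' Count objects in a detection stream
#'
#' Folds [step_tracks()] over every frame of a detection table and returns
#' the final count with full per-frame and per-track bookkeeping. Frames with
#' no detections are still processed (tracks coast and may be deleted). The
#' result is deterministic for a fixed input and configuration.
#'
#' @param detections Data frame with columns `frame`, `cx`, `cy`, `w`, `h`
#'   and optionally `conf` (one row per detection; see [read_detections()]).
#' @param cfg A [counter_config()].
#' @param model A [kf_model()].
#' @param n_frames Number of frames to process; defaults to the largest
#'   frame index present.
#' @return An object of class `ear_count`: list with `total`, `counted_ids`,
#'   `per_frame` (tibble `frame`, `new_counts`, `cumulative`), `tracks`
#'   (one-row-per-track summary tibble), `history` (tibble of per-frame track
#'   estimates) and `config`.
#' @examples
#' dets <- tibble::tibble(frame = 1:10, cx = 50, cy = seq(600, 690, by = 10),
#'                        w = 40, h = 90, conf = 1)
#' res <- count_ears(dets, counter_config(frame_size = c(100, 720)))
#' res$total
#' @export
count_ears <- function(detections, cfg = counter_config(), model = kf_model(),
                       n_frames = NULL) {
  detections <- tibble::as_tibble(detections)
  if (!"frame" %in% names(detections)) abort("detections need a frame column")
  if (nrow(detections) > 0) {
    validate_boxes(detections)
    if (is.unsorted(detections$frame)) {
      detections <- dplyr::arrange(detections, .data$frame)
    }
  }
  n_frames <- n_frames %||% if (nrow(detections)) max(detections$frame) else 0L
  state <- new_counter_state(cfg, model)
  per_frame_new <- integer(n_frames)
  split_idx <- if (nrow(detections)) split(seq_len(nrow(detections)),
                                           detections$frame) else list()
  dcx <- detections$cx; dcy <- detections$cy
  dw <- detections$w; dh <- detections$h
  dconf <- detections$conf %||% rep(1, nrow(detections))
  for (f in seq_len(n_frames)) {
    idx <- split_idx[[as.character(f)]] %||% integer()
    det_f <- new_boxes(dcx[idx], dcy[idx], dw[idx], dh[idx], dconf[idx])
    state <- step_tracks(state, det_f, f, validate = FALSE)
    per_frame_new[f] <- length(state$new_counts)
  }
  all_tracks <- c(state$dead_tracks %||% list(),
                  lapply(state$tracks, finish_track))
  new_ear_count(state, all_tracks, per_frame_new, n_frames, cfg)
}

new_ear_count <- function(state, all_tracks, per_frame_new, n_frames, cfg) {
  if (length(all_tracks)) {
    hlen <- vapply(all_tracks, function(tr) length(tr$history), integer(1))
    hmat <- do.call(rbind, unlist(lapply(all_tracks, `[[`, "history"),
                                  recursive = FALSE))
    ids <- vapply(all_tracks, `[[`, integer(1), "id")
    history <- tibble::new_tibble(
      list(frame = as.integer(hmat[, 1]), id = rep(ids, hlen),
           cx = hmat[, 2], cy = hmat[, 3], w = hmat[, 4], h = hmat[, 5]),
      nrow = nrow(hmat))
    first_frame <- as.integer(vapply(
      all_tracks, function(tr) tr$history[[1]][1], numeric(1)))
    last_frame <- as.integer(vapply(
      all_tracks, function(tr) tr$history[[length(tr$history)]][1],
      numeric(1)))
    ord <- order(ids)
    tracks <- tibble::new_tibble(
      list(id = ids[ord], first_frame = first_frame[ord],
           last_frame = last_frame[ord],
           hits = vapply(all_tracks, `[[`, integer(1), "hits")[ord],
           counted = vapply(all_tracks, `[[`, logical(1), "counted")[ord]),
      nrow = length(ids))
  } else {
    history <- tibble::tibble(frame = integer(), id = integer(),
                              cx = numeric(), cy = numeric(),
                              w = numeric(), h = numeric())
    tracks <- tibble::tibble(id = integer(), first_frame = integer(),
                             last_frame = integer(), hits = integer(),
                             counted = logical())
  }
  structure(list(total = length(state$counted_ids),
                 counted_ids = state$counted_ids,
                 per_frame = tibble::tibble(
                   frame = seq_len(n_frames),
                   new_counts = per_frame_new,
                   cumulative = cumsum(per_frame_new)),
                 tracks = tracks, history = history, config = cfg),
            class = "ear_count")
}

#' Count objects from a frame source and a pluggable detector
#'
#' Adapter around [count_ears()] for callers that have frames (images, file
#' paths, or any per-frame payload) and a detector function rather than a
#' ready-made detection table. The detector is injected, never assumed: any
#' model that emits boxes per frame can drive the counter.
#'
#' @param frames A list or vector of per-frame payloads (may be of length 0).
#' @param detector `function(frame_payload, frame_index)` returning a data
#'   frame of boxes (`cx`, `cy`, `w`, `h`, optionally `conf`).
#' @inheritParams count_ears
#' @return An `ear_count` object, identical to running [count_ears()] on the
#'   induced detection stream.
#' @export
count_video <- function(frames, detector, cfg = counter_config(),
                        model = kf_model()) {
  if (!is.function(detector)) abort("detector must be a function")
  frames <- as.list(frames)
  parts <- vector("list", length(frames))
  for (i in seq_along(frames)) {
    det <- tryCatch(detector(frames[[i]], i), error = function(e) {
      abort(sprintf("detector failed at frame %d: %s", i, conditionMessage(e)))
    })
    det <- tibble::as_tibble(det)
    if (nrow(det) > 0) {
      det$frame <- i
      parts[[i]] <- det
    }
  }
  stream <- dplyr::bind_rows(parts)
  if (nrow(stream) == 0) {
    stream <- dplyr::mutate(empty_detections(), frame = integer())
  }
  count_ears(stream, cfg = cfg, model = model, n_frames = length(frames))
}

#' @export
print.ear_count <- function(x, ...) {
  cat(sprintf("<ear_count> total = %d counted over %d frames (%d tracks)\n",
              x$total, nrow(x$per_frame), nrow(x$tracks)))
  invisible(x)
}

#' @describeIn count_ears `tidy()` returns the per-track summary tibble.
#' @param x An `ear_count` object.
#' @param ... Unused.
#' @method tidy ear_count
#' @export
tidy.ear_count <- function(x, ...) x$tracks

#' @describeIn count_ears `glance()` returns a one-row tibble with `total`,
#'   `n_frames`, `n_tracks` and mean track length.
#' @method glance ear_count
#' @export
glance.ear_count <- function(x, ...) {
  tibble::tibble(total = x$total, n_frames = nrow(x$per_frame),
                 n_tracks = nrow(x$tracks),
                 mean_track_hits = if (nrow(x$tracks)) mean(x$tracks$hits) else NA_real_)
}

#' @describeIn count_ears `autoplot()` draws the cumulative count curve.
#' @param object An `ear_count` object.
#' @method autoplot ear_count
#' @export
autoplot.ear_count <- function(object, ...) {
  ggplot2::ggplot(object$per_frame,
                  ggplot2::aes(x = .data$frame, y = .data$cumulative)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "frame", y = "cumulative count",
                  title = sprintf("Baseline-crossing count (total = %d)",
                                  object$total)) +
    ggplot2::theme_minimal()
}
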