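#' Configuration for the synthetic UAV sweep
#'
#' The simulator emulates a nadir camera window sweeping a planar field strip
#' at constant velocity: objects (wheat ears) are static points with fixed
#' pixel-sized boxes scattered over the strip; each frame the window advances
#' `sweep_speed` pixels, so objects enter at the top edge and drift down the
#' frame until they exit at the bottom. Optional sinusoidal sway displaces
#' each object's centre with a per-object phase, mimicking wind.
#'
#' Defaults reflect a 0.5 m/s sweep filmed at 30 FPS with native object sizes
#' of 30-60 x 80-100 px on a 3840x2160 sensor: the simulated frame is a
#' 1280x720 crop (1/9 of the sensor area), the object count is drawn
#' uniformly from \[33, 78\] (300-700 per full video, scaled by frame area),
#' and the sweep advances 5 px/frame (0.5/30 m per frame at a nominal
#' 300 px/m). The noise channel defaults to off (perfect detector);
#' `detect_prob`, `jitter_sigma` and `false_pos_rate` switch on detector
#' imperfection.
#'
#' @param n_objects Number of objects; `NULL` (default) draws uniformly from
#'   `n_objects_range`.
#' @param n_objects_range Integer range for the default draw.
#' @param frame_size Frame `(width, height)`, pixels.
#' @param sweep_speed Camera advance per frame, pixels.
#' @param n_frames Number of frames in the sweep.
#' @param object_w_range,object_h_range Object box size ranges, pixels.
#' @param detect_prob Per-box detection probability.
#' @param jitter_sigma Detection noise, pixels: sd of the Gaussian centre
#'   jitter, also applied to sizes at the same pixel magnitude (via the log
#'   scale).
#' @param false_pos_rate Expected false positives per frame (Poisson).
#' @param partial_miss_boost Multiplier on the miss rate `1 - detect_prob`
#'   for boxes clipped at a frame edge, whose shapes a real detector sees
#'   only partially; with a perfect detector (`detect_prob = 1`) partial
#'   boxes are still always detected.
#' @param sway_amp,sway_period Sinusoidal sway amplitude (pixels) and period
#'   (frames); amplitude 0 disables sway.
#' @param seed Integer seed; all simulator randomness derives from it, with
#'   independent sub-streams per noise source so that toggling one source
#'   does not shift the others.
#' @return A list of class `scene_config`.
#' @export
scene_config <- function(n_objects = NULL, n_objects_range = c(33L, 78L),
                         frame_size = c(1280, 720), sweep_speed = 5,
                         n_frames = 240,
                         object_w_range = c(30, 60),
                         object_h_range = c(80, 100),
                         detect_prob = 1, jitter_sigma = 0,
                         false_pos_rate = 0, partial_miss_boost = 2,
                         sway_amp = 0, sway_period = 60, seed = 1L) {
  stopifnot(detect_prob >= 0, detect_prob <= 1, sweep_speed >= 0,
            all(object_w_range > 0), all(object_h_range > 0),
            n_frames >= 1, false_pos_rate >= 0)
  structure(list(n_objects = n_objects, n_objects_range = n_objects_range,
                 frame_size = frame_size, sweep_speed = sweep_speed,
                 n_frames = as.integer(n_frames),
                 object_w_range = object_w_range,
                 object_h_range = object_h_range,
                 detect_prob = detect_prob, jitter_sigma = jitter_sigma,
                 false_pos_rate = false_pos_rate,
                 partial_miss_boost = partial_miss_boost,
                 sway_amp = sway_amp, sway_period = sway_period,
                 seed = as.integer(seed)),
            class = "scene_config")
}

# independent deterministic sub-streams from one scene seed
derive_seed <- function(seed, tag) {
  offset <- match(tag, c("placement", "dropout", "jitter", "falsepos", "conf"))
  as.integer((as.numeric(seed) * 7919 + offset * 104729) %% 2147483629)
}

#' Generate a ground-truthed synthetic sweep scene
#'
#' Places objects uniformly over the swept world strip, rolls the camera
#' window over them, and records every frame's true (edge-clipped) boxes
#' together with the number of objects whose centre trajectory crosses the
#' counting baseline during the sweep — the quantity a perfect counter must
#' recover. Deterministic given the config seed.
#'
#' @param cfg A [scene_config()].
#' @param baseline_y Baseline used for the true crossing count; default 90%
#'   of frame height (matching [counter_config()]).
#' @return Object of class `wheat_scene`: `objects` (registry tibble `id`,
#'   `x`, `y` world coordinates, `w`, `h`, `phase`), `frames` (tibble
#'   `frame`, `id`, `cx`, `cy`, `w`, `h`, `partial` of per-frame true boxes),
#'   `expected_count`, and the resolved `config`.
#' @examples
#' sc <- simulate_scene(scene_config(n_objects = 40, seed = 7))
#' sc$expected_count
#' @export
simulate_scene <- function(cfg = scene_config(), baseline_y = NULL) {
  fw <- cfg$frame_size[1]; fh <- cfg$frame_size[2]
  baseline_y <- baseline_y %||% (0.9 * fh)
  strip_h <- (cfg$n_frames - 1) * cfg$sweep_speed + fh
  objects <- withr::with_seed(derive_seed(cfg$seed, "placement"), {
    n <- cfg$n_objects %||%
      sample(seq(cfg$n_objects_range[1], cfg$n_objects_range[2]), 1L)
    tibble::tibble(
      id = seq_len(n),
      x = runif(n, 0, fw),
      y = runif(n, 0, strip_h),
      w = runif(n, cfg$object_w_range[1], cfg$object_w_range[2]),
      h = runif(n, cfg$object_h_range[1], cfg$object_h_range[2]),
      phase = runif(n, 0, 2 * pi))
  })

  grid <- tidyr::expand_grid(frame = seq_len(cfg$n_frames),
                             id = objects$id)
  grid <- dplyr::left_join(grid, objects, by = "id")
  # camera starts at the far end of the strip and backs toward y = 0, so in
  # image coordinates objects enter at the top edge and drift downward
  grid <- dplyr::mutate(grid,
    cam_top = (cfg$n_frames - .data$frame) * cfg$sweep_speed,
    cy = .data$y - .data$cam_top +
      cfg$sway_amp * sin(2 * pi * .data$frame / cfg$sway_period + .data$phase),
    cx = .data$x)

  # true crossing count: centre passes the baseline between two frames
  crossings <- grid |>
    dplyr::arrange(.data$id, .data$frame) |>
    dplyr::group_by(.data$id) |>
    dplyr::summarise(crossed = any(head(.data$cy, -1) <= baseline_y &
                                   utils::tail(.data$cy, -1) > baseline_y),
                     .groups = "drop")
  expected_count <- sum(crossings$crossed)

  frames <- grid |>
    dplyr::mutate(x1 = pmax(.data$cx - .data$w / 2, 0),
                  x2 = pmin(.data$cx + .data$w / 2, fw),
                  y1 = pmax(.data$cy - .data$h / 2, 0),
                  y2 = pmin(.data$cy + .data$h / 2, fh)) |>
    dplyr::filter(.data$x2 > .data$x1, .data$y2 > .data$y1) |>
    dplyr::mutate(partial = .data$x2 - .data$x1 < .data$w - 1e-9 |
                            .data$y2 - .data$y1 < .data$h - 1e-9,
                  cx = (.data$x1 + .data$x2) / 2,
                  cy = (.data$y1 + .data$y2) / 2,
                  w = .data$x2 - .data$x1,
                  h = .data$y2 - .data$y1) |>
    dplyr::select("frame", "id", "cx", "cy", "w", "h", "partial") |>
    dplyr::arrange(.data$frame, .data$id)

  cfg$n_objects <- nrow(objects)
  structure(list(objects = objects, frames = frames,
                 expected_count = expected_count,
                 baseline_y = baseline_y, config = cfg),
            class = "wheat_scene")
}

#' Corrupt ground-truth boxes into noisy detections
#'
#' Applies a detector-imperfection channel to a scene's true boxes: each box
#' survives with probability `detect_prob` (edge-clipped boxes miss
#' `partial_miss_boost` times as often), surviving boxes receive
#' Gaussian jitter on centre and log-size, and `Poisson(false_pos_rate)`
#' spurious boxes of plausible size are added per frame. With the noise
#' switched off the output equals the truth exactly. Each noise source draws
#' from its own seed stream derived from `seed`, so enabling one source
#' leaves the realisations of the others unchanged.
#'
#' @param scene A [simulate_scene()] result.
#' @param detect_prob,jitter_sigma,false_pos_rate Override the scene
#'   config's values.
#' @param seed Override the scene config's seed.
#' @return A detection tibble (`frame`, `cx`, `cy`, `w`, `h`, `conf`) ready
#'   for [count_ears()].
#' @export
corrupt_detections <- function(scene, detect_prob = NULL, jitter_sigma = NULL,
                               false_pos_rate = NULL, seed = NULL) {
  cfg <- scene$config
  detect_prob <- detect_prob %||% cfg$detect_prob
  jitter_sigma <- jitter_sigma %||% cfg$jitter_sigma
  false_pos_rate <- false_pos_rate %||% cfg$false_pos_rate
  seed <- seed %||% cfg$seed
  gt <- scene$frames
  ng <- nrow(gt)

  keep <- withr::with_seed(derive_seed(seed, "dropout"), {
    p <- ifelse(gt$partial,
                pmax(0, 1 - (1 - detect_prob) * cfg$partial_miss_boost),
                detect_prob)
    runif(ng) < p
  })
  jit <- withr::with_seed(derive_seed(seed, "jitter"), {
    tibble::tibble(dx = rnorm(ng), dy = rnorm(ng),
                   dw = rnorm(ng), dh = rnorm(ng))
  })
  conf <- withr::with_seed(derive_seed(seed, "conf"), runif(ng, 0.5, 1))

  dets <- gt[keep, c("frame", "cx", "cy", "w", "h")]
  if (jitter_sigma > 0 && nrow(dets) > 0) {
    j <- jit[keep, ]
    dets$cx <- dets$cx + jitter_sigma * j$dx
    dets$cy <- dets$cy + jitter_sigma * j$dy
    # log-size noise scaled so 1 sd of size change is ~jitter_sigma pixels;
    # the log-sd is capped at jitter_sigma (denominator floored at 1 px) so
    # slivers clipped at a frame edge cannot blow up to infinite size
    dets$w <- dets$w * exp(jitter_sigma / pmax(dets$w, 1) * j$dw)
    dets$h <- dets$h * exp(jitter_sigma / pmax(dets$h, 1) * j$dh)
  }
  dets$conf <- conf[keep]

  if (false_pos_rate > 0) {
    fp <- withr::with_seed(derive_seed(seed, "falsepos"), {
      n_fp <- rpois(cfg$n_frames, false_pos_rate)
      total <- sum(n_fp)
      tibble::tibble(
        frame = rep(seq_len(cfg$n_frames), n_fp),
        cx = runif(total, 0, cfg$frame_size[1]),
        cy = runif(total, 0, cfg$frame_size[2]),
        w = runif(total, cfg$object_w_range[1], cfg$object_w_range[2]),
        h = runif(total, cfg$object_h_range[1], cfg$object_h_range[2]),
        conf = runif(total, 0.5, 0.9))
    })
    dets <- dplyr::bind_rows(dets, fp)
  }
  dets |>
    dplyr::arrange(.data$frame) |>
    tibble::as_tibble()
}

#' @export
print.wheat_scene <- function(x, ...) {
  cat(sprintf(
    "<wheat_scene> %d objects, %d frames (%g x %g px), expected count %d\n",
    nrow(x$objects), x$config$n_frames, x$config$frame_size[1],
    x$config$frame_size[2], x$expected_count))
  invisible(x)
}

#' @describeIn simulate_scene `tidy()` returns the per-frame true boxes.
#' @param x A `wheat_scene` object.
#' @param ... Unused.
#' @method tidy wheat_scene
#' @export
tidy.wheat_scene <- function(x, ...) x$frames

#' @describeIn simulate_scene `glance()` returns a one-row scene summary.
#' @method glance wheat_scene
#' @export
glance.wheat_scene <- function(x, ...) {
  tibble::tibble(n_objects = nrow(x$objects),
                 n_frames = x$config$n_frames,
                 expected_count = x$expected_count,
                 mean_visible = nrow(x$frames) / x$config$n_frames)
}

#' @describeIn simulate_scene `autoplot()` shows object trajectories in
#'   image coordinates with the counting baseline.
#' @param object A `wheat_scene` object.
#' @method autoplot wheat_scene
#' @export
autoplot.wheat_scene <- function(object, ...) {
  ggplot2::ggplot(object$frames,
                  ggplot2::aes(x = .data$cx, y = .data$cy,
                               group = .data$id)) +
    ggplot2::geom_path(alpha = 0.4) +
    ggplot2::geom_hline(yintercept = object$baseline_y, colour = "red") +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "x (px)", y = "y (px)",
                  title = "Object trajectories under the camera sweep") +
    ggplot2::theme_minimal()
}
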