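test_that("counter_config validates its invariants", {
  cfg <- counter_config()
  expect_equal(cfg$baseline_y, 0.9 * 720)
  expect_equal(cfg$iou_gate, 0.7)
  expect_error(counter_config(baseline_y = 1000), "frame height")
  expect_error(counter_config(max_age = 0), "max_age")
})

test_that("first frame spawns tracks with sequential ids, none counted", {
  cfg <- test_counter_cfg()
  state <- earcount:::new_counter_state(cfg, kf_model())
  dets <- bbox(cx = c(20, 60, 100), cy = 50, w = 20, h = 40)
  state <- step_tracks(state, dets, 1L)
  expect_equal(vapply(state$tracks, `[[`, integer(1), "id"), 1:3)
  expect_equal(state$counted_ids, integer())
  expect_error(step_tracks(state, dets, 1L), class = "earcount_order_error")
})

test_that("a matched track straddling the baseline is counted", {
  cfg <- test_counter_cfg()  # baseline at 180
  dets <- tibble::tibble(frame = 1:2, cx = 100, cy = c(178, 182),
                         w = 40, h = 80, conf = 1)
  res <- count_ears(dets, cfg)
  expect_equal(res$total, 1L)
  expect_equal(res$counted_ids, 1L)
})

test_that("an object is counted exactly once while hovering near the line", {
  cfg <- test_counter_cfg()
  stream <- line_stream(cy0 = 160, v = 4, n = 12)  # crosses 180 mid-stream
  res <- count_ears(stream, cfg)
  expect_equal(res$total, 1L)
  expect_equal(sum(res$per_frame$new_counts), 1L)
  expect_equal(nrow(res$tracks), 1L)
})

test_that("cumulative counts are non-decreasing and total equals id count", {
  cfg <- test_counter_cfg()
  withr::with_seed(41, {
    streams <- lapply(1:5, function(k) {
      n_obj <- sample(2:6, 1)
      purrr::map_dfr(seq_len(n_obj), function(i) {
        line_stream(cy0 = runif(1, 100, 170), v = runif(1, 2, 6),
                    n = 25, cx = 30 * i)
      })
    })
  })
  for (s in streams) {
    res <- count_ears(dplyr::arrange(s, frame), cfg)
    expect_true(all(diff(res$per_frame$cumulative) >= 0))
    expect_equal(res$total, length(res$counted_ids))
    expect_equal(anyDuplicated(res$counted_ids), 0L)
  }
})

test_that("objects that never reach the baseline are never counted", {
  cfg <- test_counter_cfg()
  stream <- line_stream(cy0 = 20, v = 4, n = 20)  # ends at 96 < 180
  res <- count_ears(stream, cfg)
  expect_equal(res$total, 0L)
  expect_equal(nrow(res$tracks), 1L)
})

test_that("a track coasts max_age frames and is then deleted, never counted", {
  cfg <- test_counter_cfg(max_age = 1)
  state <- earcount:::new_counter_state(cfg, kf_model())
  state <- step_tracks(state, bbox(100, 170, 40, 80), 1L)
  state <- step_tracks(state, NULL, 2L)  # one miss: still alive, coasting
  expect_equal(length(state$tracks), 1L)
  expect_equal(state$tracks[[1]]$time_since_update, 1L)
  state <- step_tracks(state, NULL, 3L)  # second miss: deleted
  expect_equal(length(state$tracks), 0L)
  expect_equal(state$counted_ids, integer())
  expect_equal(length(state$dead_tracks), 1L)
})

test_that("crossing during a coast gap still counts on the next match", {
  cfg <- test_counter_cfg(max_age = 3)
  dets <- tibble::tibble(frame = c(1L, 4L), cx = 100, cy = c(176, 188),
                         w = 40, h = 80, conf = 1)
  res <- count_ears(dets, cfg, n_frames = 4)
  expect_equal(res$total, 1L)
})

test_that("pure coasting across the line does not count", {
  cfg <- test_counter_cfg(max_age = 10)
  # seen twice above the line with downward velocity, then never again:
  # the prediction coasts across the baseline but no match confirms it
  dets <- tibble::tibble(frame = 1:2, cx = 100, cy = c(168, 176),
                         w = 40, h = 80, conf = 1)
  res <- count_ears(dets, cfg, n_frames = 12)
  expect_equal(res$total, 0L)
})

test_that("deleted ids are never reused", {
  cfg <- test_counter_cfg(max_age = 1)
  dets <- dplyr::bind_rows(
    tibble::tibble(frame = 1L, cx = 100, cy = 50, w = 40, h = 80, conf = 1),
    tibble::tibble(frame = 5L, cx = 100, cy = 50, w = 40, h = 80, conf = 1))
  res <- count_ears(dets, cfg, n_frames = 5)
  expect_equal(sort(res$tracks$id), c(1L, 2L))
})

test_that("count_ears is deterministic and the empty stream counts zero", {
  cfg <- test_counter_cfg()
  empty <- tibble::tibble(frame = integer(), cx = numeric(), cy = numeric(),
                          w = numeric(), h = numeric(), conf = numeric())
  expect_equal(count_ears(empty, cfg)$total, 0L)
  withr::with_seed(42, {
    stream <- purrr::map_dfr(1:3, function(i) {
      s <- line_stream(cy0 = 150, v = 4, n = 15, cx = 40 * i)
      s[runif(nrow(s)) < 0.8, ]  # seeded dropout
    })
  })
  stream <- dplyr::arrange(stream, frame)
  r1 <- count_ears(stream, cfg)
  r2 <- count_ears(stream, cfg)
  expect_identical(r1$total, r2$total)
  expect_identical(r1$per_frame, r2$per_frame)
})

test_that("count_video adapter reproduces count_ears", {
  cfg <- test_counter_cfg()
  stream <- line_stream(cy0 = 150, v = 5, n = 12)
  by_frame <- split(stream[c("cx", "cy", "w", "h", "conf")], stream$frame)
  detector <- function(payload, i) payload
  res_v <- count_video(by_frame, detector, cfg)
  res_d <- count_ears(stream, cfg)
  expect_equal(res_v$total, res_d$total)
  expect_equal(res_v$per_frame, res_d$per_frame)
  expect_equal(count_video(list(), detector, cfg)$total, 0L)
  bad <- function(payload, i) if (i == 3) stop("boom") else payload
  expect_error(count_video(by_frame, bad, cfg), "frame 3")
})

test_that("ear_count methods expose tidy summaries", {
  res <- count_ears(line_stream(cy0 = 160, v = 4, n = 10), test_counter_cfg())
  expect_s3_class(tidy(res), "tbl_df")
  expect_named(glance(res), c("total", "n_frames", "n_tracks",
                              "mean_track_hits"))
  expect_s3_class(autoplot(res), "ggplot")
  expect_output(print(res), "total = 1")
})
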