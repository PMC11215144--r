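# small scenes keep the unit suite fast; acceptance runs the full sizes
small_cfg <- function(...) {
  args <- modifyList(list(n_objects = 15, frame_size = c(320, 180),
                          sweep_speed = 5, n_frames = 60),
                     list(...))
  do.call(scene_config, args)
}

test_that("scene_config validates and resolves defaults", {
  cfg <- scene_config()
  expect_equal(cfg$frame_size, c(1280, 720))
  expect_equal(cfg$sweep_speed, 5)
  expect_error(scene_config(detect_prob = 1.2), "detect_prob")
  expect_error(scene_config(object_w_range = c(-1, 5)), "object_w_range")
})

test_that("a static camera sees identical ground truth every frame", {
  cfg <- small_cfg(sweep_speed = 0, n_frames = 5, seed = 3)
  sc <- simulate_scene(cfg)
  per_frame <- split(sc$frames[c("id", "cx", "cy", "w", "h")], sc$frames$frame)
  for (f in seq_along(per_frame)) {
    expect_equal(as.data.frame(per_frame[[f]]), as.data.frame(per_frame[[1]]),
                 ignore_attr = TRUE)
  }
})

test_that("objects drift strictly downward when sway is off", {
  cfg <- small_cfg(seed = 4)
  sc <- simulate_scene(cfg)
  trajs <- split(sc$frames, sc$frames$id)
  expect_gt(length(trajs), 0)
  for (tr in trajs) {
    full <- tr[!tr$partial, ]
    if (nrow(full) > 1) expect_true(all(diff(full$cy) > 0))
  }
  # centres clipped into the frame
  expect_true(all(sc$frames$cy >= 0 & sc$frames$cy <= cfg$frame_size[2]))
})

test_that("expected_count matches an independent trajectory re-scan", {
  for (seed in c(5, 6, 7)) {
    cfg <- small_cfg(seed = seed)
    sc <- simulate_scene(cfg)
    # oracle: rebuild each object's unclipped centre trajectory from the
    # registry and count baseline crossings directly
    crossed <- vapply(seq_len(nrow(sc$objects)), function(i) {
      ob <- sc$objects[i, ]
      cy <- ob$y - (cfg$n_frames - seq_len(cfg$n_frames)) * cfg$sweep_speed
      any(cy[-length(cy)] <= sc$baseline_y & cy[-1] > sc$baseline_y)
    }, logical(1))
    expect_equal(sc$expected_count, sum(crossed))
    expect_lte(sc$expected_count, nrow(sc$objects))
  }
})

test_that("the identity channel returns the truth boxes exactly", {
  sc <- simulate_scene(small_cfg(seed = 8))
  dets <- corrupt_detections(sc, detect_prob = 1, jitter_sigma = 0,
                             false_pos_rate = 0)
  expect_equal(nrow(dets), nrow(sc$frames))
  expect_equal(dets[c("frame", "cx", "cy", "w", "h")],
               sc$frames[c("frame", "cx", "cy", "w", "h")])
})

test_that("detect_prob 0 yields no detections at all", {
  sc <- simulate_scene(small_cfg(seed = 9))
  expect_equal(nrow(corrupt_detections(sc, detect_prob = 0)), 0L)
})

test_that("kept fraction is binomially consistent with detect_prob", {
  sc <- simulate_scene(scene_config(n_objects = 60, n_frames = 200, seed = 10))
  full <- sc$frames[!sc$frames$partial, ]
  n <- nrow(full)
  expect_gt(n, 3000)
  dets <- corrupt_detections(sc, detect_prob = 0.8)
  # partial boxes drop more often; count survivors among full boxes only,
  # identified by exact coordinates (no jitter applied)
  kept <- sum(full$cy %in% dets$cy)
  p_hat <- kept / n
  se <- sqrt(0.8 * 0.2 / n)
  expect_lt(abs(p_hat - 0.8), 3 * se)
})

test_that("identical config and seed give bit-identical outputs", {
  a <- simulate_scene(small_cfg(seed = 11))
  b <- simulate_scene(small_cfg(seed = 11))
  expect_identical(a$frames, b$frames)
  expect_identical(corrupt_detections(a, detect_prob = 0.7, jitter_sigma = 2),
                   corrupt_detections(b, detect_prob = 0.7, jitter_sigma = 2))
  c <- simulate_scene(small_cfg(seed = 12))
  expect_false(identical(a$frames, c$frames))
})

test_that("noise sources draw from independent seed streams", {
  sc <- simulate_scene(small_cfg(seed = 13))
  plain <- corrupt_detections(sc, detect_prob = 0.8, jitter_sigma = 0)
  with_fp <- corrupt_detections(sc, detect_prob = 0.8, jitter_sigma = 0,
                                false_pos_rate = 2)
  # enabling false positives must not change which true boxes survive
  expect_identical(plain$cy, with_fp$cy[with_fp$cy %in% plain$cy])
  expect_gt(nrow(with_fp), nrow(plain))
})

test_that("doubling n_objects roughly doubles the expected count", {
  cfg1 <- scene_config(n_objects = 1000, n_frames = 120, seed = 14)
  cfg2 <- scene_config(n_objects = 2000, n_frames = 120, seed = 14)
  e1 <- simulate_scene(cfg1)$expected_count
  e2 <- simulate_scene(cfg2)$expected_count
  expect_gt(e1, 0)
  expect_lt(abs(e2 / e1 - 2), 0.1 * 2)
})

test_that("scene methods summarise the scene", {
  sc <- simulate_scene(small_cfg(seed = 15))
  expect_identical(tidy(sc), sc$frames)
  g <- glance(sc)
  expect_equal(g$n_objects, 15)
  expect_equal(g$expected_count, sc$expected_count)
  expect_s3_class(autoplot(sc), "ggplot")
  expect_output(print(sc), "expected count")
})
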