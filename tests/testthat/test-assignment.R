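test_that("solve_assignment handles the worked examples", {
  one <- solve_assignment(matrix(0.9, 1, 1))
  expect_equal(one$row, 1L)
  expect_equal(one$col, 1L)
  two <- solve_assignment(rbind(c(0.9, 0.1), c(0.2, 0.8)))
  expect_equal(two$col, c(1L, 2L))
  expect_equal(sum(two$score), 1.7)
  empty <- solve_assignment(matrix(numeric(0), 0, 3))
  expect_equal(nrow(empty), 0L)
  expect_error(solve_assignment(rbind(c(1, -0.1), c(0, 1))), "non-negative")
  expect_error(solve_assignment(rbind(c(1, Inf), c(0, 1))), "non-negative|finite")
})

test_that("assignment totals equal brute force on random square matrices", {
  withr::with_seed(31, {
    for (trial in 1:60) {
      n <- sample(1:6, 1)
      M <- matrix(runif(n * n), n, n)
      got <- solve_assignment(M)
      expect_equal(nrow(got), n)
      expect_equal(sum(got$score), brute_force_total(M), tolerance = 1e-12)
    }
  })
})

test_that("rectangular matrices return min(rows, cols) optimal pairs", {
  withr::with_seed(32, {
    for (trial in 1:30) {
      nr <- sample(1:5, 1); nc <- sample(1:5, 1)
      M <- matrix(runif(nr * nc), nr, nc)
      got <- solve_assignment(M)
      expect_equal(nrow(got), min(nr, nc))
      expect_equal(anyDuplicated(got$row), 0L)
      expect_equal(anyDuplicated(got$col), 0L)
      expect_equal(sum(got$score), brute_force_total(M), tolerance = 1e-12)
    }
  })
})

test_that("assignment totals agree with igraph's weighted bipartite matching", {
  withr::with_seed(33, {
    for (trial in 1:20) {
      n <- sample(2:6, 1)
      M <- matrix(runif(n * n, 0.01, 1), n, n)
      g <- igraph::graph_from_biadjacency_matrix(M, weighted = TRUE)
      ref <- igraph::max_bipartite_match(g, weights = igraph::E(g)$weight)
      expect_equal(sum(solve_assignment(M)$score), ref$matching_weight,
                   tolerance = 1e-9)
    }
  })
})

test_that("solve_assignment is deterministic", {
  withr::with_seed(34, M <- matrix(runif(25), 5, 5))
  expect_identical(solve_assignment(M), solve_assignment(M))
  tie <- matrix(1, 3, 3)
  expect_identical(solve_assignment(tie), solve_assignment(tie))
})

test_that("match_tracks gates as specified", {
  a <- bbox(10, 10, 4, 4)
  m <- match_tracks(a, a)
  expect_equal(nrow(m$matches), 1L)
  expect_equal(m$matches$score, 1)
  # disjoint: IoU 0 <= 0.7, both unmatched
  m2 <- match_tracks(a, bbox(100, 100, 4, 4))
  expect_equal(nrow(m2$matches), 0L)
  expect_equal(m2$unmatched_tracks, 1L)
  expect_equal(m2$unmatched_detections, 1L)
  # exact-gate similarity must NOT match (strict inequality)
  half <- match_tracks(bbox(0, 0, 10, 10), bbox(0, 0, 10, 10), gate = 0)
  expect_equal(nrow(half$matches), 1L)
  at_gate <- match_tracks(bbox(1, 1, 2, 2), bbox(2, 1, 2, 2), gate = 1 / 3)
  expect_equal(nrow(at_gate$matches), 0L)
  expect_error(match_tracks(a, a, gate = 1), "gate")
})

test_that("the gate dissolves exactly the sub-threshold assigned pairs", {
  # IoU matrix [[0.95, 0], [0, 0.5]]: optimal assignment takes both diagonal
  # pairs; the 0.5 pair must be dissolved, the 0.95 pair kept
  tracks <- bbox(cx = c(10, 100), cy = c(10, 100),
                 w = c(40, 40), h = c(40, 40))
  det1 <- bbox(10, 10, 40, 40)
  det1$cx <- 10 + 40 * (1 - 0.95) / (1 + 0.95)  # IoU 0.95 with track 1
  det2 <- bbox(100, 100, 40, 40)
  det2$cx <- 100 + 40 * (1 - 0.5) / (1 + 0.5)   # IoU 0.5 with track 2
  dets <- dplyr::bind_rows(det1, det2)
  iom <- iou_matrix(tracks, dets)
  expect_equal(iom[1, 1], 0.95, tolerance = 1e-9)
  expect_equal(iom[2, 2], 0.5, tolerance = 1e-9)
  expect_equal(iom[1, 2], 0)
  m <- match_tracks(tracks, dets, gate = 0.7)
  expect_equal(m$matches$track, 1L)
  expect_equal(m$matches$detection, 1L)
  expect_equal(m$unmatched_tracks, 2L)
  expect_equal(m$unmatched_detections, 2L)
})

test_that("gating never increases matches; gate 0 matches every row", {
  withr::with_seed(35, {
    tracks <- rand_boxes(6); dets <- rand_boxes(6)
  })
  loose <- match_tracks(tracks, dets, gate = 0)
  strict <- match_tracks(tracks, dets, gate = 0.7)
  expect_lte(nrow(strict$matches), nrow(loose$matches))
  # all-positive score matrix with gate 0: every row matched
  near <- dplyr::mutate(tracks, cx = cx + 0.1)
  m <- match_tracks(tracks, near, gate = 0)
  expect_equal(nrow(m$matches), 6L)
})

test_that("every index lands in exactly one result bucket", {
  withr::with_seed(36, {
    tracks <- rand_boxes(5, cx_max = 40); dets <- rand_boxes(7, cx_max = 40)
  })
  m <- match_tracks(tracks, dets, gate = 0.2)
  t_all <- sort(c(m$matches$track, m$unmatched_tracks))
  d_all <- sort(c(m$matches$detection, m$unmatched_detections))
  expect_equal(t_all, 1:5)
  expect_equal(d_all, 1:7)
  expect_true(all(m$matches$score > 0.2))
})

test_that("permuting detections permutes indices but not matched scores", {
  withr::with_seed(37, {
    tracks <- rand_boxes(5, cx_max = 30)
    dets <- dplyr::mutate(tracks, cx = cx + runif(5, -1, 1))
  })
  perm <- c(3, 1, 5, 2, 4)
  m1 <- match_tracks(tracks, dets, gate = 0.3)
  m2 <- match_tracks(tracks, dets[perm, ], gate = 0.3)
  expect_equal(sort(m1$matches$score), sort(m2$matches$score))
  expect_equal(m1$matches$track, sort(m1$matches$track))
  # the permuted detection indices point at the same boxes
  expect_equal(m1$matches$detection,
               perm[m2$matches$detection][order(m2$matches$track)])
})

test_that("pre-masking mode zeroes sub-gate scores before solving", {
  # post-gating can sacrifice a good pair to a globally optimal but gated
  # total; pre-masking cannot
  score_like <- list(t1 = bbox(0, 0, 10, 10), t2 = bbox(14, 0, 10, 10))
  tracks <- dplyr::bind_rows(score_like)
  dets <- bbox(cx = c(7, 100), cy = c(0, 100), w = c(10, 10), h = c(10, 10))
  pre <- match_tracks(tracks, dets, gate = 0.2, gate_mode = "pre")
  post <- match_tracks(tracks, dets, gate = 0.2, gate_mode = "post")
  expect_s3_class(pre, "match_result")
  expect_s3_class(post, "match_result")
  expect_true(all(pre$matches$score > 0.2))
  expect_true(all(post$matches$score > 0.2))
})
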