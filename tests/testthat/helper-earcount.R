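# Shared generators and independent oracles for the test suite. Each oracle
# recomputes a quantity by a different route than the package code so that
# agreement is evidence, not tautology.

# random valid boxes
rand_boxes <- function(n, cx_max = 100, wh_min = 0.5, wh_max = 20) {
  bbox(cx = runif(n, 0, cx_max), cy = runif(n, 0, cx_max),
       w = runif(n, wh_min, wh_max), h = runif(n, wh_min, wh_max))
}

# all permutations of 1..n (recursive, no external packages)
all_perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    rest <- seq_len(n)[-k]
    cbind(k, matrix(rest[sub], nrow(sub), n - 1L))
  }))
}

# brute-force optimal assignment total for a (possibly rectangular) score
# matrix: enumerate every injective row -> column map
brute_force_total <- function(score) {
  nr <- nrow(score); nc <- ncol(score)
  if (nr <= nc) {
    perms <- all_perms(nc)
    best <- -Inf
    for (p in seq_len(nrow(perms))) {
      cols <- perms[p, seq_len(nr)]
      best <- max(best, sum(score[cbind(seq_len(nr), cols)]))
    }
  } else {
    best <- brute_force_total(t(score))
  }
  best
}

# independent Kalman oracle: plain matrix arithmetic, no shared helpers
kf_oracle_run <- function(z_mat, model) {
  x <- c(z_mat[1, ], rep(0, 4))
  P <- model$P0
  states <- list(list(x = x, P = P))
  for (t in seq_len(nrow(z_mat))[-1]) {
    x <- as.numeric(model$F %*% x)
    P <- model$F %*% P %*% t(model$F) + model$Q
    P <- (P + t(P)) / 2
    S <- model$H %*% P %*% t(model$H) + model$R
    K <- P %*% t(model$H) %*% solve(S)
    x <- x + as.numeric(K %*% (z_mat[t, ] - as.numeric(model$H %*% x)))
    P <- (diag(8) - K %*% model$H) %*% P
    P <- (P + t(P)) / 2
    states[[t]] <- list(x = x, P = P)
  }
  states
}

# independent all-point-interpolated AP oracle: integrate max-precision-at-
# recall>=r over recall increments, with explicit loops
ap_oracle <- function(is_tp, n_truth) {
  if (!length(is_tp) || n_truth == 0) return(0)
  tp <- cumsum(is_tp)
  rec <- tp / n_truth
  prec <- tp / seq_along(is_tp)
  ap <- 0
  r_prev <- 0
  for (k in seq_along(rec)) {
    p_at <- max(prec[rec >= rec[k] - 1e-12])
    ap <- ap + (rec[k] - r_prev) * p_at
    r_prev <- rec[k]
  }
  ap
}

# index-loop space-to-depth oracle (row-offset-fastest stacking)
spd_oracle <- function(x, scale) {
  d <- dim(x)
  out <- array(NA_real_, dim = c(d[1] / scale, d[2] / scale, d[3] * scale^2))
  k <- 0L
  for (j in 0:(scale - 1)) {
    for (i in 0:(scale - 1)) {
      for (ch in seq_len(d[3])) {
        out[, , k * d[3] + ch] <-
          x[seq(i + 1, d[1], by = scale), seq(j + 1, d[2], by = scale), ch]
      }
      k <- k + 1L
    }
  }
  out
}

# a straight-down constant-velocity detection stream for one object
line_stream <- function(cy0, v, n, cx = 100, w = 40, h = 80) {
  tibble::tibble(frame = seq_len(n), cx = cx, cy = cy0 + (seq_len(n) - 1) * v,
                 w = w, h = h, conf = 1)
}

# small counter config for unit tests (200 x 200 frame, baseline at 180)
test_counter_cfg <- function(...) {
  counter_config(frame_size = c(200, 200), ...)
}
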