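#' Constant-velocity Kalman filter model over box state
#'
#' The track state is the 8-vector `(cx, cy, w, h, v_cx, v_cy, v_w, v_h)`:
#' box centre and size plus their per-frame velocities. With a time step of
#' one frame the transition matrix is `F = [[I4, I4], [0, I4]]` and the
#' observation matrix `H = [I4 | 0]` observes the box `(cx, cy, w, h)`
#' directly. `Q` and `R` are the process- and observation-noise covariances;
#' an optional control term `B u` is supported but defaults to absent, since
#' passively imaged objects have no control input.
#'
#' Defaults: `Q = diag(1e-2)` on the position/size block and `diag(1e-4)` on
#' velocities; `R = I4` (pixels squared); initial covariance `p_pos = 10` on
#' observed components and `p_vel = 1000` on the unobserved velocities, so
#' velocity estimates defer to the first few innovations.
#'
#' @param q_pos,q_vel Process-noise variances for the position/size and
#'   velocity blocks.
#' @param r Observation-noise variance (scalar or length-4), pixels squared.
#' @param p_pos,p_vel Initial state variances for the two blocks.
#' @param B Optional 8 x k control matrix.
#' @param u Optional length-k control vector (used with `B`).
#' @return An object of class `kf_model`: list with `F`, `H`, `Q`, `R`,
#'   `P0`, and optionally `B`, `u`.
#' @export
kf_model <- function(q_pos = 1e-2, q_vel = 1e-4, r = 1,
                     p_pos = 10, p_vel = 1000, B = NULL, u = NULL) {
  I4 <- diag(4)
  F_ <- rbind(cbind(I4, I4), cbind(matrix(0, 4, 4), I4))
  H <- cbind(I4, matrix(0, 4, 4))
  Q <- diag(c(rep(q_pos, 4), rep(q_vel, 4)))
  R <- if (length(r) == 1L) diag(rep(r, 4)) else diag(as.numeric(r))
  if (nrow(R) != 4L) abort("r must have length 1 or 4")
  check_psd(Q, "Q"); check_psd(R, "R")
  if (!is.null(B) && nrow(B) != 8L) abort("B must have 8 rows")
  structure(list(F = F_, H = H, Q = Q, R = R,
                 P0 = diag(c(rep(p_pos, 4), rep(p_vel, 4))),
                 B = B, u = u),
            class = "kf_model")
}

check_psd <- function(M, name) {
  if (!isTRUE(all.equal(M, t(M))) || any(eigen(M, symmetric = TRUE,
                                               only.values = TRUE)$values < -1e-10)) {
    abort(sprintf("%s must be symmetric positive semi-definite", name))
  }
}

#' Initialise, predict and update a Kalman track state
#'
#' `kf_init()` starts a state from a single measured box: the position/size
#' block is the measurement, velocities are zero, and the covariance is the
#' model's `P0` (large on velocities, which a single box cannot determine).
#' `kf_predict()` advances one frame, `x- = F x (+ B u)`,
#' `P- = F P F' + Q`; `kf_update()` folds in a measurement with gain
#' `K = P- H' (H P- H' + R)^{-1}`, `x = x- + K (z - H x-)`,
#' `P = (I - K H) P-`. `P` is re-symmetrised after each step.
#'
#' @param z A single-row data frame of one box.
#' @param model A [kf_model()].
#' @param s A `kf_state` (list with `x`, `P`).
#' @return A `kf_state`: list with state vector `x` and covariance `P`.
#' @examples
#' m <- kf_model()
#' s <- kf_init(bbox(10, 20, 30, 80), m)
#' s <- kf_update(kf_predict(s, m), bbox(12, 20, 30, 80), m)
#' @export
kf_init <- function(z, model) {
  validate_boxes(z)
  if (nrow(z) != 1L) abort("kf_init takes exactly one box")
  kf_init_(c(z$cx, z$cy, z$w, z$h), model)
}

# measurement as a bare numeric 4-vector; no validation (hot path)
kf_init_ <- function(z4, model) {
  structure(list(x = c(z4, 0, 0, 0, 0), P = model$P0), class = "kf_state")
}

#' @rdname kf_init
#' @export
kf_predict <- function(s, model) {
  x <- model$F %*% s$x
  if (!is.null(model$B)) x <- x + model$B %*% (model$u %||% rep(0, ncol(model$B)))
  P <- model$F %*% s$P %*% t(model$F) + model$Q
  structure(list(x = drop(x), P = (P + t(P)) / 2), class = "kf_state")
}

#' @rdname kf_init
#' @export
kf_update <- function(s, z, model) {
  validate_boxes(z)
  if (nrow(z) != 1L) abort("kf_update takes exactly one box")
  kf_update_(s, c(z$cx, z$cy, z$w, z$h), model)
}

# measurement as a bare numeric 4-vector; no validation (hot path)
kf_update_ <- function(s, z4, model) {
  H <- model$H
  S <- H %*% s$P %*% t(H) + model$R
  K <- tryCatch(s$P %*% t(H) %*% solve(S),
                error = function(e) abort(paste0(
                  "innovation covariance is singular: ", conditionMessage(e))))
  innov <- z4 - drop(H %*% s$x)
  x <- s$x + drop(K %*% innov)
  P <- (diag(8) - K %*% H) %*% s$P
  structure(list(x = x, P = (P + t(P)) / 2), class = "kf_state")
}

#' Extract the box described by a Kalman state
#'
#' @param s A `kf_state`.
#' @return A one-row box tibble, or `NULL` if the state's width or height is
#'   non-positive (such a state is flagged invalid for matching rather than
#'   floored).
#' @export
kf_box <- function(s) {
  if (s$x[3] <= 0 || s$x[4] <= 0) return(NULL)
  bbox(cx = s$x[1], cy = s$x[2], w = s$x[3], h = s$x[4])
}
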