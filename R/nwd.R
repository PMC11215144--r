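#' Model bounding boxes as 2-D Gaussian distributions
#'
#' A box `(cx, cy, w, h)` maps to the Gaussian with mean `(cx, cy)` and
#' diagonal covariance `diag(w^2/4, h^2/4)`, so one standard deviation spans
#' half the box along each axis. This is the representation under which tiny,
#' barely-overlapping boxes can still be compared: the Wasserstein distance
#' between two such Gaussians is finite and smooth even when IoU is exactly 0.
#'
#' @param boxes Data frame of boxes.
#' @return A tibble with columns `mu_x`, `mu_y`, `var_x` (= w^2/4) and
#'   `var_y` (= h^2/4).
#' @examples
#' box_to_gaussian(bbox(3, 4, 6, 8)) # vars 9 and 16
#' @export
box_to_gaussian <- function(boxes) {
  validate_boxes(boxes)
  tibble::tibble(mu_x = boxes$cx, mu_y = boxes$cy,
                 var_x = boxes$w^2 / 4, var_y = boxes$h^2 / 4)
}

#' @rdname box_to_gaussian
#' @param g A tibble as returned by `box_to_gaussian()`.
#' @export
gaussian_to_box <- function(g) {
  if (any(g$var_x <= 0) || any(g$var_y <= 0)) {
    abort("Gaussian covariance must have strictly positive diagonal",
          class = "earcount_invalid_box")
  }
  bbox(cx = g$mu_x, cy = g$mu_y, w = 2 * sqrt(g$var_x), h = 2 * sqrt(g$var_y))
}

#' Squared 2-Wasserstein distance between Gaussian boxes
#'
#' For Gaussians with diagonal covariances (the box model), the general
#' expression
#' \deqn{W_2^2 = \lVert m_1 - m_2 \rVert^2 +
#'   \mathrm{Tr}\bigl(\Sigma_1 + \Sigma_2 -
#'   2(\Sigma_2^{1/2}\Sigma_1\Sigma_2^{1/2})^{1/2}\bigr)}
#' collapses to the closed form
#' \deqn{(cx_1-cx_2)^2 + (cy_1-cy_2)^2 + ((w_1-w_2)/2)^2 + ((h_1-h_2)/2)^2,}
#' which is what this function computes, vectorised elementwise.
#' `wasserstein_sq_general()` evaluates the matrix expression for one pair of
#' arbitrary (positive-definite, possibly non-diagonal) covariances via
#' eigendecomposition; the two agree on the diagonal case.
#'
#' @param g1,g2 Gaussian tibbles from [box_to_gaussian()] (equal length, or
#'   length 1 recycled).
#' @return Numeric vector of squared distances, pixels squared.
#' @examples
#' wasserstein_sq(box_to_gaussian(bbox(0, 0, 4, 4)),
#'                box_to_gaussian(bbox(3, 4, 4, 4))) # 25
#' @export
wasserstein_sq <- function(g1, g2) {
  if (any(g1$var_x <= 0, g1$var_y <= 0, g2$var_x <= 0, g2$var_y <= 0)) {
    abort("covariances must be positive definite", class = "earcount_invalid_box")
  }
  (g1$mu_x - g2$mu_x)^2 + (g1$mu_y - g2$mu_y)^2 +
    (sqrt(g1$var_x) - sqrt(g2$var_x))^2 + (sqrt(g1$var_y) - sqrt(g2$var_y))^2
}

#' @rdname wasserstein_sq
#' @param m1,m2 Length-2 mean vectors.
#' @param S1,S2 2x2 symmetric positive-definite covariance matrices.
#' @export
wasserstein_sq_general <- function(m1, S1, m2, S2) {
  msqrt <- function(S) {
    e <- eigen(S, symmetric = TRUE)
    if (any(e$values <= 0)) {
      abort("covariance is not positive definite", class = "earcount_invalid_box")
    }
    e$vectors %*% diag(sqrt(e$values)) %*% t(e$vectors)
  }
  r2 <- msqrt(S2)
  cross <- msqrt(r2 %*% S1 %*% r2)
  sum((m1 - m2)^2) + sum(diag(S1 + S2 - 2 * cross))
}

#' Normalized Gaussian Wasserstein distance similarity and loss
#'
#' The NWD similarity between two boxes is `exp(-d / C)` where `d` is the
#' 2-Wasserstein distance between their Gaussian models and `C` a dataset
#' scale constant, in pixels, of the order of typical object extent. The
#' companion loss is `1 - nwd(...)`: zero for identical boxes and, unlike an
#' IoU loss, still informative (finite, strictly increasing in centre
#' distance) for disjoint pairs, which is why it suits very small objects.
#'
#' @param a,b Data frames of boxes (equal length, or length 1 recycled).
#' @param C Positive normalization constant, pixels. Default 12.8.
#' @param use_sqrt If `TRUE` (default) the exponent uses the Wasserstein
#'   distance `sqrt(W2^2)`; if `FALSE` it uses the squared distance `W2^2`
#'   directly (in which case `C` has units of pixels squared).
#' @return Numeric vector: `nwd()` in (0, 1\], `nwd_loss()` in \[0, 1).
#' @examples
#' nwd(bbox(0, 0, 4, 4), bbox(3, 4, 4, 4), C = 5) # exp(-1)
#' @export
nwd <- function(a, b, C = 12.8, use_sqrt = TRUE) {
  if (!is.numeric(C) || length(C) != 1L || C <= 0) {
    abort("C must be a single positive number")
  }
  w2 <- wasserstein_sq(box_to_gaussian(a), box_to_gaussian(b))
  d <- if (use_sqrt) sqrt(w2) else w2
  exp(-d / C)
}

#' @rdname nwd
#' @export
nwd_loss <- function(a, b, C = 12.8, use_sqrt = TRUE) {
  1 - nwd(a, b, C = C, use_sqrt = use_sqrt)
}
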