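#' Space-to-depth rearrangement of a feature map
#'
#' Losslessly trades spatial resolution for channels: a `(S_r, S_c, C)` array
#' becomes `(S_r/scale, S_c/scale, C * scale^2)` by slicing the map into
#' `scale^2` interleaved sub-maps `f[i, j] = x[i::scale, j::scale, ]`
#' (`i`, `j` = 0-based row/column offsets) and stacking them along the channel
#' dimension. Unlike strided convolution or pooling, no value is discarded —
#' the operation is a pure permutation — which is what makes it attractive as
#' a downsampling step when the objects of interest are only a few pixels
#' across. `depth_to_space()` is the exact inverse.
#'
#' The sub-maps are stacked in the order `f[0,0], f[1,0], ..., f[0,1], ...`
#' (row offset varies fastest); pass `order = "col"` for the transpose
#' convention. `mix`, if given, is a `k x (C*scale^2)` matrix applied to the
#' channel vector at every output location — the slot where SPDConv's trained
#' 1x1 convolution would sit (no weights are learned here).
#'
#' @param x 3-D numeric array `(rows, cols, channels)`. A 2-D matrix is
#'   treated as a single-channel map.
#' @param scale Integer block size >= 2.
#' @param order `"row"` (default; row offset fastest) or `"col"`.
#' @param mix Optional channel-mixing matrix with `C * scale^2` columns.
#' @return A 3-D array.
#' @examples
#' x <- array(1:16, dim = c(4, 4, 1))
#' dim(space_to_depth(x, 2)) # 2 2 4
#' @export
space_to_depth <- function(x, scale, order = c("row", "col"), mix = NULL) {
  order <- match.arg(order)
  x <- as_feature_map(x)
  scale <- check_scale(scale)
  d <- dim(x)
  if (d[1] %% scale != 0L || d[2] %% scale != 0L) {
    abort(sprintf("spatial dims (%d x %d) not divisible by scale %d",
                  d[1], d[2], scale), class = "earcount_shape_error")
  }
  offs <- spd_offsets(scale, order)
  blocks <- lapply(seq_len(nrow(offs)), function(k) {
    i <- offs$i[k]; j <- offs$j[k]
    x[seq(i + 1L, d[1], by = scale), seq(j + 1L, d[2], by = scale), ,
      drop = FALSE]
  })
  out <- array(unlist(blocks, use.names = FALSE),
               dim = c(d[1] / scale, d[2] / scale, d[3] * scale^2))
  if (!is.null(mix)) out <- apply_channel_mix(out, mix)
  out
}

#' @rdname space_to_depth
#' @export
depth_to_space <- function(x, scale, order = c("row", "col")) {
  order <- match.arg(order)
  x <- as_feature_map(x)
  scale <- check_scale(scale)
  d <- dim(x)
  if (d[3] %% (scale^2) != 0L) {
    abort(sprintf("channel count %d not divisible by scale^2 = %d",
                  d[3], scale^2), class = "earcount_shape_error")
  }
  c1 <- d[3] %/% (scale^2)
  offs <- spd_offsets(scale, order)
  out <- array(0, dim = c(d[1] * scale, d[2] * scale, c1))
  for (k in seq_len(nrow(offs))) {
    i <- offs$i[k]; j <- offs$j[k]
    ch <- ((k - 1L) * c1 + 1L):(k * c1)
    out[seq(i + 1L, d[1] * scale, by = scale),
        seq(j + 1L, d[2] * scale, by = scale), ] <- x[, , ch, drop = FALSE]
  }
  out
}

# sub-map offsets in stacking order
spd_offsets <- function(scale, order) {
  s <- seq_len(scale) - 1L
  if (order == "row") expand.grid(i = s, j = s) else {
    g <- expand.grid(j = s, i = s)
    g[c("i", "j")]
  }
}

as_feature_map <- function(x) {
  if (is.matrix(x)) x <- array(x, dim = c(dim(x), 1L))
  if (!is.array(x) || length(dim(x)) != 3L) {
    abort("feature map must be a 3-D array (rows, cols, channels)",
          class = "earcount_shape_error")
  }
  x
}

check_scale <- function(scale) {
  if (length(scale) != 1L || scale != round(scale) || scale < 2) {
    abort("scale must be a single integer >= 2", class = "earcount_shape_error")
  }
  as.integer(scale)
}

apply_channel_mix <- function(x, mix) {
  d <- dim(x)
  if (!is.matrix(mix) || ncol(mix) != d[3]) {
    abort(sprintf("mix must be a matrix with %d columns", d[3]),
          class = "earcount_shape_error")
  }
  flat <- matrix(x, nrow = d[1] * d[2], ncol = d[3])
  array(flat %*% t(mix), dim = c(d[1], d[2], nrow(mix)))
}
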