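#' Optimal one-to-one assignment on a similarity matrix
#'
#' Solves the linear assignment problem maximising total score, via a
#' compiled Jonker-Volgenant shortest-augmenting-path solver on the negated
#' scores. Rectangular matrices are padded internally and `min(rows, cols)`
#' pairs returned; the result is deterministic for a given matrix.
#'
#' @param score Numeric matrix of finite non-negative similarities
#'   (rows = tracks, columns = detections).
#' @return A tibble with columns `row`, `col` (1-based) and `score`, ordered
#'   by `row`.
#' @examples
#' solve_assignment(rbind(c(0.9, 0.1), c(0.2, 0.8)))
#' @export
solve_assignment <- function(score) {
  if (!is.matrix(score)) score <- as.matrix(score)
  if (length(score) == 0L) {
    return(tibble::tibble(row = integer(), col = integer(), score = numeric()))
  }
  if (!all(is.finite(score)) || any(score < 0)) {
    abort("score matrix must contain finite non-negative values")
  }
  nr <- nrow(score); nc <- ncol(score); n <- max(nr, nc)
  cost <- matrix(0, n, n)
  cost[seq_len(nr), seq_len(nc)] <- -score
  j <- lap_solve(cost) + 1L
  rows <- seq_len(nr)
  keep <- j[rows] <= nc
  tibble::new_tibble(list(row = rows[keep], col = j[rows][keep],
                          score = score[cbind(rows[keep], j[rows][keep])]),
                     nrow = sum(keep))
}

#' Match predicted track boxes to detections with a gated assignment
#'
#' Computes the pairwise similarity between Kalman-predicted boxes and
#' current-frame detections (IoU by default, NWD optionally), solves the
#' optimal assignment, and then dissolves any assigned pair whose similarity
#' does not exceed `gate` into the unmatched sets. The default gate of 0.7 on
#' IoU means a predicted and a detected box are declared the same object only
#' when they overlap by more than 70%. With `gate_mode = "pre"` sub-gate
#' similarities are zeroed before solving instead, so they cannot influence
#' which other pairs are chosen.
#'
#' @param predicted Data frame of predicted track boxes (may be empty).
#' @param detections Data frame of detected boxes (may be empty).
#' @param gate Similarity threshold in \[0, 1); a pair survives only if its
#'   similarity is strictly greater. Default 0.7.
#' @param method `"iou"` (default) or `"nwd"`.
#' @param gate_mode `"post"` (default: gate after the global solve) or
#'   `"pre"` (mask sub-gate scores before solving).
#' @param C,use_sqrt NWD parameters, used when `method = "nwd"`.
#' @return Object of class `match_result`: list with `matches` (tibble
#'   `track`, `detection`, `score`), `unmatched_tracks`, and
#'   `unmatched_detections` (integer index vectors).
#' @export
match_tracks <- function(predicted, detections, gate = 0.7,
                         method = c("iou", "nwd"),
                         gate_mode = c("post", "pre"),
                         C = 12.8, use_sqrt = TRUE) {
  method <- match.arg(method)
  gate_mode <- match.arg(gate_mode)
  if (gate < 0 || gate >= 1) abort("gate must lie in [0, 1)")
  nt <- if (is.null(predicted)) 0L else nrow(predicted)
  nd <- if (is.null(detections)) 0L else nrow(detections)
  if (nt == 0L || nd == 0L) {
    return(new_match_result(
      tibble::tibble(track = integer(), detection = integer(), score = numeric()),
      seq_len(nt), seq_len(nd)))
  }
  score <- if (method == "iou") {
    iou_matrix(predicted, detections)
  } else {
    nwd_matrix(predicted, detections, C = C, use_sqrt = use_sqrt)
  }
  solved <- if (gate_mode == "pre") {
    solve_assignment(ifelse(score > gate, score, 0))
  } else {
    solve_assignment(score)
  }
  true_score <- score[cbind(solved$row, solved$col)]
  keep <- true_score > gate
  matches <- tibble::new_tibble(list(track = solved$row[keep],
                                     detection = solved$col[keep],
                                     score = true_score[keep]),
                                nrow = sum(keep))
  new_match_result(matches,
                   setdiff(seq_len(nt), matches$track),
                   setdiff(seq_len(nd), matches$detection))
}

new_match_result <- function(matches, unmatched_tracks, unmatched_detections) {
  structure(list(matches = matches,
                 unmatched_tracks = as.integer(unmatched_tracks),
                 unmatched_detections = as.integer(unmatched_detections)),
            class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("<match_result> %d matched, %d unmatched tracks, %d unmatched detections\n",
              nrow(x$matches), length(x$unmatched_tracks),
              length(x$unmatched_detections)))
  invisible(x)
}

# pairwise NWD similarity matrix
nwd_matrix <- function(a, b, C = 12.8, use_sqrt = TRUE) {
  ga <- box_to_gaussian(a); gb <- box_to_gaussian(b)
  w2 <- outer(ga$mu_x, gb$mu_x, `-`)^2 + outer(ga$mu_y, gb$mu_y, `-`)^2 +
    outer(sqrt(ga$var_x), sqrt(gb$var_x), `-`)^2 +
    outer(sqrt(ga$var_y), sqrt(gb$var_y), `-`)^2
  d <- if (use_sqrt) sqrt(w2) else w2
  exp(-d / C)
}
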