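# Ranking library predictions and selecting the screening subset.

#' Select the upper quartile of predicted scores
#'
#' Ranks predicted pIC50 values (rank 1 = highest) and flags the
#' compounds in the upper fourth quartile. Two readings of "upper fourth
#' quartile" are supported: \code{"value-range"} (the default) selects
#' scores at or above \code{min + 0.75 * (max - min)}, i.e. the top
#' quarter of the observed value range; \code{"rank"} selects scores at
#' or above the third quartile Q3 of the score distribution
#' (linear-interpolation quantile, \code{\link[stats]{quantile}} type 7).
#' Ties at the cut are always included.
#'
#' @param scores numeric predicted values.
#' @param ids compound identifiers (defaults to names or positions).
#' @param mode \code{"value-range"} or \code{"rank"}.
#' @return data.frame with columns \code{id}, \code{predicted_pic50},
#'   \code{rank}, \code{selected}, \code{mode}, ordered by rank;
#'   attribute \code{"cut"} holds the numeric cutoff used.
#' @export
select_upper_quartile <- function(scores, ids = NULL,
                                  mode = c("value-range", "rank")) {
  mode <- match.arg(mode)
  stopifnot(length(scores) >= 1, all(is.finite(scores)))
  if (is.null(ids)) ids <- if (!is.null(names(scores))) names(scores) else
    as.character(seq_along(scores))
  cut <- if (mode == "value-range")
    min(scores) + 0.75 * (max(scores) - min(scores))
  else unname(stats::quantile(scores, 0.75, type = 7))
  ord <- order(scores, decreasing = TRUE)
  out <- data.frame(id = ids[ord], predicted_pic50 = scores[ord],
                    rank = seq_along(scores),
                    selected = scores[ord] >= cut,
                    mode = if (mode == "rank") "rank-quartile" else
                      "value-range-quartile",
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "cut") <- cut
  out
}

#' Summary statistics of a score vector
#'
#' @param scores numeric vector (n >= 1).
#' @return list with \code{mean}, \code{min}, \code{max}, \code{q1},
#'   \code{median}, \code{q3}, \code{n}.
#' @export
score_summary <- function(scores) {
  stopifnot(length(scores) >= 1)
  q <- stats::quantile(scores, c(0.25, 0.5, 0.75), type = 7)
  list(mean = mean(scores), min = min(scores), max = max(scores),
       q1 = unname(q[1L]), median = unname(q[2L]), q3 = unname(q[3L]),
       n = length(scores))
}
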