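# Kovats retention indices on an n-alkane ladder (temperature-programmed
# linear convention).

#' Construct an n-alkane retention ladder
#'
#' @param carbon Integer carbon numbers (e.g. 7:40), strictly increasing.
#' @param rt Retention times in minutes, strictly increasing, same length.
#' @return Tibble with columns `carbon`, `rt`, class `alkane_ladder`.
#' @export
alkane_ladder <- function(carbon, rt) {
  stopifnot(
    length(carbon) == length(rt), length(carbon) >= 2,
    all(diff(carbon) > 0), all(diff(rt) > 0)
  )
  out <- tibble::tibble(carbon = as.integer(carbon), rt = as.numeric(rt))
  class(out) <- c("alkane_ladder", class(out))
  out
}

#' Kovats retention index under temperature programming
#'
#' Linear interpolation between the bracketing n-alkanes:
#' `RI = 100 * (n + (rt - rt_n) / (rt_(n+1) - rt_n) * (n+1 - n))`.
#' No extrapolation: retention times outside the ladder span are rejected.
#'
#' @param rt Retention time(s) in minutes, within the ladder span.
#' @param ladder An [alkane_ladder()].
#' @return Retention index (dimensionless), vectorized over `rt`.
#' @examples
#' lad <- alkane_ladder(7:12, c(2, 4, 6, 8, 10, 12))
#' kovats_ri(9, lad) # midpoint of C10 and C11 -> 1050
#' @export
kovats_ri <- function(rt, ladder) {
  stopifnot(inherits(ladder, "alkane_ladder"))
  if (any(rt < min(ladder$rt) | rt > max(ladder$rt))) {
    stop("retention time outside the alkane ladder span (no extrapolation)",
      call. = FALSE
    )
  }
  i <- findInterval(rt, ladder$rt, rightmost.closed = TRUE)
  frac <- (rt - ladder$rt[i]) / (ladder$rt[i + 1L] - ladder$rt[i])
  100 * (ladder$carbon[i] + frac * (ladder$carbon[i + 1L] - ladder$carbon[i]))
}
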