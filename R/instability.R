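#' Instability factor of a centre-of-mass series
#'
#' The instability factor approximates the first-order differential of the
#' com trajectory: `if(t) = sqrt( (dx^2 + dy^2) / 2 )` with `dx`, `dy` the
#' component deltas from the previous sample. It measures how abruptly the
#' player shifts weight; high values flag potential balance loss. The first
#' sample has no predecessor, so `if(0) = 0`. Values are per-sample (not
#' rescaled by the 20 Hz interval); the conventional exceedance thresholds
#' 0.5, 1, 1.5, 2 are in these units.
#'
#' @inheritParams classify_intention
#' @return Non-negative numeric vector, same length as the series.
#' @examples
#' compute_if(rbind(c(0, 0), c(0.3, 0.4)))  # 0, sqrt(0.125)
#' @export
compute_if <- function(com) {
  cm <- as_com_matrix(com)
  n <- nrow(cm)
  if (n == 0L) stop("com series must be non-empty", call. = FALSE)
  if (n == 1L) return(0)
  dx <- diff(cm[, 1]); dy <- diff(cm[, 2])
  c(0, sqrt(0.5 * dx^2 + 0.5 * dy^2))
}

#' Rolling sum of the instability factor
#'
#' `if_sum(t)` sums the last `window` instability values up to and
#' including `t` (alignment `[t - window + 1, t]`); the window is truncated
#' at the start of the series rather than padded.
#'
#' @param if_values Output of [compute_if()].
#' @param window Window length in samples; default 25 (1.25 s at 20 Hz).
#' @return Numeric vector of rolling sums, same length as `if_values`.
#' @export
compute_if_sum <- function(if_values, window = 25L) {
  window <- as.integer(window)
  if (is.na(window) || window < 1L)
    stop("window must be a positive integer", call. = FALSE)
  n <- length(if_values)
  cs <- cumsum(if_values)
  lag <- c(rep(0, min(window, n)), cs[seq_len(max(0L, n - window))])
  cs - lag
}
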