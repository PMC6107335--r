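#' Prominence-based peak finding
#'
#' Locates local maxima of a series and computes their topographic
#' prominence: the height of the peak above the higher of the two lowest
#' saddles separating it from taller terrain (or from the series boundary).
#' Plateau maxima are attributed to their earliest sample. Equivalent in
#' behavior to MATLAB's `findpeaks` with `MinPeakProminence`.
#'
#' @param x Numeric series.
#' @param min_prominence Keep only peaks with prominence >= this value
#'   (default 0, all local maxima).
#' @return Data frame with columns `index`, `value`, `prominence`, ordered by
#'   index.
#' @export
find_peaks <- function(x, min_prominence = 0) {
  n <- length(x)
  empty <- data.frame(index = integer(), value = numeric(),
                      prominence = numeric())
  if (n < 3) return(empty)
  # candidate local maxima; plateaus -> earliest sample
  idx <- integer()
  i <- 2L
  while (i <= n - 1L) {
    if (x[i] > x[i - 1L]) {
      j <- i
      while (j < n && x[j + 1L] == x[j]) j <- j + 1L
      if (j < n && x[j + 1L] < x[j]) idx <- c(idx, i)
      i <- j + 1L
    } else i <- i + 1L
  }
  if (!length(idx)) return(empty)
  prom <- vapply(idx, function(p) {
    v <- x[p]
    # lowest point until a strictly higher value (or boundary), each side
    left <- x[seq_len(p - 1L)]
    higher <- which(left > v)
    lmin <- min(left[seq.int(if (length(higher)) max(higher) else 1L, p - 1L)])
    right <- x[seq.int(p + 1L, n)]
    higher <- which(right > v)
    rmin <- min(right[seq_len(if (length(higher)) min(higher) else
                              length(right))])
    v - max(lmin, rmin)
  }, 0)
  out <- data.frame(index = idx, value = x[idx], prominence = prom)
  out[out$prominence >= min_prominence, , drop = FALSE]
}
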