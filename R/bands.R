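#' Default acceleration band edges
#'
#' The movement intensity continuum is discretised into 25 contiguous
#' acceleration bands: 24 bands of width 0.25 m/s2 from 0 to 6 m/s2 plus an
#' open-topped band above 6 m/s2.  The range spans the accelerations children
#' reach in everyday activity (slow walking ~0.75 m/s2 up to running and
#' jumping >4 m/s2), so the upper open band holds only a tiny fraction of
#' wear time.
#'
#' @param width band width in m/s2.
#' @param n_closed number of closed bands before the open top band.
#' @return numeric vector of `n_closed + 2` band edges, ending in `Inf`.
#' @export
#' @examples
#' default_bands()
default_bands <- function(width = 0.25, n_closed = 24) {
  stopifnot(width > 0, n_closed >= 2)
  c(seq(0, width * n_closed, by = width), Inf)
}

#' Band midpoints for the log-log intensity fit
#'
#' Midpoint of each band defined by `edges`.  The open top band has no finite
#' midpoint; it is assigned its lower edge plus one closed-band width
#' (6.25 m/s2 for the defaults), i.e. the centre of a phantom closed band
#' above the grid.  The fitted gradient is insensitive to this choice because
#' the top band carries a negligible fraction of wear time.
#'
#' @param edges band edges as returned by [default_bands()].
#' @return numeric vector of band midpoints (one fewer than `edges`).
#' @export
band_midpoints <- function(edges) {
  stopifnot(is.numeric(edges), length(edges) >= 3, !is.unsorted(edges))
  lower <- edges[-length(edges)]
  upper <- edges[-1]
  mid <- (lower + upper) / 2
  if (is.infinite(upper[length(upper)])) {
    k <- length(mid)
    w <- lower[k] - lower[k - 1L]
    mid[k] <- lower[k] + w
  }
  mid
}

# Assign accelerations to bands: first band closed at 0, all bands
# left-open/right-closed, i.e. [0, e1], (e1, e2], ...
band_index <- function(acceleration, edges) {
  findInterval(acceleration, edges, left.open = TRUE, rightmost.closed = FALSE) +
    (acceleration == edges[1])
}
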