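#' Radar plot of group MX profiles
#'
#' Draws the per-group MX means of [group_mx_summary()] on a radar (spider)
#' chart, one spoke per X, using base graphics.  Standardized profiles
#' (`value = "std_mean"`) put all X on a common scale and make intensity
#' differences between equal-volume groups visible.
#'
#' @param summary data frame from [group_mx_summary()].
#' @param value column to plot, `"std_mean"` or `"raw_mean"`.
#' @param main plot title.
#' @param cols line colours, one per group.
#' @return invisibly, the matrix of plotted values (groups x spokes).
#' @export
plot_mx_radar <- function(summary, value = c("std_mean", "raw_mean"),
                          main = NULL, cols = NULL) {
  value <- match.arg(value)
  xs <- sort(unique(summary$X))
  groups <- unique(summary$group)
  mat <- t(vapply(groups, function(g) {
    s <- summary[summary$group == g, ]
    s[[value]][match(xs, s$X)]
  }, numeric(length(xs))))
  rownames(mat) <- groups
  if (is.null(cols)) cols <- seq_along(groups) + 1L
  rmax <- max(mat, na.rm = TRUE)
  ang <- pi / 2 - 2 * pi * (seq_along(xs) - 1) / length(xs)
  op <- graphics::par(mar = c(1, 1, 3, 1), pty = "s")
  on.exit(graphics::par(op))
  plot(NA, xlim = c(-1.3, 1.3) * rmax, ylim = c(-1.3, 1.3) * rmax,
       axes = FALSE, xlab = "", ylab = "",
       main = if (is.null(main)) paste("MX profile,", value) else main)
  for (r in pretty(c(0, rmax), 4)[-1]) {
    graphics::polygon(r * cos(ang), r * sin(ang), border = "grey80")
  }
  graphics::segments(0, 0, rmax * cos(ang), rmax * sin(ang), col = "grey80")
  graphics::text(1.15 * rmax * cos(ang), 1.15 * rmax * sin(ang),
                 paste0("M", xs), cex = 0.8)
  for (i in seq_along(groups)) {
    graphics::polygon(mat[i, ] * cos(ang), mat[i, ] * sin(ang),
                      border = cols[i], lwd = 2)
  }
  graphics::legend("topleft", legend = groups, col = cols, lwd = 2,
                   bty = "n", cex = 0.7)
  invisible(mat)
}
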