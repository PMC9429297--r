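#' Draw a patient network
#'
#' Minimal inspection plot: nodes on a circle, directed links as
#' arrows, isolated nodes unmarked by links. Intended for eyeballing
#' single networks, not publication graphics.
#'
#' @param x A `patient_network`.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.patient_network <- function(x, ...) {
  n <- length(x$nodes)
  th <- seq(0, 2 * pi, length.out = n + 1L)[seq_len(n)]
  px <- cos(th); py <- sin(th)
  graphics::plot(px, py, xlim = c(-1.3, 1.3), ylim = c(-1.3, 1.3),
                 asp = 1, axes = FALSE, xlab = "", ylab = "",
                 pch = 21, bg = "steelblue", cex = 1.6,
                 main = sprintf("%s (%d)", x$group_id, x$year), ...)
  if (nrow(x$edges)) {
    i <- match(x$edges[, 1L], x$nodes); j <- match(x$edges[, 2L], x$nodes)
    graphics::arrows(px[i], py[i], px[j] * 0.96, py[j] * 0.96,
                     length = 0.07, col = "grey40")
  }
  graphics::text(px * 1.18, py * 1.18, x$nodes, cex = 0.6)
  invisible(x)
}
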