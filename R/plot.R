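# Index plotting.

#' Plot one or more monthly index series
#'
#' Line chart of index values over months, optionally overlaying several
#' series with a legend and annotating named events with vertical markers.
#' Annotation months outside the plotted range are skipped with a warning.
#'
#' @param x an [hpu_index()] or a list of them.
#' @param annotations optional named character vector, month key -> label.
#' @param file optional output path (PNG); when `NULL`, draws on the
#'   current device.
#' @param main plot title.
#' @param ... passed to [graphics::matplot()].
#' @return invisibly, the matrix of plotted values.
#' @export
plot_index <- function(x, annotations = NULL, file = NULL,
                       main = "Health policy uncertainty index", ...) {
  series <- if (inherits(x, "hpu_index")) list(x) else x
  if (!length(series) || !all(vapply(series, inherits, logical(1L), "hpu_index"))) {
    stop_validation("x must be an hpu_index or a non-empty list of them")
  }
  labels <- vapply(seq_along(series), function(k) {
    lb <- attr(series[[k]], "label")
    if (is.null(lb) || !nzchar(lb)) paste0("series", k) else lb
  }, character(1L))
  months <- sort(unique(unlist(lapply(series, names))))
  mat <- sapply(series, function(s) as.numeric(index_values(s)[months]))
  mat <- matrix(mat, nrow = length(months), dimnames = list(months, labels))
  if (!is.null(file)) {
    grDevices::png(file, width = 960, height = 480)
    on.exit(grDevices::dev.off())
  }
  at <- seq_along(months)
  graphics::matplot(at, mat, type = "l", lty = 1, lwd = 1.5,
                    col = seq_len(ncol(mat)), xaxt = "n",
                    xlab = "month", ylab = "index (mean = 100)", main = main, ...)
  ticks <- unique(round(seq(1, length(months), length.out = min(12, length(months)))))
  graphics::axis(1, at = ticks, labels = months[ticks], las = 2, cex.axis = 0.8)
  if (ncol(mat) > 1L) {
    graphics::legend("topleft", legend = labels, col = seq_len(ncol(mat)),
                     lty = 1, lwd = 1.5, bty = "n")
  }
  if (length(annotations)) {
    if (is.null(names(annotations))) stop_validation("annotations must be named by month")
    ann_mo <- ym_canon(names(annotations))
    inside <- ann_mo %in% months
    if (any(!inside)) {
      warning("annotation month(s) outside plotted range skipped: ",
              paste(ann_mo[!inside], collapse = ", "), call. = FALSE)
    }
    for (k in which(inside)) {
      pos <- match(ann_mo[k], months)
      graphics::abline(v = pos, col = "grey50", lty = 3)
      graphics::text(pos, max(mat, na.rm = TRUE), annotations[[k]],
                     srt = 90, adj = c(1, -0.3), cex = 0.7, col = "grey30")
    }
  }
  invisible(mat)
}

#' @export
plot.hpu_index <- function(x, ...) {
  plot_index(x, ...)
}
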