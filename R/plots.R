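# Base-graphics views of the main result objects.

#' Plot a divergence landscape
#'
#' Abundance per divergence bin, with called peaks shaded.
#'
#' @param x A \code{"divergence_landscape"}.
#' @param peaks Optional peak table from \code{\link{call_peaks}}.
#' @param max_bin Rightmost bin to draw; default the last non-zero bin.
#' @param ... Passed to \code{barplot}.
#' @return Invisibly, the bar midpoints.
#' @export
plot_landscape <- function(x, peaks = NULL, max_bin = NULL, ...) {
  v <- x$values
  if (is.null(max_bin)) max_bin <- max(which(v > 0), 10L)
  v <- v[seq_len(min(max_bin, length(v)))]
  cols <- rep("grey70", length(v))
  if (!is.null(peaks) && nrow(peaks)) {
    for (i in seq_len(nrow(peaks))) {
      cols[(peaks$from[i]:peaks$to[i]) + 1L] <- "firebrick"
    }
  }
  mids <- graphics::barplot(v, col = cols, border = NA,
                            names.arg = sprintf("%.0f", (seq_along(v) - 1) * x$bin_width * 100),
                            xlab = "divergence from consensus (%)",
                            ylab = "abundance",
                            main = if (is.na(x$family_id)) "" else x$family_id, ...)
  invisible(mids)
}

#' Plot a per-family expression profile across stages
#'
#' Mean FPKM per stage, one line per sex, with +/- one standard deviation
#' whiskers where replicates allow.
#'
#' @param profile Output of \code{\link{expression_profile}} for one family.
#' @param stages Stage order on the x axis.
#' @param ... Passed to \code{matplot}.
#' @return Invisibly, the plotted matrix.
#' @export
plot_expression_profile <- function(profile,
                                    stages = c("egg", "early_larva", "mid_larva",
                                               "late_larva", "early_pupa", "late_pupa",
                                               "early_adult", "late_adult"), ...) {
  fam <- unique(profile$family_id)
  if (length(fam) != 1L) stop("plot one family at a time")
  sexes <- sort(unique(profile$sex))
  m <- sapply(sexes, function(sx) {
    vapply(stages, function(st) {
      v <- profile$mean_fpkm[profile$stage == st & profile$sex == sx]
      if (length(v)) v[1] else NA_real_
    }, numeric(1))
  })
  m <- matrix(m, nrow = length(stages),
              dimnames = list(stages, sexes))
  graphics::matplot(seq_along(stages), m, type = "b", pch = 19, lty = 1,
                    xaxt = "n", xlab = "developmental stage",
                    ylab = "mean FPKM", main = fam, ...)
  graphics::axis(1, at = seq_along(stages), labels = stages, las = 2, cex.axis = 0.7)
  graphics::legend("topleft", legend = colnames(m), col = seq_len(ncol(m)),
                   pch = 19, bty = "n")
  invisible(m)
}
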