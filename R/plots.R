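# Base-graphics summaries of the main result objects.

#' Plot a binned metagene profile
#'
#' Gene-body bins with the flanking position-wise profiles on either
#' side, in the layout used for cross-species metagene panels.
#'
#' @param x a `binned_metagene`.
#' @param ... further arguments to [plot()].
#' @export
plot.binned_metagene <- function(x, ...) {
  nb <- nrow(x$body)
  fb <- if (!is.null(x$upstream)) nrow(x$upstream) else 0L
  # map flank positions onto pseudo-bin coordinates (5 bins per flank)
  xs <- ys <- numeric(0)
  if (fb > 0L) {
    xs <- c(xs, x$upstream$offset / fb * 5)
    ys <- c(ys, x$upstream$skew)
  }
  xs <- c(xs, x$body$bin - 0.5)
  ys <- c(ys, x$body$skew)
  if (fb > 0L) {
    xs <- c(xs, nb + x$downstream$offset / fb * 5 + 5 / fb)
    ys <- c(ys, x$downstream$skew)
  }
  plot(xs, ys, type = "l",
       xlab = "gene-body bin (flanks scaled)",
       ylab = paste(x$pair, "skew"), ...)
  graphics::abline(h = 0, lty = 3)
  graphics::abline(v = c(0, nb), lty = 2, col = "grey50")
  invisible(x)
}

#' Plot a superposed skew profile
#'
#' @param x a `skew_profile`.
#' @param ... further arguments to [plot()].
#' @export
plot.skew_profile <- function(x, ...) {
  plot(x$offset, x$skew, type = "l",
       xlab = sprintf("offset from %s anchor (bp)", attr(x, "anchor")),
       ylab = paste(attr(x, "pair"), "skew"), ...)
  graphics::abline(h = 0, lty = 3)
  graphics::abline(v = 0, lty = 2, col = "grey50")
  invisible(x)
}

#' Plot terminal amino-acid bias ranked by 5'/3' ratio
#'
#' Bars are coloured by the mean GC skew of the codons encoding each
#' residue (blue = C-biased codons, red = G-biased codons), which
#' makes the agreement between terminal residue preference and codon
#' skew visible at a glance.
#'
#' @param x an `aa_bias` table from [terminal_aa_bias()].
#' @param ... further arguments to [graphics::barplot()].
#' @export
plot.aa_bias <- function(x, ...) {
  df <- x[!is.na(x$ratio5to3), , drop = FALSE]
  sk <- df$codon_skew
  sk[is.na(sk)] <- 0
  pal <- grDevices::colorRamp(c("#2166AC", "#F7F7F7", "#B2182B"))
  cols <- grDevices::rgb(pal((sk + 1) / 2), maxColorValue = 255)
  graphics::barplot(df$ratio5to3, names.arg = df$residue, col = cols,
                    ylab = "5'/3' frequency ratio", ...)
  graphics::abline(h = 1, lty = 3)
  invisible(x)
}

#' Plot a sliding-window skew track
#'
#' @param x a `skew_track`.
#' @param ... further arguments to [plot()].
#' @export
plot.skew_track <- function(x, ...) {
  plot(x$center, x$skew, type = "l", xlab = "position (bp)",
       ylab = paste(attr(x, "pair"), "skew"), ...)
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}
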