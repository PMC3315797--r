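# Three-line piecewise model of GC skew along gene bodies:
# a linear 5' ramp, a flat centre, and a linear 3' ramp, fitted to
# pooled positional skew series by exhaustive grid enumeration.

#' Build the three anchored skew regions
#'
#' Pools positional base counts over genes for three `region_len`-bp
#' windows: a 5' region aligned to the ATG, a central region aligned
#' to the middle of each gene, and a 3' region aligned to the stop
#' codon, then computes the pooled skew per position. Genes shorter
#' than a window contribute the positions they cover unless
#' `strict = TRUE`, which drops genes shorter than `region_len`.
#'
#' @param genes an [oriented_genes] table.
#' @param region_len region length in bp (default 750).
#' @param pair `"GC"` or `"AT"`.
#' @param strict drop genes shorter than `region_len`.
#' @return list of class `skew_regions`: `five`, `centre`, `three`
#'   (numeric skew series of length `region_len`; `five[i]` is i-1 bp
#'   from the ATG, `three[i]` is `region_len - i` bp before the last
#'   base of the stop), matching `*_counts` matrices, `region_len`,
#'   `n_genes`.
#' @export
build_regions <- function(genes, region_len = 750L, pair = c("GC", "AT"),
                          strict = FALSE) {
  genes <- as_oriented_genes(genes)
  pair <- match.arg(pair)
  stopifnot(region_len >= 2L)
  if (strict) {
    genes <- genes[nchar(genes$cds) >= region_len, , drop = FALSE]
  }
  if (nrow(genes) == 0L) stop("no eligible genes")
  m5 <- mc <- m3 <- matrix(0L, 4L, region_len)
  half <- region_len %/% 2L
  for (i in seq_len(nrow(genes))) {
    cds <- genes$cds[i]
    L <- nchar(cds)
    codes <- seq_codes(cds)
    span <- min(L, region_len)
    m5 <- .acc_counts(m5, codes[seq_len(span)], seq_len(span))
    m3 <- .acc_counts(m3, codes[(L - span + 1L):L],
                      (region_len - span + 1L):region_len)
    # centre window: positions mid-half .. mid+half-1 (0-based),
    # clipped to the gene
    mid <- L %/% 2L
    from <- mid - half          # 0-based inclusive
    to <- mid + half - 1L       # 0-based inclusive
    gfrom <- max(from, 0L)
    gto <- min(to, L - 1L)
    if (gfrom <= gto) {
      mc <- .acc_counts(mc, codes[(gfrom + 1L):(gto + 1L)],
                        (gfrom - from + 1L):(gto - from + 1L))
    }
  }
  structure(list(
    five = skew_from_counts(m5, pair),
    centre = skew_from_counts(mc, pair),
    three = skew_from_counts(m3, pair),
    five_counts = m5, centre_counts = mc, three_counts = m3,
    region_len = as.integer(region_len),
    pair = pair,
    n_genes = nrow(genes)
  ), class = "skew_regions")
}

#' Fit the three-line skew model by exhaustive enumeration
#'
#' The model has five parameters: `a`, the skew at the ATG minus the
#' central skew; `b`, the length of the 5' ramp in bp; `c`, the skew
#' of the central section; `d`, the length of the 3' ramp in bp
#' (measured back from the stop); and `e`, the skew at the stop minus
#' the central skew. Within the 5' region the model value at x bp from
#' the ATG is `c + a * max(0, (b - x)/b)`; within the 3' region at t
#' bp before the stop it is `c + e * max(0, (d - t)/d)`; the centre is
#' constant at `c`.
#'
#' `c` is the mean of the central series. The remaining parameters
#' minimise the total squared error over the declared grids by
#' exhaustive enumeration; because the 5' and 3' terms share no
#' parameter once `c` is fixed, the two searches factorise, which
#' changes nothing about the optimum. Ties are broken toward the
#' smallest `b`, then the smallest `d`, then grid order in `a`/`e`.
#' `b = 0` (or `d = 0`) denotes no ramp, with `a` (`e`) forced to 0.
#'
#' @param regions a `skew_regions` object from [build_regions()].
#' @param a_grid,e_grid skew-offset grids (default -1 to 1 step 0.01).
#' @param b_grid,d_grid ramp-length grids in bp (default 0 to
#'   `region_len` step 10).
#' @return list of class `three_line_fit` with `a`, `b`, `c`, `d`,
#'   `e`, `sse`, `sse_five`, `sse_centre`, `sse_three`, `region_len`.
#' @export
fit_three_line <- function(regions,
                           a_grid = seq(-1, 1, by = 0.01),
                           b_grid = seq(0L, regions$region_len, by = 10L),
                           d_grid = seq(0L, regions$region_len, by = 10L),
                           e_grid = seq(-1, 1, by = 0.01)) {
  stopifnot(inherits(regions, "skew_regions"))
  if (length(a_grid) == 0L || length(b_grid) == 0L ||
      length(d_grid) == 0L || length(e_grid) == 0L) {
    stop("empty parameter grid")
  }
  rl <- regions$region_len
  cc <- mean(regions$centre, na.rm = TRUE)
  sse_centre <- sum((regions$centre - cc)^2, na.rm = TRUE)

  # residual series against the flat level c
  fit_ramp <- function(series, dist, len_grid, amp_grid) {
    r <- series - cc
    ok <- !is.na(r)
    best <- list(len = len_grid[1L], amp = 0,
                 sse = sum(r[ok]^2))
    first <- TRUE
    for (len in sort(len_grid)) {
      if (len <= 0L) {
        sse0 <- sum(r[ok]^2)
        if (first || sse0 < best$sse) best <- list(len = 0L, amp = 0,
                                                   sse = sse0)
        first <- FALSE
        next
      }
      w <- pmax(0, (len - dist) / len)
      Sww <- sum(w[ok]^2)
      Srw <- sum(r[ok] * w[ok])
      Srr <- sum(r[ok]^2)
      sse_all <- Srr - 2 * amp_grid * Srw + amp_grid^2 * Sww
      j <- which.min(sse_all)
      if (first || sse_all[j] < best$sse) {
        best <- list(len = len, amp = amp_grid[j], sse = sse_all[j])
      }
      first <- FALSE
    }
    best
  }
  x5 <- seq_len(rl) - 1L            # bp from ATG
  t3 <- rl - seq_len(rl)            # bp before last stop base
  f5 <- fit_ramp(regions$five, x5, b_grid, a_grid)
  f3 <- fit_ramp(regions$three, t3, d_grid, e_grid)
  structure(list(
    a = f5$amp, b = f5$len, c = cc, d = f3$len, e = f3$amp,
    sse = f5$sse + sse_centre + f3$sse,
    sse_five = f5$sse, sse_centre = sse_centre, sse_three = f3$sse,
    region_len = rl
  ), class = "three_line_fit")
}

#' @export
print.three_line_fit <- function(x, ...) {
  cat("three_line_fit: a=", signif(x$a, 4), " b=", x$b,
      " c=", signif(x$c, 4), " d=", x$d, " e=", signif(x$e, 4),
      "  sse=", signif(x$sse, 5), " (region ", x$region_len, " bp)\n",
      sep = "")
  invisible(x)
}

#' Evaluate the fitted three-line model
#'
#' @param fit a `three_line_fit`.
#' @param region `"five"`, `"centre"` or `"three"`.
#' @param x positions: bp from the ATG for `"five"` (0 = first base of
#'   ATG), bp before the last base of the stop for `"three"` (0 =
#'   stop), ignored for `"centre"`. Must lie in
#'   \[0, region_len\].
#' @return model skew values.
#' @export
predict_three_line <- function(fit, region = c("five", "centre", "three"),
                               x = 0) {
  stopifnot(inherits(fit, "three_line_fit"))
  region <- match.arg(region)
  if (region != "centre" &&
      (any(x < 0) || any(x > fit$region_len))) {
    stop("position outside the fitted region")
  }
  switch(region,
    five = if (fit$b > 0L) {
      fit$c + fit$a * pmax(0, (fit$b - x) / fit$b)
    } else rep(fit$c, length(x)),
    centre = rep(fit$c, length(x)),
    three = if (fit$d > 0L) {
      fit$c + fit$e * pmax(0, (fit$d - x) / fit$d)
    } else rep(fit$c, length(x))
  )
}

#' Write a three-line fit report as JSON
#'
#' @param fit a `three_line_fit`.
#' @param path output path.
#' @export
write_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "three_line_fit"))
  jsonlite::write_json(
    list(a = fit$a, b = fit$b, c = fit$c, d = fit$d, e = fit$e,
         sse = fit$sse, region_len = fit$region_len),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
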