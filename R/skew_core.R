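# Skew profiles: superposed (metagene at bp resolution), binned
# metagene with flanks, and sliding-window chromosomal tracks.

# Accumulate positional base counts into a 4 x width matrix.
# `offsets` gives, for base i of `codes`, its 1-based column; bases
# with NA code or out-of-range column are skipped. Positions within
# one sequence are unique, so plain matrix-index increment is safe.
.acc_counts <- function(m, codes, cols) {
  ok <- !is.na(codes) & cols >= 1L & cols <= ncol(m)
  if (any(ok)) {
    idx <- cbind(codes[ok], cols[ok])
    m[idx] <- m[idx] + 1L
  }
  m
}

#' Superposed (metagene) skew profile anchored at start or stop codon
#'
#' All genes are aligned at a common anchor and the skew at each
#' offset is computed from base counts pooled over genes ("total skew
#' per position"). With `anchor = "start"`, offset 0 is the A of the
#' ATG; negative offsets run into the upstream flank. With
#' `anchor = "stop"`, offset 0 is the first base after the stop codon,
#' so offset -1 is the last base of the stop and negative offsets run
#' into the CDS.
#'
#' Because each offset is a single base per gene, pooled-count skew at
#' an offset equals the mean of per-gene one-base skews over the genes
#' carrying G or C (resp. A or T) there; there is no separate
#' mean-of-genes mode for this profile.
#'
#' @param genes an [oriented_genes] table.
#' @param anchor `"start"` or `"stop"`.
#' @param upstream_bp,downstream_bp span of negative / non-negative
#'   offsets covered.
#' @param pair `"GC"` or `"AT"`.
#' @param codon_average replace each coding-region value by the mean
#'   over its codon triplet (frame taken from the anchor side).
#' @param smooth_bp width (bp) of a centred moving average applied
#'   last; 0 disables smoothing.
#' @return data frame of class `skew_profile` with columns `offset`,
#'   `skew` (NA where the pair is absent), `n` (genes contributing a
#'   counted base).
#' @export
superposed_profile <- function(genes, anchor = c("start", "stop"),
                               upstream_bp = 200L, downstream_bp = 750L,
                               pair = c("GC", "AT"),
                               codon_average = FALSE, smooth_bp = 0L) {
  genes <- as_oriented_genes(genes)
  anchor <- match.arg(anchor)
  pair <- match.arg(pair)
  if (nrow(genes) == 0L) stop("no genes")
  width <- upstream_bp + downstream_bp
  if (width < 1L) stop("empty span")
  m <- matrix(0L, 4L, width)
  for (i in seq_len(nrow(genes))) {
    if (anchor == "start") {
      up <- genes$upstream[i]
      lu <- nchar(up)
      if (lu > 0L) {
        # upstream flank is right-aligned to the ATG
        m <- .acc_counts(m, seq_codes(up),
                         upstream_bp - lu + seq_len(lu))
      }
      cds <- genes$cds[i]
      m <- .acc_counts(m, seq_codes(cds),
                       upstream_bp + seq_len(nchar(cds)))
    } else {
      cds <- genes$cds[i]
      lc <- nchar(cds)
      # CDS is right-aligned: last base of the stop at column upstream_bp
      m <- .acc_counts(m, seq_codes(cds),
                       upstream_bp - lc + seq_len(lc))
      dn <- genes$downstream[i]
      if (nchar(dn) > 0L) {
        m <- .acc_counts(m, seq_codes(dn),
                         upstream_bp + seq_len(nchar(dn)))
      }
    }
  }
  offsets <- seq_len(width) - upstream_bp - 1L
  val <- skew_from_counts(m, pair)
  n <- if (pair == "GC") m[2L, ] + m[3L, ] else m[1L, ] + m[4L, ]
  if (codon_average) {
    # coding side only, frame anchored at the ATG / end of stop
    cds_cols <- if (anchor == "start") {
      which(offsets >= 0L)
    } else {
      which(offsets < 0L)
    }
    if (length(cds_cols) > 0L) {
      rel <- if (anchor == "start") {
        offsets[cds_cols]                 # 0,1,2 | 3,4,5 | ...
      } else {
        -offsets[cds_cols] - 1L           # 0 = last stop base
      }
      grp <- rel %/% 3L
      means <- tapply(val[cds_cols], grp, mean, na.rm = TRUE)
      val[cds_cols] <- as.numeric(means[as.character(grp)])
      val[is.nan(val)] <- NA_real_
    }
  }
  if (smooth_bp > 0L) {
    w <- as.integer(smooth_bp)
    if (w %% 2L == 0L) w <- w + 1L
    val <- moving_average(val, w)
  }
  out <- data.frame(offset = offsets, skew = val, n = n)
  attr(out, "anchor") <- anchor
  attr(out, "pair") <- pair
  attr(out, "n_genes") <- nrow(genes)
  class(out) <- c("skew_profile", "data.frame")
  out
}

# Centred moving average ignoring NA; keeps NA where the full window
# has no data.
moving_average <- function(x, w) {
  h <- (w - 1L) %/% 2L
  n <- length(x)
  out <- numeric(n)
  xs <- ifelse(is.na(x), 0, x)
  cnt <- as.numeric(!is.na(x))
  cx <- c(0, cumsum(xs))
  cn <- c(0, cumsum(cnt))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  s <- cx[hi + 1L] - cx[lo]
  k <- cn[hi + 1L] - cn[lo]
  ifelse(k == 0, NA_real_, s / k)
}

#' Binned metagene skew profile with flanks
#'
#' Each gene body is divided into `n_bins` bins from the ATG to the
#' stop codon: base i (0-based) of a gene of length L maps to bin
#' `floor(i * n_bins / L)`, so every base lands in exactly one bin
#' regardless of gene length. Counts are pooled over genes per bin and
#' the skew computed on the pooled counts (default), or per-gene bin
#' skews are averaged (`mode = "mean"`, for sensitivity analysis).
#' Flanks are pooled position-wise over the `flank_bp` bases adjacent
#' to the gene.
#'
#' @param genes an [oriented_genes] table.
#' @param n_bins number of gene-body bins (default 40).
#' @param flank_bp flank span (bp) profiled position-wise; 0 disables.
#' @param pair `"GC"` or `"AT"`.
#' @param mode `"pooled"` (skew of summed counts) or `"mean"` (mean of
#'   per-gene bin skews, undefined bins excluded).
#' @return list of class `binned_metagene` with elements `body`
#'   (data frame `bin`, `skew`, `n`), `upstream` and `downstream`
#'   (data frames `offset`, `skew`, `n`), `body_counts` (4 x n_bins
#'   pooled count matrix), `pair`, `mode`, `n_genes`.
#' @export
binned_metagene <- function(genes, n_bins = 40L, flank_bp = 200L,
                            pair = c("GC", "AT"),
                            mode = c("pooled", "mean")) {
  genes <- as_oriented_genes(genes)
  pair <- match.arg(pair)
  mode <- match.arg(mode)
  if (n_bins < 1L) stop("n_bins must be >= 1")
  if (nrow(genes) == 0L) stop("no genes")
  body <- matrix(0L, 4L, n_bins)
  per_gene_sum <- numeric(n_bins)
  per_gene_cnt <- integer(n_bins)
  up_m <- matrix(0L, 4L, max(flank_bp, 1L))
  dn_m <- matrix(0L, 4L, max(flank_bp, 1L))
  for (i in seq_len(nrow(genes))) {
    cds <- genes$cds[i]
    L <- nchar(cds)
    codes <- seq_codes(cds)
    # integer arithmetic avoids floating-point edge effects at bin
    # boundaries: bin(i) = floor(i * n_bins / L), i 0-based
    bins <- ((seq_len(L) - 1L) * as.integer(n_bins)) %/% L + 1L
    ok <- !is.na(codes)
    tab <- matrix(tabulate(codes[ok] + 4L * (bins[ok] - 1L),
                           nbins = 4L * n_bins), 4L, n_bins)
    body <- body + tab
    if (mode == "mean") {
      s <- skew_from_counts(tab, pair)
      def <- !is.na(s)
      per_gene_sum[def] <- per_gene_sum[def] + s[def]
      per_gene_cnt[def] <- per_gene_cnt[def] + 1L
    }
    if (flank_bp > 0L) {
      up <- genes$upstream[i]
      lu <- nchar(up)
      if (lu > 0L) {
        up_m <- .acc_counts(up_m, seq_codes(up),
                            flank_bp - lu + seq_len(lu))
      }
      dn <- genes$downstream[i]
      if (nchar(dn) > 0L) {
        dn_m <- .acc_counts(dn_m, seq_codes(dn), seq_len(nchar(dn)))
      }
    }
  }
  body_skew <- if (mode == "pooled") {
    skew_from_counts(body, pair)
  } else {
    ifelse(per_gene_cnt == 0L, NA_real_, per_gene_sum / per_gene_cnt)
  }
  pair_n <- function(m) {
    if (pair == "GC") m[2L, ] + m[3L, ] else m[1L, ] + m[4L, ]
  }
  out <- list(
    body = data.frame(bin = seq_len(n_bins), skew = body_skew,
                      n = pair_n(body)),
    upstream = if (flank_bp > 0L) {
      data.frame(offset = seq_len(flank_bp) - flank_bp - 1L,
                 skew = skew_from_counts(up_m, pair), n = pair_n(up_m))
    } else NULL,
    downstream = if (flank_bp > 0L) {
      data.frame(offset = seq_len(flank_bp) - 1L,
                 skew = skew_from_counts(dn_m, pair), n = pair_n(dn_m))
    } else NULL,
    body_counts = body,
    pair = pair, mode = mode, n_genes = nrow(genes)
  )
  class(out) <- "binned_metagene"
  out
}

#' @export
print.binned_metagene <- function(x, ...) {
  cat("binned_metagene (", x$pair, " skew, ", x$mode, "): ",
      nrow(x$body), " bins over ", x$n_genes, " genes\n", sep = "")
  cat("  body skew range: ",
      paste(signif(range(x$body$skew, na.rm = TRUE), 3), collapse = " to "),
      "\n", sep = "")
  invisible(x)
}

#' Sliding-window skew track along a sequence
#'
#' @param seq a single nucleotide string (e.g. a chromosome).
#' @param window window size in bp (default 2000).
#' @param step step between window starts; default `window / 10`.
#' @param pair `"GC"` or `"AT"`.
#' @return data frame of class `skew_track` with columns `center`
#'   (1-based window centre), `skew`.
#' @export
sliding_track <- function(seq, window = 2000L, step = max(1L, window %/% 10L),
                          pair = c("GC", "AT")) {
  pair <- match.arg(pair)
  stopifnot(is.character(seq), length(seq) == 1L)
  seq <- toupper(seq)
  L <- nchar(seq)
  if (window <= 0L) stop("window must be positive")
  if (step <= 0L) stop("step must be positive")
  if (window > L) stop("window larger than sequence")
  codes <- seq_codes(seq)
  b1 <- if (pair == "GC") 3L else 1L   # G or A
  b2 <- if (pair == "GC") 2L else 4L   # C or T
  c1 <- c(0L, cumsum(!is.na(codes) & codes == b1))
  c2 <- c(0L, cumsum(!is.na(codes) & codes == b2))
  starts <- seq(1L, L - window + 1L, by = step)
  n1 <- c1[starts + window] - c1[starts]
  n2 <- c2[starts + window] - c2[starts]
  den <- n1 + n2
  out <- data.frame(
    center = starts + (window - 1) / 2,
    skew = ifelse(den == 0L, NA_real_, (n1 - n2) / den)
  )
  attr(out, "window") <- window
  attr(out, "step") <- step
  attr(out, "pair") <- pair
  attr(out, "seq_length") <- L
  class(out) <- c("skew_track", "data.frame")
  out
}

#' Export a skew track as bedGraph
#'
#' Windows are written as fixed-width intervals centred on each window
#' centre; undefined values are skipped.
#'
#' @param track a `skew_track` from [sliding_track()].
#' @param path output path.
#' @param seqname sequence name for column 1.
#' @export
write_bedgraph <- function(track, path, seqname = "seq") {
  stopifnot(inherits(track, "skew_track"))
  w <- attr(track, "window")
  keep <- !is.na(track$skew)
  start0 <- as.integer(track$center[keep] - (w - 1) / 2) - 1L  # 0-based
  df <- data.frame(seqname, start0, start0 + w, track$skew[keep])
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Export a profile or metagene as TSV
#'
#' @param x a `skew_profile`, `skew_track` or `binned_metagene`.
#' @param path output path.
#' @export
write_profile_tsv <- function(x, path) {
  if (inherits(x, "binned_metagene")) {
    parts <- list()
    if (!is.null(x$upstream)) {
      parts$up <- data.frame(section = "upstream",
                             position = x$upstream$offset,
                             skew = x$upstream$skew, n = x$upstream$n)
    }
    parts$body <- data.frame(section = "body", position = x$body$bin,
                             skew = x$body$skew, n = x$body$n)
    if (!is.null(x$downstream)) {
      parts$dn <- data.frame(section = "downstream",
                             position = x$downstream$offset,
                             skew = x$downstream$skew, n = x$downstream$n)
    }
    df <- do.call(rbind, parts)
    rownames(df) <- NULL
  } else {
    df <- as.data.frame(x)
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
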