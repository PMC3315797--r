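# Correlation analyses: local AT-skew / GC-content vs GC-skew across
# genes, cross-species skew scatter, expression vs end-window skews,
# and the methylation association.

#' Per-gene skew and composition summaries
#'
#' @param genes an [oriented_genes] table.
#' @param end_bp width of the 5' and 3' end windows (default 75).
#' @param use_flanks take the end windows from the upstream /
#'   downstream flanks instead of the CDS ends.
#' @return data frame `gene_id`, `length`, `gc_skew`, `at_skew`,
#'   `gc_content`, `gc_skew_5end`, `gc_skew_3end`.
#' @export
gene_summaries <- function(genes, end_bp = 75L, use_flanks = FALSE) {
  genes <- as_oriented_genes(genes)
  n <- nrow(genes)
  cnt <- vapply(genes$cds, function(s) tabulate(seq_codes(s), 4L),
                integer(4L))
  tot <- colSums(cnt)
  gc_skew <- skew_from_counts(cnt, "GC")
  at_skew <- skew_from_counts(cnt, "AT")
  gc_content <- ifelse(tot == 0, NA_real_, (cnt[2L, ] + cnt[3L, ]) / tot)
  end_skew <- function(which_end) {
    vapply(seq_len(n), function(i) {
      s <- if (use_flanks) {
        if (which_end == 5L) genes$upstream[i] else genes$downstream[i]
      } else {
        genes$cds[i]
      }
      L <- nchar(s)
      if (L < end_bp) return(NA_real_)
      win <- if (use_flanks) {
        if (which_end == 5L) substring(s, L - end_bp + 1L, L)
        else substr(s, 1L, end_bp)
      } else {
        if (which_end == 5L) substr(s, 1L, end_bp)
        else substring(s, L - end_bp + 1L, L)
      }
      skew(win, "GC")
    }, numeric(1L))
  }
  data.frame(
    gene_id = genes$gene_id,
    length = nchar(genes$cds),
    gc_skew = gc_skew,
    at_skew = at_skew,
    gc_content = gc_content,
    gc_skew_5end = end_skew(5L),
    gc_skew_3end = end_skew(3L),
    stringsAsFactors = FALSE
  )
}

# Per-gene binned count arrays: genes x 4 x n_bins.
.per_gene_bins <- function(genes, n_bins) {
  n <- nrow(genes)
  arr <- array(0L, dim = c(n, 4L, n_bins))
  for (i in seq_len(n)) {
    cds <- genes$cds[i]
    L <- nchar(cds)
    codes <- seq_codes(cds)
    bins <- ((seq_len(L) - 1L) * as.integer(n_bins)) %/% L + 1L
    ok <- !is.na(codes)
    arr[i, , ] <- matrix(tabulate(codes[ok] + 4L * (bins[ok] - 1L),
                                  nbins = 4L * n_bins), 4L, n_bins)
  }
  arr
}

#' Per-bin correlation of local GC skew with AT skew and GC content
#'
#' For each gene-body bin, computes per-gene GC skew, AT skew and GC
#' content in that bin and the Pearson correlation across genes of GC
#' skew with each of the other two. Undefined per-gene bin values are
#' excluded pairwise; bins with fewer than 3 complete pairs give NA.
#'
#' @param genes an [oriented_genes] table (>= 3 genes).
#' @param n_bins number of gene-body bins (default 40).
#' @return data frame `bin`, `r_at` (GC skew vs AT skew), `n_at`,
#'   `r_gc` (GC skew vs GC content), `n_gc`.
#' @export
local_skew_correlation <- function(genes, n_bins = 40L) {
  genes <- as_oriented_genes(genes)
  if (nrow(genes) < 3L) stop("need at least 3 genes")
  arr <- .per_gene_bins(genes, n_bins)
  res <- lapply(seq_len(n_bins), function(b) {
    m <- t(arr[, , b])              # 4 x genes
    gcs <- skew_from_counts(m, "GC")
    ats <- skew_from_counts(m, "AT")
    tot <- colSums(m)
    gcc <- ifelse(tot == 0, NA_real_, (m[2L, ] + m[3L, ]) / tot)
    pair_r <- function(x, y) {
      ok <- !is.na(x) & !is.na(y)
      if (sum(ok) < 3L) return(c(NA_real_, sum(ok)))
      if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
        return(c(NA_real_, sum(ok)))
      }
      c(stats::cor(x[ok], y[ok]), sum(ok))
    }
    at <- pair_r(gcs, ats)
    gc <- pair_r(gcs, gcc)
    c(at, gc)
  })
  res <- do.call(rbind, res)
  data.frame(bin = seq_len(n_bins), r_at = res[, 1L], n_at = res[, 2L],
             r_gc = res[, 3L], n_gc = res[, 4L])
}

#' Cross-species skew scatter statistics
#'
#' @param species data frame with one row per species and columns
#'   `gc_skew` and `at_skew` (overall coding-strand skews); an
#'   optional first column of species names is carried through.
#' @return list of class `species_scatter`: `r` (Pearson), `slope`,
#'   `intercept` (of `at_skew ~ gc_skew`), `n`, and `table` with
#'   residuals appended.
#' @export
species_scatter <- function(species) {
  stopifnot(is.data.frame(species),
            all(c("gc_skew", "at_skew") %in% names(species)))
  ok <- stats::complete.cases(species[, c("gc_skew", "at_skew")])
  df <- species[ok, , drop = FALSE]
  if (nrow(df) < 3L) stop("need at least 3 species")
  if (stats::sd(df$gc_skew) == 0 || stats::sd(df$at_skew) == 0) {
    stop("constant skew column; correlation undefined")
  }
  r <- stats::cor(df$gc_skew, df$at_skew)
  fit <- stats::lm(at_skew ~ gc_skew, data = df)
  df$residual <- stats::residuals(fit)
  structure(list(
    r = r,
    slope = unname(stats::coef(fit)[2L]),
    intercept = unname(stats::coef(fit)[1L]),
    n = nrow(df),
    table = df
  ), class = "species_scatter")
}

#' @export
print.species_scatter <- function(x, ...) {
  cat("species_scatter: R = ", signif(x$r, 3), " over ", x$n,
      " species (slope ", signif(x$slope, 3), ")\n", sep = "")
  invisible(x)
}

#' Correlation of expression with end-window GC skews
#'
#' Pearson correlation between per-gene expression and the GC skew of
#' the first and last `end_bp` bases of the CDS, with p-values from
#' permutation of the gene labels. Expression is rank-transformed by
#' default (RNA-seq levels are heavy-tailed); set
#' `rank_transform = FALSE` for raw Pearson.
#'
#' @param genes an [oriented_genes] table.
#' @param expression data frame `gene_id`, `level` or named numeric
#'   vector.
#' @param end_bp end-window width (default 75).
#' @param n_perm label permutations for the p-values (default 1000).
#' @param rank_transform rank-transform expression first.
#' @param seed optional RNG seed for the permutations.
#' @return list of class `expression_correlation`: `r5`, `p5`, `r3`,
#'   `p3`, `n`, `table` (matched per-gene values).
#' @export
expression_correlation <- function(genes, expression, end_bp = 75L,
                                   n_perm = 1000L, rank_transform = TRUE,
                                   seed = NULL) {
  genes <- as_oriented_genes(genes)
  expr <- as_gene_table(expression)
  gs <- gene_summaries(genes, end_bp = end_bp)
  m <- merge(gs, expr, by = "gene_id")
  m <- m[stats::complete.cases(m[, c("gc_skew_5end", "gc_skew_3end",
                                     "level")]), , drop = FALSE]
  if (nrow(m) == 0L) stop("no genes shared between sequence and expression")
  if (nrow(m) < 10L) stop("fewer than 10 matched genes")
  x <- if (rank_transform) rank(m$level) else m$level
  if (!is.null(seed)) set.seed(seed)
  perm_cor <- function(y) {
    r_obs <- stats::cor(x, y)
    r_null <- vapply(seq_len(n_perm),
                     function(i) stats::cor(sample(x), y), numeric(1L))
    p <- (1 + sum(abs(r_null) >= abs(r_obs))) / (1 + n_perm)
    c(r_obs, p)
  }
  r5 <- perm_cor(m$gc_skew_5end)
  r3 <- perm_cor(m$gc_skew_3end)
  structure(list(
    r5 = r5[1L], p5 = r5[2L], r3 = r3[1L], p3 = r3[2L],
    n = nrow(m), rank_transform = rank_transform,
    table = m
  ), class = "expression_correlation")
}

#' @export
print.expression_correlation <- function(x, ...) {
  cat("expression_correlation (n = ", x$n, "):\n",
      "  5' end: R = ", signif(x$r5, 3), " (p = ", signif(x$p5, 3), ")\n",
      "  3' end: R = ", signif(x$r3, 3), " (p = ", signif(x$p3, 3), ")\n",
      sep = "")
  invisible(x)
}

#' Association of DNA methylation with end-window GC skews
#'
#' One-sided Welch two-sample t-test of whether the methylated genes
#' have greater mean end-window GC skew than the remaining genes, plus
#' the Pearson correlation of methylation level with the end skews
#' within the methylated set.
#'
#' @param genes an [oriented_genes] table.
#' @param methylation data frame `gene_id`, `level` or named numeric
#'   vector for the methylated genes (must be a strict subset of
#'   `genes`).
#' @param end_bp end-window width (default 75).
#' @return list of class `methylation_association` with per-window
#'   `t`, `p` (one-sided, methylated greater), `r_level`, and counts.
#' @export
methylation_association <- function(genes, methylation, end_bp = 75L) {
  genes <- as_oriented_genes(genes)
  meth <- as_gene_table(methylation)
  gs <- gene_summaries(genes, end_bp = end_bp)
  in_meth <- gs$gene_id %in% meth$gene_id
  n_overlap <- sum(in_meth)
  if (n_overlap < 3L) stop("fewer than 3 methylated genes matched")
  if (n_overlap == nrow(gs)) {
    stop("methylated set must be a strict subset of the gene set")
  }
  lev <- meth$level[match(gs$gene_id[in_meth], meth$gene_id)]
  one <- function(col) {
    xm <- gs[[col]][in_meth]
    xr <- gs[[col]][!in_meth]
    tt <- stats::t.test(xm, xr, alternative = "greater")
    okl <- !is.na(xm) & !is.na(lev)
    r <- if (sum(okl) >= 3L && stats::sd(xm[okl]) > 0 &&
             stats::sd(lev[okl]) > 0) {
      stats::cor(xm[okl], lev[okl])
    } else NA_real_
    list(t = unname(tt$statistic), p = tt$p.value, r_level = r)
  }
  structure(list(
    end5 = one("gc_skew_5end"),
    end3 = one("gc_skew_3end"),
    n_methylated = n_overlap,
    n_background = nrow(gs) - n_overlap
  ), class = "methylation_association")
}

#' @export
print.methylation_association <- function(x, ...) {
  cat("methylation_association (", x$n_methylated, " methylated vs ",
      x$n_background, " background genes):\n",
      "  5' end: t = ", signif(x$end5$t, 3), ", p = ",
      signif(x$end5$p, 3), ", r(level) = ", signif(x$end5$r_level, 3),
      "\n  3' end: t = ", signif(x$end3$t, 3), ", p = ",
      signif(x$end3$p, 3), ", r(level) = ", signif(x$end3$r_level, 3),
      "\n", sep = "")
  invisible(x)
}
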