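# Terminal nucleotide / amino-acid usage bias, codon-position skews
# and fourfold-degenerate-site skews.

#' Codon table
#'
#' Returns the codon-to-residue map as a named character vector of all
#' 64 codons. `"standard"` is the standard nuclear code;
#' `"cug_clade"` is the alternative yeast nuclear code in which CTG
#' encodes serine (relevant for Candida albicans and relatives).
#'
#' @param id `"standard"` or `"cug_clade"`.
#' @return named character vector, codon (DNA alphabet) -> one-letter
#'   residue, `"*"` for stops.
#' @export
codon_table <- function(id = c("standard", "cug_clade")) {
  id <- match.arg(id)
  code <- switch(id,
    standard = Biostrings::getGeneticCode("1"),
    cug_clade = Biostrings::getGeneticCode("12")
  )
  stopifnot(length(code) == 64L)
  code
}

# Window accounting shared by the terminal-bias functions: genes must
# accommodate disjoint 5' and 3' codon windows plus the stop codon.
.terminal_eligible <- function(genes, n5_codons, n3_codons) {
  nchar(genes$cds) >= (n5_codons + n3_codons + 1L) * 3L
}

# First n5 codons and the n3 codons immediately preceding the stop.
.terminal_windows <- function(cds, n5_codons, n3_codons) {
  L <- nchar(cds)
  list(
    w5 = substr(cds, 1L, 3L * n5_codons),
    w3 = substring(cds, L - 3L - 3L * n3_codons + 1L, L - 3L)
  )
}

#' 5'/3' frequency ratio of each nucleotide at gene ends
#'
#' Pools the nucleotides of the first `n5_codons` codons and of the
#' `n3_codons` codons preceding the stop across genes, and reports the
#' frequency of each base in the 5' pool divided by its frequency in
#' the 3' pool. Genes too short for disjoint windows are excluded.
#'
#' @param genes an [oriented_genes] table.
#' @param n5_codons,n3_codons window sizes in codons (defaults 21 and
#'   20).
#' @return data frame `base`, `freq5`, `freq3`, `ratio` (NA when the
#'   3' frequency is 0), with attribute `n_genes` (genes included).
#' @export
terminal_nucleotide_ratios <- function(genes, n5_codons = 21L,
                                       n3_codons = 20L) {
  genes <- as_oriented_genes(genes)
  keep <- .terminal_eligible(genes, n5_codons, n3_codons)
  if (!any(keep)) stop("no genes long enough for the requested windows")
  cds <- genes$cds[keep]
  w <- .terminal_windows(cds, n5_codons, n3_codons)
  c5 <- rowSums(vapply(w$w5, function(s) {
    tabulate(seq_codes(s), 4L)
  }, integer(4L)))
  c3 <- rowSums(vapply(w$w3, function(s) {
    tabulate(seq_codes(s), 4L)
  }, integer(4L)))
  f5 <- c5 / sum(c5)
  f3 <- c3 / sum(c3)
  out <- data.frame(base = c("A", "C", "G", "T"), freq5 = f5, freq3 = f3,
                    ratio = ifelse(f3 == 0, NA_real_, f5 / f3))
  attr(out, "n_genes") <- sum(keep)
  attr(out, "n_excluded") <- sum(!keep)
  out
}

#' Per-residue GC skew of the encoding codons
#'
#' Mean over synonymous codons of the skew of each codon's own G/C
#' counts; codons containing neither G nor C are skipped. With
#' `weights = "usage"` the mean is weighted by observed codon counts.
#'
#' @param residue one-letter residue code.
#' @param table a codon table from [codon_table()].
#' @param weights `"uniform"` or `"usage"`.
#' @param usage named codon count vector (required for usage weights).
#' @return mean skew in \[-1, 1\], NA if no synonymous codon contains
#'   G or C.
#' @export
codon_gc_skew <- function(residue, table = codon_table(),
                          weights = c("uniform", "usage"), usage = NULL) {
  weights <- match.arg(weights)
  codons <- names(table)[table == residue]
  if (length(codons) == 0L) stop("unknown residue: ", residue)
  s <- vapply(codons, function(cd) skew(cd, "GC"), numeric(1L))
  ok <- !is.na(s)
  if (!any(ok)) return(NA_real_)
  if (weights == "uniform") {
    mean(s[ok])
  } else {
    if (is.null(usage)) stop("usage weights require a codon count vector")
    w <- usage[codons]
    w[is.na(w)] <- 0
    if (sum(w[ok]) == 0) return(mean(s[ok]))
    sum(s[ok] * w[ok]) / sum(w[ok])
  }
}

#' Terminal amino-acid usage bias
#'
#' Translates the first `n5_codons` codons and the `n3_codons` codons
#' preceding the stop of every eligible gene and compares residue
#' usage between the pooled 5' and 3' windows. Per residue, a 2x2
#' chi-square test (this residue vs all others, 5' vs 3' window,
#' without continuity correction) gives `chi2_p`; `ratio5to3` is the
#' 5' frequency over the 3' frequency and `codon_skew` the mean GC
#' skew of the encoding codons. Rows are ordered by decreasing ratio.
#'
#' @param genes an [oriented_genes] table of strict ORFs.
#' @param n5_codons,n3_codons window sizes in codons.
#' @param drop_initial_met exclude the initiator ATG (codon 1 of every
#'   gene) from the 5' methionine count, since it is fixed by the
#'   genetic code rather than chosen.
#' @param table a codon table from [codon_table()].
#' @return data frame of class `aa_bias`: `residue`, `count5`,
#'   `count3`, `ratio5to3`, `codon_skew`, `chi2_p`; attribute
#'   `n_genes`.
#' @export
terminal_aa_bias <- function(genes, n5_codons = 21L, n3_codons = 20L,
                             drop_initial_met = FALSE,
                             table = codon_table()) {
  genes <- as_oriented_genes(genes)
  keep <- .terminal_eligible(genes, n5_codons, n3_codons)
  if (!any(keep)) stop("no genes long enough for the requested windows")
  cds <- genes$cds[keep]
  w <- .terminal_windows(cds, n5_codons, n3_codons)
  aa5 <- unlist(lapply(w$w5, function(s) unname(table[codon_split(s)])),
                use.names = FALSE)
  aa3 <- unlist(lapply(w$w3, function(s) unname(table[codon_split(s)])),
                use.names = FALSE)
  if (drop_initial_met) {
    # codon 1 is always the first element of each gene's window
    first <- seq(1L, by = n5_codons, length.out = length(cds))
    aa5 <- aa5[-first]
  }
  aa5 <- aa5[!is.na(aa5) & aa5 != "*"]
  aa3 <- aa3[!is.na(aa3) & aa3 != "*"]
  residues <- sort(setdiff(unique(unname(table)), "*"))
  t5 <- length(aa5)
  t3 <- length(aa3)
  rows <- lapply(residues, function(r) {
    k5 <- sum(aa5 == r)
    k3 <- sum(aa3 == r)
    if (k5 + k3 == 0L) {
      return(data.frame(residue = r, count5 = 0L, count3 = 0L,
                        ratio5to3 = NA_real_,
                        codon_skew = codon_gc_skew(r, table),
                        chi2_p = NA_real_))
    }
    tab <- matrix(c(k5, t5 - k5, k3, t3 - k3), nrow = 2L)
    expd <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    if (min(expd) < 5) {
      warning("expected count < 5 for residue ", r,
              "; chi-square approximation may be poor")
    }
    pv <- suppressWarnings(
      stats::chisq.test(tab, correct = FALSE)$p.value
    )
    data.frame(residue = r, count5 = k5, count3 = k3,
               ratio5to3 = if (k3 > 0L) (k5 / t5) / (k3 / t3) else NA_real_,
               codon_skew = codon_gc_skew(r, table),
               chi2_p = pv)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$ratio5to3, out$residue, na.last = TRUE), ]
  rownames(out) <- NULL
  attr(out, "n_genes") <- sum(keep)
  attr(out, "n5_total") <- t5
  attr(out, "n3_total") <- t3
  class(out) <- c("aa_bias", "data.frame")
  out
}

#' Binned skew restricted to one codon position
#'
#' As [binned_metagene()] on the gene bodies, but counting only bases
#' at the given position (1, 2 or 3) within each in-frame codon. The
#' bin of a base is still determined by its position in the whole
#' gene, so the per-position pooled counts over the three positions
#' sum to the whole-gene pooled counts.
#'
#' @param genes an [oriented_genes] table of strict ORFs.
#' @param position codon position, 1, 2 or 3.
#' @param n_bins number of gene-body bins.
#' @param pair `"GC"` or `"AT"`.
#' @return data frame `bin`, `skew`, `n` with attribute `counts`
#'   (4 x n_bins pooled matrix).
#' @export
codon_position_skew <- function(genes, position, n_bins = 40L,
                                pair = c("GC", "AT")) {
  genes <- as_oriented_genes(genes)
  pair <- match.arg(pair)
  stopifnot(position %in% 1:3, n_bins >= 1L)
  m <- matrix(0L, 4L, n_bins)
  for (i in seq_len(nrow(genes))) {
    cds <- genes$cds[i]
    L <- nchar(cds)
    pos <- seq(position, L, by = 3L)
    codes <- seq_codes(cds)[pos]
    bins <- ((pos - 1L) * as.integer(n_bins)) %/% L + 1L
    ok <- !is.na(codes)
    m <- m + matrix(tabulate(codes[ok] + 4L * (bins[ok] - 1L),
                             nbins = 4L * n_bins), 4L, n_bins)
  }
  n <- if (pair == "GC") m[2L, ] + m[3L, ] else m[1L, ] + m[4L, ]
  out <- data.frame(bin = seq_len(n_bins),
                    skew = skew_from_counts(m, pair), n = n)
  attr(out, "counts") <- m
  attr(out, "position") <- position
  out
}

#' Fourfold-degenerate codon families of a codon table
#'
#' @param table a codon table from [codon_table()].
#' @return character vector of two-base codon prefixes whose four
#'   completions all encode the same residue.
#' @export
fourfold_families <- function(table = codon_table()) {
  bases <- c("A", "C", "G", "T")
  prefixes <- as.vector(outer(bases, bases, paste0))
  keep <- vapply(prefixes, function(p) {
    aa <- table[paste0(p, bases)]
    length(unique(aa)) == 1L && !"*" %in% aa
  }, logical(1L))
  prefixes[keep]
}

# 1-based positions of fourfold-degenerate third bases in one CDS.
fourfold_sites <- function(cds, table = codon_table()) {
  fams <- fourfold_families(table)
  cod <- codon_split(cds)
  idx <- which(substr(cod, 1L, 2L) %in% fams)
  3L * idx
}

#' Skew at fourfold-degenerate third codon positions
#'
#' Restricts counting to the third bases of codons whose first two
#' bases already determine the residue, binned along the gene body as
#' in [binned_metagene()]. With an expression table, the profile is
#' additionally computed for the genes in the lowest and highest
#' expression quantile.
#'
#' @param genes an [oriented_genes] table of strict ORFs.
#' @param expression optional data frame `gene_id`, `level` (or named
#'   numeric vector) of expression values.
#' @param quantile fraction of genes in each extreme expression group
#'   (default 0.10).
#' @param n_bins number of gene-body bins.
#' @param table a codon table from [codon_table()].
#' @param pair `"GC"` or `"AT"`.
#' @return list of class `fourfold_skew`: `overall` (data frame `bin`,
#'   `skew`, `n`), and when expression is given `low` and `high`
#'   (same shape) plus `low_ids`, `high_ids`.
#' @export
fourfold_degenerate_skew <- function(genes, expression = NULL,
                                     quantile = 0.10, n_bins = 40L,
                                     table = codon_table(),
                                     pair = c("GC", "AT")) {
  genes <- as_oriented_genes(genes)
  pair <- match.arg(pair)
  fams <- fourfold_families(table)
  profile_of <- function(sub) {
    m <- matrix(0L, 4L, n_bins)
    for (i in seq_len(nrow(sub))) {
      cds <- sub$cds[i]
      L <- nchar(cds)
      cod <- codon_split(cds)
      pos <- 3L * which(substr(cod, 1L, 2L) %in% fams)
      if (length(pos) == 0L) next
      codes <- seq_codes(cds)[pos]
      bins <- ((pos - 1L) * as.integer(n_bins)) %/% L + 1L
      ok <- !is.na(codes)
      m <- m + matrix(tabulate(codes[ok] + 4L * (bins[ok] - 1L),
                               nbins = 4L * n_bins), 4L, n_bins)
    }
    n <- if (pair == "GC") m[2L, ] + m[3L, ] else m[1L, ] + m[4L, ]
    data.frame(bin = seq_len(n_bins), skew = skew_from_counts(m, pair),
               n = n)
  }
  out <- list(overall = profile_of(genes))
  if (!is.null(expression)) {
    expr <- as_gene_table(expression)
    matched <- expr[expr$gene_id %in% genes$gene_id, , drop = FALSE]
    k <- max(1L, floor(nrow(matched) * quantile))
    if (k < 10L) {
      warning("fewer than 10 genes in an expression quantile group")
    }
    ord <- order(matched$level)
    low_ids <- matched$gene_id[ord[seq_len(k)]]
    high_ids <- matched$gene_id[ord[(nrow(matched) - k + 1L):nrow(matched)]]
    out$low <- profile_of(genes[genes$gene_id %in% low_ids, , drop = FALSE])
    out$high <- profile_of(genes[genes$gene_id %in% high_ids, , drop = FALSE])
    out$low_ids <- low_ids
    out$high_ids <- high_ids
  }
  class(out) <- "fourfold_skew"
  out
}

# Normalise a gene-keyed covariate (data frame or named vector) to a
# two-column data frame gene_id / level.
as_gene_table <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(ncol(x) >= 2L)
    df <- data.frame(gene_id = as.character(x[[1L]]),
                     level = as.numeric(x[[2L]]),
                     stringsAsFactors = FALSE)
  } else if (is.numeric(x) && !is.null(names(x))) {
    df <- data.frame(gene_id = names(x), level = as.numeric(x),
                     stringsAsFactors = FALSE)
  } else {
    stop("expected a two-column data frame or a named numeric vector")
  }
  if (anyDuplicated(df$gene_id)) stop("duplicate gene ids in table")
  df
}

#' Read a two-column gene/value TSV (expression or methylation)
#'
#' @param path TSV path; column 1 gene id, column 2 numeric level. A
#'   header line is detected automatically.
#' @return data frame `gene_id`, `level`.
#' @export
read_gene_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  first <- readLines(path, n = 1L)
  has_header <- is.na(suppressWarnings(
    as.numeric(strsplit(first, "\t", fixed = TRUE)[[1L]][2L])
  ))
  df <- utils::read.delim(path, header = has_header,
                          stringsAsFactors = FALSE)
  as_gene_table(df)
}
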