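# Gene-table container: coding-strand sequences plus flanks.

#' Construct a table of coding-strand oriented genes
#'
#' An `oriented_genes` table holds, per gene, the coding-strand CDS
#' sequence together with its upstream flank (5' of the ATG) and
#' downstream flank (3' of the stop codon), both already in
#' coding-strand orientation. All downstream analyses take this table
#' as input, so strand resolution happens exactly once, at extraction.
#'
#' @param gene_id character vector of unique gene identifiers.
#' @param cds coding-strand CDS sequences.
#' @param upstream,downstream flank sequences (may be "" when absent).
#' @param trunc5,trunc3 logical: flank truncated at a contig edge.
#' @return a data frame of class `oriented_genes`.
#' @export
oriented_genes <- function(gene_id, cds, upstream = "", downstream = "",
                           trunc5 = FALSE, trunc3 = FALSE) {
  gene_id <- as.character(gene_id)
  n <- length(gene_id)
  if (n == 0L) {
    df <- data.frame(gene_id = character(), cds = character(),
                     upstream = character(), downstream = character(),
                     trunc5 = logical(), trunc3 = logical(),
                     stringsAsFactors = FALSE)
    class(df) <- c("oriented_genes", "data.frame")
    return(df)
  }
  if (anyDuplicated(gene_id)) stop("gene ids must be unique")
  cds <- toupper(rep_len(as.character(cds), n))
  bad <- grepl("[^ACGTNRYSWKMBDHV]", cds)
  if (any(bad)) {
    stop("non-IUPAC characters in cds of: ",
         paste(gene_id[bad][seq_len(min(3, sum(bad)))], collapse = ", "))
  }
  df <- data.frame(
    gene_id = gene_id,
    cds = cds,
    upstream = toupper(rep_len(as.character(upstream), n)),
    downstream = toupper(rep_len(as.character(downstream), n)),
    trunc5 = rep_len(trunc5, n),
    trunc3 = rep_len(trunc3, n),
    stringsAsFactors = FALSE
  )
  class(df) <- c("oriented_genes", "data.frame")
  df
}

#' @export
print.oriented_genes <- function(x, ...) {
  cat("oriented_genes: ", nrow(x), " genes\n", sep = "")
  if (nrow(x) > 0L) {
    L <- nchar(x$cds)
    cat("  cds length: ", min(L), "-", max(L),
        " (median ", stats::median(L), ")\n", sep = "")
    cat("  flanks: up ", max(nchar(x$upstream)), " bp, down ",
        max(nchar(x$downstream)), " bp\n", sep = "")
  }
  invisible(x)
}

#' Test whether CDS sequences are strict open reading frames
#'
#' A strict ORF starts with ATG, ends with one of the stop codons
#' TAA/TAG/TGA, and has length at least 6 and divisible by 3.
#' Internal stop codons are optionally checked.
#'
#' @param cds character vector of CDS sequences.
#' @param check_internal_stops also require no in-frame internal stop.
#' @return logical vector.
#' @export
is_strict_orf <- function(cds, check_internal_stops = FALSE) {
  L <- nchar(cds)
  ok <- L >= 6L & L %% 3L == 0L &
    substr(cds, 1L, 3L) == "ATG" &
    substring(cds, L - 2L, L) %in% c("TAA", "TAG", "TGA")
  if (check_internal_stops && any(ok)) {
    for (i in which(ok)) {
      cod <- codon_split(cds[i])
      if (any(cod[-length(cod)] %in% c("TAA", "TAG", "TGA"))) ok[i] <- FALSE
    }
  }
  ok
}

# Split one CDS into its in-frame codons.
codon_split <- function(x) {
  L <- nchar(x)
  substring(x, seq(1L, L - 2L, by = 3L), seq(3L, L, by = 3L))
}

# Validate an oriented_genes argument.
as_oriented_genes <- function(genes) {
  if (inherits(genes, "oriented_genes")) return(genes)
  if (is.character(genes)) {
    ids <- names(genes)
    if (is.null(ids)) ids <- sprintf("gene%04d", seq_along(genes))
    return(oriented_genes(ids, genes))
  }
  if (is.data.frame(genes) && all(c("gene_id", "cds") %in% names(genes))) {
    up <- if ("upstream" %in% names(genes)) genes$upstream else ""
    dn <- if ("downstream" %in% names(genes)) genes$downstream else ""
    return(oriented_genes(genes$gene_id, genes$cds, up, dn))
  }
  stop("expected an 'oriented_genes' table (see ?oriented_genes)")
}
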