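# FASTA / GFF input and coding-strand gene extraction.

#' Read a (multi-record) FASTA file
#'
#' Sequences are upper-cased and line folds collapsed. Record ids are
#' the first whitespace-delimited token of each header and must be
#' unique.
#'
#' @param path path to a FASTA file.
#' @return named character vector of sequences (a sequence set).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ss <- Biostrings::readDNAStringSet(path)
  if (length(ss) == 0L) stop("empty or headerless FASTA: ", path)
  ids <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(ids)) {
    stop("duplicate sequence id in ", path, ": ",
         ids[duplicated(ids)][1L])
  }
  if (any(ids == "")) stop("empty sequence id in ", path)
  seqs <- toupper(as.character(ss))
  if (any(nchar(seqs) == 0L)) {
    stop("zero-length sequence in ", path, ": ",
         ids[nchar(seqs) == 0L][1L])
  }
  names(seqs) <- ids
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @param width line width for wrapping.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  ss <- Biostrings::DNAStringSet(seqs)
  names(ss) <- names(seqs)
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}

#' Read gene annotations from GFF3 or GTF
#'
#' Rows of the requested feature type are grouped into genes by, in
#' order of preference, the `Parent` attribute (GFF3), the `gene_id`
#' attribute (GTF), or the `ID` attribute. The format is detected from
#' the file extension by the importer. Coordinates stay 1-based
#' inclusive as in GFF; conversion to string offsets happens inside
#' [extract_genes()].
#'
#' @param path path to a GFF3 or GTF file.
#' @param feature_type feature rows to keep (default `"CDS"`).
#' @return data frame with columns `gene_id`, `seqid`, `start`, `end`,
#'   `strand`, one row per feature interval, intervals sorted by start
#'   within gene.
#' @export
read_annotations <- function(path, feature_type = "CDS") {
  if (!file.exists(path)) stop("no such file: ", path)
  gr <- rtracklayer::import(path)
  gr <- gr[!is.na(gr$type) & as.character(gr$type) == feature_type]
  if (length(gr) == 0L) {
    stop("no '", feature_type, "' features in ", path)
  }
  md <- S4Vectors::mcols(gr)
  pick <- function(field) {
    if (!field %in% names(md)) return(NULL)
    v <- md[[field]]
    if (methods::is(v, "List") || is.list(v)) {
      v <- vapply(v, function(el) {
        if (length(el) == 0L) NA_character_ else as.character(el[[1L]])
      }, character(1L))
    }
    v <- as.character(v)
    if (all(is.na(v))) NULL else v
  }
  gene_id <- pick("Parent")
  if (is.null(gene_id)) gene_id <- pick("gene_id")
  if (is.null(gene_id)) gene_id <- pick("ID")
  if (is.null(gene_id)) {
    stop("cannot group features: no Parent/gene_id/ID attribute in ", path)
  }
  ann <- data.frame(
    gene_id = gene_id,
    seqid = as.character(GenomeInfoDb::seqnames(gr)),
    start = BiocGenerics::start(gr),
    end = BiocGenerics::end(gr),
    strand = as.character(BiocGenerics::strand(gr)),
    stringsAsFactors = FALSE
  )
  drop <- is.na(ann$gene_id) | !ann$strand %in% c("+", "-")
  if (any(drop)) {
    warning(sum(drop), " feature(s) without gene id or stranded ",
            "orientation dropped")
    ann <- ann[!drop, , drop = FALSE]
  }
  if (nrow(ann) == 0L) stop("no usable '", feature_type, "' rows in ", path)
  ann <- ann[order(ann$gene_id, ann$start), , drop = FALSE]
  rownames(ann) <- NULL
  ann
}

#' Extract coding-strand gene sequences with flanks
#'
#' Multi-part CDS intervals are concatenated in transcription order;
#' minus-strand genes are reverse-complemented, so `cds`, `upstream`
#' and `downstream` all read 5' to 3' on the coding strand. Flanks
#' shorter than `flank` (gene at a contig edge) are truncated and
#' flagged. With `strict_orf`, genes that do not start with ATG, do
#' not end with a stop codon, or whose length is not a positive
#' multiple of 3 are excluded; the exclusion count is attached as the
#' `"excluded"` attribute.
#'
#' @param seqs named character vector of chromosome/contig sequences
#'   (as from [read_fasta()]).
#' @param ann annotation data frame (as from [read_annotations()]).
#' @param flank flank length in bp (>= 0).
#' @param strict_orf exclude genes failing ATG/stop/frame checks.
#' @return an [oriented_genes] table, with attributes `excluded`
#'   (genes failing strict-ORF checks) and `dropped` (genes on unknown
#'   chromosomes or with out-of-bounds intervals).
#' @export
extract_genes <- function(seqs, ann, flank = 0L, strict_orf = TRUE) {
  stopifnot(flank >= 0L)
  parts <- split(ann, ann$gene_id)
  ids <- names(parts)
  cds <- upstream <- downstream <- character(length(ids))
  trunc5 <- trunc3 <- logical(length(ids))
  keep <- rep(TRUE, length(ids))
  dropped <- 0L
  for (i in seq_along(parts)) {
    p <- parts[[i]]
    chrom <- p$seqid[1L]
    if (!chrom %in% names(seqs)) {
      warning("gene ", ids[i], ": unknown sequence '", chrom, "', dropped")
      keep[i] <- FALSE; dropped <- dropped + 1L
      next
    }
    chr_seq <- seqs[[chrom]]
    chr_len <- nchar(chr_seq)
    if (any(p$start < 1L) || any(p$end > chr_len) || any(p$start > p$end)) {
      warning("gene ", ids[i], ": interval outside sequence bounds, dropped")
      keep[i] <- FALSE; dropped <- dropped + 1L
      next
    }
    p <- p[order(p$start), , drop = FALSE]
    body <- paste(substring(chr_seq, p$start, p$end), collapse = "")
    strand <- p$strand[1L]
    gstart <- min(p$start); gend <- max(p$end)
    if (strand == "+") {
      u_from <- max(1L, gstart - flank)
      up <- if (flank > 0L && gstart > 1L)
        substring(chr_seq, u_from, gstart - 1L) else ""
      d_to <- min(chr_len, gend + flank)
      dn <- if (flank > 0L && gend < chr_len)
        substring(chr_seq, gend + 1L, d_to) else ""
      cds[i] <- body
      upstream[i] <- up
      downstream[i] <- dn
    } else {
      # coding strand is the minus strand: reverse-complement; the
      # genomic right side becomes the 5' (upstream) flank
      d_to <- min(chr_len, gend + flank)
      up_g <- if (flank > 0L && gend < chr_len)
        substring(chr_seq, gend + 1L, d_to) else ""
      u_from <- max(1L, gstart - flank)
      dn_g <- if (flank > 0L && gstart > 1L)
        substring(chr_seq, u_from, gstart - 1L) else ""
      cds[i] <- revcomp(body)
      upstream[i] <- if (nzchar(up_g)) revcomp(up_g) else ""
      downstream[i] <- if (nzchar(dn_g)) revcomp(dn_g) else ""
    }
    trunc5[i] <- flank > 0L && nchar(upstream[i]) < flank
    trunc3[i] <- flank > 0L && nchar(downstream[i]) < flank
  }
  res <- oriented_genes(ids[keep], cds[keep], upstream[keep],
                        downstream[keep], trunc5[keep], trunc3[keep])
  excluded <- 0L
  if (strict_orf && nrow(res) > 0L) {
    ok <- is_strict_orf(res$cds)
    excluded <- sum(!ok)
    res <- res[ok, , drop = FALSE]
    class(res) <- c("oriented_genes", "data.frame")
  }
  attr(res, "excluded") <- excluded
  attr(res, "dropped") <- dropped
  res
}

#' Read pre-extracted ORFs from a multi-FASTA file
#'
#' Convenience route for gene lists distributed as ORF FASTA files:
#' each record is taken as one coding-strand CDS with no flanks.
#' Strict-ORF filtering is off by default for this input route.
#'
#' @param path ORF multi-FASTA path.
#' @param strict_orf exclude records failing ATG/stop/frame checks.
#' @return an [oriented_genes] table.
#' @export
read_orf_fasta <- function(path, strict_orf = FALSE) {
  seqs <- read_fasta(path)
  res <- oriented_genes(names(seqs), unname(seqs))
  excluded <- 0L
  if (strict_orf) {
    ok <- is_strict_orf(res$cds)
    excluded <- sum(!ok)
    res <- res[ok, , drop = FALSE]
    class(res) <- c("oriented_genes", "data.frame")
  }
  attr(res, "excluded") <- excluded
  res
}
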