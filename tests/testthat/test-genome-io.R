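# FASTA/GFF input and coding-strand extraction.

write_tmp <- function(lines, ext) {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

test_that("read_fasta normalises case and line folds, enforces unique ids", {
  f <- write_tmp(c(">g1", "atg", "AAA", "taa"), ".fa")
  expect_equal(read_fasta(f), c(g1 = "ATGAAATAA"))
  f2 <- write_tmp(c(">g1 description here", "ATGAAATAA"), ".fa")
  expect_equal(names(read_fasta(f2)), "g1")
  f3 <- write_tmp(c(">g1", "ACGT", ">g1", "ACGT"), ".fa")
  expect_error(read_fasta(f3), "duplicate")
  f4 <- write_tmp(character(0), ".fa")
  expect_error(read_fasta(f4))
  expect_error(read_fasta(tempfile()), "no such file")
})

test_that("FASTA round trip reproduces sequences exactly", {
  set.seed(2)
  seqs <- stats::setNames(
    vapply(1:10, function(i) paste(sample(c(BASES, "N"), 137,
                                          replace = TRUE), collapse = ""),
           character(1)),
    sprintf("s%02d", 1:10))
  f <- tempfile(fileext = ".fa")
  write_fasta(seqs, f, width = 60)
  expect_equal(read_fasta(f), seqs)
})

test_that("read_annotations groups GFF3 CDS rows by Parent", {
  f <- write_tmp(c(
    "##gff-version 3",
    "chr1\tsrc\tgene\t1\t9\t.\t+\t.\tID=gA",
    "chr1\tsrc\tCDS\t1\t9\t.\t+\t0\tID=cA;Parent=gA",
    "chr1\tsrc\tCDS\t30\t35\t.\t-\t0\tID=cB2;Parent=gB",
    "chr1\tsrc\tCDS\t20\t25\t.\t-\t0\tID=cB1;Parent=gB"
  ), ".gff3")
  ann <- read_annotations(f)
  expect_equal(sort(unique(ann$gene_id)), c("gA", "gB"))
  b <- ann[ann$gene_id == "gB", ]
  expect_equal(b$start, c(20, 30))      # sorted ascending
  expect_equal(unique(b$strand), "-")
  a <- ann[ann$gene_id == "gA", ]
  expect_equal(c(a$start, a$end, a$strand), c("1", "9", "+"))
  expect_error(read_annotations(f, feature_type = "exon"), "exon")
})

test_that("read_annotations accepts GTF with gene_id attributes", {
  f <- write_tmp(c(
    paste0("chr1\tsrc\tCDS\t4\t12\t.\t+\t0\t",
           "gene_id \"gX\"; transcript_id \"tX\";")
  ), ".gtf")
  ann <- read_annotations(f)
  expect_equal(ann$gene_id, "gX")
  expect_equal(ann$start, 4)
})

test_that("extraction follows substring arithmetic on both strands", {
  seqs <- c(chr1 = "CCATGAAATAACC")
  ann <- data.frame(gene_id = "g1", seqid = "chr1", start = 3, end = 11,
                    strand = "+", stringsAsFactors = FALSE)
  g <- extract_genes(seqs, ann, flank = 2)
  expect_equal(g$cds, "ATGAAATAA")
  expect_equal(g$upstream, "CC")
  expect_equal(g$downstream, "CC")
  # reverse-complement genome, same gene on the minus strand
  seqs2 <- c(chr1 = "GGTTATTTCATGG")
  ann2 <- data.frame(gene_id = "g1", seqid = "chr1", start = 3, end = 11,
                     strand = "-", stringsAsFactors = FALSE)
  g2 <- extract_genes(seqs2, ann2, flank = 2)
  expect_equal(g2$cds, g$cds)
  expect_equal(g2$upstream, g$upstream)
  expect_equal(g2$downstream, g$downstream)
})

test_that("multi-part CDS concatenates in transcription order", {
  #                 123456789012345678
  seqs <- c(chr1 = "AAATGGCTTTTGGTAAAA")
  ann <- data.frame(gene_id = "gs", seqid = "chr1",
                    start = c(3, 10), end = c(8, 15),
                    strand = "+", stringsAsFactors = FALSE)
  g <- extract_genes(seqs, ann, flank = 0, strict_orf = FALSE)
  expect_equal(g$cds, paste0("ATGGCT", "TTGGTA"))
  # same parts on the minus strand: transcription runs right to left
  ann2 <- ann; ann2$strand <- "-"
  g2 <- extract_genes(seqs, ann2, flank = 0, strict_orf = FALSE)
  expect_equal(g2$cds, oracle_revcomp(paste0("ATGGCT", "TTGGTA")))
})

test_that("strand antisymmetry: extraction from the reverse-complement genome", {
  set.seed(31)
  chr <- paste(sample(BASES, 400, replace = TRUE), collapse = "")
  L <- nchar(chr)
  ann <- data.frame(gene_id = c("p", "m"), seqid = "c",
                    start = c(51, 201), end = c(110, 290),
                    strand = c("+", "-"), stringsAsFactors = FALSE)
  g <- extract_genes(c(c = chr), ann, flank = 20, strict_orf = FALSE)
  # remap coordinates onto the reverse-complemented chromosome
  ann_rc <- data.frame(gene_id = ann$gene_id, seqid = "c",
                       start = L - ann$end + 1, end = L - ann$start + 1,
                       strand = ifelse(ann$strand == "+", "-", "+"),
                       stringsAsFactors = FALSE)
  g_rc <- extract_genes(c(c = oracle_revcomp(chr)), ann_rc, flank = 20,
                        strict_orf = FALSE)
  g_rc <- g_rc[match(g$gene_id, g_rc$gene_id), ]
  expect_equal(g_rc$cds, g$cds)
  expect_equal(g_rc$upstream, g$upstream)
  expect_equal(g_rc$downstream, g$downstream)
})

test_that("flank truncation at contig edges is flagged", {
  seqs <- c(chr1 = "ATGAAATAACCCC")
  ann <- data.frame(gene_id = "g1", seqid = "chr1", start = 1, end = 9,
                    strand = "+", stringsAsFactors = FALSE)
  g <- extract_genes(seqs, ann, flank = 200)
  expect_equal(g$upstream, "")
  expect_true(g$trunc5)
  expect_equal(g$downstream, "CCCC")
  expect_true(g$trunc3)
})

test_that("strict ORF filtering excludes and counts invalid genes", {
  seqs <- c(chr1 = "ATGAAATAAATGCCCCCC")
  ann <- data.frame(gene_id = c("good", "bad"), seqid = "chr1",
                    start = c(1, 10), end = c(9, 18),
                    strand = "+", stringsAsFactors = FALSE)
  g <- extract_genes(seqs, ann, flank = 0, strict_orf = TRUE)
  expect_equal(g$gene_id, "good")
  expect_equal(attr(g, "excluded"), 1L)
  g2 <- extract_genes(seqs, ann, flank = 0, strict_orf = FALSE)
  expect_equal(nrow(g2), 2L)
})

test_that("unknown chromosomes and out-of-bounds intervals drop with warning", {
  seqs <- c(chr1 = "ATGAAATAA")
  ann <- data.frame(gene_id = c("g1", "g2", "g3"),
                    seqid = c("chr1", "chrX", "chr1"),
                    start = c(1, 1, 5), end = c(9, 9, 50),
                    strand = "+", stringsAsFactors = FALSE)
  expect_warning(extract_genes(seqs, ann[1:2, ], strict_orf = FALSE),
                 "unknown sequence")
  expect_warning(extract_genes(seqs, ann[c(1, 3), ], strict_orf = FALSE),
                 "outside sequence bounds")
  g <- suppressWarnings(extract_genes(seqs, ann, strict_orf = FALSE))
  expect_equal(g$gene_id, "g1")
  expect_equal(attr(g, "dropped"), 2L)
})

test_that("strict ORF predicate checks start, stop, frame and length", {
  expect_true(is_strict_orf("ATGAAATAA"))
  expect_false(is_strict_orf("ATGAAATA"))      # frame
  expect_false(is_strict_orf("TTGAAATAA"))     # start
  expect_false(is_strict_orf("ATGAAAAAA"))     # stop
  expect_true(is_strict_orf("ATGTAA"))         # minimal length 6
  expect_false(is_strict_orf("ATGAA"))         # below minimal length
  expect_true(is_strict_orf("ATGTAATAA"))
  expect_false(is_strict_orf("ATGTAATAA", check_internal_stops = TRUE))
})
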