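# Terminal nucleotide/amino-acid bias, codon-position and
# fourfold-degenerate-site skews.

test_that("codon GC skew enumerates the standard code correctly", {
  expect_equal(codon_gc_skew("W"), 1.0)    # TGG, G-only
  expect_equal(codon_gc_skew("K"), 1.0)    # AAA (no G/C) + AAG
  expect_equal(codon_gc_skew("F"), -1.0)   # TTT + TTC
  expect_equal(codon_gc_skew("M"), 1.0)    # ATG
  expect_equal(codon_gc_skew("P"),
               mean(c(-1, -1, -1, -1/3)))  # CCT CCC CCA CCG
  expect_error(codon_gc_skew("Z"), "unknown residue")
  # usage weighting shifts the mean toward the used codons (codons
  # without G or C stay excluded)
  u <- c(CTC = 100)
  expect_equal(codon_gc_skew("L", weights = "usage", usage = u), -1)
})

test_that("the CUG-clade table reassigns CTG to serine", {
  std <- codon_table("standard")
  cug <- codon_table("cug_clade")
  expect_equal(unname(std[["CTG"]]), "L")
  expect_equal(unname(cug[["CTG"]]), "S")
  expect_equal(sum(std == "*"), 3L)
})

test_that("identical windows give ratio 1 and chi-square p 1", {
  # every gene: ATG + (TGC GAT)x10 + filler + (TGC GAT)x10 + TAA, so
  # both windows hold the same 20 non-initiator codons
  cds <- paste0("ATG", strrep("TGCGAT", 10), strrep("AAA", 10),
                strrep("TGCGAT", 10), "TAA")
  genes <- oriented_genes(sprintf("g%d", 1:4), rep(cds, 4))
  nt <- terminal_nucleotide_ratios(genes, n5_codons = 21, n3_codons = 20)
  # 5' window = ATG + 10x(TGC GAT), 3' window = 10x(TGC GAT)
  expect_equal(nt$ratio[nt$base == "C"],
               (10 / 63) / (10 / 60))
  ab <- suppressWarnings(
    terminal_aa_bias(genes, drop_initial_met = TRUE))
  cys <- ab[ab$residue == "C", ]
  expect_equal(cys$count5, cys$count3)
  expect_equal(cys$ratio5to3, 1.0)
  expect_equal(cys$chi2_p, 1.0)
})

test_that("a 2x C enrichment at the 5' windows is recovered", {
  set.seed(14)
  n <- 300
  w5 <- vapply(1:n, function(i)
    paste(sample(BASES, 63, replace = TRUE,
                 prob = c(0.2, 0.4, 0.2, 0.2)), collapse = ""),
    character(1))
  mid <- vapply(1:n, function(i)
    paste(sample(BASES, 30, replace = TRUE), collapse = ""), character(1))
  w3 <- vapply(1:n, function(i)
    paste(sample(BASES, 60, replace = TRUE,
                 prob = c(0.25, 0.2, 0.25, 0.3)), collapse = ""),
    character(1))
  genes <- oriented_genes(sprintf("g%d", 1:n),
                          paste0(w5, mid, w3, "TAA"))
  nt <- terminal_nucleotide_ratios(genes)
  expect_gt(nt$ratio[nt$base == "C"], 1.7)
  expect_lt(nt$ratio[nt$base == "C"], 2.3)
  expect_lt(abs(nt$ratio[nt$base == "A"] - 0.8), 0.1)
})

test_that("short genes are excluded from terminal windows", {
  genes <- oriented_genes(c("long", "short"),
                          c(paste0("ATG", strrep("GCA", 45), "TAA"),
                            "ATGGCATAA"))
  nt <- terminal_nucleotide_ratios(genes)
  expect_equal(attr(nt, "n_genes"), 1L)
  expect_equal(attr(nt, "n_excluded"), 1L)
})

test_that("terminal aa bias recovers an engineered Trp enrichment", {
  set.seed(15)
  all_codons <- names(codon_table())
  sense <- setdiff(all_codons, c("TAA", "TAG", "TGA"))
  n <- 400
  cds <- vapply(1:n, function(i) {
    body5 <- sample(sense, 20, replace = TRUE)
    mid <- sample(sense, 8, replace = TRUE)
    w <- ifelse(sense == "TGG", 2, 1)
    body3 <- sample(sense, 20, replace = TRUE, prob = w)
    paste0("ATG", paste(c(body5, mid, body3), collapse = ""), "TAA")
  }, character(1))
  genes <- oriented_genes(sprintf("g%d", 1:n), cds)
  ab <- suppressWarnings(terminal_aa_bias(genes))
  w_row <- ab[ab$residue == "W", ]
  expect_lt(w_row$ratio5to3, 0.75)
  expect_lt(w_row$chi2_p, 0.01)
  expect_equal(w_row$codon_skew, 1.0)
})

test_that("counts are conserved and Met accounting follows the flag", {
  genes <- rand_orf_set(30, 50, seed = 16)
  ab <- suppressWarnings(terminal_aa_bias(genes))
  expect_equal(sum(ab$count5), 21 * 30)
  expect_equal(sum(ab$count3), 20 * 30)
  ab2 <- suppressWarnings(terminal_aa_bias(genes, drop_initial_met = TRUE))
  expect_equal(sum(ab2$count5), 20 * 30)
  met_drop <- ab$count5[ab$residue == "M"] -
    ab2$count5[ab2$residue == "M"]
  expect_equal(met_drop, 30)
})

test_that("chi-square p-values are well behaved under a null codon set", {
  set.seed(17)
  genes <- rand_orf_set(400, 50)
  ab <- suppressWarnings(terminal_aa_bias(genes, drop_initial_met = TRUE))
  p <- ab$chi2_p[!is.na(ab$chi2_p)]
  # 20 independent-ish tests under the null: none should be extreme
  expect_gt(min(p), 1e-4)
  expect_gt(mean(p), 0.2)
})

test_that("codon-position skews partition the whole-gene counts", {
  genes <- oriented_genes("g", strrep("GCA", 20))
  p1 <- codon_position_skew(genes, 1, n_bins = 5)
  p2 <- codon_position_skew(genes, 2, n_bins = 5)
  p3 <- codon_position_skew(genes, 3, n_bins = 5)
  expect_equal(p1$skew, rep(1, 5))    # all G
  expect_equal(p2$skew, rep(-1, 5))   # all C
  expect_true(all(is.na(p3$skew)))    # all A: undefined
  total <- attr(p1, "counts") + attr(p2, "counts") + attr(p3, "counts")
  bm <- binned_metagene(genes, n_bins = 5, flank_bp = 0)
  expect_equal(total, bm$body_counts)
})

test_that("codon-position profiles see the embedded ramp at every position", {
  sp <- synthetic_spec(n_genes = 300, length = 900, a = -0.5, b = 450,
                       c = 0.2, d = 0, e = 0, noise_sd = 0,
                       codon_mode = FALSE, flank_bp = 0, seed = 18)
  genes <- generate_genes(sp)
  for (pos in 1:3) {
    pr <- codon_position_skew(genes, pos, n_bins = 10)
    expect_lt(pr$skew[1], pr$skew[10])   # rising 5' ramp
  }
})

test_that("fourfold families and sites match the standard code", {
  fams <- fourfold_families(codon_table())
  expect_setequal(fams, c("CT", "GT", "TC", "CC", "AC", "GC", "CG", "GG"))
  # glycine repeats: all third positions are fourfold sites
  g <- strrep("GGG", 10)
  expect_equal(skewscape:::fourfold_sites(g), seq(3, 30, by = 3))
  ff <- fourfold_degenerate_skew(oriented_genes("g", g), n_bins = 2)
  expect_equal(ff$overall$skew, c(1, 1))
})

test_that("expression deciles partition the gene set disjointly", {
  genes <- rand_orf_set(60, 40, seed = 19)
  expr <- data.frame(gene_id = genes$gene_id,
                     level = seq_len(nrow(genes)))
  ff <- suppressWarnings(
    fourfold_degenerate_skew(genes, expression = expr, quantile = 0.1))
  expect_length(intersect(ff$low_ids, ff$high_ids), 0)
  expect_lte(length(ff$low_ids) + length(ff$high_ids), nrow(genes))
  expect_equal(length(ff$low_ids), 6L)
})
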