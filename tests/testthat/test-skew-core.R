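# Skew metric and the three profile representations.

test_that("skew statistic matches its definition and bounds", {
  expect_equal(skew(composition_counts(nG = 4, nC = 0)), 1.0)
  expect_equal(skew(composition_counts(nG = 1, nC = 1)), 0.0)
  expect_equal(skew(composition_counts(nG = 3, nC = 1)), 0.5)
  expect_true(is.na(skew(composition_counts(nG = 0, nC = 0))))
  expect_equal(skew("GGGG"), 1.0)
  expect_equal(skew("CCCC"), -1.0)
  expect_equal(skew("AAAT", pair = "AT"), 0.5)
  expect_true(is.na(skew("GGCC", pair = "AT")))
  # N bases never enter the counts
  expect_equal(skew("GNNNC"), 0.0)
  expect_error(composition_counts(nG = -1), "non-negative")
})

test_that("skew is antisymmetric under reverse complement", {
  set.seed(42)
  for (i in 1:25) {
    s <- paste(sample(c("A", "C", "G", "T", "N"), sample(5:80, 1),
                      replace = TRUE), collapse = "")
    rc <- oracle_revcomp(s)
    for (p in c("GC", "AT")) {
      a <- skew(s, p); b <- skew(rc, p)
      if (is.na(a)) expect_true(is.na(b)) else expect_equal(b, -a)
    }
  }
})

test_that("pooled skew of a concatenation equals skew of summed counts", {
  set.seed(7)
  parts <- replicate(6, paste(sample(BASES, 30, replace = TRUE),
                              collapse = ""))
  pooled <- Reduce(`+`, lapply(parts, base_counts))
  expect_equal(skew(paste(parts, collapse = "")),
               skew(composition_counts(pooled[1], pooled[2], pooled[3],
                                       pooled[4])))
})

test_that("superposed profile pins the G of the ATG to 1 on strict ORFs", {
  genes <- rand_orf_set(40, 30, seed = 1)
  pr <- superposed_profile(genes, "start", upstream_bp = 0,
                           downstream_bp = 30)
  expect_equal(pr$skew[pr$offset == 2], 1.0)
  # A and T of the ATG carry no G/C: undefined
  expect_true(all(is.na(pr$skew[pr$offset %in% c(0, 1)])))
  expect_equal(pr$n[pr$offset == 2], 40)
})

test_that("superposed profile pools counts per offset", {
  genes <- oriented_genes(c("g1", "g2"),
                          c("ATGGGGTAA", "ATGGGGTAA"))
  pr <- superposed_profile(genes, "start", upstream_bp = 0,
                           downstream_bp = 9)
  expect_equal(pr$skew[pr$offset %in% 3:5], rep(1.0, 3))
  # stop anchor: offset -1 is the last base of the stop
  pr2 <- superposed_profile(genes, "stop", upstream_bp = 9,
                            downstream_bp = 0)
  expect_equal(pr2$skew[pr2$offset == -7], 1.0)  # G of ATG again
  expect_true(is.na(pr2$skew[pr2$offset == -1]))      # A of TAA
})

test_that("superposed profile on uniform-composition genes stays near 0", {
  set.seed(5)
  cds <- vapply(1:1000, function(i)
    paste(sample(BASES, 300, replace = TRUE), collapse = ""),
    character(1))
  genes <- oriented_genes(sprintf("g%d", 1:1000), cds)
  pr <- superposed_profile(genes, "start", upstream_bp = 0,
                           downstream_bp = 300)
  # pooled n ~ 500 G/C per offset; 3 binomial sd ~ 0.134
  expect_lt(mean(abs(pr$skew)), 0.05)
  expect_true(all(abs(pr$skew) < 0.2))
})

test_that("codon averaging and smoothing act on the profile", {
  genes <- oriented_genes("g1", "ATGGGGCACTAA")
  pr <- superposed_profile(genes, "start", upstream_bp = 0,
                           downstream_bp = 12, codon_average = TRUE)
  # codon 2 = GGG -> all three offsets 1; codon 3 = CAC -> mean of
  # (-1, NA, -1) = -1 at its defined offsets
  expect_equal(pr$skew[pr$offset %in% 3:5], rep(1, 3))
  expect_equal(pr$skew[pr$offset %in% 6:8], rep(-1, 3))
  pr2 <- superposed_profile(genes, "start", upstream_bp = 0,
                            downstream_bp = 12, smooth_bp = 3)
  expect_false(identical(pr$skew, pr2$skew))
})

test_that("binned metagene matches hand enumeration and flags undefined bins", {
  g <- oriented_genes("g1", "ATGGGGCCCTAG")
  bm <- binned_metagene(g, n_bins = 4, flank_bp = 0)
  expect_equal(bm$body$skew, c(1, 1, -1, 1))
  # a TAA-final gene has no G/C in its last bin: undefined, not 0
  g2 <- oriented_genes("g1", "ATGGGGCCCTAA")
  bm2 <- binned_metagene(g2, n_bins = 4, flank_bp = 0)
  expect_equal(bm2$body$skew, c(1, 1, -1, NA))
  expect_error(binned_metagene(g, n_bins = 0), "n_bins")
})

test_that("binned metagene equals the brute-force oracle", {
  set.seed(9)
  genes <- oriented_genes(sprintf("g%d", 1:30),
                          vapply(1:30, function(i) {
                            paste(sample(c(BASES, "N"),
                                         sample(20:90, 1),
                                         replace = TRUE), collapse = "")
                          }, character(1)))
  for (p in c("GC", "AT")) {
    bm <- binned_metagene(genes, n_bins = 7, flank_bp = 0, pair = p)
    expect_equal(bm$body$skew, oracle_binned(genes, 7, p))
  }
})

test_that("reverse-complemented genes mirror the metagene", {
  # gene length (3 * 40 = 120) divisible by n_bins so the bin map is
  # exactly antisymmetric under reversal
  genes <- rand_orf_set(25, 39, seed = 13)
  rc <- oriented_genes(genes$gene_id,
                       vapply(genes$cds, oracle_revcomp, character(1)))
  bm <- binned_metagene(genes, n_bins = 8, flank_bp = 0)
  bmr <- binned_metagene(rc, n_bins = 8, flank_bp = 0)
  expect_equal(rev(bmr$body$skew), -bm$body$skew)
})

test_that("flank profiles are pooled position-wise and right-aligned", {
  genes <- oriented_genes(c("a", "b"), c("ATGTAA", "ATGTAA"),
                          upstream = c("GG", "CGG"),
                          downstream = c("CC", "CC"))
  bm <- binned_metagene(genes, n_bins = 2, flank_bp = 3)
  # upstream offset -1 pools the last base of both flanks: G,G -> +1
  expect_equal(bm$upstream$skew[bm$upstream$offset == -1], 1)
  # offset -3 has only the longer flank's C
  expect_equal(bm$upstream$skew[bm$upstream$offset == -3], -1)
  expect_equal(bm$downstream$skew[bm$downstream$offset == 0], -1)
})

test_that("mean-of-genes mode differs from pooled where genes are unbalanced", {
  genes <- oriented_genes(c("a", "b"), c("GGGGGG", "GC"))
  pooled <- binned_metagene(genes, n_bins = 1, flank_bp = 0)
  avg <- binned_metagene(genes, n_bins = 1, flank_bp = 0, mode = "mean")
  expect_equal(pooled$body$skew, (7 - 1) / 8)
  expect_equal(avg$body$skew, mean(c(1, 0)))
})

test_that("sliding track computes windowed skew and its mirror property", {
  s <- paste0(strrep("G", 2000), strrep("C", 2000))
  tr <- sliding_track(s, window = 2000, step = 2000)
  expect_equal(tr$skew, c(1, -1))
  expect_error(sliding_track("ACGT", window = 10), "window")
  set.seed(21)
  s2 <- paste(sample(BASES, 5000, replace = TRUE), collapse = "")
  tr2 <- sliding_track(s2, window = 500, step = 100)
  # 3 sd binomial bound at ~250 informative bases per window
  expect_true(all(abs(tr2$skew) < 3 / sqrt(250) + 0.05))
  tr_rc <- sliding_track(oracle_revcomp(s2), window = 500, step = 100)
  expect_equal(rev(tr_rc$skew), -tr2$skew)
})

test_that("all emitted skew values stay within [-1, 1]", {
  genes <- rand_orf_set(50, 60, seed = 3)
  bm <- binned_metagene(genes, n_bins = 40, flank_bp = 0)
  pr <- superposed_profile(genes, "start", upstream_bp = 0,
                           downstream_bp = 180)
  ok <- function(v) all(v >= -1 & v <= 1, na.rm = TRUE)
  expect_true(ok(bm$body$skew))
  expect_true(ok(pr$skew))
})
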