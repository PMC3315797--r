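# Synthetic gene sets and genomes with known embedded skew structure.
# Base composition is generated directly from target per-position
# skews (no substitution-process simulation).

#' Specification for a synthetic gene set
#'
#' The target coding-strand GC skew along each gene follows the
#' three-line shape: skew `c + a` at the ATG decaying linearly to `c`
#' over the first `b` bp, a flat centre at `c`, and a linear rise to
#' `c + e` over the final `d` bp before the stop. AT skew is constant
#' along the gene. Flanks get constant skews of their own
#' (`promoter_skew` upstream, `utr_skew` downstream). At each position
#' the target GC skew s maps to base probabilities
#' P(G) = gc_content (1 + s)/2, P(C) = gc_content (1 - s)/2, and
#' analogously for A/T from the AT skew.
#'
#' Gaussian noise with standard deviation `noise_sd` is added to the
#' per-gene, per-position target skew (clipped to keep probabilities
#' valid), emulating gene-to-gene heterogeneity.
#'
#' @param n_genes number of genes.
#' @param length gene length in bp (scalar for fixed length, or
#'   `c(min, max)` for uniform lengths; rounded to codon multiples in
#'   codon mode).
#' @param gc_content fraction of G+C (0 to 1).
#' @param at_skew constant AT skew of the gene body.
#' @param a,b,c,d,e three-line GC-skew parameters (see
#'   [fit_three_line()]).
#' @param promoter_skew,utr_skew constant GC skews of the upstream and
#'   downstream flanks.
#' @param flank_bp flank length (default 200).
#' @param noise_sd per-position skew noise standard deviation.
#' @param codon_mode enforce valid ORFs: ATG start, sampled stop,
#'   no in-frame internal stop (violating codons are resampled).
#' @param seed RNG seed.
#' @return list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_genes = 2000L, length = 1500L,
                           gc_content = 0.40, at_skew = 0.10,
                           a = -0.3, b = 300L, c = 0.1, d = 200L,
                           e = 0.2, promoter_skew = -0.3,
                           utr_skew = 0.2, flank_bp = 200L,
                           noise_sd = 0.02, codon_mode = TRUE,
                           seed = NULL) {
  spec <- list(n_genes = as.integer(n_genes), length = as.integer(length),
               gc_content = gc_content, at_skew = at_skew,
               a = a, b = as.integer(b), c = c, d = as.integer(d), e = e,
               promoter_skew = promoter_skew, utr_skew = utr_skew,
               flank_bp = as.integer(flank_bp), noise_sd = noise_sd,
               codon_mode = isTRUE(codon_mode), seed = seed)
  validate_spec(spec)
  class(spec) <- "synthetic_spec"
  spec
}

validate_spec <- function(spec) {
  with(spec, {
    if (n_genes < 1L) stop("n_genes must be >= 1")
    if (any(length < 9L)) stop("gene length must be >= 9")
    if (length(spec$length) > 2L) stop("length must be scalar or c(min, max)")
    if (gc_content <= 0 || gc_content >= 1) stop("gc_content must be in (0,1)")
    ext <- max(abs(c + a), abs(c + e), abs(c), abs(at_skew),
               abs(promoter_skew), abs(utr_skew))
    if (ext > 1) stop("implied |skew| exceeds 1: base probabilities invalid")
    if (b < 0L || d < 0L) stop("ramp lengths must be >= 0")
    if (noise_sd < 0) stop("noise_sd must be >= 0")
  })
  invisible(spec)
}

# Three-line target skew for positions x = 0..L-1 (0-based from ATG).
three_line_target <- function(x, L, a, b, cc, d, e) {
  s <- rep(cc, length(x))
  if (b > 0L) s <- s + a * pmax(0, (b - x) / b)
  t <- (L - 1L) - x
  if (d > 0L) s <- s + e * pmax(0, (d - t) / d)
  s
}

# Sample an n x L matrix of base codes (1=A,2=C,3=G,4=T) from a
# target GC-skew matrix (or vector recycled over rows), constant AT
# skew, and GC content.
.sample_codes <- function(n, L, s_gc, gc, at_skew) {
  if (is.null(dim(s_gc))) s_gc <- matrix(s_gc, n, L, byrow = TRUE)
  pA <- (1 - gc) * (1 + at_skew) / 2
  pC <- gc * (1 - s_gc) / 2
  pG <- gc * (1 + s_gc) / 2
  u <- matrix(stats::runif(n * L), n, L)
  1L + (u > pA) + (u > pA + pC) + (u > pA + pC + pG)
}

.codes_to_seq <- function(codes) {
  # codes: matrix row per gene
  letters4 <- c("A", "C", "G", "T")
  apply(codes, 1L, function(r) paste(letters4[r], collapse = ""))
}

.STOP_CODES <- list(c(4L, 1L, 1L), c(4L, 1L, 3L), c(4L, 3L, 1L))  # TAA TAG TGA

#' Generate a synthetic gene set with known skew structure
#'
#' Genes are sampled per the spec (see [synthetic_spec()]); in codon
#' mode the first codon is set to ATG, the last to a uniformly chosen
#' stop codon, and internal in-frame stop codons are resampled from
#' the local base probabilities until none remain. The `spec` and the
#' realised per-position target skew are attached as the `"truth"`
#' attribute.
#'
#' @param spec a `synthetic_spec`.
#' @return an [oriented_genes] table with attribute `truth`
#'   (list: `spec`, `target_skew` function of 0-based position and
#'   gene length).
#' @export
generate_genes <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  validate_spec(spec)
  if (!is.null(spec$seed)) set.seed(spec$seed)
  n <- spec$n_genes
  lens <- if (length(spec$length) == 1L) {
    rep(spec$length, n)
  } else {
    sample(spec$length[1L]:spec$length[2L], n, replace = TRUE)
  }
  if (spec$codon_mode) lens <- pmax(9L, (lens %/% 3L) * 3L)
  ids <- sprintf("sgene%05d", seq_len(n))
  cds <- character(n)
  for (L in unique(lens)) {
    rows <- which(lens == L)
    nr <- length(rows)
    s_base <- three_line_target(0:(L - 1L), L, spec$a, spec$b, spec$c,
                                spec$d, spec$e)
    s <- matrix(s_base, nr, L, byrow = TRUE)
    if (spec$noise_sd > 0) {
      s <- s + matrix(stats::rnorm(nr * L, sd = spec$noise_sd), nr, L)
    }
    s <- pmin(pmax(s, -0.999), 0.999)
    codes <- .sample_codes(nr, L, s, spec$gc_content, spec$at_skew)
    if (spec$codon_mode) {
      codes[, 1L] <- 1L; codes[, 2L] <- 4L; codes[, 3L] <- 3L   # ATG
      stop_pick <- sample.int(3L, nr, replace = TRUE)
      for (j in 1:3) {
        codes[, L - 3L + j] <- vapply(stop_pick,
                                      function(k) .STOP_CODES[[k]][j],
                                      integer(1L))
      }
      # resample internal in-frame stops
      n_codons <- L %/% 3L
      repeat {
        first <- codes[, seq(1L, L - 2L, by = 3L), drop = FALSE]
        second <- codes[, seq(2L, L - 1L, by = 3L), drop = FALSE]
        third <- codes[, seq(3L, L, by = 3L), drop = FALSE]
        is_stop <- first == 4L &
          ((second == 1L & (third == 1L | third == 3L)) |
             (second == 3L & third == 1L))
        is_stop[, c(1L, n_codons)] <- FALSE
        hits <- which(is_stop, arr.ind = TRUE)
        if (nrow(hits) == 0L) break
        for (h in seq_len(nrow(hits))) {
          g <- hits[h, 1L]
          cpos <- (hits[h, 2L] - 1L) * 3L + 1:3
          codes[g, cpos] <- .sample_codes(1L, 3L, s[g, cpos],
                                          spec$gc_content, spec$at_skew)
        }
      }
    }
    cds[rows] <- .codes_to_seq(codes)
  }
  fb <- spec$flank_bp
  if (fb > 0L) {
    up <- .codes_to_seq(.sample_codes(n, fb, spec$promoter_skew,
                                      spec$gc_content, spec$at_skew))
    dn <- .codes_to_seq(.sample_codes(n, fb, spec$utr_skew,
                                      spec$gc_content, spec$at_skew))
  } else {
    up <- dn <- ""
  }
  out <- oriented_genes(ids, cds, up, dn)
  attr(out, "truth") <- list(
    spec = spec,
    target_skew = function(x, L) {
      three_line_target(x, L, spec$a, spec$b, spec$c, spec$d, spec$e)
    }
  )
  out
}

#' Generate position-homogeneous null genes
#'
#' Every base is i.i.d. with the given GC content and zero skew, so
#' there is no positional structure of any kind: the null input for
#' type-I calibration of the shuffle test.
#'
#' @param n number of genes.
#' @param length gene length in bp.
#' @param gc_content fraction G+C.
#' @param at_skew constant AT skew (default 0).
#' @param seed RNG seed.
#' @return an [oriented_genes] table (no flanks).
#' @export
generate_null_genes <- function(n, length = 600L, gc_content = 0.40,
                                at_skew = 0, seed = NULL) {
  stopifnot(n >= 0L, length >= 1L)
  if (!is.null(seed)) set.seed(seed)
  if (n == 0L) return(oriented_genes(character(), character()))
  codes <- .sample_codes(n, length, 0, gc_content, at_skew)
  oriented_genes(sprintf("null%05d", seq_len(n)), .codes_to_seq(codes))
}

#' Write a synthetic genome (FASTA + GFF3) from a gene set
#'
#' Places the genes, with their flanks, on a single contig separated
#' by random intergenic spacers, assigning strands at random (or all
#' plus). Each gene's upstream flank, CDS and downstream flank are
#' written contiguously, so re-extraction with
#' `extract_genes(flank = <flank length>)` reproduces the input genes
#' exactly.
#'
#' @param genes an [oriented_genes] table.
#' @param fasta_path,gff_path output paths.
#' @param intergenic_len spacer length between gene blocks (>= 0).
#' @param strand_assignment `"random"` or `"plus"`.
#' @param contig_id contig name.
#' @param spacer_gc GC content of the spacers.
#' @param seed RNG seed.
#' @return invisibly, a data frame with the genomic layout (`gene_id`,
#'   `start`, `end`, `strand` of each CDS).
#' @export
emit_genome <- function(genes, fasta_path, gff_path,
                        intergenic_len = 500L,
                        strand_assignment = c("random", "plus"),
                        contig_id = "contig1", spacer_gc = 0.5,
                        seed = NULL) {
  genes <- as_oriented_genes(genes)
  strand_assignment <- match.arg(strand_assignment)
  stopifnot(intergenic_len >= 0L)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(genes)
  if (n == 0L) stop("no genes to place")
  strands <- if (strand_assignment == "random") {
    sample(c("+", "-"), n, replace = TRUE)
  } else {
    rep("+", n)
  }
  spacer <- function(len) {
    if (len == 0L) return("")
    .codes_to_seq(.sample_codes(1L, len, 0, spacer_gc, 0))
  }
  pieces <- character(2L * n + 1L)
  layout <- data.frame(gene_id = genes$gene_id, start = 0L, end = 0L,
                       strand = strands, stringsAsFactors = FALSE)
  pos <- 0L
  pieces[1L] <- spacer(intergenic_len)
  pos <- pos + nchar(pieces[1L])
  for (i in seq_len(n)) {
    block <- paste0(genes$upstream[i], genes$cds[i], genes$downstream[i])
    lu <- nchar(genes$upstream[i])
    ld <- nchar(genes$downstream[i])
    lc <- nchar(genes$cds[i])
    if (strands[i] == "+") {
      layout$start[i] <- pos + lu + 1L
      layout$end[i] <- pos + lu + lc
    } else {
      block <- revcomp(block)
      layout$start[i] <- pos + ld + 1L
      layout$end[i] <- pos + ld + lc
    }
    pieces[2L * i] <- block
    pos <- pos + nchar(block)
    pieces[2L * i + 1L] <- spacer(intergenic_len)
    pos <- pos + nchar(pieces[2L * i + 1L])
  }
  contig <- paste(pieces, collapse = "")
  seqs <- stats::setNames(contig, contig_id)
  write_fasta(seqs, fasta_path)
  gff <- c(
    "##gff-version 3",
    sprintf("##sequence-region %s 1 %d", contig_id, nchar(contig)),
    sprintf("%s\tskewscape\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
            contig_id, layout$start, layout$end, layout$strand,
            layout$gene_id),
    sprintf("%s\tskewscape\tCDS\t%d\t%d\t.\t%s\t0\tID=cds_%s;Parent=%s",
            contig_id, layout$start, layout$end, layout$strand,
            layout$gene_id, layout$gene_id)
  )
  writeLines(gff, gff_path)
  invisible(layout)
}

#' Co-generate a covariate correlated with an end-window skew
#'
#' Produces a per-gene covariate (e.g. an expression or methylation
#' level) with a specified population correlation to one of the
#' per-gene summary columns, for power analyses of the correlation
#' module.
#'
#' @param genes an [oriented_genes] table.
#' @param target summary column to correlate with (default
#'   `"gc_skew_3end"`).
#' @param r target correlation.
#' @param end_bp end-window width for the summaries.
#' @param seed RNG seed.
#' @return data frame `gene_id`, `level`.
#' @export
generate_covariate <- function(genes, target = "gc_skew_3end", r = 0,
                               end_bp = 75L, seed = NULL) {
  stopifnot(abs(r) <= 1)
  if (!is.null(seed)) set.seed(seed)
  gs <- gene_summaries(genes, end_bp = end_bp)
  z <- gs[[target]]
  if (is.null(z)) stop("unknown target column: ", target)
  z[is.na(z)] <- mean(z, na.rm = TRUE)
  zs <- as.numeric(scale(z))
  lev <- r * zs + sqrt(1 - r^2) * stats::rnorm(length(zs))
  data.frame(gene_id = gs$gene_id, level = lev, stringsAsFactors = FALSE)
}
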