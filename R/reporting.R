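# End-to-end per-species analysis and multi-species merging. These
# functions are the package's orchestration surface; they are thin
# compositions of the stage functions and write plain-text outputs
# (TSV/JSON) suitable for version control and downstream tooling.

#' Run the full single-species skew analysis
#'
#' Loads genes from an annotated genome (`fasta` + `gff`), an ORF
#' multi-FASTA (`orf_fasta`), or an already-extracted
#' [oriented_genes] table, then computes: start- and stop-anchored
#' superposed profiles, GC and AT binned metagenes, the per-gene
#' shuffle test, the three-line model fit, terminal nucleotide and
#' amino-acid bias tables, and (when covariate tables are supplied)
#' the expression and methylation analyses. All randomness flows from
#' `seed`; outputs contain no timestamps, so a rerun with the same
#' inputs is byte-identical.
#'
#' @param genes an [oriented_genes] table (alternative to file input).
#' @param fasta,gff genome FASTA and GFF3/GTF annotation paths.
#' @param orf_fasta ORF multi-FASTA path.
#' @param outdir output directory (created if needed); `NULL` skips
#'   writing.
#' @param species species label used in the summary.
#' @param flank_bp flank span for extraction and metagenes.
#' @param n_bins gene-body bins.
#' @param end_bp shuffle-test end-window width.
#' @param n_shuffles shuffles per gene.
#' @param alpha shuffle-test significance level.
#' @param region_len three-line model region length.
#' @param expression,methylation optional covariate tables
#'   (data frame `gene_id`,`level`, named vector, or TSV path).
#' @param seed RNG seed for the whole run.
#' @return invisibly, a list with every stage result plus `summary`.
#' @export
run_species_report <- function(genes = NULL, fasta = NULL, gff = NULL,
                               orf_fasta = NULL, outdir = NULL,
                               species = "species",
                               flank_bp = 200L, n_bins = 40L,
                               end_bp = 100L, n_shuffles = 1000L,
                               alpha = 0.05, region_len = 750L,
                               expression = NULL, methylation = NULL,
                               seed = 1L) {
  if (is.null(genes)) {
    if (!is.null(orf_fasta)) {
      genes <- read_orf_fasta(orf_fasta)
    } else if (!is.null(fasta) && !is.null(gff)) {
      seqs <- read_fasta(fasta)
      ann <- read_annotations(gff)
      genes <- extract_genes(seqs, ann, flank = flank_bp,
                             strict_orf = TRUE)
    } else {
      stop("supply `genes`, `orf_fasta`, or both `fasta` and `gff`")
    }
  }
  genes <- as_oriented_genes(genes)
  if (nrow(genes) == 0L) stop("no genes after input processing")
  load_cov <- function(x) {
    if (is.null(x)) return(NULL)
    if (is.character(x) && length(x) == 1L && file.exists(x)) {
      return(read_gene_table(x))
    }
    as_gene_table(x)
  }
  expression <- load_cov(expression)
  methylation <- load_cov(methylation)
  set.seed(seed)

  res <- list(species = species, n_genes = nrow(genes))
  res$profile_start <- superposed_profile(genes, "start",
                                          upstream_bp = flank_bp,
                                          downstream_bp = region_len)
  res$profile_stop <- superposed_profile(genes, "stop",
                                         upstream_bp = region_len,
                                         downstream_bp = flank_bp)
  res$metagene_gc <- binned_metagene(genes, n_bins = n_bins,
                                     flank_bp = flank_bp, pair = "GC")
  res$metagene_at <- binned_metagene(genes, n_bins = n_bins,
                                     flank_bp = flank_bp, pair = "AT")
  res$shuffle <- significant_fraction(genes, end_bp = end_bp,
                                      n_shuffles = n_shuffles,
                                      alpha = alpha)
  res$regions <- build_regions(genes, region_len = region_len)
  res$fit <- fit_three_line(res$regions)
  res$nt_ratio <- terminal_nucleotide_ratios(genes)
  res$aa_bias <- suppressWarnings(terminal_aa_bias(genes))
  if (!is.null(expression)) {
    res$expression <- expression_correlation(genes, expression)
  }
  if (!is.null(methylation)) {
    res$methylation <- methylation_association(genes, methylation)
  }
  pooled <- rowSums(vapply(genes$cds,
                           function(s) tabulate(seq_codes(s), 4L),
                           integer(4L)))
  res$summary <- list(
    species = species,
    n_genes = nrow(genes),
    gc_skew = skew(composition_counts(pooled[1L], pooled[2L], pooled[3L],
                                      pooled[4L]), "GC"),
    at_skew = skew(composition_counts(pooled[1L], pooled[2L], pooled[3L],
                                      pooled[4L]), "AT"),
    fraction_significant = res$shuffle$fraction,
    fit = res$fit[c("a", "b", "c", "d", "e", "sse")],
    parameters = list(flank_bp = flank_bp, n_bins = n_bins,
                      end_bp = end_bp, n_shuffles = n_shuffles,
                      alpha = alpha, region_len = region_len,
                      seed = seed),
    package_version = as.character(utils::packageVersion("skewscape"))
  )
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    p <- function(f) file.path(outdir, f)
    write_profile_tsv(res$profile_start, p("profile_start.tsv"))
    write_profile_tsv(res$profile_stop, p("profile_stop.tsv"))
    write_profile_tsv(res$metagene_gc, p("metagene_GC.tsv"))
    write_profile_tsv(res$metagene_at, p("metagene_AT.tsv"))
    utils::write.table(res$shuffle$table, p("shuffle_test.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_fit_json(res$fit, p("three_line_fit.json"))
    utils::write.table(res$nt_ratio, p("nt_ratio.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(res$aa_bias, p("aa_bias.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    jsonlite::write_json(res$summary, p("summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(res)
}

#' Merge per-species runs into a species table and skew scatter
#'
#' @param gene_sets named list of [oriented_genes] tables, one per
#'   species (names must be unique), or a named list of
#'   `run_species_report()` results.
#' @param outdir optional output directory for `species_table.tsv`.
#' @return list of class `multi_species`: `table` (species, gc_skew,
#'   at_skew, n_genes) and `scatter` (a [species_scatter()] result,
#'   `NULL` with fewer than 3 species).
#' @export
run_multi_species <- function(gene_sets, outdir = NULL) {
  stopifnot(is.list(gene_sets), length(gene_sets) >= 1L)
  ids <- names(gene_sets)
  if (is.null(ids) || any(ids == "")) stop("gene sets must be named")
  if (anyDuplicated(ids)) stop("duplicate species ids")
  rows <- lapply(ids, function(sp) {
    x <- gene_sets[[sp]]
    genes <- if (is.list(x) && !is.data.frame(x) && !is.null(x$summary)) {
      # accept a full report; reuse its summary
      return(data.frame(species = sp,
                        gc_skew = x$summary$gc_skew,
                        at_skew = x$summary$at_skew,
                        n_genes = x$summary$n_genes,
                        stringsAsFactors = FALSE))
    } else {
      as_oriented_genes(x)
    }
    pooled <- rowSums(vapply(genes$cds,
                             function(s) tabulate(seq_codes(s), 4L),
                             integer(4L)))
    cnt <- composition_counts(pooled[1L], pooled[2L], pooled[3L],
                              pooled[4L])
    data.frame(species = sp, gc_skew = skew(cnt, "GC"),
               at_skew = skew(cnt, "AT"), n_genes = nrow(genes),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  scatter <- if (nrow(tab) >= 3L) species_scatter(tab) else NULL
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(tab, file.path(outdir, "species_table.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  structure(list(table = tab, scatter = scatter),
            class = "multi_species")
}

#' @export
print.multi_species <- function(x, ...) {
  cat("multi_species: ", nrow(x$table), " species\n", sep = "")
  if (!is.null(x$scatter)) {
    cat("  AT vs GC skew: R = ", signif(x$scatter$r, 3), "\n", sep = "")
  }
  invisible(x)
}
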