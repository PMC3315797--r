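# Test helpers: independent brute-force oracles and small fixture
# builders. These deliberately share no code with the implementation.

BASES <- c("A", "C", "G", "T")

# A random valid ORF of n_codons coding codons plus a stop.
rand_orf <- function(n_codons, codon_weights = NULL) {
  all_codons <- as.vector(outer(as.vector(outer(BASES, BASES, paste0)),
                                BASES, paste0))
  stops <- c("TAA", "TAG", "TGA")
  sense <- setdiff(all_codons, stops)
  w <- if (is.null(codon_weights)) NULL else codon_weights[sense]
  body <- sample(sense, n_codons - 1L, replace = TRUE, prob = w)
  paste0("ATG", paste(body, collapse = ""), sample(stops, 1L))
}

rand_orf_set <- function(n, n_codons, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  oriented_genes(sprintf("orf%04d", seq_len(n)),
                 vapply(seq_len(n), function(i) rand_orf(n_codons),
                        character(1L)))
}

# Naive per-base skew oracle.
oracle_skew <- function(s, pair = "GC") {
  ch <- strsplit(s, "")[[1L]]
  if (pair == "GC") {
    num <- sum(ch == "G") - sum(ch == "C")
    den <- sum(ch == "G") + sum(ch == "C")
  } else {
    num <- sum(ch == "A") - sum(ch == "T")
    den <- sum(ch == "A") + sum(ch == "T")
  }
  if (den == 0) NA_real_ else num / den
}

# Brute-force binned metagene: walk every base of every gene.
oracle_binned <- function(genes, n_bins, pair = "GC") {
  counts <- matrix(0L, 4L, n_bins)
  for (cds in genes$cds) {
    ch <- strsplit(cds, "")[[1L]]
    L <- length(ch)
    for (i in seq_len(L)) {
      b <- floor((i - 1L) * n_bins / L) + 1L
      j <- match(ch[i], BASES)
      if (!is.na(j)) counts[j, b] <- counts[j, b] + 1L
    }
  }
  vapply(seq_len(n_bins), function(b) {
    if (pair == "GC") {
      num <- counts[3L, b] - counts[2L, b]; den <- counts[3L, b] + counts[2L, b]
    } else {
      num <- counts[1L, b] - counts[4L, b]; den <- counts[1L, b] + counts[4L, b]
    }
    if (den == 0L) NA_real_ else num / den
  }, numeric(1L))
}

# Naive exhaustive three-line fit: plain quadruple loop, same
# tie-break order (b ascending, a in grid order; strict improvement).
oracle_fit <- function(regions, a_grid, b_grid, d_grid, e_grid) {
  rl <- regions$region_len
  cc <- mean(regions$centre, na.rm = TRUE)
  sse_of <- function(series, pred) sum((series - pred)^2, na.rm = TRUE)
  x <- seq_len(rl) - 1L
  best5 <- NULL
  for (b in sort(b_grid)) {
    if (b <= 0) {
      sse <- sse_of(regions$five, rep(cc, rl))
      if (is.null(best5) || sse < best5$sse) best5 <- list(a = 0, b = 0, sse = sse)
      next
    }
    for (a in a_grid) {
      pred <- cc + a * pmax(0, (b - x) / b)
      sse <- sse_of(regions$five, pred)
      if (is.null(best5) || sse < best5$sse) best5 <- list(a = a, b = b, sse = sse)
    }
  }
  t <- rl - seq_len(rl)
  best3 <- NULL
  for (d in sort(d_grid)) {
    if (d <= 0) {
      sse <- sse_of(regions$three, rep(cc, rl))
      if (is.null(best3) || sse < best3$sse) best3 <- list(e = 0, d = 0, sse = sse)
      next
    }
    for (e in e_grid) {
      pred <- cc + e * pmax(0, (d - t) / d)
      sse <- sse_of(regions$three, pred)
      if (is.null(best3) || sse < best3$sse) best3 <- list(e = e, d = d, sse = sse)
    }
  }
  list(a = best5$a, b = best5$b, c = cc, d = best3$d, e = best3$e,
       sse = best5$sse + sum((regions$centre - cc)^2, na.rm = TRUE) +
         best3$sse)
}

# Two-pass Pearson correlation oracle.
oracle_pearson <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# String reverse complement without Biostrings.
oracle_revcomp <- function(s) {
  ch <- rev(strsplit(s, "")[[1L]])
  paste(c(T = "A", A = "T", G = "C", C = "G", N = "N")[ch], collapse = "")
}
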