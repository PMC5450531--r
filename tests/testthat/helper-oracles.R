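# Independent brute-force recomputations used as oracles.  Deliberately
# naive (explicit loops, no shared code with the package internals).

ALL_CODONS <- genetic_code()$codons
SENSE <- genetic_code()$sense_codons
STOPS <- genetic_code()$stop_codons
FAMS <- genetic_code()$families

oracle_count_codons <- function(sequence) {
  out <- stats::setNames(integer(64), ALL_CODONS)
  skipped <- 0L
  i <- 1
  while (i + 2 <= nchar(sequence)) {
    cod <- substr(sequence, i, i + 2)
    if (cod %in% ALL_CODONS) out[cod] <- out[cod] + 1L
    else skipped <- skipped + 1L
    i <- i + 3
  }
  attr(out, "skipped") <- skipped
  out
}

oracle_rscu <- function(counts) {
  out <- stats::setNames(rep(NA_real_, length(SENSE)), SENSE)
  for (aa in names(FAMS)) {
    fam <- FAMS[[aa]]
    total <- 0
    for (cod in fam) total <- total + counts[[cod]]
    if (total > 0) {
      for (cod in fam) out[cod] <- length(fam) * counts[[cod]] / total
    }
  }
  out
}

oracle_gc_positions <- function(counts) {
  tot <- 0; g <- c(0, 0, 0)
  for (cod in ALL_CODONS) {
    n <- counts[[cod]]
    if (n == 0) next
    tot <- tot + n
    for (k in 1:3)
      if (substr(cod, k, k) %in% c("G", "C")) g[k] <- g[k] + n
  }
  c(gc = mean(g / tot), gc1 = g[1] / tot, gc2 = g[2] / tot, gc3 = g[3] / tot)
}

oracle_gc3s <- function(counts) {
  num <- 0; den <- 0
  for (cod in setdiff(SENSE, c("ATG", "TGG"))) {
    den <- den + counts[[cod]]
    if (substr(cod, 3, 3) %in% c("G", "C")) num <- num + counts[[cod]]
  }
  if (den == 0) NA_real_ else num / den
}

# chi-squared statistic of a count table by explicit summation
oracle_chisq_over_n <- function(m) {
  n <- sum(m)
  rs <- rowSums(m); cs <- colSums(m)
  stat <- 0
  for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m))) {
    e <- rs[i] * cs[j] / n
    if (e > 0) stat <- stat + (m[i, j] - e)^2 / e
  }
  unname(stat / n)
}

oracle_flags <- function(freq, means, sds) {
  out <- matrix(FALSE, nrow(freq), ncol(freq), dimnames = dimnames(freq))
  for (i in seq_len(nrow(freq))) for (j in seq_len(ncol(freq)))
    out[i, j] <- freq[i, j] > means[j] + sds[j]
  out
}

oracle_revcomp <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
}

# random in-frame gene, independent of the package generator
random_gene <- function(n_codons, alphabet = SENSE) {
  paste(sample(alphabet, n_codons, replace = TRUE), collapse = "")
}

random_counts <- function(lambda = 3) {
  stats::setNames(stats::rpois(64, lambda), ALL_CODONS)
}
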