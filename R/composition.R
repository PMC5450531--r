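# Dinucleotide observed/expected ratios and the within-sequence
# codon-bias flagging statistic.

.NTS <- c("A", "C", "G", "T")
.DINUCS <- as.vector(outer(.NTS, .NTS, paste0))

.get_seqs <- function(x) {
  if (is.data.frame(x)) x$nucleotides %||% x$sequence else as.character(x)
}

#' Dinucleotide observed/expected profile
#'
#' Counts overlapping adjacent nucleotide pairs within each sequence
#' (never across sequence boundaries), pooled over the input set, and
#' compares the observed frequencies with those expected from the
#' pooled mononucleotide frequencies of the same sequences:
#' `expected(xy) = f(x) f(y)`.  A ratio of 1.00 indicates no pairing
#' preference.  Pairs or bases involving `N` are excluded.
#'
#' @param x coding-sequence data frame or character vector of sequences.
#' @return data frame over the 16 dinucleotides: `dinucleotide`,
#'   `observed`, `expected`, `ratio`; attribute `mononucleotide` holds
#'   the base frequencies.
#' @export
dinucleotide_profile <- function(x) {
  seqs <- .get_seqs(x)
  seqs <- seqs[nchar(seqs) > 0]
  if (length(seqs) == 0) stopf("no sequences supplied")
  di_counts <- stats::setNames(numeric(16), .DINUCS)
  nt_counts <- stats::setNames(numeric(4), .NTS)
  for (s in seqs) {
    s <- toupper(s)
    n <- nchar(s)
    b <- strsplit(s, "", fixed = TRUE)[[1]]
    tb <- table(factor(b, levels = .NTS))
    nt_counts <- nt_counts + as.numeric(tb)
    if (n >= 2) {
      pairs <- paste0(b[-n], b[-1])
      tp <- table(factor(pairs, levels = .DINUCS))
      di_counts <- di_counts + as.numeric(tp)
    }
  }
  if (sum(di_counts) == 0) stopf("sequences too short to form pairs")
  obs <- di_counts / sum(di_counts)
  f <- nt_counts / sum(nt_counts)
  expd <- as.vector(outer(f, f))
  names(expd) <- as.vector(outer(.NTS, .NTS, paste0))
  expd <- expd[.DINUCS]
  out <- data.frame(dinucleotide = .DINUCS,
                    observed = unname(obs),
                    expected = unname(expd),
                    ratio = unname(ifelse(expd > 0, obs / expd, NA_real_)),
                    stringsAsFactors = FALSE)
  attr(out, "mononucleotide") <- f
  out
}

#' Within-sequence codon frequency statistics for a species
#'
#' For each of the 64 codons, the mean and standard deviation of its
#' within-sequence frequency (codon count divided by the sequence's
#' codon total), taken across all sequences with zero frequencies
#' included.  These are the reference distributions for
#' [flag_biased_codons()].
#'
#' @param x coding-sequence data frame, character vector, or codon count
#'   matrix from [codon_count_matrix()].
#' @param sd_type `"population"` (default; divisor `n`) or `"sample"`
#'   (divisor `n - 1`).
#' @return data frame: `codon`, `mean`, `sd`; attributes `n_sequences`
#'   and `sd_type`.
#' @export
species_codon_stats <- function(x, sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  m <- if (is.matrix(x)) x else codon_count_matrix(x)
  if (nrow(m) < 2)
    stopf("at least 2 sequences are required (sd undefined otherwise)")
  tot <- rowSums(m)
  if (any(tot == 0)) stopf("sequences with zero counted codons present")
  freq <- m / tot
  mu <- colMeans(freq)
  dev2 <- colMeans(sweep(freq, 2, mu)^2)
  sdv <- if (sd_type == "population") sqrt(dev2)
         else sqrt(dev2 * nrow(m) / (nrow(m) - 1))
  out <- data.frame(codon = colnames(m), mean = unname(mu),
                    sd = unname(sdv), stringsAsFactors = FALSE)
  attr(out, "n_sequences") <- nrow(m)
  attr(out, "sd_type") <- sd_type
  out
}

#' Flag codons used at high frequency within a sequence
#'
#' A codon is flagged in a sequence when its within-sequence frequency
#' strictly exceeds the species mean plus one standard deviation for
#' that codon (from [species_codon_stats()]).  Only over-use can be
#' flagged this way: amino acids absent from a protein give zero
#' frequencies that would make under-use calls meaningless.
#'
#' @param x coding-sequence data frame, character vector, or codon count
#'   matrix.
#' @param stats optional precomputed [species_codon_stats()] for the
#'   same species; computed from `x` when omitted.
#' @return object of class `bias_flags`: list with `flags` (logical
#'   sequences x 64 matrix), `per_codon` (named flag totals),
#'   `n_observations` (sequences x codons), `n_flagged`, `fraction`.
#' @export
flag_biased_codons <- function(x, stats = NULL) {
  m <- if (is.matrix(x)) x else codon_count_matrix(x)
  if (is.null(stats)) stats <- species_codon_stats(m)
  if (!identical(stats$codon, colnames(m)))
    stopf("stats codon order does not match the count matrix")
  tot <- rowSums(m)
  if (any(tot == 0)) stopf("sequences with zero counted codons present")
  freq <- m / tot
  thr <- stats$mean + stats$sd
  flags <- sweep(freq, 2, thr, ">")
  per_codon <- colSums(flags)
  structure(list(flags = flags,
                 per_codon = per_codon,
                 n_observations = length(flags),
                 n_flagged = sum(flags),
                 fraction = sum(flags) / length(flags)),
            class = "bias_flags")
}

#' @export
print.bias_flags <- function(x, ...) {
  cat("Within-sequence codon bias flags\n")
  cat(sprintf("  %d sequences x %d codons = %d observations\n",
              nrow(x$flags), ncol(x$flags), x$n_observations))
  cat(sprintf("  flagged: %d (%.1f%%)\n", x$n_flagged, 100 * x$fraction))
  top <- sort(x$per_codon, decreasing = TRUE)[1:5]
  cat("  top codons:", paste(sprintf("%s=%d", names(top), top),
                             collapse = ", "), "\n")
  invisible(x)
}
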