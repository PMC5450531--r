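# Per-gene and per-species codon statistics: counts, RSCU, positional GC,
# GC3s, Wright's effective number of codons, CBI and Fop.

#' Count codons in a frame-+1 coding sequence
#'
#' Counts non-overlapping triplets left to right.  Codons containing `N`
#' (or any non-ACGT character) are excluded from the counts and tallied
#' in the `skipped` attribute.
#'
#' @param sequence a nucleotide string whose length is a multiple of 3.
#' @return named integer vector over the 64 codons (alphabetical order)
#'   with attribute `skipped` = number of ambiguous codons dropped.
#' @export
count_codons <- function(sequence) {
  sequence <- toupper(sequence)
  n <- nchar(sequence)
  if (n %% 3 != 0)
    stopf("sequence length %d is not a multiple of 3", n)
  if (n == 0) {
    out <- stats::setNames(integer(64), .CODONS)
    attr(out, "skipped") <- 0L
    return(out)
  }
  cod <- substring(sequence, seq(1, n - 2, 3), seq(3, n, 3))
  ok <- !grepl("[^ACGT]", cod)
  out <- table(factor(cod[ok], levels = .CODONS))
  out <- stats::setNames(as.integer(out), .CODONS)
  attr(out, "skipped") <- sum(!ok)
  out
}

# counts for many sequences at once: genes x 64 integer matrix with a
# "skipped" attribute (per-gene ambiguous-codon tally)
#' Codon count matrix for a set of coding sequences
#'
#' @param x data frame with `id` and `nucleotides` columns (as produced
#'   by [extract_coding_regions()] or [generate_species()]), or a
#'   character vector of sequences (optionally named).
#' @return integer matrix, genes x 64 codons, rownames = gene ids, with
#'   attribute `skipped` (integer vector of ambiguous codons per gene).
#' @export
codon_count_matrix <- function(x) {
  if (is.data.frame(x)) {
    seqs <- x$nucleotides %||% x$sequence
    ids <- x$id
  } else {
    seqs <- as.character(x)
    ids <- names(x) %||% paste0("gene", seq_along(seqs))
  }
  m <- matrix(0L, nrow = length(seqs), ncol = 64,
              dimnames = list(ids, .CODONS))
  skipped <- integer(length(seqs))
  for (i in seq_along(seqs)) {
    ci <- count_codons(seqs[i])
    m[i, ] <- ci
    skipped[i] <- attr(ci, "skipped")
  }
  attr(m, "skipped") <- stats::setNames(skipped, ids)
  m
}

.as_counts64 <- function(counts) {
  if (is.null(names(counts))) {
    if (length(counts) != 64)
      stopf("unnamed codon counts must have length 64")
    return(stats::setNames(as.numeric(counts), .CODONS))
  }
  out <- stats::setNames(numeric(64), .CODONS)
  nm <- toupper(names(counts))
  unknown <- setdiff(nm, .CODONS)
  if (length(unknown))
    stopf("unknown codon names: %s", paste(unknown, collapse = ", "))
  out[nm] <- out[nm] + as.numeric(counts)
  out
}

#' Relative synonymous codon usage
#'
#' For codon \eqn{c} of an amino acid with \eqn{n} synonymous codons and
#' family total \eqn{X}, \eqn{RSCU(c) = n x_c / X}: the observed count
#' relative to uniform use of the family.  Values over one family sum to
#' the family size (six for leucine).  Families that are entirely absent
#' get `NA`; the single-codon amino acids `ATG` and `TGG` are reported
#' as 1 when observed.
#'
#' @param counts codon counts (named vector, as from [count_codons()],
#'   or any subset naming codons).
#' @return named numeric vector over the 61 sense codons.
#' @export
rscu <- function(counts) {
  x <- .as_counts64(counts)
  out <- stats::setNames(rep(NA_real_, length(.SENSE_CODONS)), .SENSE_CODONS)
  for (aa in names(.FAMILIES)) {
    fam <- .FAMILIES[[aa]]
    tot <- sum(x[fam])
    if (length(fam) == 1) {
      out[fam] <- if (tot > 0) 1 else NA_real_
    } else if (tot > 0) {
      out[fam] <- length(fam) * x[fam] / tot
    }
  }
  out
}

#' GC content by codon position
#'
#' @param counts codon counts over the codons to include (all counted
#'   codons; use on count vectors or pooled matrix column sums).
#' @return named numeric: `gc` (mean of the three positions), `gc1`,
#'   `gc2`, `gc3` — each the fraction of codons with G or C at that
#'   position.
#' @export
gc_by_position <- function(counts) {
  x <- .as_counts64(counts)
  tot <- sum(x)
  if (tot <= 0) stopf("gc_by_position: no codons counted")
  gc_at <- function(k) {
    sum(x[substr(.CODONS, k, k) %in% c("G", "C")]) / tot
  }
  g1 <- gc_at(1); g2 <- gc_at(2); g3 <- gc_at(3)
  c(gc = (g1 + g2 + g3) / 3, gc1 = g1, gc2 = g2, gc3 = g3)
}

#' Synonymous third-position GC content (GC3s)
#'
#' Fraction of third positions that are G or C, computed over sense
#' codons whose third position admits synonymous substitution — i.e.
#' excluding `ATG`, `TGG` and the stop codons (the codonW convention).
#'
#' @param counts codon counts.
#' @return a fraction in \[0, 1\], or `NA` if no qualifying codons.
#' @export
gc3s <- function(counts) {
  x <- .as_counts64(counts)
  qual <- .VARIABLE_CODONS
  tot <- sum(x[qual])
  if (tot <= 0) return(NA_real_)
  sum(x[qual][.THIRD_GC[qual]]) / tot
}

#' Wright's effective number of codons (Nc)
#'
#' Estimates how many codons a gene effectively uses, from 20 (exactly
#' one codon per amino acid) to 61 (uniform use of all sense codons).
#' For each synonymous family with usage \eqn{n \ge 2} and codon
#' frequencies \eqn{p_i}, codon homozygosity is estimated as
#' \eqn{\hat F = (n \sum p_i^2 - 1) / (n - 1)}; class averages
#' \eqn{\bar F_k} are taken over observed families of each degeneracy
#' class \eqn{k}, and
#' \deqn{N_c = 2 + 9/\bar F_2 + 1/\bar F_3 + 5/\bar F_4 + 3/\bar F_6.}
#'
#' Missing-data rules: families with usage below 2 contribute nothing;
#' families with \eqn{\hat F = 0} are uninformative and are dropped from
#' their class mean; if the isoleucine (3-fold) class is unobserved,
#' \eqn{\bar F_3 := (\bar F_2 + \bar F_4)/2}; if the 2-, 4- or 6-fold
#' class has no contributing family the estimate is undefined (`NA`).
#' The estimate is capped at 61 (it can exceed the bound on short
#' genes).
#'
#' @param counts codon counts.
#' @return Nc in \[20, 61\], or `NA` when undefined.
#' @export
effective_number_of_codons <- function(counts) {
  x <- .as_counts64(counts)
  fhat <- lapply(names(.FAMILIES), function(aa) {
    fam <- .FAMILIES[[aa]]
    if (length(fam) < 2) return(NULL)
    n <- sum(x[fam])
    if (n < 2) return(NULL)
    p <- x[fam] / n
    f <- (n * sum(p^2) - 1) / (n - 1)
    list(k = length(fam), f = f)
  })
  fhat <- Filter(Negate(is.null), fhat)
  fbar <- function(k) {
    fs <- vapply(Filter(function(z) z$k == k, fhat), `[[`, numeric(1), "f")
    fs <- fs[fs > 0]
    if (length(fs) == 0) NA_real_ else mean(fs)
  }
  f2 <- fbar(2); f3 <- fbar(3); f4 <- fbar(4); f6 <- fbar(6)
  if (is.na(f3) && !is.na(f2) && !is.na(f4)) f3 <- (f2 + f4) / 2
  if (anyNA(c(f2, f3, f4, f6))) return(NA_real_)
  nc <- 2 + 9 / f2 + 1 / f3 + 5 / f4 + 3 / f6
  min(nc, 61)
}

.check_optimal <- function(optimal) {
  optimal <- toupper(optimal)
  bad <- setdiff(optimal, .SENSE_CODONS)
  if (length(bad))
    stopf("optimal set contains non-sense codons: %s",
          paste(bad, collapse = ", "))
  aa <- .CODON_AA[optimal]
  if (anyDuplicated(aa))
    stopf("optimal set has more than one codon for amino acid(s): %s",
          paste(unique(aa[duplicated(aa)]), collapse = ", "))
  optimal
}

#' Codon bias index (CBI)
#'
#' Excess usage of a designated optimal-codon set over random
#' expectation, scaled to \[-1, 1\]:
#' \eqn{CBI = (N_{opt} - N_{ran}) / (N_{tot} - N_{ran})}, where
#' \eqn{N_{opt}} counts optimal codons, \eqn{N_{tot}} counts all codons
#' of amino acids possessing an optimal codon, and \eqn{N_{ran}} is the
#' usage expected if synonymous codons were chosen uniformly
#' (family usage / family size, summed over those amino acids).
#'
#' @param counts codon counts.
#' @param optimal character vector of optimal codons, at most one per
#'   amino acid (e.g. the `codon` column of [determine_optimal_codons()]
#'   output).
#' @return CBI, or `NA` when `N_tot = N_ran`.
#' @export
codon_bias_index <- function(counts, optimal) {
  if (length(optimal) == 0) stopf("optimal set is empty")
  optimal <- .check_optimal(optimal)
  x <- .as_counts64(counts)
  aas <- unique(.CODON_AA[optimal])
  n_opt <- sum(x[optimal])
  n_tot <- 0; n_ran <- 0
  for (aa in aas) {
    fam <- .FAMILIES[[aa]]
    usage <- sum(x[fam])
    n_tot <- n_tot + usage
    n_ran <- n_ran + usage / length(fam)
  }
  if (n_tot == n_ran) return(NA_real_)
  (n_opt - n_ran) / (n_tot - n_ran)
}

#' Frequency of optimal codons (Fop)
#'
#' Fraction of codons that are optimal, among codons of amino acids that
#' possess an optimal codon: \eqn{F_{op} = N_{opt} / N_{tot}}.
#'
#' @inheritParams codon_bias_index
#' @return Fop in \[0, 1\], or `NA` when no qualifying codons observed.
#' @export
frequency_optimal_codons <- function(counts, optimal) {
  if (length(optimal) == 0) stopf("optimal set is empty")
  optimal <- .check_optimal(optimal)
  x <- .as_counts64(counts)
  aas <- unique(.CODON_AA[optimal])
  n_tot <- sum(vapply(aas, function(aa) sum(x[.FAMILIES[[aa]]]), numeric(1)))
  if (n_tot == 0) return(NA_real_)
  sum(x[optimal]) / n_tot
}

#' Infer an optimal-codon set from a correspondence analysis
#'
#' Genes at the two extremes of the first correspondence-analysis axis
#' (top and bottom `quantile`) form a putatively high-bias and a
#' low-bias group; the high-bias group is the extreme with the lower
#' pooled Nc.  For each multi-codon amino acid a chi-squared test on the
#' 2 x k contingency table of group x codon counts is performed; when it
#' is significant at `alpha`, the codon with the highest RSCU in the
#' high-bias group — provided its RSCU is higher there than in the
#' low-bias group — is declared optimal.  Amino acids with no
#' significant codon contribute none.
#'
#' @param counts codon count matrix (genes x 64) from
#'   [codon_count_matrix()]; rownames must match the CA gene ids.
#' @param ca a [codon_ca()] fit on (a subset of) the same genes.
#' @param quantile fraction of genes in each extreme group (default
#'   0.05).
#' @param alpha significance level for the per-amino-acid chi-squared
#'   test (default 0.01).
#' @return data frame with columns `amino_acid`, `codon`, `p_value`,
#'   `rscu_biased`, `rscu_unbiased`; attribute `method_tag` records the
#'   derivation.
#' @export
determine_optimal_codons <- function(counts, ca, quantile = 0.05,
                                     alpha = 0.01) {
  ids <- rownames(ca$row_coordinates)
  counts <- counts[ids, , drop = FALSE]
  ax1 <- ca$row_coordinates[, 1]
  n <- length(ax1)
  g <- max(1L, ceiling(quantile * n))
  if (g < 10)
    stopf(paste("only %d genes per extreme group at quantile %.3f;",
                "at least 10 required - provide a larger input"), g, quantile)
  ord <- order(ax1)
  lo_ids <- ids[ord[seq_len(g)]]
  hi_ids <- ids[ord[seq(n - g + 1, n)]]
  pool_lo <- colSums(counts[lo_ids, , drop = FALSE])
  pool_hi <- colSums(counts[hi_ids, , drop = FALSE])
  # the biased extreme is the one using fewer effective codons
  nc_lo <- effective_number_of_codons(pool_lo)
  nc_hi <- effective_number_of_codons(pool_hi)
  if (!is.na(nc_lo) && !is.na(nc_hi) && nc_lo < nc_hi) {
    tmp <- pool_lo; pool_lo <- pool_hi; pool_hi <- tmp
  }
  rscu_hi <- rscu(pool_hi)
  rscu_lo <- rscu(pool_lo)
  rows <- list()
  for (aa in names(.FAMILIES)) {
    fam <- .FAMILIES[[aa]]
    if (length(fam) < 2) next
    tab <- rbind(high = pool_hi[fam], low = pool_lo[fam])
    tab <- tab[, colSums(tab) > 0, drop = FALSE]
    if (ncol(tab) < 2 || any(rowSums(tab) == 0)) next
    p <- suppressWarnings(stats::chisq.test(tab)$p.value)
    if (is.na(p) || p >= alpha) next
    cand <- fam[which.max(rscu_hi[fam])]
    if (is.na(rscu_lo[cand]) || rscu_hi[cand] <= rscu_lo[cand]) next
    rows[[aa]] <- data.frame(amino_acid = aa, codon = cand, p_value = p,
                             rscu_biased = unname(rscu_hi[cand]),
                             rscu_unbiased = unname(rscu_lo[cand]),
                             stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(amino_acid = character(), codon = character(),
               p_value = numeric(), rscu_biased = numeric(),
               rscu_unbiased = numeric(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "method_tag") <- sprintf("ca_axis1_quantile%.2f_alpha%.2g",
                                     quantile, alpha)
  out
}

#' Per-gene codon-usage indices
#'
#' Computes the classical per-gene index set: codon total, Nc, GC and
#' positional GC, GC3s, and (when an optimal-codon set is supplied) CBI
#' and Fop.  Genes shorter than `min_codons` get `NA` indices — short
#' genes give wild Nc estimates — but keep their row.
#'
#' @param x coding-sequence data frame, character vector of sequences,
#'   or a precomputed count matrix from [codon_count_matrix()].
#' @param optimal optional optimal-codon set (character vector or the
#'   data frame from [determine_optimal_codons()]).
#' @param min_codons minimum codon count for indices (default 30).
#' @return data frame, one row per gene: `id`, `n_codons`, `skipped`,
#'   `nc`, `gc`, `gc1`, `gc2`, `gc3`, `gc3s`, `cbi`, `fop`.
#' @export
gene_indices <- function(x, optimal = NULL, min_codons = 30) {
  m <- if (is.matrix(x)) x else codon_count_matrix(x)
  skipped <- attr(m, "skipped") %||% stats::setNames(
    integer(nrow(m)), rownames(m))
  if (is.data.frame(optimal)) optimal <- optimal$codon
  has_opt <- length(optimal) > 0
  n <- nrow(m)
  out <- data.frame(id = rownames(m),
                    n_codons = as.integer(rowSums(m)),
                    skipped = as.integer(skipped),
                    nc = NA_real_, gc = NA_real_, gc1 = NA_real_,
                    gc2 = NA_real_, gc3 = NA_real_, gc3s = NA_real_,
                    cbi = NA_real_, fop = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    if (out$n_codons[i] < min_codons || out$n_codons[i] == 0) next
    cts <- m[i, ]
    out$nc[i] <- effective_number_of_codons(cts)
    g <- gc_by_position(cts)
    out$gc[i] <- g["gc"]; out$gc1[i] <- g["gc1"]
    out$gc2[i] <- g["gc2"]; out$gc3[i] <- g["gc3"]
    out$gc3s[i] <- gc3s(cts)
    if (has_opt) {
      out$cbi[i] <- codon_bias_index(cts, optimal)
      out$fop[i] <- frequency_optimal_codons(cts, optimal)
    }
  }
  rownames(out) <- NULL
  out
}

#' Species-level summary of codon usage
#'
#' Aggregates per-gene indices into one summary row: gene, codon and
#' stop totals; unweighted gene means for Nc, CBI and Fop; pooled
#' (usage-weighted) GC3s and transcriptome GC.  Gene-mean GC3s and a
#' pooled-count Nc are carried alongside, since reported tables use
#' sometimes one convention, sometimes the other.  Missing per-gene
#' values are excluded from means, never zero-filled.
#'
#' @param indices per-gene data frame from [gene_indices()].
#' @param counts the matching codon count matrix (for pooled GC3s/GC/Nc);
#'   optional — without it pooled columns are usage-weighted means.
#' @param stops total internal stop count (e.g. from [tabulate_stops()]).
#' @param species species label.
#' @return one-row data frame: `species`, `genes`, `codons`, `stops`,
#'   `cbi`, `fop`, `nc`, `gc3s`, `transcriptome_gc`, plus `nc_pooled`
#'   and `gc3s_mean`.
#' @export
summarize_species <- function(indices, counts = NULL, stops = 0,
                              species = "species") {
  if (nrow(indices) == 0) stopf("no genes to summarise")
  mn <- function(v) if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  wmn <- function(v, w) {
    ok <- !is.na(v)
    if (!any(ok)) return(NA_real_)
    sum(v[ok] * w[ok]) / sum(w[ok])
  }
  if (!is.null(counts)) {
    pooled <- colSums(counts)
    gc3s_pooled <- gc3s(pooled)
    gc_pooled <- unname(gc_by_position(pooled)["gc"])
    nc_pooled <- effective_number_of_codons(pooled)
  } else {
    gc3s_pooled <- wmn(indices$gc3s, indices$n_codons)
    gc_pooled <- wmn(indices$gc, indices$n_codons)
    nc_pooled <- NA_real_
  }
  data.frame(species = species,
             genes = nrow(indices),
             codons = sum(indices$n_codons),
             stops = as.integer(stops),
             cbi = mn(indices$cbi),
             fop = mn(indices$fop),
             nc = mn(indices$nc),
             gc3s = gc3s_pooled,
             transcriptome_gc = gc_pooled,
             nc_pooled = nc_pooled,
             gc3s_mean = mn(indices$gc3s),
             stringsAsFactors = FALSE)
}
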