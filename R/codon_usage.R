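# The central analysis object: all codon-usage statistics of one
# species' coding set, fitted in one call.

#' Fit the codon-usage statistics of a coding set
#'
#' Computes, for one species' set of frame-+1 coding regions, every
#' statistic of the classical codon-usage toolbox: the codon count
#' matrix, per-gene indices (Nc, GC/GC1/GC2/GC3, GC3s, and CBI/Fop once
#' an optimal-codon set is available), pooled RSCU, a correspondence
#' analysis of the 59 variable codons, an optimal-codon set inferred
#' from the CA extremes (or supplied), the species summary row, and the
#' composition statistics (dinucleotide observed/expected ratios,
#' within-sequence codon frequency stats and high-frequency flags).
#'
#' @param x coding-sequence data frame from [extract_coding_regions()]
#'   or [generate_species()]`$truth` ORFs, or a (named) character vector
#'   of in-frame sequences.
#' @param species species label (default taken from `x$species` when
#'   present).
#' @param optimal `"ca"` (default) to infer the optimal-codon set from
#'   the correspondence analysis; `"none"` to skip CBI/Fop; or an
#'   explicit codon vector / [determine_optimal_codons()] data frame.
#' @param min_codons minimum codons per gene for indices and CA
#'   inclusion (default 30).
#' @param ca_axes number of CA axes to keep (default 4).
#' @param optimal_quantile extreme-group quantile for optimal-codon
#'   inference (default 0.05).
#' @param composition logical: compute dinucleotide and flagging
#'   statistics (default TRUE).
#' @return object of class `codon_usage`; see Details.
#' @details The returned list carries `counts` (genes x 64), `indices`
#'   (per-gene data frame), `rscu` (pooled, 61 sense codons), `ca`
#'   (`codon_ca` or NULL), `optimal` (data frame + method tag),
#'   `axis_cor` (axis-1 vs GC3s correlation), `stops`, `summary`
#'   (one-row species summary), `dinucleotide`, `codon_stats`, `flags`.
#' @examples
#' sp <- generate_species(generator_spec("demo", n_genes = 60, seed = 42))
#' cu <- codon_usage(sp$truth$orf, species = "demo", optimal = "none")
#' cu$summary[, c("genes", "codons", "nc", "gc3s")]
#' @export
codon_usage <- function(x, species = NULL, optimal = "ca", min_codons = 30,
                        ca_axes = 4, optimal_quantile = 0.05,
                        composition = TRUE) {
  if (is.data.frame(x)) {
    species <- species %||% (if (!is.null(x$species) && nrow(x) > 0)
      x$species[1] else "species")
  } else species <- species %||% "species"
  m <- codon_count_matrix(x)
  if (nrow(m) == 0) stopf("no coding sequences supplied")
  stops <- if (is.data.frame(x) && !is.null(x$internal_stops))
    sum(x$internal_stops)
  else sum(vapply(.get_seqs(x), count_internal_stops, integer(1)))

  idx0 <- gene_indices(m, optimal = NULL, min_codons = min_codons)
  eligible <- idx0$n_codons >= min_codons
  ca <- NULL
  if (sum(eligible) >= 2) {
    mv <- m[eligible, .VARIABLE_CODONS, drop = FALSE]
    nz <- rowSums(mv) > 0
    if (sum(nz) >= 2)
      ca <- codon_ca(mv[nz, , drop = FALSE], n_axes = ca_axes)
  }

  opt <- NULL
  if (is.character(optimal) && length(optimal) == 1 &&
      optimal %in% c("ca", "none")) {
    if (optimal == "ca" && !is.null(ca)) {
      opt <- tryCatch(
        determine_optimal_codons(m, ca, quantile = optimal_quantile),
        error = function(e) {
          warnf("optimal-codon inference skipped: %s", conditionMessage(e))
          NULL
        })
    }
  } else if (is.data.frame(optimal)) {
    opt <- optimal
  } else if (is.character(optimal)) {
    opt <- data.frame(amino_acid = unname(.CODON_AA[toupper(optimal)]),
                      codon = toupper(optimal), stringsAsFactors = FALSE)
    attr(opt, "method_tag") <- "user_supplied"
  }

  opt_codons <- if (!is.null(opt) && nrow(opt) > 0) opt$codon else NULL
  indices <- gene_indices(m, optimal = opt_codons, min_codons = min_codons)
  axis_cor <- if (!is.null(ca)) axis_gc3s_correlation(ca, indices) else NULL
  summary_row <- summarize_species(indices, counts = m, stops = stops,
                                   species = species)

  dinuc <- codon_stats <- flags <- NULL
  if (composition) {
    seqs <- .get_seqs(x)
    dinuc <- dinucleotide_profile(seqs)
    if (nrow(m) >= 2 && all(rowSums(m) > 0)) {
      codon_stats <- species_codon_stats(m)
      flags <- flag_biased_codons(m, codon_stats)
    }
  }

  structure(list(species = species,
                 counts = m,
                 indices = indices,
                 rscu = rscu(colSums(m)),
                 ca = ca,
                 optimal = opt,
                 axis_cor = axis_cor,
                 stops = as.integer(stops),
                 summary = summary_row,
                 dinucleotide = dinuc,
                 codon_stats = codon_stats,
                 flags = flags,
                 min_codons = min_codons),
            class = "codon_usage")
}

#' @export
print.codon_usage <- function(x, ...) {
  s <- x$summary
  cat(sprintf("Codon usage fit for '%s'\n", x$species))
  cat(sprintf("  genes: %d   codons: %d   internal stops: %d\n",
              s$genes, s$codons, s$stops))
  cat(sprintf("  Nc (gene mean): %s   GC3s (pooled): %s   GC: %s\n",
              fmt(s$nc), fmt(s$gc3s), fmt(s$transcriptome_gc)))
  if (!is.null(x$optimal) && nrow(x$optimal) > 0)
    cat(sprintf("  optimal codons: %d (%s); CBI %s, Fop %s\n",
                nrow(x$optimal),
                attr(x$optimal, "method_tag") %||% "supplied",
                fmt(s$cbi), fmt(s$fop)))
  if (!is.null(x$axis_cor))
    cat(sprintf("  |cor(CA axis 1, GC3s)| = %s\n", fmt(x$axis_cor$abs_r)))
  invisible(x)
}

fmt <- function(v, digits = 3) {
  if (is.null(v) || is.na(v)) "NA" else formatC(v, digits = digits,
                                                format = "f")
}

#' @export
summary.codon_usage <- function(object, ...) {
  out <- list(summary = object$summary,
              rscu = object$rscu,
              optimal = object$optimal,
              flags = object$flags,
              species = object$species)
  class(out) <- "summary.codon_usage"
  out
}

#' @export
print.summary.codon_usage <- function(x, ...) {
  cat(sprintf("Species summary for '%s'\n", x$species))
  print(x$summary, row.names = FALSE)
  cat("\nMost and least used codons by RSCU:\n")
  r <- sort(x$rscu[.VARIABLE_CODONS], decreasing = TRUE)
  r <- r[!is.na(r)]
  show <- rbind(utils::head(r, 5), utils::tail(r, 5))
  top <- utils::head(r, 5); bot <- utils::tail(r, 5)
  cat("  high:", paste(sprintf("%s=%.2f", names(top), top),
                       collapse = ", "), "\n")
  cat("  low: ", paste(sprintf("%s=%.2f", names(bot), bot),
                       collapse = ", "), "\n")
  if (!is.null(x$flags))
    cat(sprintf("\nHigh-frequency flags: %d of %d observations (%.1f%%)\n",
                x$flags$n_flagged, x$flags$n_observations,
                100 * x$flags$fraction))
  invisible(x)
}

#' Pooled RSCU of a codon-usage fit
#'
#' @param object a [codon_usage()] fit.
#' @param ... unused.
#' @return named numeric vector of pooled RSCU over the 61 sense codons.
#' @export
coef.codon_usage <- function(object, ...) object$rscu

#' Plot a codon-usage fit
#'
#' Per-gene effective number of codons against GC3s, with the analytic
#' composition-only expectation for reference.
#'
#' @param x a [codon_usage()] fit.
#' @param ... passed to [graphics::plot()].
#' @export
plot.codon_usage <- function(x, ...) {
  idx <- x$indices
  ok <- !is.na(idx$nc) & !is.na(idx$gc3s)
  graphics::plot(idx$gc3s[ok], idx$nc[ok], pch = 16, cex = 0.5,
                 col = "grey30", xlab = "GC3s",
                 ylab = "Effective number of codons",
                 xlim = c(0, 1), ylim = c(20, 62),
                 main = x$species, ...)
  ss <- seq(0.01, 0.99, by = 0.01)
  graphics::lines(ss, wright_enc(ss), col = "red", lwd = 2)
  invisible(x)
}
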