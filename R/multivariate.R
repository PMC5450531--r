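# Correspondence analysis of per-gene codon usage, and the simulated
# expected-Nc null curve against synonymous GC content.

#' Correspondence analysis of a codon count matrix
#'
#' Standard correspondence analysis: with relative matrix
#' \eqn{P = X / N}, row masses \eqn{r} and column masses \eqn{c}, the
#' standardized residuals \eqn{S = D_r^{-1/2} (P - r c^T) D_c^{-1/2}}
#' are decomposed by SVD; principal coordinates are returned for the
#' leading `n_axes` axes and the per-axis inertia is the squared
#' singular values (summing to the total inertia, i.e. the chi-squared
#' statistic of the table divided by \eqn{N}).
#'
#' The sign of axis 1 is normalised so that it correlates non-negatively
#' with per-gene third-position GC computed from the matrix itself,
#' making runs comparable.  Columns with zero totals are dropped with a
#' warning; all-zero rows are an error.
#'
#' @param x non-negative count matrix, genes x codons (typically the 59
#'   variable codons; see [codon_count_matrix()]).
#' @param n_axes number of axes to return (default 4; capped at
#'   `min(dim) - 1`).
#' @return object of class `codon_ca`: list with `row_coordinates`,
#'   `column_coordinates` (principal coordinates), `inertia` (all
#'   axes), `total_inertia`, `row_masses`, `column_masses`, `n`.
#' @examples
#' m <- rbind(g1 = c(10, 0), g2 = c(0, 10))
#' colnames(m) <- c("GCC", "GCA")
#' fit <- codon_ca(m, n_axes = 1)
#' fit$total_inertia  # 1: perfect association in a 2x2
#' @export
codon_ca <- function(x, n_axes = 4) {
  x <- as.matrix(x)
  if (any(x < 0)) stopf("count matrix has negative entries")
  if (sum(x) == 0) stopf("degenerate count matrix: all zeros")
  zero_row <- rowSums(x) == 0
  if (any(zero_row))
    stopf("all-zero rows in count matrix: %s",
          paste(utils::head(rownames(x)[zero_row], 5), collapse = ", "))
  zero_col <- colSums(x) == 0
  if (any(zero_col)) {
    warnf("dropping %d all-zero columns from correspondence analysis",
          sum(zero_col))
    x <- x[, !zero_col, drop = FALSE]
  }
  if (nrow(x) < 2 || ncol(x) < 2)
    stopf("correspondence analysis needs at least 2 rows and 2 columns")
  n <- sum(x)
  p <- x / n
  r <- rowSums(p)
  cc <- colSums(p)
  s <- (p - outer(r, cc)) / outer(sqrt(r), sqrt(cc))
  dec <- svd(s)
  maxax <- min(nrow(x), ncol(x)) - 1L
  d <- dec$d[seq_len(maxax)]
  d[d < 0] <- 0
  k <- max(1L, min(n_axes, maxax))
  row_pc <- sweep(dec$u[, seq_len(k), drop = FALSE], 1, sqrt(r), "/") %*%
    diag(d[seq_len(k)], k)
  col_pc <- sweep(dec$v[, seq_len(k), drop = FALSE], 1, sqrt(cc), "/") %*%
    diag(d[seq_len(k)], k)
  dimnames(row_pc) <- list(rownames(x), paste0("axis", seq_len(k)))
  dimnames(col_pc) <- list(colnames(x), paste0("axis", seq_len(k)))
  # orient axis 1 along increasing third-position GC
  third_gc <- substr(colnames(x), 3, 3) %in% c("G", "C")
  gene_gc3 <- rowSums(x[, third_gc, drop = FALSE]) / rowSums(x)
  if (stats::sd(row_pc[, 1]) > 0 && stats::sd(gene_gc3) > 0) {
    if (stats::cor(row_pc[, 1], gene_gc3) < 0) {
      row_pc[, 1] <- -row_pc[, 1]
      col_pc[, 1] <- -col_pc[, 1]
    }
  }
  structure(list(row_coordinates = row_pc,
                 column_coordinates = col_pc,
                 inertia = d^2,
                 total_inertia = sum(d^2),
                 row_masses = r,
                 column_masses = cc,
                 n = n),
            class = "codon_ca")
}

#' @export
print.codon_ca <- function(x, ...) {
  cat("Correspondence analysis of codon usage\n")
  cat(sprintf("  %d genes x %d codons, N = %d codon observations\n",
              nrow(x$row_coordinates), nrow(x$column_coordinates),
              round(x$n)))
  cat(sprintf("  total inertia: %.4f\n", x$total_inertia))
  k <- min(4, length(x$inertia))
  pct <- 100 * x$inertia / max(x$total_inertia, .Machine$double.eps)
  cat(sprintf("  axis %d: inertia %.4f (%.1f%%)\n",
              seq_len(k), x$inertia[seq_len(k)], pct[seq_len(k)]), sep = "")
  invisible(x)
}

#' @export
plot.codon_ca <- function(x, axes = c(1, 2), col = "grey30", ...) {
  rc <- x$row_coordinates
  if (ncol(rc) < 2) stopf("fit has fewer than 2 axes")
  pct <- 100 * x$inertia / max(x$total_inertia, .Machine$double.eps)
  graphics::plot(rc[, axes[1]], rc[, axes[2]], col = col, pch = 16,
                 cex = 0.6,
                 xlab = sprintf("Axis %d (%.1f%%)", axes[1], pct[axes[1]]),
                 ylab = sprintf("Axis %d (%.1f%%)", axes[2], pct[axes[2]]),
                 ...)
  graphics::abline(h = 0, v = 0, lty = 3, col = "grey70")
  invisible(x)
}

#' Correlation between CA axis 1 and GC3s
#'
#' Pearson correlation between the first correspondence-analysis axis
#' and per-gene GC3s.  CA axis signs are arbitrary, so the absolute
#' value is reported alongside the signed value.
#'
#' @param ca a [codon_ca()] fit.
#' @param indices per-gene data frame with `id` and `gc3s` columns
#'   ([gene_indices()] output).
#' @return list with `r` (signed), `abs_r`, and `n` (genes used);
#'   `NA`s when fewer than 3 genes match.
#' @export
axis_gc3s_correlation <- function(ca, indices) {
  ids <- rownames(ca$row_coordinates)
  g <- indices$gc3s[match(ids, indices$id)]
  ok <- !is.na(g)
  if (sum(ok) < 3) return(list(r = NA_real_, abs_r = NA_real_,
                               n = sum(ok)))
  r <- stats::cor(ca$row_coordinates[ok, 1], g[ok])
  list(r = r, abs_r = abs(r), n = sum(ok))
}

#' Wright's expected Nc at a given synonymous GC content
#'
#' The closed-form approximation for the effective number of codons
#' expected when codon choice depends only on third-position GC content
#' \eqn{s}: \eqn{N_c(s) = 2 + s + 29 / (s^2 + (1-s)^2)}, capped at 61.
#'
#' @param s synonymous (third-position) GC fraction in \[0, 1\].
#' @return expected Nc.
#' @export
wright_enc <- function(s) {
  pmin(2 + s + 29 / (s^2 + (1 - s)^2), 61)
}

# simulate one gene's codon counts under the composition-only null:
# amino acids uniform over the 18 multi-codon families, third-position
# G/C class chosen with probability s, uniform within class
.null_codon_probs <- function(s) {
  p <- stats::setNames(numeric(length(.VARIABLE_CODONS)), .VARIABLE_CODONS)
  fams <- .FAMILIES[.DEGENERACY >= 2]
  for (fam in fams) {
    gc_cls <- fam[.THIRD_GC[fam]]
    at_cls <- fam[!.THIRD_GC[fam]]
    p[gc_cls] <- s / (length(fams) * length(gc_cls))
    p[at_cls] <- (1 - s) / (length(fams) * length(at_cls))
  }
  p
}

#' Simulated expected-Nc null curve
#'
#' Simulates the Nc expected when codon usage reflects composition
#' alone: for each point a synonymous GC bias \eqn{s} is drawn uniformly
#' on (0, 1), a gene of `gene_length_codons` codons is simulated whose
#' synonymous codon probabilities depend only on \eqn{s} (G/C third
#' positions with probability \eqn{s}, uniform within class), and Nc is
#' computed on the simulated counts.  Binned means give the null
#' (maximum) curve; [wright_enc()] is carried alongside as the analytic
#' reference.
#'
#' @param n_points number of simulated genes (default 1000).
#' @param gene_length_codons length of each simulated gene (default 300).
#' @param seed optional RNG seed for reproducibility.
#' @param bin_width GC3s bin width for the summarised curve (default
#'   0.02).
#' @return object of class `enc_curve`: `points` (data frame `s`, `nc`),
#'   `binned` (data frame `s`, `nc_expected`, `se`, `n`),
#'   `gene_length_codons`.
#' @export
enc_null_curve <- function(n_points = 1000, gene_length_codons = 300,
                           seed = NULL, bin_width = 0.02) {
  if (n_points < 1) stopf("n_points must be >= 1")
  with_seed(seed, {
    s <- stats::runif(n_points)
    nc <- vapply(s, function(si) {
      pr <- .null_codon_probs(si)
      cod <- sample(names(pr), gene_length_codons, replace = TRUE,
                    prob = pr)
      cts <- table(factor(cod, levels = .CODONS))
      effective_number_of_codons(stats::setNames(as.integer(cts), .CODONS))
    }, numeric(1))
    pts <- data.frame(s = s, nc = nc)
    brk <- seq(0, 1, by = bin_width)
    bin <- cut(pts$s, brk, include.lowest = TRUE)
    ok <- !is.na(pts$nc)
    agg_mean <- tapply(pts$nc[ok], bin[ok], mean)
    agg_se <- tapply(pts$nc[ok], bin[ok], function(v)
      if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else NA_real_)
    agg_n <- tapply(pts$nc[ok], bin[ok], length)
    mids <- (brk[-length(brk)] + brk[-1]) / 2
    keep <- !is.na(agg_mean)
    binned <- data.frame(s = mids[keep],
                         nc_expected = as.numeric(agg_mean[keep]),
                         se = as.numeric(agg_se[keep]),
                         n = as.integer(agg_n[keep]))
    structure(list(points = pts, binned = binned,
                   gene_length_codons = gene_length_codons),
              class = "enc_curve")
  })
}

#' Evaluate an Nc null curve at given GC3s values
#'
#' Linear interpolation of the binned simulated curve.
#'
#' @param object an [enc_null_curve()] result.
#' @param s GC3s values at which to evaluate.
#' @param ... unused.
#' @return expected Nc at each `s`.
#' @export
predict.enc_curve <- function(object, s, ...) {
  b <- object$binned
  if (any(s < min(b$s) - 1e-9 | s > max(b$s) + 1e-9))
    stopf("GC3s value outside the simulated curve support [%.3f, %.3f]",
          min(b$s), max(b$s))
  stats::approx(b$s, b$nc_expected, xout = s, rule = 2)$y
}

#' @export
plot.enc_curve <- function(x, ...) {
  graphics::plot(x$points$s, x$points$nc, pch = 16, cex = 0.4,
                 col = "grey70", xlab = "GC3s",
                 ylab = "Effective number of codons", ylim = c(20, 62), ...)
  graphics::lines(x$binned$s, x$binned$nc_expected, col = "red", lwd = 2)
  ss <- seq(0.01, 0.99, by = 0.01)
  graphics::lines(ss, wright_enc(ss), col = "blue", lty = 2)
  graphics::legend("bottomleft", bty = "n", lwd = c(2, 1), lty = c(1, 2),
                   col = c("red", "blue"),
                   legend = c("simulated null", "analytic reference"))
  invisible(x)
}

#' Offset of observed Nc from the null curve
#'
#' For each species, the expected Nc at its GC3s (from the simulated
#' null curve) minus the observed mean Nc.  Positive offsets mean codon
#' usage is more restricted than composition alone predicts; a negative
#' offset is reported with a warning.
#'
#' @param summaries species summary data frame (needs `species`, `gc3s`,
#'   `nc` columns; see [summarize_species()]).
#' @param curve an [enc_null_curve()] result covering the species'
#'   GC3s values.
#' @return data frame: `species`, `gc3s`, `nc`, `nc_expected`, `offset`.
#' @export
enc_offset <- function(summaries, curve) {
  exp_nc <- predict(curve, summaries$gc3s)
  off <- exp_nc - summaries$nc
  if (any(off < 0, na.rm = TRUE))
    warnf("observed Nc above the null curve for: %s",
          paste(summaries$species[which(off < 0)], collapse = ", "))
  data.frame(species = summaries$species, gc3s = summaries$gc3s,
             nc = summaries$nc, nc_expected = exp_nc, offset = off,
             stringsAsFactors = FALSE)
}
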