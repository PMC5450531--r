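# Seeded synthetic "species" transcriptomes with controllable
# third-position GC bias, within-family codon preferences, stop-bearing
# contaminants, and matching BLAST-tabular fixtures.

#' A realistic average amino-acid composition
#'
#' Frequencies close to the average composition of well-annotated
#' protein databases; used as the generator default so synthetic coding
#' regions have believable first- and second-position statistics.
#'
#' @return named numeric vector of 20 frequencies summing to 1.
#' @export
default_aa_profile <- function() {
  p <- c(A = 0.083, R = 0.055, N = 0.040, D = 0.054, C = 0.014,
         Q = 0.039, E = 0.067, G = 0.071, H = 0.023, I = 0.059,
         L = 0.097, K = 0.058, M = 0.024, F = 0.039, P = 0.047,
         S = 0.066, T = 0.054, W = 0.011, Y = 0.029, V = 0.069)
  p / sum(p)
}

#' Specification of one synthetic species
#'
#' Collects and validates the parameters of the generator.  The codon
#' model: amino acids i.i.d. from `amino_acid_profile`; within each
#' synonymous family the third-position G/C class is chosen with the
#' gene's GC3 bias (drawn per gene around `theta_gc3` with spread
#' `theta_gc3_sd`), and codons within a class follow fixed per-species
#' weights drawn from a symmetric Dirichlet with concentration
#' `preference_concentration` (large = uniform usage, small = one
#' sharply preferred codon per class).
#'
#' @param species_label species name (unique within a panel).
#' @param n_genes number of genes (default 500).
#' @param gene_length_meanlog,gene_length_sdlog lognormal parameters of
#'   gene length in codons (defaults `log(300)` and 0.35, matching the
#'   roughly 300-codon average of BLAST-extracted coding regions).
#' @param min_gene_length floor on gene length in codons (default 30).
#' @param theta_gc3 mean probability that a variable third position is
#'   G/C, in (0, 1).
#' @param theta_gc3_sd per-gene spread of the GC3 bias (Beta-distributed
#'   around `theta_gc3`; default 0.05, the scale of per-gene GC3s
#'   variation in real coding transcriptomes).
#' @param preference_concentration Dirichlet concentration of the
#'   within-class codon weights (default 5: mild, realistic preference).
#' @param amino_acid_profile 20 amino-acid frequencies (normalised).
#' @param contamination_fraction fraction of genes given 1--3 in-frame
#'   stop codons (default 0.006).
#' @param utr_length integer range (length-2 vector) of UTR lengths in
#'   nucleotides on each side of the ORF (default `c(50, 150)`).
#' @param ua_penalty multiplicative penalty on TA-ending codons within
#'   their class (default 1 = off; values < 1 reproduce avoidance of
#'   UA-ending codons by construction).
#' @param minus_strand_fraction fraction of ORFs embedded on the reverse
#'   strand of their transcript (default 0.1).
#' @param seed RNG seed; all generator randomness flows from it.
#' @return object of class `generator_spec` (a validated list).
#' @export
generator_spec <- function(species_label,
                           n_genes = 500,
                           gene_length_meanlog = log(300),
                           gene_length_sdlog = 0.35,
                           min_gene_length = 30,
                           theta_gc3 = 0.5,
                           theta_gc3_sd = 0.05,
                           preference_concentration = 5,
                           amino_acid_profile = default_aa_profile(),
                           contamination_fraction = 0.006,
                           utr_length = c(50, 150),
                           ua_penalty = 1,
                           minus_strand_fraction = 0.1,
                           seed = 1) {
  if (missing(species_label) || !nzchar(species_label))
    stopf("species_label is required")
  if (n_genes < 1) stopf("n_genes must be >= 1")
  if (min_gene_length < 1) stopf("min_gene_length must be >= 1")
  if (theta_gc3 <= 0 || theta_gc3 >= 1)
    stopf("theta_gc3 must be strictly inside (0, 1)")
  if (theta_gc3_sd < 0) stopf("theta_gc3_sd must be >= 0")
  if (preference_concentration <= 0)
    stopf("preference_concentration must be > 0")
  if (contamination_fraction < 0 || contamination_fraction > 1)
    stopf("contamination_fraction must be in [0, 1]")
  if (length(utr_length) != 2 || any(utr_length < 0) ||
      utr_length[1] > utr_length[2])
    stopf("utr_length must be a non-decreasing pair of non-negative ints")
  if (ua_penalty <= 0) stopf("ua_penalty must be > 0")
  prof <- amino_acid_profile[sort(names(amino_acid_profile))]
  if (!identical(names(prof), sort(names(default_aa_profile()))))
    stopf("amino_acid_profile must name the 20 standard amino acids")
  if (any(prof < 0) || sum(prof) <= 0)
    stopf("amino_acid_profile must be non-negative with positive sum")
  prof <- prof / sum(prof)
  structure(list(species_label = species_label, n_genes = as.integer(n_genes),
                 gene_length_meanlog = gene_length_meanlog,
                 gene_length_sdlog = gene_length_sdlog,
                 min_gene_length = as.integer(min_gene_length),
                 theta_gc3 = theta_gc3, theta_gc3_sd = theta_gc3_sd,
                 preference_concentration = preference_concentration,
                 amino_acid_profile = prof,
                 contamination_fraction = contamination_fraction,
                 utr_length = as.integer(utr_length),
                 ua_penalty = ua_penalty,
                 minus_strand_fraction = minus_strand_fraction,
                 seed = as.integer(seed)),
            class = "generator_spec")
}

# symmetric Dirichlet draw
.rdirichlet1 <- function(k, alpha) {
  g <- stats::rgamma(k, shape = alpha)
  if (sum(g) == 0) g <- rep(1, k)
  g / sum(g)
}

# per-species within-class codon weights: list aa -> named weights over
# the family, normalised within GC class and AT class separately
.draw_class_weights <- function(spec) {
  out <- list()
  for (aa in names(.FAMILIES)) {
    fam <- .FAMILIES[[aa]]
    if (length(fam) < 2) {
      out[[aa]] <- stats::setNames(rep(1, length(fam)), fam)
      next
    }
    w <- stats::setNames(numeric(length(fam)), fam)
    for (cls in list(fam[.THIRD_GC[fam]], fam[!.THIRD_GC[fam]])) {
      wc <- .rdirichlet1(length(cls), spec$preference_concentration)
      ta <- substr(cls, 2, 3) == "TA" | endsWith(cls, "TA")
      wc[ta] <- wc[ta] * spec$ua_penalty
      w[cls] <- wc / sum(wc)
    }
    out[[aa]] <- w
  }
  out
}

# full codon probability vector over the 61 sense codons for one gene
.codon_probs <- function(theta, prof, weights) {
  p <- stats::setNames(numeric(length(.SENSE_CODONS)), .SENSE_CODONS)
  for (aa in names(.FAMILIES)) {
    fam <- .FAMILIES[[aa]]
    if (length(fam) == 1) {
      p[fam] <- prof[aa]
      next
    }
    w <- weights[[aa]]
    gc_cls <- fam[.THIRD_GC[fam]]
    at_cls <- fam[!.THIRD_GC[fam]]
    p[gc_cls] <- prof[aa] * theta * w[gc_cls]
    p[at_cls] <- prof[aa] * (1 - theta) * w[at_cls]
  }
  p
}

.rand_utr <- function(len) {
  if (len == 0) return("")
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

#' Generate one synthetic species transcriptome
#'
#' Emits transcripts (ORFs embedded between random UTRs, a configurable
#' fraction reverse-strand), one BLAST-tabular hit per gene covering at
#' least 90 percent of the true ORF in whole codons with e-value below
#' `1e-12`, and a truth table.  Clean genes contain no in-frame stops;
#' contaminant genes carry 1--3.  Given the same spec (including seed),
#' output is reproducible byte for byte.
#'
#' @param spec a [generator_spec()].
#' @return list with elements `transcripts` (data frame `id`,
#'   `sequence`, `description`), `hits` (13-column BLAST-tabular data
#'   frame including `frame`), `truth` (per-gene data frame: coordinates,
#'   strand, gene theta, contamination), `preferred` (data frame
#'   `amino_acid`, `codon`: the generator's most likely codon per
#'   family), and `spec`.
#' @export
generate_species <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  with_seed(spec$seed, {
    n <- spec$n_genes
    weights <- .draw_class_weights(spec)
    # most likely codon per multi-codon family at the species-mean theta
    pref <- lapply(names(.FAMILIES), function(aa) {
      fam <- .FAMILIES[[aa]]
      if (length(fam) < 2) return(NULL)
      p <- .codon_probs(spec$theta_gc3, spec$amino_acid_profile,
                        weights)[fam]
      data.frame(amino_acid = aa, codon = fam[which.max(p)],
                 stringsAsFactors = FALSE)
    })
    pref <- do.call(rbind, Filter(Negate(is.null), pref))

    lens <- pmax(spec$min_gene_length,
                 round(stats::rlnorm(n, spec$gene_length_meanlog,
                                     spec$gene_length_sdlog)))
    thetas <- if (spec$theta_gc3_sd > 0) {
      v <- min(spec$theta_gc3_sd,
               sqrt(spec$theta_gc3 * (1 - spec$theta_gc3)) * 0.95)^2
      nu <- spec$theta_gc3 * (1 - spec$theta_gc3) / v - 1
      stats::rbeta(n, spec$theta_gc3 * nu, (1 - spec$theta_gc3) * nu)
    } else rep(spec$theta_gc3, n)
    is_cont <- stats::runif(n) < spec$contamination_fraction
    minus <- stats::runif(n) < spec$minus_strand_fraction
    u5 <- sample(seq(spec$utr_length[1], spec$utr_length[2]), n,
                 replace = TRUE)
    u3 <- sample(seq(spec$utr_length[1], spec$utr_length[2]), n,
                 replace = TRUE)
    ids <- sprintf("%s_g%05d", spec$species_label, seq_len(n))

    orfs <- character(n)
    n_stops <- integer(n)
    for (i in seq_len(n)) {
      p <- .codon_probs(thetas[i], spec$amino_acid_profile, weights)
      cod <- sample(names(p), lens[i], replace = TRUE, prob = p)
      if (is_cont[i] && lens[i] >= 4) {
        k <- sample(1:3, 1)
        pos <- sample(seq(2, lens[i] - 1), min(k, lens[i] - 2))
        cod[pos] <- sample(.STOP_CODONS, length(pos), replace = TRUE)
        n_stops[i] <- length(pos)
      }
      orfs[i] <- paste(cod, collapse = "")
    }

    transcripts <- character(n)
    for (i in seq_len(n)) {
      body <- if (minus[i]) revcomp(orfs[i]) else orfs[i]
      transcripts[i] <- paste0(.rand_utr(u5[i]), body, .rand_utr(u3[i]))
    }

    # one hit per gene, trimmed in whole codons, covering >= ~94%
    full <- stats::runif(n) < 0.85
    mx <- pmax(1L, floor(0.03 * lens))
    t5 <- ifelse(full, 0L,
                 vapply(mx, function(m) sample(0:m, 1), integer(1)))
    t3 <- ifelse(full, 0L,
                 vapply(mx, function(m) sample(0:m, 1), integer(1)))
    cov_len <- lens - t5 - t3
    qstart <- ifelse(minus, u5 + 1 + 3 * t3, u5 + 1 + 3 * t5)
    qend <- ifelse(minus, u5 + 3 * (lens - t5), u5 + 3 * (lens - t3))
    frame <- ifelse(minus,
                    -(((nchar(transcripts) - qend) %% 3) + 1),
                    ((qstart - 1) %% 3) + 1)
    pid <- round(stats::runif(n, 40, 98), 2)
    alen <- cov_len
    evalue <- 10^(-stats::runif(n, 13, 180))
    hits <- data.frame(
      query_id = ids,
      subject_id = sprintf("ref_%05d", sample.int(99999, n)),
      percent_identity = pid,
      alignment_length = alen,
      mismatches = as.integer(round(alen * (1 - pid / 100))),
      gap_opens = 0L,
      query_start = as.integer(qstart),
      query_end = as.integer(qend),
      subject_start = as.integer(t5 + 1),
      subject_end = as.integer(t5 + cov_len),
      e_value = evalue,
      bit_score = round(alen * stats::runif(n, 1.5, 2.2), 1),
      frame = as.integer(frame),
      stringsAsFactors = FALSE)

    truth <- data.frame(
      id = ids,
      orf_start = as.integer(u5 + 1),
      orf_end = as.integer(u5 + 3 * lens),
      strand = ifelse(minus, "-", "+"),
      length_codons = as.integer(lens),
      theta_gc3 = thetas,
      is_contaminant = is_cont,
      n_stops = n_stops,
      orf = orfs,
      stringsAsFactors = FALSE)

    list(transcripts = data.frame(id = ids, sequence = transcripts,
                                  description = "", stringsAsFactors = FALSE),
         hits = hits,
         truth = truth,
         preferred = pref,
         spec = spec)
  })
}

#' Generate a panel of synthetic species
#'
#' @param specs list of [generator_spec()]s with distinct labels.
#' @return list with `bundles` (named list of [generate_species()]
#'   results) and `manifest` (one row per species: label, n_genes,
#'   theta_gc3, contamination, seed).
#' @export
generate_panel <- function(specs) {
  if (length(specs) == 0) stopf("specs must contain at least one species")
  labels <- vapply(specs, `[[`, character(1), "species_label")
  if (anyDuplicated(labels))
    stopf("duplicate species labels: %s",
          paste(unique(labels[duplicated(labels)]), collapse = ", "))
  bundles <- lapply(specs, generate_species)
  names(bundles) <- labels
  manifest <- data.frame(
    species = labels,
    n_genes = vapply(specs, `[[`, integer(1), "n_genes"),
    theta_gc3 = vapply(specs, `[[`, numeric(1), "theta_gc3"),
    contamination_fraction = vapply(specs, `[[`, numeric(1),
                                    "contamination_fraction"),
    seed = vapply(specs, `[[`, integer(1), "seed"),
    stringsAsFactors = FALSE)
  list(bundles = bundles, manifest = manifest)
}

#' Convenience constructor for a GC-gradient species panel
#'
#' A panel of species whose mean third-position GC bias spans
#' `theta_range` in equal steps — the shape of a set of coding
#' transcriptomes ordered by GC content.
#'
#' @param n_species number of species (default 15).
#' @param theta_range range of `theta_gc3` across the panel (default
#'   0.55 to 0.89).
#' @param n_genes genes per species (default 500).
#' @param seed base seed; each species gets a distinct seed derived from
#'   it.
#' @param ... further arguments passed to [generator_spec()].
#' @return list of [generator_spec()]s.
#' @export
panel_specs <- function(n_species = 15, theta_range = c(0.55, 0.89),
                        n_genes = 500, seed = 1, ...) {
  thetas <- seq(theta_range[1], theta_range[2], length.out = n_species)
  lapply(seq_len(n_species), function(i) {
    generator_spec(species_label = sprintf("sp%02d", i),
                   n_genes = n_genes, theta_gc3 = thetas[i],
                   seed = (seed + 101L * i) %% .Machine$integer.max, ...)
  })
}

#' Write a generated species bundle to disk
#'
#' Writes `<label>.fasta` (60-column wrapped), `<label>_hits.tsv`
#' (13-column BLAST tabular) and `<label>_truth.tsv`.
#'
#' @param bundle a [generate_species()] result.
#' @param dir output directory (created if needed).
#' @return named character vector of the three paths, invisibly.
#' @export
write_species_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  lab <- bundle$spec$species_label
  fa <- file.path(dir, paste0(lab, ".fasta"))
  ht <- file.path(dir, paste0(lab, "_hits.tsv"))
  tr <- file.path(dir, paste0(lab, "_truth.tsv"))
  write_fasta(bundle$transcripts, fa)
  write_blast_table(bundle$hits, ht)
  write_tsv(bundle$truth[, setdiff(names(bundle$truth), "orf")], tr)
  invisible(c(fasta = fa, hits = ht, truth = tr))
}
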