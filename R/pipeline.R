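# End-to-end orchestration: extract -> metrics -> CA -> composition,
# with all figure/table data written as bit-stable TSVs.

#' Run configuration for one species
#'
#' @param fasta path to the transcript FASTA.
#' @param blast path to the BLAST tabular hit file.
#' @param species_label species name used in outputs.
#' @param outdir output directory for the TSV artifacts.
#' @param min_length transcript length filter, exclusive (default 500).
#' @param e_value_max BLAST e-value threshold, exclusive (default
#'   `1e-10`).
#' @param min_gene_codons minimum codons per gene for indices (default
#'   30).
#' @param ca_axes correspondence-analysis axes kept (default 4).
#' @param optimal_quantile extreme-group quantile for optimal-codon
#'   inference (default 0.05).
#' @param seed seed for any stochastic step (default 1).
#' @param blast_col_names optional column order for
#'   [read_blast_table()].
#' @return object of class `run_config`.
#' @export
run_config <- function(fasta, blast, species_label, outdir,
                       min_length = 500, e_value_max = 1e-10,
                       min_gene_codons = 30, ca_axes = 4,
                       optimal_quantile = 0.05, seed = 1,
                       blast_col_names = NULL) {
  if (min_length < 0 || e_value_max <= 0 || min_gene_codons < 1)
    stopf("thresholds must be positive")
  structure(list(fasta = fasta, blast = blast,
                 species_label = species_label, outdir = outdir,
                 min_length = min_length, e_value_max = e_value_max,
                 min_gene_codons = min_gene_codons, ca_axes = ca_axes,
                 optimal_quantile = optimal_quantile, seed = seed,
                 blast_col_names = blast_col_names),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Reads a YAML mapping whose keys are the arguments of [run_config()];
#' explicitly supplied arguments in `...` override the file.
#'
#' @param path YAML file.
#' @param ... overrides passed on to [run_config()].
#' @return object of class `run_config`.
#' @export
read_run_config <- function(path, ...) {
  cfg <- yaml::read_yaml(path)
  dots <- list(...)
  cfg[names(dots)] <- dots
  do.call(run_config, cfg)
}

#' Run the full pipeline for one species
#'
#' Reads the transcripts and hits, applies the length and e-value
#' filters, extracts frame-+1 coding regions, fits [codon_usage()], and
#' writes the stage TSVs into `config$outdir`: `coding_regions.tsv`,
#' `gene_indices.tsv`, `rscu_long.tsv`, `species_summary.tsv`,
#' `ca_coordinates.tsv`, `dinucleotide_ratios.tsv`,
#' `bias_flags_per_codon.tsv` and `codon_frequency_stats.tsv`.
#' Record counts in and out of every filter are reported via
#' [message()].
#'
#' @param config a [run_config()].
#' @return the [codon_usage()] fit, invisibly, with attribute `paths`
#'   naming the written files.
#' @export
run_species <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  lab <- config$species_label

  records <- read_fasta(config$fasta)
  message(sprintf("[%s] read_fasta: %d records", lab, nrow(records)))
  kept <- filter_by_length(records, config$min_length)
  message(sprintf("[%s] filter_by_length(>%d): %d -> %d records", lab,
                  config$min_length, nrow(records), nrow(kept)))
  hits <- read_blast_table(config$blast, col_names = config$blast_col_names)
  top <- select_top_hits(hits, config$e_value_max)
  message(sprintf("[%s] select_top_hits(<%g): %d hits -> %d queries", lab,
                  config$e_value_max, nrow(hits), nrow(top)))
  top <- top[top$query_id %in% kept$id, , drop = FALSE]
  coding <- extract_coding_regions(kept, top, species_label = lab)
  message(sprintf("[%s] extract_coding_regions: %d coding regions", lab,
                  nrow(coding)))

  paths <- character(0)
  out <- function(name) file.path(config$outdir, name)
  write_tsv(coding[, c("id", "source_start", "source_end", "strand",
                       "n_codons", "internal_stops")],
            out("coding_regions.tsv"))
  paths["coding_regions"] <- out("coding_regions.tsv")

  if (nrow(coding) == 0) {
    warnf("[%s] no coding regions extracted; writing empty outputs", lab)
    empty <- data.frame()
    write_tsv(data.frame(species = lab, genes = 0L, codons = 0L,
                         stops = 0L, cbi = NA, fop = NA, nc = NA,
                         gc3s = NA, transcriptome_gc = NA),
              out("species_summary.tsv"))
    return(invisible(structure(list(species = lab, summary = empty),
                               paths = paths, class = "codon_usage")))
  }

  fit <- with_seed(config$seed,
                   codon_usage(coding, species = lab, optimal = "ca",
                               min_codons = config$min_gene_codons,
                               ca_axes = config$ca_axes,
                               optimal_quantile = config$optimal_quantile))

  gi <- fit$indices
  write_tsv(data.frame(id = gi$id, n_codons = gi$n_codons, nc = gi$nc,
                       gc = gi$gc, gc1 = gi$gc1, gc2 = gi$gc2,
                       gc3 = gi$gc3, gc3s = gi$gc3s, cbi = gi$cbi,
                       fop = gi$fop), out("gene_indices.tsv"))
  paths["gene_indices"] <- out("gene_indices.tsv")

  rs <- fit$rscu[.VARIABLE_CODONS]
  write_tsv(data.frame(species = lab, codon = names(rs),
                       amino_acid = unname(.CODON_AA[names(rs)]),
                       rscu = unname(rs),
                       gc_weight = unname(codon_gc_weight(names(rs)))),
            out("rscu_long.tsv"))
  paths["rscu_long"] <- out("rscu_long.tsv")

  write_tsv(fit$summary[, c("species", "genes", "codons", "stops", "cbi",
                            "fop", "nc", "gc3s", "transcriptome_gc")],
            out("species_summary.tsv"))
  paths["species_summary"] <- out("species_summary.tsv")

  if (!is.null(fit$ca)) {
    rc <- fit$ca$row_coordinates
    ids <- rownames(rc)
    mi <- match(ids, gi$id)
    cadf <- data.frame(gene = ids, rc,
                       gc3s = gi$gc3s[mi], nc = gi$nc[mi],
                       stringsAsFactors = FALSE)
    write_tsv(cadf, out("ca_coordinates.tsv"))
    paths["ca_coordinates"] <- out("ca_coordinates.tsv")
  }

  if (!is.null(fit$dinucleotide)) {
    d <- fit$dinucleotide
    write_tsv(data.frame(species = lab, d), out("dinucleotide_ratios.tsv"))
    paths["dinucleotide_ratios"] <- out("dinucleotide_ratios.tsv")
  }
  if (!is.null(fit$flags)) {
    write_tsv(data.frame(codon = names(fit$flags$per_codon), species = lab,
                         count = as.integer(fit$flags$per_codon)),
              out("bias_flags_per_codon.tsv"))
    paths["bias_flags_per_codon"] <- out("bias_flags_per_codon.tsv")
    write_tsv(data.frame(species = lab, fit$codon_stats),
              out("codon_frequency_stats.tsv"))
    paths["codon_frequency_stats"] <- out("codon_frequency_stats.tsv")
  }
  attr(fit, "paths") <- paths
  invisible(fit)
}

#' Run the pipeline over a panel of species
#'
#' Runs [run_species()] per configuration and writes the panel-level
#' tables into `outdir`: `panel_summary.tsv` (one summary row per
#' species), `gc_by_position.tsv` (pooled positional GC versus overall
#' GC), `enc_observed.tsv` (species Nc versus GC3s with null-curve
#' expectation and offset), `enc_curve.tsv` (the simulated null curve)
#' and `rscu_by_gc_weight.tsv` (pooled RSCU long table across species).
#'
#' @param configs list of [run_config()]s.
#' @param outdir panel output directory (default: directory of the
#'   first config's outdir).
#' @param curve optional precomputed [enc_null_curve()]; simulated with
#'   the first config's seed when omitted.
#' @return list with `fits`, `summary`, `gc_by_position`, `enc`,
#'   `curve`, invisibly.
#' @export
run_panel <- function(configs, outdir = NULL, curve = NULL) {
  if (length(configs) == 0) stopf("configs must contain at least one run")
  outdir <- outdir %||% dirname(configs[[1]]$outdir)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  fits <- lapply(configs, run_species)
  labels <- vapply(configs, `[[`, character(1), "species_label")
  names(fits) <- labels

  summaries <- do.call(rbind, lapply(fits, function(f) f$summary))
  rownames(summaries) <- NULL
  write_tsv(summaries[, c("species", "genes", "codons", "stops", "cbi",
                          "fop", "nc", "gc3s", "transcriptome_gc")],
            file.path(outdir, "panel_summary.tsv"))

  gcpos <- do.call(rbind, lapply(fits, function(f) {
    g <- gc_by_position(colSums(f$counts))
    data.frame(species = f$species, transcriptome_gc = unname(g["gc"]),
               gc1 = unname(g["gc1"]), gc2 = unname(g["gc2"]),
               gc3 = unname(g["gc3"]), stringsAsFactors = FALSE)
  }))
  rownames(gcpos) <- NULL
  write_tsv(gcpos, file.path(outdir, "gc_by_position.tsv"))

  if (is.null(curve))
    curve <- enc_null_curve(seed = configs[[1]]$seed)
  write_tsv(curve$binned, file.path(outdir, "enc_curve.tsv"))
  enc <- suppressWarnings(enc_offset(summaries, curve))
  write_tsv(enc, file.path(outdir, "enc_observed.tsv"))

  rscu_long <- do.call(rbind, lapply(fits, function(f) {
    rs <- f$rscu[.VARIABLE_CODONS]
    data.frame(species = f$species, codon = names(rs),
               amino_acid = unname(.CODON_AA[names(rs)]),
               rscu = unname(rs),
               gc_weight = unname(codon_gc_weight(names(rs))),
               stringsAsFactors = FALSE)
  }))
  rownames(rscu_long) <- NULL
  write_tsv(rscu_long, file.path(outdir, "rscu_by_gc_weight.tsv"))

  invisible(list(fits = fits, summary = summaries,
                 gc_by_position = gcpos, enc = enc, curve = curve))
}
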