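# BLAST-guided coding-region extraction: length filter, top-hit selection,
# frame-correct extraction in +1, and internal stop tabulation.

#' Filter transcripts by length
#'
#' Retains records whose sequence is strictly longer than `min_length`
#' (the pre-filter applied before BLAST-guided extraction; the default
#' 500 keeps assembled sequences greater than 500 bases).
#'
#' @param records transcript data frame from [read_fasta()].
#' @param min_length minimum length in nucleotides, exclusive (default 500).
#' @return the surviving rows of `records`.
#' @export
filter_by_length <- function(records, min_length = 500) {
  if (min_length < 0) stopf("min_length must be >= 0")
  records[nchar(records$sequence) > min_length, , drop = FALSE]
}

#' Select the top BLAST hit per query
#'
#' Discards hits with e-value at or above `e_value_max` (strict
#' "less than"), then keeps one hit per query id: lowest e-value, ties
#' broken by highest bit score, then by input order.
#'
#' @param hits hit data frame from [read_blast_table()].
#' @param e_value_max e-value threshold, exclusive (default `1e-10`).
#' @return one row per surviving query id, in first-appearance order.
#' @export
select_top_hits <- function(hits, e_value_max = 1e-10) {
  if (!is.numeric(e_value_max) || e_value_max <= 0)
    stopf("e_value_max must be > 0")
  keep <- hits[hits$e_value < e_value_max, , drop = FALSE]
  if (nrow(keep) == 0) return(keep)
  keep$.ord <- seq_len(nrow(keep))
  keep <- keep[order(keep$query_id, keep$e_value, -keep$bit_score, keep$.ord), ,
               drop = FALSE]
  top <- keep[!duplicated(keep$query_id), , drop = FALSE]
  top <- top[order(match(top$query_id, hits$query_id)), , drop = FALSE]
  top$.ord <- NULL
  rownames(top) <- NULL
  top
}

# count in-frame stop codons of a frame-+1 sequence
count_internal_stops <- function(sequence) {
  n <- nchar(sequence)
  if (n < 3) return(0L)
  cod <- substring(sequence, seq(1, n - 2, 3), seq(3, n, 3))
  sum(cod %in% .STOP_CODONS)
}

#' Extract the coding region covered by a BLAST hit
#'
#' Takes the query nucleotides between the hit's start and end
#' coordinates (1-based inclusive), reverse-complements when the hit
#' frame is negative (or when `query_start > query_end` and no frame is
#' given), and trims the 3' end to a multiple of three so that the
#' result is in reading frame +1 anchored at the hit start.  In-frame
#' stop codons (`TAA`/`TAG`/`TGA`) are counted as a contamination
#' indicator.
#'
#' @param record one transcript row (list or single-row data frame with
#'   `id` and `sequence`).
#' @param hit one BLAST hit row for that transcript.
#' @param species_label label stored with the output (default "").
#' @return one-row data frame: `id`, `species`, `nucleotides`,
#'   `source_start`, `source_end`, `strand` (`+`/`-`), `n_codons`,
#'   `internal_stops`.
#' @export
extract_coding_region <- function(record, hit, species_label = "") {
  if (record$id != hit$query_id)
    stopf("hit query id '%s' does not match record id '%s'",
          hit$query_id, record$id)
  qs <- as.integer(hit$query_start)
  qe <- as.integer(hit$query_end)
  frame <- if (!is.null(hit$frame) && !is.na(hit$frame)) as.integer(hit$frame)
           else NA_integer_
  minus <- if (!is.na(frame)) frame < 0 else qs > qe
  lo <- min(qs, qe); hi <- max(qs, qe)
  n <- nchar(record$sequence)
  if (lo < 1 || hi > n)
    stopf("hit coordinates %d..%d exceed sequence '%s' of length %d",
          lo, hi, record$id, n)
  seg <- substr(record$sequence, lo, hi)
  if (minus) seg <- revcomp(seg)
  keep <- (nchar(seg) %/% 3) * 3
  if (keep == 0)
    stopf("alignment on '%s' shorter than one codon", record$id)
  seg <- substr(seg, 1, keep)
  data.frame(id = record$id,
             species = species_label,
             nucleotides = seg,
             source_start = lo,
             source_end = hi,
             strand = if (minus) "-" else "+",
             n_codons = keep %/% 3L,
             internal_stops = count_internal_stops(seg),
             stringsAsFactors = FALSE)
}

#' Extract coding regions for all transcripts with a top hit
#'
#' Vectorised driver for [extract_coding_region()]: pairs each top hit
#' with its transcript and extracts the frame-+1 coding region.
#' Transcripts without a hit are skipped.
#'
#' @param records transcript data frame (after any length filter).
#' @param hits one-hit-per-query data frame from [select_top_hits()].
#' @param species_label species label stored with each output row.
#' @return data frame of coding regions, one row per extracted gene.
#' @export
extract_coding_regions <- function(records, hits, species_label = "") {
  idx <- match(hits$query_id, records$id)
  use <- which(!is.na(idx))
  out <- vector("list", length(use))
  for (k in seq_along(use)) {
    i <- use[k]
    out[[k]] <- extract_coding_region(
      list(id = records$id[idx[i]], sequence = records$sequence[idx[i]]),
      hits[i, , drop = FALSE], species_label)
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(id = character(), species = character(),
                      nucleotides = character(), source_start = integer(),
                      source_end = integer(), strand = character(),
                      n_codons = integer(), internal_stops = integer(),
                      stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

#' Tabulate internal stop codons across a coding set
#'
#' Internal in-frame stops should be absent from genuine coding regions
#' under the standard code, so their prevalence estimates the fraction
#' of contaminating or mis-framed sequences.
#'
#' @param coding data frame from [extract_coding_regions()] (needs an
#'   `internal_stops` column, or `nucleotides` to recompute it).
#' @return list with `total_stops` (sum of in-frame stops) and
#'   `stop_fraction` (fraction of sequences with at least one stop).
#' @export
tabulate_stops <- function(coding) {
  if (nrow(coding) == 0) return(list(total_stops = 0L, stop_fraction = 0))
  stops <- coding$internal_stops
  if (is.null(stops))
    stops <- vapply(coding$nucleotides, count_internal_stops, integer(1))
  list(total_stops = as.integer(sum(stops)),
       stop_fraction = mean(stops > 0))
}
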