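#' Read transcript sequences from a FASTA file
#'
#' Reads nucleotide FASTA into a plain data frame of transcript records.
#' Sequences are uppercased and `U` is mapped to `T` so downstream codon
#' arithmetic works on one DNA alphabet; ambiguity `N`s are retained
#' (codons containing them are skipped, not guessed, by the counting
#' functions).
#'
#' @param path path to a FASTA file.
#' @return data frame with columns `id` (first whitespace-delimited token
#'   of the header), `sequence`, `description` (remainder of the header).
#' @details Duplicate ids are an error; characters outside `A,C,G,T,N`
#'   (after the `U -> T` mapping) are an error naming the offending
#'   record.  An empty file returns zero rows with a warning.
#' @seealso [write_fasta()], [read_blast_table()]
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stopf("FASTA file not found: %s", path)
  if (!any(startsWith(readLines(path, warn = FALSE), ">"))) {
    warnf("FASTA file %s contains no sequences", path)
    return(data.frame(id = character(), sequence = character(),
                      description = character(), stringsAsFactors = FALSE))
  }
  recs <- tryCatch(
    seqinr::read.fasta(path, seqtype = "DNA", as.string = TRUE,
                       forceDNAtolower = FALSE, whole.header = TRUE),
    error = function(e) stopf("malformed FASTA in %s: %s", path,
                              conditionMessage(e)))
  if (length(recs) == 0) {
    warnf("FASTA file %s contains no sequences", path)
    return(data.frame(id = character(), sequence = character(),
                      description = character(), stringsAsFactors = FALSE))
  }
  headers <- vapply(recs, function(r) attr(r, "name"), character(1))
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  if (anyDuplicated(ids))
    stopf("duplicate FASTA ids in %s: %s", path,
          paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- chartr("uU", "tT", toupper(vapply(recs, as.character, character(1))))
  seqs <- toupper(seqs)
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad))
    stopf("record '%s' in %s contains characters outside A/C/G/T/N/U",
          ids[which(bad)[1]], path)
  if (any(!nzchar(seqs)))
    stopf("record '%s' in %s has an empty sequence",
          ids[which(!nzchar(seqs))[1]], path)
  data.frame(id = ids, sequence = unname(seqs), description = unname(desc),
             stringsAsFactors = FALSE)
}

#' Write sequences as wrapped FASTA
#'
#' @param x data frame with columns `id` and `sequence` (and optionally
#'   `description`), as returned by [read_fasta()], or a named character
#'   vector of sequences.
#' @param path output path.
#' @param width line width for sequence wrapping (default 60).
#' @return the path, invisibly.
#' @export
write_fasta <- function(x, path, width = 60) {
  if (is.character(x)) {
    x <- data.frame(id = names(x) %||% paste0("seq", seq_along(x)),
                    sequence = unname(x), stringsAsFactors = FALSE)
  }
  nm <- x$id
  if (!is.null(x$description))
    nm <- ifelse(nzchar(x$description), paste(x$id, x$description), x$id)
  seqinr::write.fasta(as.list(x$sequence), names = nm,
                      file.out = path, nbchar = width, as.string = TRUE)
  invisible(path)
}

.BLAST6_COLS <- c("query_id", "subject_id", "percent_identity",
                  "alignment_length", "mismatches", "gap_opens",
                  "query_start", "query_end", "subject_start",
                  "subject_end", "e_value", "bit_score")

#' Read BLAST tabular (outfmt 6) hits
#'
#' Parses the 12-column BLAST/tBLASTn tabular format, with an optional
#' 13th `frame` column (values in -3..-1, 1..3) as produced by adding
#' `qframe`/`sframe` to the output format.
#'
#' @param path path to a tab-separated hit table without header.
#' @param col_names optional character vector naming the columns in file
#'   order, for non-default column arrangements.  Must contain the
#'   standard names `query_id`, `subject_id`, `percent_identity`,
#'   `alignment_length`, `mismatches`, `gap_opens`, `query_start`,
#'   `query_end`, `subject_start`, `subject_end`, `e_value`, `bit_score`
#'   and optionally `frame`.
#' @return data frame of hits, one row per HSP, in input order.
#' @export
read_blast_table <- function(path, col_names = NULL) {
  if (!file.exists(path)) stopf("BLAST table not found: %s", path)
  raw <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                           comment.char = "#")
  if (nrow(raw) == 0)
    return(stats::setNames(
      as.data.frame(matrix(nrow = 0, ncol = 13)), c(.BLAST6_COLS, "frame")))
  if (is.null(col_names)) {
    col_names <- if (ncol(raw) >= 13) c(.BLAST6_COLS, "frame") else .BLAST6_COLS
  }
  if (ncol(raw) < length(col_names))
    stopf("BLAST table %s has %d columns; %d expected", path, ncol(raw),
          length(col_names))
  raw <- raw[, seq_along(col_names)]
  names(raw) <- col_names
  missing <- setdiff(.BLAST6_COLS, col_names)
  if (length(missing))
    stopf("col_names is missing required columns: %s",
          paste(missing, collapse = ", "))
  num <- intersect(c("percent_identity", "alignment_length", "mismatches",
                     "gap_opens", "query_start", "query_end",
                     "subject_start", "subject_end", "e_value", "bit_score",
                     "frame"), names(raw))
  for (cn in num) raw[[cn]] <- as.numeric(raw[[cn]])
  if (any(raw$e_value < 0)) stopf("negative e-values in %s", path)
  if (any(raw$query_start < 1)) stopf("query_start < 1 in %s", path)
  raw
}

#' Write BLAST tabular hits
#'
#' @param hits data frame as returned by [read_blast_table()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_blast_table <- function(hits, path) {
  cols <- intersect(c(.BLAST6_COLS, "frame"), names(hits))
  utils::write.table(hits[, cols], file = path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE, eol = "\n")
  invisible(path)
}
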