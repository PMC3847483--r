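HIT_COLS <- c("query_id", "subject_id", "raw_score", "bitscore", "evalue",
              "pident", "qcov", "qstart", "qend", "sstart", "send")

empty_hits <- function() {
  data.frame(query_id = character(0), subject_id = character(0),
             raw_score = numeric(0), bitscore = numeric(0),
             evalue = numeric(0), pident = numeric(0), qcov = numeric(0),
             qstart = integer(0), qend = integer(0),
             sstart = integer(0), send = integer(0),
             stringsAsFactors = FALSE)
}

#' Read tabular BLAST output (12-column outfmt 6)
#'
#' Adapter so that real BLAST alignments can substitute the internal
#' Smith–Waterman engine anywhere a hit table is consumed. Expects the
#' standard 12 tab-separated columns (`qseqid sseqid pident length mismatch
#' gapopen qstart qend sstart send evalue bitscore`). BLAST does not emit
#' query coverage, so it is recomputed as `100 * (qend - qstart + 1) /
#' query_length` from a supplied query-length table.
#'
#' @param path path to the tabular file.
#' @param query_lengths named numeric vector mapping every query id that
#'   occurs in the file to its sequence length (e.g. from a [seq_set()] via
#'   `setNames(nchar(x$residues), x$id)`).
#' @return A hit data frame with columns `query_id`, `subject_id`,
#'   `raw_score` (`NA` for imported hits), `bitscore`, `evalue`, `pident`,
#'   `qcov`, `qstart`, `qend`, `sstart`, `send`.
#' @export
read_blast_tab <- function(path, query_lengths) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) return(empty_hits())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nfield <- lengths(parts)
  if (any(nfield != 12L)) {
    bad <- which(nfield != 12L)[1L]
    stop("line ", bad, ": expected 12 tab-separated columns, found ",
         nfield[bad], call. = FALSE)
  }
  m <- do.call(rbind, parts)
  num <- function(j) as.numeric(m[, j])
  qid <- m[, 1L]
  unknown <- setdiff(unique(qid), names(query_lengths))
  if (length(unknown)) {
    stop("query id(s) missing from query_lengths: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  qlen <- as.numeric(query_lengths[qid])
  hits <- data.frame(
    query_id = qid, subject_id = m[, 2L],
    raw_score = NA_real_, bitscore = num(12L), evalue = num(11L),
    pident = num(3L), qcov = 100 * (num(8L) - num(7L) + 1) / qlen,
    qstart = as.integer(m[, 7L]), qend = as.integer(m[, 8L]),
    sstart = as.integer(m[, 9L]), send = as.integer(m[, 10L]),
    stringsAsFactors = FALSE)
  if (any(!is.finite(hits$evalue)) || any(!is.finite(hits$pident))) {
    stop("non-numeric pident/evalue field in ", path, call. = FALSE)
  }
  hits
}
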