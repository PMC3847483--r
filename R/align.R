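as_xstringset <- function(x, alphabet) {
  switch(alphabet,
         protein = Biostrings::AAStringSet(setNames(x$residues, x$id)),
         nucleotide = Biostrings::DNAStringSet(setNames(x$residues, x$id)))
}

as_one_record <- function(x) {
  if (inherits(x, "seq_set")) {
    if (nrow(x) != 1L) stop("expected a single sequence record", call. = FALSE)
    return(list(id = x$id, residues = x$residues,
                alphabet = seq_alphabet(x)))
  }
  if (is.list(x) && all(c("id", "residues") %in% names(x))) {
    return(list(id = x$id, residues = toupper(x$residues),
                alphabet = x$alphabet %||% NA_character_))
  }
  stop("expected a one-row seq_set or a list(id=, residues=)", call. = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Karlin–Altschul E-value and bit score for a raw alignment score
#'
#' Uses the classical formula `E = K * m * n * exp(-lambda * S)` with
#' `m` the query length, `n` the number of residues in the searched
#' database and `S` the raw Smith–Waterman score; the bit score is
#' `(lambda * S - ln K) / ln 2`. No composition-based or length
#' adjustments are applied, so E-values are reproducible but only
#' approximate those of BLAST.
#'
#' @param raw_score positive raw alignment score.
#' @param query_length positive query length (residues).
#' @param database_residues positive total residue count of the database.
#' @param scheme a [scoring_scheme()] supplying `lambda` and `K`.
#' @return list with elements `evalue` and `bitscore`.
#' @export
#' @examples
#' sc <- scoring_scheme("protein")
#' estimate_evalue(0, 1, 1, sc)$evalue  # = K = 0.041
estimate_evalue <- function(raw_score, query_length, database_residues, scheme) {
  stopifnot(inherits(scheme, "scoring_scheme"))
  if (any(query_length <= 0) || any(database_residues <= 0)) {
    stop("query_length and database_residues must be positive", call. = FALSE)
  }
  list(evalue = scheme$K * query_length * database_residues *
         exp(-scheme$lambda * raw_score),
       bitscore = (scheme$lambda * raw_score - log(scheme$K)) / log(2))
}

# Align a set of queries against one subject sequence; returns hit rows for
# alignments with positive raw score (a zero-score optimum is "no hit").
align_block <- function(queries, subject_id, subject_residues, scheme,
                        database_residues) {
  pat <- as_xstringset(queries, scheme$alphabet)
  subj <- switch(scheme$alphabet,
                 protein = Biostrings::AAString(subject_residues),
                 nucleotide = Biostrings::DNAString(subject_residues))
  aln <- Biostrings::pairwiseAlignment(
    pattern = pat, subject = subj, type = "local",
    substitutionMatrix = scheme$matrix,
    gapOpening = scheme$gap_open, gapExtension = scheme$gap_extend)
  raw <- Biostrings::score(aln)
  keep <- which(raw > 0)
  if (!length(keep)) return(empty_hits())
  pa <- strsplit(as.character(Biostrings::alignedPattern(aln)[keep]), "")
  sa <- strsplit(as.character(Biostrings::alignedSubject(aln)[keep]), "")
  # gaps and alphabet ambiguity codes never count as identities
  # (N is a plain residue in protein mode: asparagine)
  ambig <- c("-", if (scheme$alphabet == "protein") "X" else "N")
  ident <- mapply(function(p, s) {
    matches <- sum(p == s & !(p %in% ambig))
    100 * matches / length(p)
  }, pa, sa)
  qlen <- nchar(queries$residues)[keep]
  qstart <- Biostrings::start(Biostrings::pattern(aln))[keep]
  qend <- Biostrings::end(Biostrings::pattern(aln))[keep]
  ka <- estimate_evalue(raw[keep], qlen, database_residues, scheme)
  data.frame(
    query_id = queries$id[keep], subject_id = subject_id,
    raw_score = raw[keep], bitscore = ka$bitscore, evalue = ka$evalue,
    pident = ident, qcov = 100 * (qend - qstart + 1) / qlen,
    qstart = qstart, qend = qend,
    sstart = Biostrings::start(Biostrings::subject(aln))[keep],
    send = Biostrings::end(Biostrings::subject(aln))[keep],
    stringsAsFactors = FALSE)
}

# All-vs-all alignment of two seq_sets; database_residues defaults to the
# total residue count of the subject set.
align_all <- function(queries, subjects, scheme, database_residues = NULL) {
  stopifnot(inherits(queries, "seq_set"), inherits(subjects, "seq_set"))
  if (seq_alphabet(queries) != scheme$alphabet ||
      seq_alphabet(subjects) != scheme$alphabet) {
    stop("sequence alphabet does not match the scoring scheme", call. = FALSE)
  }
  if (!nrow(queries) || !nrow(subjects)) {
    stop("empty sequence set", call. = FALSE)
  }
  db <- database_residues %||% sum(nchar(subjects$residues))
  out <- lapply(seq_len(nrow(subjects)), function(j) {
    align_block(queries, subjects$id[j], subjects$residues[j], scheme, db)
  })
  do.call(rbind, out)
}

#' Smith–Waterman local alignment of two sequences
#'
#' Optimal local alignment with affine gap penalties under the scheme's
#' substitution matrix (a gap of length L costs `gap_open + L *
#' gap_extend`). Percent identity is computed over alignment columns,
#' never counting ambiguity residues (`X`/`N`) as identities; query
#' coverage is the aligned query span as a percentage of query length. An
#' optimal score of zero is reported as no hit (`NULL`) rather than a
#' degenerate alignment.
#'
#' @param query,subject one-row [seq_set()]s (or `list(id=, residues=)`)
#'   sharing the scheme's alphabet.
#' @param scheme a [scoring_scheme()].
#' @param database_residues database size used for the E-value; defaults to
#'   the subject length (single-pair search).
#' @return A one-row hit data frame (see [read_blast_tab()] for columns),
#'   or `NULL` if the optimal local alignment has score 0.
#' @export
#' @examples
#' s <- seq_set("a", "MKVLW")
#' local_align(s, seq_set("b", "MKVLW"))$pident  # 100
local_align <- function(query, subject, scheme = scoring_scheme("protein"),
                        database_residues = NULL) {
  q <- as_one_record(query)
  s <- as_one_record(subject)
  for (r in list(q, s)) {
    if (!nzchar(r$residues)) stop("empty sequence", call. = FALSE)
    if (!is.na(r$alphabet) && r$alphabet != scheme$alphabet) {
      stop("sequence alphabet does not match the scoring scheme", call. = FALSE)
    }
  }
  qset <- seq_set(q$id, q$residues, alphabet = scheme$alphabet)
  hit <- align_block(qset, s$id, toupper(s$residues), scheme,
                     database_residues %||% nchar(s$residues))
  if (!nrow(hit)) return(NULL)
  hit
}

#' All-vs-all best hits between two proteomes
#'
#' Aligns every query against every subject and returns all positive-score
#' hits ordered, within each query, by bit score (descending), E-value
#' (ascending) and subject id (ascending) — the deterministic tie-break
#' used throughout the reciprocal-best-hit machinery. E-values use the
#' total residue count of the subject set as the database size.
#'
#' @param queries,subjects [seq_set()]s on the scheme's alphabet.
#' @param scheme a [scoring_scheme()].
#' @return A hit data frame; `split(hits, hits$query_id)` yields the
#'   per-query ordered hit lists.
#' @export
best_hits <- function(queries, subjects, scheme = scoring_scheme("protein")) {
  hits <- align_all(queries, subjects, scheme)
  order_hits(hits, queries$id)
}

order_hits <- function(hits, query_order = NULL) {
  if (!nrow(hits)) return(hits)
  qf <- if (is.null(query_order)) hits$query_id
        else factor(hits$query_id, levels = query_order)
  hits <- hits[order(qf, -hits$bitscore, hits$evalue, hits$subject_id), ,
               drop = FALSE]
  rownames(hits) <- NULL
  hits
}

# Best hit per query under the (bitscore desc, evalue asc, subject asc)
# tie-break; returns one row per query id present in `hits`.
top_hits <- function(hits) {
  hits <- order_hits(hits)
  if (!nrow(hits)) return(hits)
  hits[!duplicated(hits$query_id), , drop = FALSE]
}
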