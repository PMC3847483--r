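ALPHABETS <- list(
  protein    = c("A","R","N","D","C","Q","E","G","H","I","L","K","M",
                 "F","P","S","T","W","Y","V","X"),
  nucleotide = c("A","C","G","T","N")
)

#' Construct a set of sequence records
#'
#' A `seq_set` is the package's container for a proteome, a gene set or a
#' probe library: a data frame with columns `id`, `species` and `residues`
#' and an `alphabet` attribute (`"protein"` or `"nucleotide"`). Residues are
#' stored uppercase; ids must be unique and contain no whitespace.
#'
#' @param id character vector of unique, whitespace-free identifiers.
#' @param residues character vector of sequences (case-insensitive; stored
#'   uppercase). Protein sequences may use the 20 amino acids plus `X`;
#'   nucleotide sequences `ACGT` plus `N`.
#' @param species single species label, recycled to all records.
#' @param alphabet `"protein"` or `"nucleotide"`.
#' @return A data frame of class `seq_set`.
#' @export
#' @examples
#' seq_set(c("g1", "g2"), c("MKVL", "MKIL"), species = "cassava")
seq_set <- function(id, residues, species = "", alphabet = "protein") {
  alphabet <- match.arg(alphabet, names(ALPHABETS))
  id <- as.character(id)
  residues <- toupper(as.character(residues))
  if (length(id) != length(residues)) {
    stop("'id' and 'residues' must have the same length", call. = FALSE)
  }
  x <- data.frame(id = id, species = rep_len(as.character(species), length(id)),
                  residues = residues, stringsAsFactors = FALSE)
  attr(x, "alphabet") <- alphabet
  class(x) <- c("seq_set", "data.frame")
  validate_seq_set(x)
}

validate_seq_set <- function(x) {
  alphabet <- seq_alphabet(x)
  if (anyDuplicated(x$id)) {
    dup <- unique(x$id[duplicated(x$id)])
    stop("duplicate sequence id(s): ", paste(dup, collapse = ", "), call. = FALSE)
  }
  if (any(grepl("[[:space:]]", x$id)) || any(!nzchar(x$id))) {
    stop("sequence ids must be non-empty and contain no whitespace", call. = FALSE)
  }
  if (any(!nzchar(x$residues))) {
    stop("empty sequence for record(s): ",
         paste(x$id[!nzchar(x$residues)], collapse = ", "), call. = FALSE)
  }
  ok <- ALPHABETS[[alphabet]]
  bad <- vapply(strsplit(x$residues, ""), function(r) any(!r %in% ok), logical(1))
  if (any(bad)) {
    stop("illegal ", alphabet, " residue in record(s): ",
         paste(x$id[bad], collapse = ", "), call. = FALSE)
  }
  x
}

#' @export
print.seq_set <- function(x, ...) {
  cat(sprintf("<seq_set> %d %s sequence(s)", nrow(x), seq_alphabet(x)))
  sp <- unique(x$species[nzchar(x$species)])
  if (length(sp)) cat(", species:", paste(sp, collapse = ", "))
  cat("\n")
  if (nrow(x)) {
    shown <- head(x, 6L)
    cat(sprintf("  %-20s %6s  %s\n", shown$id, nchar(shown$residues),
                substr(shown$residues, 1, 40)), sep = "")
    if (nrow(x) > 6L) cat("  ...\n")
  }
  invisible(x)
}

seq_alphabet <- function(x) attr(x, "alphabet", exact = TRUE)

seq_lengths <- function(x) setNames(nchar(x$residues), x$id)

#' Read a FASTA file into a `seq_set`
#'
#' Records keep their file order; residues are uppercased; the record id is
#' the first whitespace-delimited token of the header. Duplicate ids, empty
#' files and residues outside the declared alphabet are format errors.
#'
#' @param path path to a FASTA file.
#' @param alphabet `"protein"` or `"nucleotide"`.
#' @param species species label attached to every record.
#' @return A [seq_set()].
#' @export
read_fasta <- function(path, alphabet = "protein", species = "") {
  alphabet <- match.arg(alphabet, names(ALPHABETS))
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("malformed FASTA file '", path, "': ",
                                           conditionMessage(e), call. = FALSE))
  if (length(set) == 0L) stop("empty FASTA file: ", path, call. = FALSE)
  ids <- sub("[[:space:]].*$", "", names(set))
  seq_set(ids, as.character(set), species = species, alphabet = alphabet)
}

#' Write a `seq_set` to a FASTA file
#'
#' @param x a [seq_set()].
#' @param path output path.
#' @param width line-wrap width for residues.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, width = 60L) {
  stopifnot(inherits(x, "seq_set"))
  wrap <- function(s) {
    starts <- seq(1L, nchar(s), by = width)
    paste(substring(s, starts, pmin(starts + width - 1L, nchar(s))),
          collapse = "\n")
  }
  lines <- character(0)
  if (nrow(x)) {
    lines <- as.vector(rbind(paste0(">", x$id),
                             vapply(x$residues, wrap, character(1))))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Parse the 12-digit gene/transcript id convention
#'
#' Reconstructed-pathway maps identify proteins by a 12-digit numeral id in
#' which the first six digits are the gene id and the last six the
#' transcript id (an `xxxxxx` run marks an unassigned transcript). Ids not
#' matching `^\\d{6}_(\\d{6}|x{6})$` are treated as opaque: the gene id is
#' the id itself and the transcript id is `NA`.
#'
#' @param id character vector of sequence ids.
#' @return data frame with columns `id`, `gene_id`, `transcript_id`.
#' @export
#' @examples
#' parse_seq_ids(c("001042_001042", "003884_xxxxxx", "AT1G01050"))
parse_seq_ids <- function(id) {
  id <- as.character(id)
  hit <- grepl("^[0-9]{6}_([0-9]{6}|x{6})$", id)
  gene <- ifelse(hit, substr(id, 1L, 6L), id)
  tx <- ifelse(hit, substr(id, 8L, 13L), NA_character_)
  tx[hit & tx == "xxxxxx"] <- NA_character_
  data.frame(id = id, gene_id = gene, transcript_id = tx,
             stringsAsFactors = FALSE)
}
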