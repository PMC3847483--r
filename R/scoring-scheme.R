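protein_matrix <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      m <- e$BLOSUM62
      keep <- ALPHABETS$protein
      m <- m[keep, keep]
      # ambiguity codes carry no evidence: X scores 0 and never counts as identity
      m["X", ] <- 0L
      m[, "X"] <- 0L
      cache <<- m
    }
    cache
  }
})

nucleotide_matrix <- function(match = 5L, mismatch = -4L) {
  b <- ALPHABETS$nucleotide
  m <- matrix(mismatch, length(b), length(b), dimnames = list(b, b))
  diag(m) <- match
  m["N", ] <- 0L
  m[, "N"] <- 0L
  m
}

#' Alignment scoring scheme
#'
#' Bundles the substitution matrix, affine gap penalties and Karlin–Altschul
#' statistical constants used by the alignment engine. A gap of length L
#' costs `gap_open + L * gap_extend` (the BLAST convention). Defaults follow
#' standard protein BLAST practice: BLOSUM62 with gap open 11 / extend 1 and
#' the published gapped constants lambda = 0.267, K = 0.041. The nucleotide
#' scheme uses match +5 / mismatch -4 with open 5 / extend 2 and the classic
#' ungapped constants lambda = 0.192, K = 0.176. Ambiguity residues (`X`,
#' `N`) score 0 against everything and never count as identities.
#'
#' @param alphabet `"protein"` or `"nucleotide"`.
#' @param gap_open,gap_extend positive integer penalties,
#'   `gap_open >= gap_extend >= 1`.
#' @param lambda,K positive Karlin–Altschul constants for the E-value model.
#' @param substitution optional substitution matrix overriding the default
#'   (rows/columns must cover the alphabet).
#' @return An object of class `scoring_scheme`.
#' @export
scoring_scheme <- function(alphabet = c("protein", "nucleotide"),
                           gap_open = NULL, gap_extend = NULL,
                           lambda = NULL, K = NULL, substitution = NULL) {
  alphabet <- match.arg(alphabet)
  defaults <- switch(alphabet,
    protein    = list(gap_open = 11L, gap_extend = 1L, lambda = 0.267,
                      K = 0.041, matrix = protein_matrix(),
                      matrix_name = "BLOSUM62"),
    nucleotide = list(gap_open = 5L, gap_extend = 2L, lambda = 0.192,
                      K = 0.176, matrix = nucleotide_matrix(),
                      matrix_name = "NUC.5.4"))
  gap_open <- if (is.null(gap_open)) defaults$gap_open else as.integer(gap_open)
  gap_extend <- if (is.null(gap_extend)) defaults$gap_extend else as.integer(gap_extend)
  lambda <- if (is.null(lambda)) defaults$lambda else lambda
  K <- if (is.null(K)) defaults$K else K
  mat <- if (is.null(substitution)) defaults$matrix else substitution
  if (!(gap_open >= gap_extend && gap_extend >= 1L)) {
    stop("require gap_open >= gap_extend >= 1", call. = FALSE)
  }
  if (!(lambda > 0 && K > 0)) stop("lambda and K must be positive", call. = FALSE)
  letters_needed <- ALPHABETS[[alphabet]]
  if (!all(letters_needed %in% rownames(mat)) ||
      !all(letters_needed %in% colnames(mat))) {
    stop("substitution matrix does not cover the ", alphabet, " alphabet",
         call. = FALSE)
  }
  structure(list(alphabet = alphabet, matrix = mat,
                 matrix_name = if (is.null(substitution)) defaults$matrix_name else "custom",
                 gap_open = gap_open, gap_extend = gap_extend,
                 lambda = lambda, K = K),
            class = "scoring_scheme")
}

#' @export
print.scoring_scheme <- function(x, ...) {
  cat(sprintf("<scoring_scheme> %s: %s, gap open %d / extend %d, lambda %.3f, K %.3f\n",
              x$alphabet, x$matrix_name, x$gap_open, x$gap_extend, x$lambda, x$K))
  invisible(x)
}

#' Export a substitution matrix as a plain-text NCBI-format table
#'
#' @param scheme a [scoring_scheme()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_scoring_matrix <- function(scheme, path) {
  stopifnot(inherits(scheme, "scoring_scheme"))
  m <- scheme$matrix
  lines <- c(paste0("# ", scheme$matrix_name),
             paste(c(" ", colnames(m)), collapse = " "),
             vapply(rownames(m), function(r) {
               paste(c(r, format(m[r, ], trim = TRUE)), collapse = " ")
             }, character(1)))
  writeLines(lines, path)
  invisible(path)
}
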