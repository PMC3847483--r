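# Independent brute-force Smith-Waterman oracle: enumerates every local
# alignment (all start cells, all move sequences, affine gap cost
# open + L * extend), with an admissible upper bound for pruning (at most
# max(mat) per remaining diagonal move; gaps only subtract). Used only in
# tests; deliberately shares no code with the package's engine.
bf_local_score <- function(a, b, mat, gap_open, gap_extend) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  m <- length(A)
  n <- length(B)
  max_cell <- max(mat)
  cost_open <- gap_open + gap_extend
  best <- 0
  rec <- function(i, j, cur, state) {
    if (cur > best) best <<- cur
    bound <- max_cell * min(m - i + 1L, n - j + 1L)
    if (bound <= 0 || cur + bound <= best) return(invisible(NULL))
    rec(i + 1L, j + 1L, cur + mat[A[i], B[j]], 1L)
    if (i < m) rec(i + 1L, j, cur - if (state == 2L) gap_extend else cost_open, 2L)
    if (j < n) rec(i, j + 1L, cur - if (state == 3L) gap_extend else cost_open, 3L)
    invisible(NULL)
  }
  for (i0 in seq_len(m)) {
    for (j0 in seq_len(n)) {
      rec(i0 + 1L, j0 + 1L, mat[A[i0], B[j0]], 1L)
    }
  }
  best
}

# all sequences of the given lengths over an alphabet
all_seqs <- function(alphabet, lengths) {
  unlist(lapply(lengths, function(L) {
    do.call(paste0, expand.grid(rep(list(alphabet), L), stringsAsFactors = FALSE))
  }))
}

random_seq <- function(alphabet, len) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

# engine raw score for two residue strings (0 when the engine reports no hit)
engine_score <- function(a, b, scheme) {
  hit <- local_align(list(id = "a", residues = a), list(id = "b", residues = b),
                     scheme)
  if (is.null(hit)) 0 else hit$raw_score
}
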