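#' Confidence-score configuration
#'
#' `n_templates` is the number of template species employed in the study
#' (N_t; five in the root-crop design this package mirrors). The region
#' thresholds carve the MS–CS plane into the three qualitative confidence
#' zones: A (low, MS below `ms_threshold`), B (high, MS at or above
#' `ms_threshold` but CS below `cs_threshold`) and C (extremely high, both
#' at or above their thresholds). The published region figure is
#' qualitative; 0.7/0.5 are this package's defaults and are configurable.
#'
#' @param n_templates positive integer N_t.
#' @param ms_threshold,cs_threshold region boundaries in (0, 1].
#' @return An object of class `score_config`.
#' @export
score_config <- function(n_templates = 5L, ms_threshold = 0.7,
                         cs_threshold = 0.5) {
  n_templates <- as.integer(n_templates)
  if (is.na(n_templates) || n_templates < 1L) {
    stop("n_templates must be a positive integer", call. = FALSE)
  }
  for (th in c(ms_threshold, cs_threshold)) {
    if (!(th > 0 && th <= 1)) {
      stop("region thresholds must lie in (0, 1]", call. = FALSE)
    }
  }
  structure(list(n_templates = n_templates, ms_threshold = ms_threshold,
                 cs_threshold = cs_threshold), class = "score_config")
}

check_evidence_df <- function(evidence) {
  if (is.null(evidence) || !is.data.frame(evidence) ||
      !all(c("H", "F") %in% names(evidence))) {
    stop("evidence must be a data frame with columns H and F", call. = FALSE)
  }
  if (!nrow(evidence)) {
    stop("empty evidence: a protein with no evidence is unannotated, not score 0",
         call. = FALSE)
  }
  if (!all(evidence$H %in% c(1, 0.5)) || !all(evidence$F %in% c(1, 0.5))) {
    stop("H and F weights must each be 1 or 0.5", call. = FALSE)
  }
  evidence
}

#' Match score (MS) of an evidence profile
#'
#' MS = sum(H_i * F_i) / N_m over the N_m evidence items of an annotation,
#' where H is the match-quality weight (1 for reciprocal best hits, 0.5 for
#' second-pass-confirmed hits) and F the function-clarity weight (1 for
#' clear template annotations, 0.5 otherwise). MS measures how well the
#' annotation is supported by the alignments that produced it, ranging up
#' to 1 for an all-RBH, all-clear profile.
#'
#' @param evidence data frame with columns `H` and `F` (one row per
#'   template species that identified the function), e.g. a subset of an
#'   [assign_functions()] result.
#' @return The match score.
#' @export
#' @examples
#' compute_ms(data.frame(H = c(1, 0.5), F = c(1, 1)))  # 0.75
compute_ms <- function(evidence) {
  evidence <- check_evidence_df(evidence)
  sum(evidence$H * evidence$F) / nrow(evidence)
}

#' Conservation score (CS) of an evidence profile
#'
#' CS = sum(H_i * F_i) / N_t, with N_t the total number of template species
#' employed. CS measures how conserved the annotated protein is across the
#' template species: it equals MS * N_m / N_t and reaches 1 only when every
#' template contributed clear RBH evidence.
#'
#' @param evidence data frame with columns `H` and `F`.
#' @param config a [score_config()] supplying N_t.
#' @return The conservation score.
#' @export
#' @examples
#' compute_cs(data.frame(H = 1, F = 1), score_config(n_templates = 5))  # 0.2
compute_cs <- function(evidence, config = score_config()) {
  stopifnot(inherits(config, "score_config"))
  evidence <- check_evidence_df(evidence)
  if (nrow(evidence) > config$n_templates) {
    stop("evidence count (", nrow(evidence), ") exceeds n_templates (",
         config$n_templates, ")", call. = FALSE)
  }
  sum(evidence$H * evidence$F) / config$n_templates
}

#' Classify annotations into MS–CS confidence regions
#'
#' Region A (low confidence): MS below the MS threshold. Region B (high):
#' MS at or above the MS threshold but CS below the CS threshold — well
#' matched in alignment but poorly conserved across templates. Region C
#' (extremely high): both scores at or above their thresholds. The
#' partition is total over attainable (MS, CS) pairs.
#'
#' @param ms,cs numeric vectors of equal length with `0 < cs <= ms <= 1`.
#' @param config a [score_config()].
#' @return Character vector of `"A"`, `"B"` or `"C"`.
#' @export
#' @examples
#' classify_region(c(1, 1, 0.25), c(1, 0.2, 0.05))  # "C" "B" "A"
classify_region <- function(ms, cs, config = score_config()) {
  stopifnot(inherits(config, "score_config"))
  if (length(ms) != length(cs)) stop("ms and cs lengths differ", call. = FALSE)
  tol <- 1e-9
  if (any(ms <= 0 | ms > 1 + tol | cs <= 0 | cs > ms + tol)) {
    stop("scores must satisfy 0 < CS <= MS <= 1", call. = FALSE)
  }
  ifelse(ms < config$ms_threshold, "A",
         ifelse(cs < config$cs_threshold, "B", "C"))
}

#' Score all annotation candidates
#'
#' Collapses an evidence table into one row per (query protein, function)
#' candidate with its evidence count N_m, MS, CS and confidence region.
#' Scores are computed per protein–function pair because evidence lists
#' are function-specific.
#'
#' @param annotations an `annotation_set` from [assign_functions()] (or any
#'   evidence data frame with columns `query_id`, `function_label`,
#'   `ec_numbers`, `species`, `H`, `F`).
#' @param config a [score_config()].
#' @return A data frame of class `annotated_proteins` with columns
#'   `query_id`, `function_label`, `ec_numbers`, `species` (`;`-joined),
#'   `n_m`, `MS`, `CS`, `region`, `validated`; the evidence table is kept
#'   in the `"evidence"` attribute.
#' @export
score_table <- function(annotations, config = score_config()) {
  stopifnot(inherits(config, "score_config"))
  ev <- as.data.frame(annotations)
  if (!nrow(ev)) {
    out <- data.frame(query_id = character(0), function_label = character(0),
                      ec_numbers = character(0), species = character(0),
                      n_m = integer(0), MS = numeric(0), CS = numeric(0),
                      region = character(0), validated = logical(0),
                      stringsAsFactors = FALSE)
    attr(out, "evidence") <- ev
    attr(out, "config") <- config
    class(out) <- c("annotated_proteins", "data.frame")
    return(out)
  }
  key <- paste(ev$query_id, norm_label(ev$function_label), sep = "\r")
  groups <- split(seq_len(nrow(ev)), key)
  rows <- lapply(groups, function(idx) {
    e <- ev[idx, , drop = FALSE]
    data.frame(
      query_id = e$query_id[1L], function_label = e$function_label[1L],
      ec_numbers = paste(sort(unique(unlist(split_multi(e$ec_numbers)))),
                         collapse = ";"),
      species = paste(sort(e$species), collapse = ";"),
      n_m = nrow(e), MS = compute_ms(e), CS = compute_cs(e, config),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$region <- classify_region(out$MS, out$CS, config)
  out$validated <- FALSE
  out <- out[order(out$query_id, norm_label(out$function_label)), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "evidence") <- ev
  attr(out, "config") <- config
  class(out) <- c("annotated_proteins", "data.frame")
  out
}

#' @export
print.annotated_proteins <- function(x, ...) {
  cat(sprintf("<annotated_proteins> %d annotation(s) on %d protein(s)\n",
              nrow(x), length(unique(x$query_id))))
  if (nrow(x)) {
    tab <- table(factor(x$region, levels = c("A", "B", "C")))
    cat(sprintf("  region A (low) %d | B (high) %d | C (extremely high) %d\n",
                tab[["A"]], tab[["B"]], tab[["C"]]))
  }
  invisible(x)
}

#' MS–CS scatter plot of all annotations
#'
#' Plots every annotation's match score against its conservation score over
#' the attainable wedge `CS <= MS`, draws the A/B/C region boundaries as
#' dashed lines and circles validated annotations.
#'
#' @param x an [score_table()] result.
#' @param ... further arguments passed to [plot()].
#' @return `x`, invisibly.
#' @export
plot.annotated_proteins <- function(x, ...) {
  cfg <- attr(x, "config") %||% score_config()
  graphics::plot(x$MS, x$CS, xlim = c(0, 1), ylim = c(0, 1),
                 xlab = "match score (MS)", ylab = "conservation score (CS)",
                 pch = 4, col = c(A = "grey50", B = "steelblue",
                                  C = "darkgreen")[x$region], ...)
  graphics::abline(v = cfg$ms_threshold, lty = 2, col = "grey40")
  graphics::segments(cfg$ms_threshold, cfg$cs_threshold, 1,
                     cfg$cs_threshold, lty = 2, col = "grey40")
  graphics::abline(0, 1, lty = 3, col = "grey70")  # CS = MS upper edge
  if (any(x$validated)) {
    graphics::points(x$MS[x$validated], x$CS[x$validated], pch = 1, cex = 1.8)
  }
  graphics::legend("topleft", bty = "n",
                   legend = c("region A (low)", "region B (high)",
                              "region C (extremely high)", "validated"),
                   pch = c(4, 4, 4, 1),
                   col = c("grey50", "steelblue", "darkgreen", "black"))
  invisible(x)
}

#' Write the MS–CS scatter table as TSV
#'
#' @param scored an [score_table()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_score_table <- function(scored, path) {
  stopifnot(inherits(scored, "annotated_proteins"))
  cols <- c("query_id", "function_label", "ec_numbers", "species", "n_m",
            "MS", "CS", "region", "validated")
  write.table(as.data.frame(scored)[cols], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
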