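subset_seq <- function(x, ids) {
  out <- x[match(ids, x$id), , drop = FALSE]
  class(out) <- class(x)
  attr(out, "alphabet") <- seq_alphabet(x)
  rownames(out) <- NULL
  out
}

#' Assemble a pathway from scored annotations
#'
#' Attaches every annotated protein to each template reaction whose EC set
#' intersects the annotation's EC set; reactions left without any protein
#' are the metabolic gaps. Proteins within a reaction are ordered by MS
#' (descending), CS (descending), then query id; annotations whose ECs
#' match no reaction are reported as unplaced.
#'
#' @param template a [pathway_template()].
#' @param annotations an [score_table()] result.
#' @return An object of class `pathway`: list with `template`,
#'   `assignments` (named list, reaction id to annotation rows), `gaps`
#'   (character vector of reaction ids) and `unplaced`.
#' @export
build_pathway <- function(template, annotations) {
  stopifnot(inherits(template, "pathway_template"),
            inherits(annotations, "annotated_proteins"))
  ann <- as.data.frame(annotations)
  attr(ann, "evidence") <- NULL
  attr(ann, "config") <- NULL
  class(ann) <- "data.frame"
  ann_ecs <- split_multi(ann$ec_numbers)
  rec_ecs <- template_reaction_ecs(template)
  placed <- rep(FALSE, nrow(ann))
  assignments <- lapply(rec_ecs, function(ecs) {
    idx <- which(vapply(ann_ecs, function(e) any(e %in% ecs), logical(1)))
    placed[idx] <<- TRUE
    rows <- ann[idx, , drop = FALSE]
    rows <- rows[order(-rows$MS, -rows$CS, rows$query_id), , drop = FALSE]
    rownames(rows) <- NULL
    rows
  })
  gaps <- names(assignments)[vapply(assignments, nrow, integer(1)) == 0L]
  structure(list(template = template, assignments = assignments,
                 gaps = gaps, unplaced = ann[!placed, , drop = FALSE],
                 scored = annotations),
            class = "pathway")
}

#' @export
print.pathway <- function(x, ...) {
  n_prot <- length(unique(unlist(lapply(x$assignments, `[[`, "query_id"))))
  cat(sprintf("<pathway> '%s': %d reaction(s), %d gap(s), %d protein(s) attached\n",
              x$template$name, nrow(x$template$reactions), length(x$gaps),
              n_prot))
  if (length(x$gaps)) cat("  gaps:", paste(x$gaps, collapse = ", "), "\n")
  if (nrow(x$unplaced)) cat("  unplaced annotations:", nrow(x$unplaced), "\n")
  invisible(x)
}

#' Per-sub-pathway and per-species reconstruction statistics
#'
#' For each sub-pathway: reaction count, gap count, mean and median number
#' of distinct proteins per covered (non-gap) reaction, and distinct
#' protein count. For each template species: number of template genes and
#' number of distinct query proteins annotated from it — the shape of the
#' paper-style "template sequences / query sequences annotated" summary.
#'
#' @param pathway a [build_pathway()] result.
#' @return List of class `pathway_stats` with data frames `sub_pathways`
#'   and `species`, plus `n_gaps` and `n_proteins`.
#' @export
pathway_stats <- function(pathway) {
  stopifnot(inherits(pathway, "pathway"))
  reactions <- pathway$template$reactions
  counts <- vapply(pathway$assignments,
                   function(a) length(unique(a$query_id)), integer(1))
  sub <- lapply(unique(reactions$sub_pathway), function(sp) {
    rids <- reactions$reaction_id[reactions$sub_pathway == sp]
    cv <- counts[rids]
    covered <- cv[cv > 0]
    prot <- unique(unlist(lapply(pathway$assignments[rids], `[[`, "query_id")))
    data.frame(sub_pathway = sp, n_reactions = length(rids),
               n_gaps = sum(cv == 0),
               mean_proteins = if (length(covered)) mean(covered) else 0,
               median_proteins = if (length(covered)) median(covered) else 0,
               n_distinct_proteins = length(prot),
               stringsAsFactors = FALSE)
  })
  ev <- attr(pathway$scored, "evidence")
  genes <- pathway$template$genes
  spec <- lapply(unique(genes$species), function(s) {
    data.frame(species = s,
               n_template_genes = sum(genes$species == s),
               n_query_annotated = length(unique(ev$query_id[ev$species == s])),
               stringsAsFactors = FALSE)
  })
  structure(list(sub_pathways = do.call(rbind, sub),
                 species = do.call(rbind, spec),
                 n_gaps = length(pathway$gaps),
                 n_proteins = length(unique(unlist(
                   lapply(pathway$assignments, `[[`, "query_id"))))),
            class = "pathway_stats")
}

#' @export
print.pathway_stats <- function(x, ...) {
  cat(sprintf("<pathway_stats> %d protein(s) attached, %d gap(s)\n",
              x$n_proteins, x$n_gaps))
  print(x$sub_pathways, row.names = FALSE)
  print(x$species, row.names = FALSE)
  invisible(x)
}

#' Validate annotations against a set of known genes
#'
#' Each known (experimentally supported) protein sequence is aligned
#' against the annotated query proteins; a known gene matches when its
#' best alignment has `evalue <= max_evalue` and `pident >= min_pident`
#' (both inclusive, no coverage criterion). Matched annotations are marked
#' `validated`, and the report states which fraction of validated
#' annotations falls into confidence regions B or C — the diagnostic that
#' experimentally supported annotations should concentrate in the
#' high-confidence regions.
#'
#' @param annotations an [score_table()] result.
#' @param known protein [seq_set()] of known genes.
#' @param query_proteome protein [seq_set()] the annotations refer to.
#' @param scheme a [scoring_scheme()].
#' @param max_evalue,min_pident the validation thresholds (defaults 1e-10
#'   and 90).
#' @return List of class `validation_report`: updated `annotations`,
#'   `pairs` (known gene, matched protein, alignment stats), counts
#'   `n_known`, `matched_genes`, `matched_proteins`, and
#'   `frac_validated_bc`.
#' @export
validate_against_known <- function(annotations, known, query_proteome,
                                   scheme = scoring_scheme("protein"),
                                   max_evalue = 1e-10, min_pident = 90) {
  stopifnot(inherits(annotations, "annotated_proteins"))
  if (is.null(known) || !nrow(known)) {
    warning("empty known-gene set: nothing to validate")
    return(structure(list(annotations = annotations,
                          pairs = data.frame(), n_known = 0L,
                          matched_genes = 0L, matched_proteins = 0L,
                          frac_validated_bc = NA_real_),
                     class = "validation_report"))
  }
  ann_ids <- unique(annotations$query_id)
  targets <- subset_seq(query_proteome, ann_ids)
  hits <- align_all(known, targets, scheme)
  best <- top_hits(hits)
  best$matched <- best$evalue <= max_evalue & best$pident >= min_pident
  matched <- best[best$matched, , drop = FALSE]
  annotations$validated <- annotations$query_id %in% matched$subject_id
  val <- annotations[annotations$validated, , drop = FALSE]
  frac_bc <- if (nrow(val)) mean(val$region %in% c("B", "C")) else NA_real_
  pairs <- data.frame(known_id = best$query_id, protein_id = best$subject_id,
                      pident = best$pident, evalue = best$evalue,
                      bitscore = best$bitscore, matched = best$matched,
                      stringsAsFactors = FALSE)
  structure(list(annotations = annotations, pairs = pairs,
                 n_known = nrow(known), matched_genes = nrow(matched),
                 matched_proteins = length(unique(matched$subject_id)),
                 frac_validated_bc = frac_bc),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("<validation_report> %d/%d known gene(s) matched (%d protein(s))\n",
              x$matched_genes, x$n_known, x$matched_proteins))
  if (!is.na(x$frac_validated_bc)) {
    cat(sprintf("  validated annotations in regions B+C: %.1f%%\n",
                100 * x$frac_validated_bc))
  }
  invisible(x)
}
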