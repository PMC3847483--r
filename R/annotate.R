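#' Hit-filter thresholds
#'
#' The three critical values applied to every first- and second-pass hit:
#' E-value at most `max_evalue`, percent identity at least `min_pident` and
#' query coverage at least `min_qcov`. All comparisons are inclusive, so a
#' hit exactly at a printed threshold is retained. Defaults are the
#' orthology-search criteria (1e-10 / 60 / 80); validation and probe
#' mapping reuse the type with their own values.
#'
#' @param max_evalue non-negative E-value ceiling.
#' @param min_pident,min_qcov percent floors in \[0, 100\].
#' @return An object of class `filter_config`.
#' @export
filter_config <- function(max_evalue = 1e-10, min_pident = 60, min_qcov = 80) {
  if (max_evalue < 0) stop("max_evalue must be non-negative", call. = FALSE)
  if (min_pident < 0 || min_pident > 100 || min_qcov < 0 || min_qcov > 100) {
    stop("min_pident and min_qcov must be in [0, 100]", call. = FALSE)
  }
  structure(list(max_evalue = max_evalue, min_pident = min_pident,
                 min_qcov = min_qcov), class = "filter_config")
}

#' Apply threshold filters to a hit table
#'
#' Keeps exactly the hits with `evalue <= max_evalue`, `pident >=
#' min_pident` and `qcov >= min_qcov` (all inclusive); input order is
#' preserved.
#'
#' @param hits a hit data frame (see [read_blast_tab()]).
#' @param config a [filter_config()].
#' @return The filtered hit data frame.
#' @export
apply_filters <- function(hits, config = filter_config()) {
  stopifnot(inherits(config, "filter_config"))
  keep <- hits$evalue <= config$max_evalue &
    hits$pident >= config$min_pident &
    hits$qcov >= config$min_qcov
  out <- hits[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

norm_label <- function(x) tolower(gsub("[[:space:]]+", " ", trimws(x)))

# Per-species annotation work-horse shared by find_rbh() and
# assign_functions(). Returns the evidence rows contributed by one species.
annotate_species <- function(genes, template_proteome, query_proteome,
                             scheme, config, forward = NULL, reverse = NULL) {
  missing_genes <- setdiff(genes$gene_id, template_proteome$id)
  if (length(missing_genes)) {
    stop("template gene(s) absent from the ", genes$species[1],
         " proteome: ", paste(missing_genes, collapse = ", "), call. = FALSE)
  }
  if (is.null(forward)) {
    gene_seqs <- template_proteome[match(genes$gene_id, template_proteome$id), ,
                                   drop = FALSE]
    class(gene_seqs) <- class(template_proteome)
    attr(gene_seqs, "alphabet") <- seq_alphabet(template_proteome)
    forward <- align_all(gene_seqs, query_proteome, scheme)
  }
  ffilt <- order_hits(apply_filters(forward, config))
  ffilt <- ffilt[ffilt$query_id %in% genes$gene_id, , drop = FALSE]
  if (!nrow(ffilt)) return(NULL)
  cand_ids <- unique(ffilt$subject_id)
  if (is.null(reverse)) {
    cands <- query_proteome[match(cand_ids, query_proteome$id), , drop = FALSE]
    class(cands) <- class(query_proteome)
    attr(cands, "alphabet") <- seq_alphabet(query_proteome)
    reverse <- align_all(cands, template_proteome, scheme)
  }
  rbest <- top_hits(apply_filters(reverse, config))
  rbest_subject <- setNames(rbest$subject_id, rbest$query_id)

  label_of <- setNames(genes$function_label, genes$gene_id)
  clarity_of <- setNames(genes$clarity, genes$gene_id)
  ec_of <- setNames(genes$ec_numbers, genes$gene_id)

  rows <- lapply(genes$gene_id, function(g) {
    gh <- ffilt[ffilt$query_id == g, , drop = FALSE]
    if (!nrow(gh)) return(NULL)
    best_query <- gh$subject_id[1L]
    out <- lapply(seq_len(nrow(gh)), function(i) {
      q <- gh$subject_id[i]
      rsub <- rbest_subject[q]
      if (is.na(rsub)) return(NULL)
      if (q == best_query && rsub == g) {
        kind <- "rbh"; H <- 1
      } else {
        # the non-RBH rule: function assigned only when the best second-pass
        # hit carries an identical function label
        rlab <- label_of[rsub]
        if (is.na(rlab) || norm_label(rlab) != norm_label(label_of[g])) {
          return(NULL)
        }
        kind <- "secondary_confirmed"; H <- 0.5
      }
      data.frame(query_id = q, species = genes$species[1L],
                 template_gene = g, function_label = label_of[g],
                 ec_numbers = ec_of[g],
                 hit_kind = kind, H = H,
                 F = if (clarity_of[g] == "clear") 1 else 0.5,
                 fwd_bitscore = gh$bitscore[i], fwd_evalue = gh$evalue[i],
                 fwd_pident = gh$pident[i], fwd_qcov = gh$qcov[i],
                 rev_best = unname(rsub),
                 stringsAsFactors = FALSE, row.names = NULL)
    })
    do.call(rbind, out)
  })
  do.call(rbind, rows)
}

#' Find the reciprocal best hit of one template gene
#'
#' First pass: the template gene is aligned against the query proteome and
#' hits are filtered; the best filtered hit is the RBH candidate. Second
#' pass: the candidate is aligned back against the template proteome; the
#' pair is an RBH only if the best filtered second-pass hit is the template
#' gene itself. Ties are broken by (bit score desc, E-value asc, subject id
#' asc).
#'
#' @param gene_id id of the template gene (must be in `template_proteome`).
#' @param template_proteome,query_proteome protein [seq_set()]s.
#' @param scheme a [scoring_scheme()].
#' @param config a [filter_config()].
#' @return `NULL` if no RBH, else a list with `query_id`, the forward hit
#'   and the reverse hit rows.
#' @export
find_rbh <- function(gene_id, template_proteome, query_proteome,
                     scheme = scoring_scheme("protein"),
                     config = filter_config()) {
  if (!gene_id %in% template_proteome$id) {
    stop("gene '", gene_id, "' not found in the template proteome",
         call. = FALSE)
  }
  gene <- template_proteome[template_proteome$id == gene_id, , drop = FALSE]
  class(gene) <- class(template_proteome)
  attr(gene, "alphabet") <- seq_alphabet(template_proteome)
  forward <- order_hits(apply_filters(align_all(gene, query_proteome, scheme),
                                      config))
  if (!nrow(forward)) return(NULL)
  cand_id <- forward$subject_id[1L]
  cand <- query_proteome[query_proteome$id == cand_id, , drop = FALSE]
  class(cand) <- class(query_proteome)
  attr(cand, "alphabet") <- seq_alphabet(query_proteome)
  reverse <- top_hits(apply_filters(align_all(cand, template_proteome, scheme),
                                    config))
  if (!nrow(reverse) || reverse$subject_id[1L] != gene_id) return(NULL)
  list(query_id = cand_id, forward = forward[1L, ], reverse = reverse[1L, ])
}

#' Two-pass function assignment from multiple template species
#'
#' For every template gene the first pass aligns it against the query
#' proteome; each filtered hit becomes annotation evidence either as the
#' reciprocal best hit (match-quality weight `H = 1`) or, for non-RBH hits,
#' only when the best filtered second-pass hit carries an identical
#' function label (after case-folding and whitespace normalisation;
#' `H = 0.5`). The function-clarity weight `F` is 1 for clearly annotated
#' template genes and 0.5 otherwise. Within a (query, function, species)
#' triple only the strongest evidence item is kept (larger `H`, then larger
#' forward bit score, then template gene id), so the number of evidence
#' items per candidate counts template species.
#'
#' @param template a [pathway_template()].
#' @param template_proteomes named list of protein [seq_set()]s, one per
#'   template species (names must cover the species in the template's gene
#'   table).
#' @param query_proteome protein [seq_set()] to annotate.
#' @param scheme a [scoring_scheme()].
#' @param config a [filter_config()].
#' @param forward_hits,reverse_hits optional named lists (by species) of
#'   precomputed hit tables (e.g. from [read_blast_tab()]): forward =
#'   template genes vs query proteome, reverse = candidate query proteins
#'   vs template proteome. When supplied the internal aligner is skipped
#'   for that pass.
#' @return An `annotation_set`: the evidence data frame (one row per
#'   evidence item) with candidate grouping by `(query_id,
#'   function_label)`.
#' @export
assign_functions <- function(template, template_proteomes, query_proteome,
                             scheme = scoring_scheme("protein"),
                             config = filter_config(),
                             forward_hits = NULL, reverse_hits = NULL) {
  stopifnot(inherits(template, "pathway_template"))
  species <- unique(template$genes$species)
  missing_sp <- setdiff(species, names(template_proteomes))
  if (length(missing_sp)) {
    stop("no proteome supplied for template species: ",
         paste(missing_sp, collapse = ", "), call. = FALSE)
  }
  ev <- lapply(species, function(s) {
    annotate_species(template$genes[template$genes$species == s, , drop = FALSE],
                     template_proteomes[[s]], query_proteome, scheme, config,
                     forward = forward_hits[[s]], reverse = reverse_hits[[s]])
  })
  ev <- do.call(rbind, ev)
  if (is.null(ev)) ev <- empty_evidence()
  ev <- dedupe_evidence(ev)
  structure(ev, class = c("annotation_set", "data.frame"))
}

empty_evidence <- function() {
  data.frame(query_id = character(0), species = character(0),
             template_gene = character(0), function_label = character(0),
             ec_numbers = character(0), hit_kind = character(0),
             H = numeric(0), F = numeric(0), fwd_bitscore = numeric(0),
             fwd_evalue = numeric(0), fwd_pident = numeric(0),
             fwd_qcov = numeric(0), rev_best = character(0),
             stringsAsFactors = FALSE)
}

# keep the strongest evidence item per (query, function, species)
dedupe_evidence <- function(ev) {
  if (!nrow(ev)) return(ev)
  key <- paste(ev$query_id, norm_label(ev$function_label), ev$species,
               sep = "\r")
  ev <- ev[order(key, -ev$H, -ev$fwd_bitscore, ev$template_gene), ,
           drop = FALSE]
  ev <- ev[!duplicated(paste(ev$query_id, norm_label(ev$function_label),
                             ev$species, sep = "\r")), , drop = FALSE]
  ev <- ev[order(ev$query_id, norm_label(ev$function_label), ev$species), ,
           drop = FALSE]
  rownames(ev) <- NULL
  ev
}

#' @export
print.annotation_set <- function(x, ...) {
  n_cand <- if (nrow(x)) {
    nrow(unique(data.frame(q = x$query_id, f = norm_label(x$function_label))))
  } else 0L
  cat(sprintf("<annotation_set> %d evidence item(s), %d candidate(s), %d species\n",
              nrow(x), n_cand, length(unique(x$species))))
  invisible(x)
}
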