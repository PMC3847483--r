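#' Read a probe-by-condition expression matrix
#'
#' TSV with probe ids in the first column and one column per condition
#' (e.g. the three root types fibrous, developing, mature). Values must be
#' finite and non-negative; condition labels must be unique.
#'
#' @param path TSV path.
#' @return Data frame of class `expression_table`, first column `probe_id`.
#' @export
read_expression <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(tab) < 2L) stop("expression table needs probe ids plus >= 1 condition",
                           call. = FALSE)
  names(tab)[1L] <- "probe_id"
  tab$probe_id <- as.character(tab$probe_id)
  conds <- names(tab)[-1L]
  if (anyDuplicated(conds)) stop("duplicate condition labels", call. = FALSE)
  vals <- as.matrix(tab[, -1L, drop = FALSE])
  if (!is.numeric(vals) || any(!is.finite(vals)) || any(vals < 0)) {
    stop("expression values must be finite and non-negative", call. = FALSE)
  }
  if (anyDuplicated(tab$probe_id)) stop("duplicate probe ids", call. = FALSE)
  class(tab) <- c("expression_table", "data.frame")
  tab
}

#' Map microarray probes to gene sequences
#'
#' A probe represents a gene when the best local alignment of the probe
#' (as query) against the gene sequence passes `evalue <= max_evalue` and
#' `pident >= min_pident` (both inclusive; no coverage criterion, matching
#' the transcriptome-integration filter). A probe may represent several
#' genes. Both sides must be nucleotide sequences; the E-value database
#' size is the total residue count of the gene set.
#'
#' @param genes nucleotide [seq_set()] of gene (transcript) sequences.
#' @param probes nucleotide [seq_set()] of probe sequences.
#' @param scheme nucleotide [scoring_scheme()].
#' @param max_evalue,min_pident mapping thresholds (defaults 1e-10 and 95).
#' @return Data frame with columns `probe_id`, `gene_id`, `pident`,
#'   `evalue`, ordered by gene then probe.
#' @export
map_probes <- function(genes, probes, scheme = scoring_scheme("nucleotide"),
                       max_evalue = 1e-10, min_pident = 95) {
  if (seq_alphabet(genes) != "nucleotide" ||
      seq_alphabet(probes) != "nucleotide") {
    stop("probe mapping requires nucleotide sequences on both sides",
         call. = FALSE)
  }
  hits <- align_all(probes, genes, scheme)
  keep <- hits[hits$evalue <= max_evalue & hits$pident >= min_pident, ,
               drop = FALSE]
  out <- data.frame(probe_id = keep$query_id, gene_id = keep$subject_id,
                    pident = keep$pident, evalue = keep$evalue,
                    stringsAsFactors = FALSE)
  out <- out[order(out$gene_id, out$probe_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Fold-change filter and gene-level expression overlay
#'
#' Gene expression per condition is the arithmetic mean over the gene's
#' mapped probes. A gene passes the fold-change criterion when the ratio of
#' its highest to lowest condition mean is at least `fold` (the classic
#' two-fold-change rule, taken symmetrically over all conditions since no
#' reference condition is singled out); the denominator is clamped at
#' `floor` signal units to avoid division by zero. Only passing genes
#' enter the overlay; excluded genes are kept in the `"excluded"`
#' attribute, and mapped genes absent from the expression table are
#' dropped with a warning.
#'
#' @param table an [read_expression()] table (or equivalent data frame).
#' @param mapping a [map_probes()] result.
#' @param fold fold-change threshold (default 2, inclusive).
#' @param floor minimum denominator in signal units (default 1).
#' @return Data frame of class `expression_overlay`: one row per passing
#'   gene with the per-condition means, `n_probes` and `probes`.
#' @export
fold_change_filter <- function(table, mapping, fold = 2, floor = 1) {
  if (!nrow(mapping)) stop("empty probe-to-gene mapping", call. = FALSE)
  conds <- setdiff(names(table), "probe_id")
  known <- mapping$probe_id %in% table$probe_id
  if (any(!known)) {
    warning("dropping ", sum(!known),
            " mapped probe(s) absent from the expression table")
    mapping <- mapping[known, , drop = FALSE]
  }
  genes <- unique(mapping$gene_id)
  rows <- lapply(genes, function(g) {
    pids <- mapping$probe_id[mapping$gene_id == g]
    vals <- table[match(pids, table$probe_id), conds, drop = FALSE]
    means <- colMeans(vals)
    ratio <- max(means) / max(min(means), floor)
    cbind(data.frame(gene_id = g, stringsAsFactors = FALSE),
          as.data.frame(as.list(means)),
          data.frame(n_probes = length(pids),
                     probes = paste(sort(pids), collapse = ";"),
                     fold_ratio = ratio, passed_filter = ratio >= fold,
                     stringsAsFactors = FALSE))
  })
  all_genes <- do.call(rbind, rows)
  names(all_genes)[2:(1 + length(conds))] <- conds
  out <- all_genes[all_genes$passed_filter, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "excluded") <- all_genes[!all_genes$passed_filter, , drop = FALSE]
  attr(out, "conditions") <- conds
  class(out) <- c("expression_overlay", "data.frame")
  out
}

#' Attach an expression overlay to a pathway
#'
#' Adds, for every reaction and every assigned protein whose gene passed
#' the fold-change filter, the ordered per-condition expression vector.
#' Protein ids are mapped to gene ids through the 12-digit gene/transcript
#' convention when they follow it ([parse_seq_ids()]); otherwise the
#' protein id itself is the gene id. Genes that did not pass the filter
#' appear on no node.
#'
#' @param pathway a [build_pathway()] result.
#' @param overlay a [fold_change_filter()] result.
#' @return The pathway with an `expression` element: named list (by
#'   reaction id) of data frames with `protein_id`, `gene_id` and one
#'   column per condition.
#' @export
attach_overlay <- function(pathway, overlay) {
  stopifnot(inherits(pathway, "pathway"), inherits(overlay, "expression_overlay"))
  conds <- attr(overlay, "conditions")
  pathway$expression <- lapply(pathway$assignments, function(a) {
    if (!nrow(a)) return(NULL)
    prot <- unique(a$query_id)
    gene <- parse_seq_ids(prot)$gene_id
    idx <- match(gene, overlay$gene_id)
    keep <- !is.na(idx)
    if (!any(keep)) return(NULL)
    cbind(data.frame(protein_id = prot[keep], gene_id = gene[keep],
                     stringsAsFactors = FALSE),
          overlay[idx[keep], conds, drop = FALSE], row.names = NULL)
  })
  pathway$overlay <- overlay
  pathway
}
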