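#' Configuration of a full reconstruction run
#'
#' Collects every input path and threshold of the pipeline. All referenced
#' files must exist when the configuration is built. The defaults are the
#' published critical values: orthology filters (E-value at most 1e-10,
#' identity at least 60, coverage at least 80), validation identity at
#' least 90, probe identity at least 95, and a two-fold expression change.
#'
#' @param query_fasta protein FASTA of the query species.
#' @param template_fastas named character vector of template proteome FASTA
#'   paths (names are the species labels used in the pathway template).
#' @param template_file pathway template (`.json` or `.tsv`).
#' @param out_dir output directory (created on run).
#' @param known_fasta optional protein FASTA of known genes (validation).
#' @param genes_fasta,probes_fasta,expression_tsv optional nucleotide gene
#'   FASTA, probe FASTA and expression TSV (transcriptome integration).
#' @param filter a [filter_config()].
#' @param score a [score_config()]; defaults to N_t = number of template
#'   proteomes.
#' @param validate_evalue,validate_pident validation thresholds.
#' @param probe_evalue,probe_pident probe-mapping thresholds.
#' @param fold fold-change threshold.
#' @return An object of class `run_config`.
#' @export
run_config <- function(query_fasta, template_fastas, template_file, out_dir,
                       known_fasta = NULL, genes_fasta = NULL,
                       probes_fasta = NULL, expression_tsv = NULL,
                       filter = filter_config(), score = NULL,
                       validate_evalue = 1e-10, validate_pident = 90,
                       probe_evalue = 1e-10, probe_pident = 95, fold = 2) {
  if (is.null(names(template_fastas)) || any(!nzchar(names(template_fastas)))) {
    stop("template_fastas must be a named vector (names = species)",
         call. = FALSE)
  }
  inputs <- c(query_fasta, template_fastas, template_file, known_fasta,
              genes_fasta, probes_fasta, expression_tsv)
  missing_in <- inputs[!file.exists(inputs)]
  if (length(missing_in)) {
    stop("input file(s) not found: ", paste(missing_in, collapse = ", "),
         call. = FALSE)
  }
  stopifnot(inherits(filter, "filter_config"))
  if (is.null(score)) score <- score_config(n_templates = length(template_fastas))
  stopifnot(inherits(score, "score_config"))
  structure(list(query_fasta = query_fasta, template_fastas = template_fastas,
                 template_file = template_file, out_dir = out_dir,
                 known_fasta = known_fasta, genes_fasta = genes_fasta,
                 probes_fasta = probes_fasta, expression_tsv = expression_tsv,
                 filter = filter, score = score,
                 validate_evalue = validate_evalue,
                 validate_pident = validate_pident,
                 probe_evalue = probe_evalue, probe_pident = probe_pident,
                 fold = fold),
            class = "run_config")
}

#' Run the full pathway-reconstruction pipeline
#'
#' Executes align / annotate / score / assemble, then (when the inputs are
#' configured) validation against known genes and transcriptome overlay,
#' and exports every artifact to `out_dir`: `score_table.tsv`,
#' `pathway.graphml`, `pathway.json`, `stats_subpathways.tsv`,
#' `stats_species.tsv`, `validation.tsv`, `overlay.tsv` and
#' `run_manifest.json` (configuration echo, input checksums and package
#' version — no timestamps, so reruns on identical inputs are
#' byte-identical). Per-stage counts are logged via `message()`.
#'
#' @param config a [run_config()].
#' @param quiet suppress stage logging.
#' @return Invisibly, a list with `annotations`, `scored`, `pathway`,
#'   `stats`, `validation` (or `NULL`), `overlay` (or `NULL`) and the
#'   output `paths`.
#' @export
run_reconstruct <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (!quiet) message("[orthopath] ", sprintf(...))
  scheme <- scoring_scheme("protein")

  say("reading inputs")
  query <- read_fasta(config$query_fasta, "protein", species = "query")
  templates <- lapply(names(config$template_fastas), function(s) {
    read_fasta(config$template_fastas[[s]], "protein", species = s)
  })
  names(templates) <- names(config$template_fastas)
  template <- read_pathway_template(config$template_file)
  say("query proteome: %d sequence(s); %d template species; %d reaction(s)",
      nrow(query), length(templates), nrow(template$reactions))

  say("annotating (two-pass reciprocal search, E<=%g, id>=%g, cov>=%g)",
      config$filter$max_evalue, config$filter$min_pident, config$filter$min_qcov)
  annotations <- assign_functions(template, templates, query, scheme,
                                  config$filter)
  say("evidence items: %d (%d RBH, %d secondary)", nrow(annotations),
      sum(annotations$hit_kind == "rbh"),
      sum(annotations$hit_kind == "secondary_confirmed"))

  scored <- score_table(annotations, config$score)
  say("candidates: %d on %d protein(s); regions A/B/C = %d/%d/%d",
      nrow(scored), length(unique(scored$query_id)),
      sum(scored$region == "A"), sum(scored$region == "B"),
      sum(scored$region == "C"))

  validation <- NULL
  if (!is.null(config$known_fasta)) {
    known <- read_fasta(config$known_fasta, "protein", species = "known")
    validation <- validate_against_known(scored, known, query, scheme,
                                         config$validate_evalue,
                                         config$validate_pident)
    scored <- validation$annotations
    say("validation: %d/%d known gene(s) matched", validation$matched_genes,
        validation$n_known)
  }

  pathway <- build_pathway(template, scored)
  stats <- pathway_stats(pathway)
  say("pathway: %d reaction(s), %d gap(s)%s", nrow(template$reactions),
      length(pathway$gaps),
      if (length(pathway$gaps)) paste0(" (", paste(pathway$gaps, collapse = ", "), ")")
      else "")

  overlay <- NULL
  if (!is.null(config$genes_fasta) && !is.null(config$probes_fasta) &&
      !is.null(config$expression_tsv)) {
    genes_nt <- read_fasta(config$genes_fasta, "nucleotide", species = "query")
    probes <- read_fasta(config$probes_fasta, "nucleotide", species = "array")
    expr <- read_expression(config$expression_tsv)
    mapping <- map_probes(genes_nt, probes, scoring_scheme("nucleotide"),
                          config$probe_evalue, config$probe_pident)
    say("probe mapping: %d probe-gene pair(s) over %d gene(s)",
        nrow(mapping), length(unique(mapping$gene_id)))
    overlay <- fold_change_filter(expr, mapping, fold = config$fold)
    say("fold-change filter (>= %g-fold): %d gene(s) pass, %d excluded",
        config$fold, nrow(overlay), nrow(attr(overlay, "excluded")))
    pathway <- attach_overlay(pathway, overlay)
  }

  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(score_table = file.path(config$out_dir, "score_table.tsv"),
                graphml = file.path(config$out_dir, "pathway.graphml"),
                json = file.path(config$out_dir, "pathway.json"),
                stats_sub = file.path(config$out_dir, "stats_subpathways.tsv"),
                stats_species = file.path(config$out_dir, "stats_species.tsv"),
                manifest = file.path(config$out_dir, "run_manifest.json"))
  write_score_table(scored, paths$score_table)
  write_pathway_graph(pathway, paths$graphml, "graphml")
  write_pathway_graph(pathway, paths$json, "json")
  write.table(stats$sub_pathways, paths$stats_sub, sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(stats$species, paths$stats_species, sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (!is.null(validation)) {
    paths$validation <- file.path(config$out_dir, "validation.tsv")
    write.table(validation$pairs, paths$validation, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  if (!is.null(overlay)) {
    paths$overlay <- file.path(config$out_dir, "overlay.tsv")
    write.table(as.data.frame(overlay), paths$overlay, sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  inputs <- c(query = config$query_fasta, config$template_fastas,
              template = config$template_file, known = config$known_fasta,
              genes = config$genes_fasta, probes = config$probes_fasta,
              expression = config$expression_tsv)
  thresholds <- config[c("validate_evalue", "validate_pident", "probe_evalue",
                         "probe_pident", "fold")]
  jsonlite::write_json(
    list(package_version = as.character(utils::packageVersion("orthopath")),
         filter = unclass(config$filter), score = unclass(config$score),
         thresholds = thresholds,
         input_md5 = as.list(setNames(unname(tools::md5sum(inputs)),
                                      names(inputs)))),
    paths$manifest, auto_unbox = TRUE, pretty = TRUE)
  say("outputs written to %s", config$out_dir)
  invisible(list(annotations = annotations, scored = scored,
                 pathway = pathway, stats = stats, validation = validation,
                 overlay = overlay, paths = paths))
}
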