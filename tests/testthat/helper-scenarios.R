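# Memoised synthetic scenarios shared across test files (generation and
# alignment are the expensive steps; the bundles are deterministic per seed).
.scenario_cache <- new.env(parent = emptyenv())

# small, fast scenario for unit tests
small_scenario <- function() {
  if (is.null(.scenario_cache$small)) {
    .scenario_cache$small <- generate_scenario(
      scenario_config(seed = 42, n_species = 3, n_families = 8, n_decoys = 6,
                      n_paralog_families = 2, gap_families = 2, n_known = 4,
                      length_range = c(120L, 200L)),
      file.path(tempdir(), "orthopath-small-scenario"))
  }
  .scenario_cache$small
}

small_annotation <- function() {
  if (is.null(.scenario_cache$small_ann)) {
    scen <- small_scenario()
    .scenario_cache$small_ann <- assign_functions(
      scen$template, scen$template_proteomes, scen$query_proteome)
  }
  .scenario_cache$small_ann
}

# the stated default world (5 species, 30 families, 3 gaps, 30 decoys)
default_scenario <- function() {
  if (is.null(.scenario_cache$default)) {
    .scenario_cache$default <- generate_scenario(
      scenario_config(seed = 1),
      file.path(tempdir(), "orthopath-default-scenario"))
  }
  .scenario_cache$default
}

scenario_run_config <- function(scen, out_dir, ...) {
  species <- names(scen$template_proteomes)
  run_config(
    query_fasta = scen$paths$query,
    template_fastas = setNames(unlist(scen$paths$templates), species),
    template_file = scen$paths$template_file,
    out_dir = out_dir,
    known_fasta = scen$paths$known,
    genes_fasta = scen$paths$genes,
    probes_fasta = scen$paths$probes,
    expression_tsv = scen$paths$expression,
    score = score_config(n_templates = length(species)),
    ...)
}

make_seqs <- function(residues, prefix = "s", ...) {
  seq_set(paste0(prefix, seq_along(residues)), residues, ...)
}

# two-reaction sucrose/starch toy template shared by pathway and graph tests
toy_template <- function() {
  pathway_template(
    "toy",
    data.frame(reaction_id = c("R1", "R2"),
               ec_numbers = c("2.4.1.13", "2.7.7.27"),
               substrates = c("sucrose", "G1P"), products = c("fructose", "ADPG"),
               sub_pathway = c("sucrose_synthesis", "starch_synthesis"),
               stringsAsFactors = FALSE),
    data.frame(species = "arabidopsis", gene_id = c("g1", "g2"),
               function_label = c("sucrose synthase", "AGPase"),
               ec_numbers = c("2.4.1.13", "2.7.7.27"), clarity = "clear",
               stringsAsFactors = FALSE))
}

mk_scored <- function(query_id, function_label, ec_numbers,
                      species = "arabidopsis", H = 1, F = 1, n_t = 5) {
  ev <- data.frame(query_id = query_id, function_label = function_label,
                   ec_numbers = ec_numbers, species = species, H = H, F = F,
                   stringsAsFactors = FALSE)
  score_table(ev, score_config(n_templates = n_t))
}
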