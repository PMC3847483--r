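AA20 <- setdiff(ALPHABETS$protein, "X")

CODON_TABLE <- list(
  A = c("GCT","GCC","GCA","GCG"), R = c("CGT","CGC","CGA","CGG","AGA","AGG"),
  N = c("AAT","AAC"), D = c("GAT","GAC"), C = c("TGT","TGC"),
  Q = c("CAA","CAG"), E = c("GAA","GAG"), G = c("GGT","GGC","GGA","GGG"),
  H = c("CAT","CAC"), I = c("ATT","ATC","ATA"),
  L = c("TTA","TTG","CTT","CTC","CTA","CTG"), K = c("AAA","AAG"),
  M = "ATG", F = c("TTT","TTC"), P = c("CCT","CCC","CCA","CCG"),
  S = c("TCT","TCC","TCA","TCG","AGT","AGC"), T = c("ACT","ACC","ACA","ACG"),
  W = "TGG", Y = c("TAT","TAC"), V = c("GTT","GTC","GTA","GTG"))

#' Draw a random unrelated sequence
#'
#' Uniform residues over the 20 amino acids (or 4 bases); used for family
#' ancestors and for decoys, whose expected identity to anything else is
#' far below the filter thresholds. Driven by R's RNG stream.
#'
#' @param n sequence length.
#' @param alphabet `"protein"` or `"nucleotide"`.
#' @return A residue string.
#' @export
random_residues <- function(n, alphabet = "protein") {
  pool <- if (alphabet == "protein") AA20 else c("A", "C", "G", "T")
  paste(sample(pool, n, replace = TRUE), collapse = "")
}

ident_frac <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  mean(strsplit(a, "")[[1]] == strsplit(b, "")[[1]])
}

mutate_residues <- function(residues, target_identity, alphabet) {
  L <- nchar(residues)
  if (target_identity <= 0 || target_identity > 1) {
    stop("target_identity must lie in (0, 1]", call. = FALSE)
  }
  if (target_identity < 1 / L) {
    stop("target_identity below 1/length is not constructible", call. = FALSE)
  }
  k <- round((1 - target_identity) * L)
  if (k == 0L) return(residues)
  chars <- strsplit(residues, "")[[1]]
  pos <- sample.int(L, k)
  mat <- if (alphabet == "protein") protein_matrix() else NULL
  for (p in pos) {
    orig <- chars[p]
    if (alphabet == "protein") {
      plausible <- AA20[mat[orig, AA20] >= 0 & AA20 != orig]
      if (!length(plausible)) plausible <- setdiff(AA20, orig)
    } else {
      plausible <- setdiff(c("A", "C", "G", "T"), orig)
    }
    chars[p] <- plausible[sample.int(length(plausible), 1L)]
  }
  paste(chars, collapse = "")
}

#' Mutate a sequence to an exact target identity
#'
#' Substitutes residues at `round((1 - target_identity) * length)` uniformly
#' chosen positions, so the realized (gapless) identity to the parent is
#' exact by construction. Protein replacements are BLOSUM-plausible
#' (substitution score >= 0 against the original residue) to mimic accepted
#' point mutations; nucleotide replacements are any other base. Driven by
#' R's RNG stream: call `set.seed()` for reproducibility.
#'
#' @param parent one-row [seq_set()].
#' @param target_identity identity fraction in (0, 1]; must be at least
#'   `1/length`.
#' @param id id of the mutated record (default: parent id plus `_mut`).
#' @return A one-row [seq_set()].
#' @export
#' @examples
#' set.seed(1)
#' p <- seq_set("anc", random_residues(50))
#' mutate_sequence(p, 0.9)
mutate_sequence <- function(parent, target_identity, id = NULL) {
  r <- as_one_record(parent)
  alphabet <- if (is.na(r$alphabet)) "protein" else r$alphabet
  out <- mutate_residues(r$residues, target_identity, alphabet)
  seq_set(id %||% paste0(r$id, "_mut"), out, alphabet = alphabet)
}

#' Back-translate a protein to a nucleotide sequence
#'
#' Picks a uniformly random synonymous codon per residue (standard genetic
#' code, no stop codon appended). Deterministic under `set.seed()`.
#'
#' @param residues protein residue string (20 amino acids, no `X`).
#' @return Nucleotide string of length `3 * nchar(residues)`.
#' @export
back_translate <- function(residues) {
  chars <- strsplit(toupper(residues), "")[[1]]
  bad <- setdiff(unique(chars), names(CODON_TABLE))
  if (length(bad)) stop("cannot back-translate residue(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  paste(vapply(chars, function(a) {
    cods <- CODON_TABLE[[a]]
    cods[sample.int(length(cods), 1L)]
  }, character(1)), collapse = "")
}

DEFAULT_SPECIES <- c(arabidopsis = "ath", rice = "osa", maize = "zma",
                     castor_bean = "rco", potato = "stu")

REAL_ECS <- c("4.1.1.39", "2.7.2.3", "1.2.1.13", "5.3.1.1", "3.1.3.11",
              "2.2.1.1", "2.7.1.19", "2.4.1.13", "2.4.1.14", "3.1.3.24",
              "2.7.7.27", "2.4.1.21", "2.4.1.18", "3.2.1.68", "4.1.1.31")

ENZYME_NAMES <- c("ribulose-bisphosphate carboxylase", "phosphoglycerate kinase",
                  "glyceraldehyde-3-phosphate dehydrogenase (NADP+)",
                  "triose-phosphate isomerase", "fructose-1,6-bisphosphatase",
                  "transketolase", "phosphoribulokinase", "sucrose synthase",
                  "sucrose-phosphate synthase", "sucrose-6-phosphatase",
                  "ADP-glucose pyrophosphorylase", "starch synthase",
                  "1,4-alpha-glucan branching enzyme",
                  "starch debranching enzyme (isoamylase)",
                  "phosphoenolpyruvate carboxylase")

#' Synthetic-scenario configuration
#'
#' States the simulated world: `n_families` ortholog families shared by
#' `n_species` template plants and the query species, with per-branch
#' identities to the family ancestor drawn from `ortholog_identity`;
#' unrelated decoy query proteins; paralogs derived from query orthologs
#' at `paralog_identity`; a fraction of template genes with unclear
#' function labels (suffixed "putative"); `gap_families` families whose
#' query ortholog is withheld so their reactions become metabolic gaps;
#' probe sequences as exact (or single-mismatch) transcript substrings;
#' and expression over three root-type conditions with planted at least
#' two-fold monotone patterns for the sucrose/starch families and flat
#' patterns for the Calvin-cycle controls.
#'
#' @param seed integer RNG seed.
#' @param n_species number of template species (up to 5 named defaults).
#' @param n_families number of ortholog families (= reactions).
#' @param length_range ancestor protein length range (residues).
#' @param ortholog_identity identity range to the family ancestor.
#' @param decoy_identity_max stated decoy identity ceiling; must stay below
#'   the ortholog floor (decoys are unrelated random sequences, far below
#'   the ceiling in practice).
#' @param n_decoys number of decoy query proteins.
#' @param n_paralog_families families that also carry a query paralog.
#' @param paralog_identity paralog identity to its query ortholog.
#' @param frac_unclear probability a template gene is labelled unclear.
#' @param gap_families number of planted gap reactions.
#' @param n_known number of known (validation) genes.
#' @param probes_per_gene probes planted per transcript.
#' @param n_decoy_probes unrelated decoy probes.
#' @param probe_length probe length (nt).
#' @param conditions ordered condition labels.
#' @return An object of class `scenario_config`.
#' @export
scenario_config <- function(seed = 1L, n_species = 5L, n_families = 30L,
                            length_range = c(200L, 400L),
                            ortholog_identity = c(0.80, 0.95),
                            decoy_identity_max = 0.30, n_decoys = 30L,
                            n_paralog_families = 5L, paralog_identity = 0.95,
                            frac_unclear = 0.2, gap_families = 3L,
                            n_known = 18L, probes_per_gene = 1L,
                            n_decoy_probes = 10L, probe_length = 60L,
                            conditions = c("fibrous", "developing", "mature")) {
  cfg <- list(seed = as.integer(seed), n_species = as.integer(n_species),
              n_families = as.integer(n_families),
              length_range = as.integer(length_range),
              ortholog_identity = ortholog_identity,
              decoy_identity_max = decoy_identity_max,
              n_decoys = as.integer(n_decoys),
              n_paralog_families = as.integer(n_paralog_families),
              paralog_identity = paralog_identity,
              frac_unclear = frac_unclear,
              gap_families = as.integer(gap_families),
              n_known = as.integer(n_known),
              probes_per_gene = as.integer(probes_per_gene),
              n_decoy_probes = as.integer(n_decoy_probes),
              probe_length = as.integer(probe_length),
              conditions = conditions)
  with(cfg, {
    if (n_species < 1L || n_species > length(DEFAULT_SPECIES)) {
      stop("n_species must be between 1 and ", length(DEFAULT_SPECIES),
           call. = FALSE)
    }
    if (any(ortholog_identity <= 0) || any(ortholog_identity > 1)) {
      stop("ortholog_identity must lie in (0, 1]", call. = FALSE)
    }
    if (decoy_identity_max >= ortholog_identity[1L]) {
      stop("decoy identity ceiling must stay below the ortholog identity floor",
           call. = FALSE)
    }
    if (paralog_identity <= 0 || paralog_identity > 1) {
      stop("paralog_identity must lie in (0, 1]", call. = FALSE)
    }
    if (gap_families >= n_families) {
      stop("gap_families must be smaller than n_families", call. = FALSE)
    }
    if (length(conditions) < 2L || anyDuplicated(conditions)) {
      stop("need >= 2 unique condition labels", call. = FALSE)
    }
  })
  if (cfg$n_known > cfg$n_families - cfg$gap_families) {
    stop("n_known exceeds the number of recoverable families", call. = FALSE)
  }
  structure(cfg, class = "scenario_config")
}

#' Generate a synthetic reconstruction scenario with a truth manifest
#'
#' Writes a complete, seed-deterministic input bundle — template proteomes
#' (`<species>.faa`), query proteome (`query.faa`), pathway template
#' (`template.json`), known-gene set (`known_genes.faa`), transcript
#' sequences (`genes.fna`), probe library (`probes.fna`) and expression
#' matrix (`expression.tsv`) — together with `manifest.json`, the
#' ground-truth manifest stating every expected reciprocal best hit,
#' evidence item (with H/F weights), candidate (with N_m/MS/CS), gap
#' reaction, probe-to-gene mapping and fold-filter survivor. Paralogs are
#' checked by construction to sit strictly between the filter floor and
#' their family's true ortholog in identity, so the manifest is exact.
#'
#' @param config a [scenario_config()].
#' @param dir output directory (created if missing).
#' @return Invisibly, a list with the in-memory objects (`query_proteome`,
#'   `template_proteomes`, `template`, `known`, `genes_nt`, `probes`,
#'   `expression`), the `manifest` and the file `paths`.
#' @export
generate_scenario <- function(config = scenario_config(), dir) {
  stopifnot(inherits(config, "scenario_config"))
  if (missing(dir)) stop("an output directory is required", call. = FALSE)
  set.seed(config$seed)
  species <- names(DEFAULT_SPECIES)[seq_len(config$n_species)]
  abbr <- DEFAULT_SPECIES[species]
  nf <- config$n_families
  lo <- config$ortholog_identity[1L]; hi <- config$ortholog_identity[2L]

  gap_idx <- sort(sample.int(nf, config$gap_families))
  non_gap <- setdiff(seq_len(nf), gap_idx)
  paralog_idx <- sort(sample(non_gap,
                             min(config$n_paralog_families, length(non_gap))))

  ecs <- c(REAL_ECS, sprintf("2.4.1.%d", 200 + seq_len(nf)))[seq_len(nf)]
  base_labels <- c(ENZYME_NAMES, sprintf("enzyme family %03d", seq_len(nf)))[seq_len(nf)]
  thirds <- ceiling(nf / 3)
  sub_pathway <- rep(c("calvin_cycle", "sucrose_synthesis", "starch_synthesis"),
                     times = c(thirds, thirds, nf - 2 * thirds))

  fam <- vector("list", nf)
  tmpl_records <- setNames(rep(list(NULL), length(species)), species)
  gene_rows <- list()
  query_rows <- list()
  for (i in seq_len(nf)) {
    L <- sample(seq(config$length_range[1L], config$length_range[2L]), 1L)
    ancestor <- random_residues(L)
    n_present <- sample(seq(max(1L, config$n_species - 2L), config$n_species), 1L)
    present <- sort(sample(species, n_present))
    # paralog families sample branch identities from the top of the range so
    # the paralog band below the ortholog stays clear of the filter floor
    id_lo <- if (i %in% paralog_idx) max(lo, 0.90) else lo

    draw_family <- function() {
      tg <- lapply(present, function(s) {
        mutate_residues(ancestor, runif(1, id_lo, hi), "protein")
      })
      q <- if (i %in% gap_idx) NULL else
        mutate_residues(ancestor, runif(1, id_lo, hi), "protein")
      p <- NULL
      if (!is.null(q) && i %in% paralog_idx) {
        p <- mutate_residues(q, config$paralog_identity, "protein")
      }
      list(tg = tg, q = q, p = p)
    }
    ok <- FALSE
    for (try in 1:20) {
      d <- draw_family()
      ok <- TRUE
      if (!is.null(d$q)) {
        for (j in seq_along(present)) {
          qi <- ident_frac(d$q, d$tg[[j]])
          if (qi < 0.62) ok <- FALSE
          if (!is.null(d$p)) {
            pi_ <- ident_frac(d$p, d$tg[[j]])
            if (pi_ < 0.62 || pi_ > qi - 0.02) ok <- FALSE
          }
        }
      }
      if (ok) break
    }
    if (!ok && !is.null(d$p)) { d$p <- NULL; ok <- TRUE }

    gene_ids <- sprintf("%s_f%03d", abbr[present], i)
    for (j in seq_along(present)) {
      s <- present[j]
      tmpl_records[[s]] <- rbind(tmpl_records[[s]],
        data.frame(id = gene_ids[j], residues = d$tg[[j]],
                   stringsAsFactors = FALSE))
    }
    clarity <- ifelse(runif(length(present)) < config$frac_unclear,
                      "unclear", "clear")
    labels <- ifelse(clarity == "unclear",
                     paste(base_labels[i], "putative"), base_labels[i])
    gene_rows[[i]] <- data.frame(species = present, gene_id = gene_ids,
                                 function_label = labels, ec_numbers = ecs[i],
                                 clarity = clarity, stringsAsFactors = FALSE)
    query_id <- if (is.null(d$q)) NA_character_ else
      sprintf("%06d_%06d", 100000L + i, 100000L + i)
    paralog_id <- if (is.null(d$p)) NA_character_ else
      sprintf("%06d_%06d", 300000L + i, 300000L + i)
    if (!is.null(d$q)) {
      query_rows[[length(query_rows) + 1L]] <-
        data.frame(id = query_id, residues = d$q, stringsAsFactors = FALSE)
    }
    if (!is.null(d$p)) {
      query_rows[[length(query_rows) + 1L]] <-
        data.frame(id = paralog_id, residues = d$p, stringsAsFactors = FALSE)
    }
    fam[[i]] <- list(i = i, present = present, gene_ids = gene_ids,
                     clarity = clarity, labels = labels,
                     query_id = query_id, paralog_id = paralog_id,
                     query_res = d$q)
  }

  for (j in seq_len(config$n_decoys)) {
    L <- sample(seq(config$length_range[1L], config$length_range[2L]), 1L)
    query_rows[[length(query_rows) + 1L]] <-
      data.frame(id = sprintf("%06d_%06d", 900000L + j, 900000L + j),
                 residues = random_residues(L), stringsAsFactors = FALSE)
  }
  query_df <- do.call(rbind, query_rows)
  query_proteome <- seq_set(query_df$id, query_df$residues, species = "query")
  template_proteomes <- lapply(species, function(s) {
    seq_set(tmpl_records[[s]]$id, tmpl_records[[s]]$residues, species = s)
  })
  names(template_proteomes) <- species

  # pathway template: one reaction per family, chained metabolites per
  # sub-pathway with biologically named endpoints
  chain_pos <- ave(seq_len(nf), sub_pathway, FUN = seq_along)
  subs <- sprintf("%s_m%02d", substr(sub_pathway, 1, 3), chain_pos - 1L)
  prods <- sprintf("%s_m%02d", substr(sub_pathway, 1, 3), chain_pos)
  subs[1L] <- "CO2"
  prods[which(sub_pathway == "starch_synthesis")[sum(sub_pathway == "starch_synthesis")]] <- "starch"
  reactions <- data.frame(reaction_id = sprintf("R%02d", seq_len(nf)),
                          ec_numbers = ecs, substrates = subs,
                          products = prods, sub_pathway = sub_pathway,
                          stringsAsFactors = FALSE)
  template <- pathway_template("synthetic starch biosynthesis", reactions,
                               do.call(rbind, gene_rows))

  known_fams <- sort(sample(non_gap, config$n_known))
  known_ids <- sprintf("genbank_%02d", seq_along(known_fams))
  known <- seq_set(known_ids,
                   vapply(fam[known_fams], function(f) f$query_res, character(1)),
                   species = "query_known")

  gene_prefix <- vapply(fam[non_gap], function(f) substr(f$query_id, 1L, 6L),
                        character(1))
  genes_nt <- seq_set(gene_prefix,
                      vapply(fam[non_gap], function(f) back_translate(f$query_res),
                             character(1)),
                      species = "query", alphabet = "nucleotide")

  probe_rows <- list()
  probe_map <- list()
  for (k in seq_along(non_gap)) {
    g <- gene_prefix[k]
    nt <- genes_nt$residues[k]
    for (p in seq_len(config$probes_per_gene)) {
      start <- sample.int(nchar(nt) - config$probe_length + 1L, 1L)
      pr <- substr(nt, start, start + config$probe_length - 1L)
      if (p > 1L) pr <- mutate_residues(pr, 1 - 1 / config$probe_length,
                                        "nucleotide")
      pid <- sprintf("probe_%s_%d", g, p)
      probe_rows[[length(probe_rows) + 1L]] <-
        data.frame(id = pid, residues = pr, stringsAsFactors = FALSE)
      probe_map[[length(probe_map) + 1L]] <-
        data.frame(probe_id = pid, gene_id = g, stringsAsFactors = FALSE)
    }
  }
  for (j in seq_len(config$n_decoy_probes)) {
    probe_rows[[length(probe_rows) + 1L]] <-
      data.frame(id = sprintf("probe_decoy_%02d", j),
                 residues = random_residues(config$probe_length, "nucleotide"),
                 stringsAsFactors = FALSE)
  }
  probe_df <- do.call(rbind, probe_rows)
  probes <- seq_set(probe_df$id, probe_df$residues, species = "array",
                    alphabet = "nucleotide")
  probe_map <- do.call(rbind, probe_map)

  conds <- config$conditions
  expr_rows <- list()
  pass_genes <- character(0)
  for (k in seq_along(non_gap)) {
    i <- non_gap[k]
    b <- round(runif(1, 20, 100), 2)
    increasing <- sub_pathway[i] %in% c("sucrose_synthesis", "starch_synthesis")
    prof <- if (increasing) {
      round(b * seq(1, 4.6, length.out = length(conds)), 2)
    } else {
      round(b * seq(1, 1.15, length.out = length(conds)), 2)
    }
    if (increasing) pass_genes <- c(pass_genes, gene_prefix[k])
    pids <- probe_map$probe_id[probe_map$gene_id == gene_prefix[k]]
    for (pid in pids) {
      expr_rows[[length(expr_rows) + 1L]] <-
        cbind(data.frame(probe_id = pid, stringsAsFactors = FALSE),
              as.data.frame(as.list(setNames(prof, conds))))
    }
  }
  for (j in seq_len(config$n_decoy_probes)) {
    b <- round(runif(1, 20, 100), 2)
    expr_rows[[length(expr_rows) + 1L]] <-
      cbind(data.frame(probe_id = sprintf("probe_decoy_%02d", j),
                       stringsAsFactors = FALSE),
            as.data.frame(as.list(setNames(rep(b, length(conds)), conds))))
  }
  expression <- do.call(rbind, expr_rows)
  class(expression) <- c("expression_table", "data.frame")

  # expected outcomes, by construction
  ev <- list()
  for (f in fam) {
    if (is.na(f$query_id)) next
    for (j in seq_along(f$present)) {
      ev[[length(ev) + 1L]] <- data.frame(
        query_id = f$query_id, function_label = f$labels[j],
        species = f$present[j], template_gene = f$gene_ids[j], H = 1,
        F = if (f$clarity[j] == "clear") 1 else 0.5,
        stringsAsFactors = FALSE)
      if (!is.na(f$paralog_id)) {
        ev[[length(ev) + 1L]] <- data.frame(
          query_id = f$paralog_id, function_label = f$labels[j],
          species = f$present[j], template_gene = f$gene_ids[j], H = 0.5,
          F = if (f$clarity[j] == "clear") 1 else 0.5,
          stringsAsFactors = FALSE)
      }
    }
  }
  expected_evidence <- do.call(rbind, ev)
  expected_evidence <- expected_evidence[order(expected_evidence$query_id,
                                               expected_evidence$function_label,
                                               expected_evidence$species), ,
                                         drop = FALSE]
  rownames(expected_evidence) <- NULL
  key <- paste(expected_evidence$query_id, expected_evidence$function_label,
               sep = "\r")
  expected_candidates <- do.call(rbind, lapply(split(seq_len(nrow(expected_evidence)), key),
    function(idx) {
      e <- expected_evidence[idx, , drop = FALSE]
      data.frame(query_id = e$query_id[1L], function_label = e$function_label[1L],
                 n_m = nrow(e), MS = sum(e$H * e$F) / nrow(e),
                 CS = sum(e$H * e$F) / config$n_species,
                 stringsAsFactors = FALSE)
    }))
  expected_candidates <- expected_candidates[order(expected_candidates$query_id,
                                                   expected_candidates$function_label), ,
                                             drop = FALSE]
  rownames(expected_candidates) <- NULL
  expected_rbh <- do.call(rbind, lapply(fam, function(f) {
    if (is.na(f$query_id)) return(NULL)
    data.frame(species = f$present, template_gene = f$gene_ids,
               query_id = f$query_id, stringsAsFactors = FALSE)
  }))

  manifest <- list(
    seed = config$seed,
    species = as.list(species),
    families = data.frame(
      family = seq_len(nf), reaction_id = reactions$reaction_id,
      ec = ecs, function_label = base_labels, sub_pathway = sub_pathway,
      gap = seq_len(nf) %in% gap_idx,
      present_species = vapply(fam, function(f) paste(f$present, collapse = ";"),
                               character(1)),
      query_id = vapply(fam, function(f) f$query_id, character(1)),
      paralog_id = vapply(fam, function(f) f$paralog_id, character(1)),
      stringsAsFactors = FALSE),
    expected_rbh = expected_rbh,
    expected_evidence = expected_evidence,
    expected_candidates = expected_candidates,
    expected_gaps = as.list(reactions$reaction_id[gap_idx]),
    known = data.frame(known_id = known_ids,
                       query_id = vapply(fam[known_fams], function(f) f$query_id,
                                         character(1)),
                       stringsAsFactors = FALSE),
    probe_map = probe_map,
    expression_pass = as.list(sort(pass_genes)))

  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    query = file.path(dir, "query.faa"),
    templates = setNames(file.path(dir, paste0(species, ".faa")), species),
    template_file = file.path(dir, "template.json"),
    known = file.path(dir, "known_genes.faa"),
    genes = file.path(dir, "genes.fna"),
    probes = file.path(dir, "probes.fna"),
    expression = file.path(dir, "expression.tsv"),
    manifest = file.path(dir, "manifest.json"))
  write_fasta(query_proteome, paths$query)
  for (s in species) write_fasta(template_proteomes[[s]], paths$templates[[s]])
  write_pathway_template(template, paths$template_file)
  write_fasta(known, paths$known)
  write_fasta(genes_nt, paths$genes)
  write_fasta(probes, paths$probes)
  write.table(expression, paths$expression, sep = "\t", quote = FALSE,
              row.names = FALSE)
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(config = config, query_proteome = query_proteome,
                 template_proteomes = template_proteomes, template = template,
                 known = known, genes_nt = genes_nt, probes = probes,
                 expression = expression, manifest = manifest, paths = paths))
}
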