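test_that("filters are inclusive at the printed thresholds and keep order", {
  hits <- data.frame(
    query_id = "q", subject_id = paste0("s", 1:5),
    evalue = c(1e-10, 1e-11, 2e-10, 1e-10, 1e-10),
    pident = c(60, 59.9, 60, 60, 85),
    qcov = c(80, 80, 80, 79.9, 90),
    stringsAsFactors = FALSE)
  kept <- apply_filters(hits, filter_config())
  expect_identical(kept$subject_id, c("s1", "s5"))  # boundary row s1 retained
})

test_that("kept-set size is non-increasing as thresholds tighten", {
  set.seed(6)
  hits <- data.frame(
    query_id = "q", subject_id = sprintf("s%04d", 1:1000),
    evalue = 10^runif(1000, -40, 0),
    pident = runif(1000, 0, 100), qcov = runif(1000, 0, 100),
    stringsAsFactors = FALSE)
  evs <- c(1e-5, 1e-10, 1e-20)
  ids <- c(40, 60, 80)
  covs <- c(60, 80, 95)
  sizes <- sapply(seq_along(evs), function(i) {
    nrow(apply_filters(hits, filter_config(evs[i], ids[i], covs[i])))
  })
  expect_true(all(diff(sizes) <= 0))
  # tightening one axis keeps a subset
  a <- apply_filters(hits, filter_config(1e-10, 60, 80))
  b <- apply_filters(hits, filter_config(1e-10, 70, 80))
  expect_true(all(b$subject_id %in% a$subject_id))
})

test_that("find_rbh detects planted orthologs and rejects planted paralogs", {
  set.seed(8)
  anc <- random_residues(150)
  other <- replicate(4, random_residues(150))
  tmpl <- seq_set(c("g1", paste0("t", 1:4)), c(anc, other), species = "tmpl")
  qry <- seq_set(c("c1", paste0("d", 1:4)),
                 c(mutate_residues(anc, 0.9, "protein"), other),
                 species = "qry")
  rbh <- find_rbh("g1", tmpl, qry)
  expect_identical(rbh$query_id, "c1")
  expect_identical(rbh$reverse$subject_id, "g1")

  # plant a template paralog identical to the candidate: the second pass now
  # prefers it, so the pair is no longer reciprocal
  tmpl2 <- seq_set(c("g1", "g1b", paste0("t", 1:4)),
                   c(anc, qry$residues[1], other), species = "tmpl")
  expect_null(find_rbh("g1", tmpl2, qry))
  expect_error(find_rbh("nope", tmpl, qry), "not found")
})

test_that("RBH relation is symmetric under deterministic tie-breaking", {
  scen <- small_scenario()
  exp_rbh <- scen$manifest$expected_rbh
  picks <- exp_rbh[unique(round(seq(1, nrow(exp_rbh), length.out = 4))), ]
  for (k in seq_len(nrow(picks))) {
    tp <- scen$template_proteomes[[picks$species[k]]]
    fwd <- find_rbh(picks$template_gene[k], tp, scen$query_proteome)
    expect_identical(fwd$query_id, picks$query_id[k])
    rev <- find_rbh(picks$query_id[k], scen$query_proteome, tp)
    expect_identical(rev$query_id, picks$template_gene[k])
  }
})

test_that("assign_functions recovers the planted evidence exactly", {
  scen <- small_scenario()
  ann <- small_annotation()
  got <- as.data.frame(ann)[, c("query_id", "function_label", "species",
                                "template_gene", "H", "F")]
  got <- got[order(got$query_id, got$function_label, got$species), ]
  rownames(got) <- NULL
  expect_identical(got, scen$manifest$expected_evidence)
  # both evidence kinds are exercised
  expect_true(any(ann$hit_kind == "rbh"))
  expect_true(any(ann$hit_kind == "secondary_confirmed"))
  expect_true(all(ann$H[ann$hit_kind == "rbh"] == 1))
  expect_true(all(ann$H[ann$hit_kind == "secondary_confirmed"] == 0.5))
})

test_that("every evidence item's forward hit passes the filter thresholds", {
  ann <- small_annotation()
  cfg <- filter_config()
  expect_true(all(ann$fwd_evalue <= cfg$max_evalue))
  expect_true(all(ann$fwd_pident >= cfg$min_pident))
  expect_true(all(ann$fwd_qcov >= cfg$min_qcov))
  # at most one evidence item per (query, function, species)
  key <- paste(ann$query_id, tolower(ann$function_label), ann$species)
  expect_false(anyDuplicated(key) > 0)
})

test_that("non-RBH hits need an identical second-pass function label", {
  set.seed(9)
  anc <- random_residues(150)
  g2res <- mutate_residues(anc, 0.8, "protein")
  tmpl_prot <- seq_set(c("g1", "g2"), c(anc, g2res), species = "sp1")
  qry <- seq_set(c("c1", "c2"), c(anc, g2res), species = "qry")
  reactions <- data.frame(reaction_id = c("R1", "R2"),
                          ec_numbers = c("1.1.1.1", "1.1.1.2"),
                          substrates = c("a", "b"), products = c("b", "c"),
                          sub_pathway = "other", stringsAsFactors = FALSE)
  genes <- data.frame(species = "sp1", gene_id = c("g1", "g2"),
                      function_label = c("alpha", "beta"),
                      ec_numbers = c("1.1.1.1", "1.1.1.2"),
                      clarity = "clear", stringsAsFactors = FALSE)
  tpl <- pathway_template("micro", reactions, genes)
  ann <- assign_functions(tpl, list(sp1 = tmpl_prot), qry)
  # c2 hits g1 above threshold, but its best second-pass match is g2 whose
  # label differs -> no 'alpha' evidence for c2; both proteins keep their RBH
  expect_false(any(ann$query_id == "c2" & ann$function_label == "alpha"))
  expect_true(any(ann$query_id == "c2" & ann$function_label == "beta" &
                    ann$H == 1))
  expect_true(any(ann$query_id == "c1" & ann$function_label == "alpha" &
                    ann$H == 1))

  # same fixture but identical labels: the non-RBH hit is now confirmed
  genes$function_label <- c("alpha", " ALPHA ")  # equal after normalization
  tpl2 <- pathway_template("micro2", reactions, genes)
  ann2 <- assign_functions(tpl2, list(sp1 = tmpl_prot), qry)
  expect_true(all(ann2$H == 1))  # RBH beats secondary within each pair
  expect_identical(sort(unique(ann2$query_id)), c("c1", "c2"))
})

test_that("precomputed hit tables reproduce the internal-engine annotation", {
  scen <- small_scenario()
  sc <- scoring_scheme("protein")
  fwd <- list(); rev <- list()
  for (s in names(scen$template_proteomes)) {
    tp <- scen$template_proteomes[[s]]
    genes <- scen$template$genes$gene_id[scen$template$genes$species == s]
    gene_seqs <- seq_set(genes, tp$residues[match(genes, tp$id)], species = s)
    fwd[[s]] <- best_hits(gene_seqs, scen$query_proteome, sc)
    rev[[s]] <- best_hits(scen$query_proteome, tp, sc)
  }
  ann_pre <- assign_functions(scen$template, scen$template_proteomes,
                              scen$query_proteome,
                              forward_hits = fwd, reverse_hits = rev)
  expect_identical(as.data.frame(ann_pre), as.data.frame(small_annotation()))
})
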