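test_that("EC intersection attaches proteins and reports gaps", {
  scored <- mk_scored("p1", "sucrose synthase", "2.4.1.13")
  pw <- build_pathway(toy_template(), scored)
  expect_identical(pw$assignments$R1$query_id, "p1")
  expect_identical(nrow(pw$assignments$R2), 0L)
  expect_identical(pw$gaps, "R2")
  expect_identical(nrow(pw$unplaced), 0L)

  # an annotation with two ECs attaches to both reactions
  scored2 <- mk_scored("p2", "bifunctional", "2.4.1.13;2.7.7.27")
  pw2 <- build_pathway(toy_template(), scored2)
  expect_identical(pw2$assignments$R1$query_id, "p2")
  expect_identical(pw2$assignments$R2$query_id, "p2")
  expect_identical(pw2$gaps, character(0))

  # ECs matching no reaction land in unplaced
  scored3 <- mk_scored("p3", "unrelated", "9.9.9.9")
  pw3 <- build_pathway(toy_template(), scored3)
  expect_identical(pw3$unplaced$query_id, "p3")
  expect_identical(sort(pw3$gaps), c("R1", "R2"))
})

test_that("proteins within a reaction are ordered by MS, CS, then id", {
  ev <- data.frame(
    query_id = c("pz", "pa", "pa", "pm"), function_label = "sucrose synthase",
    ec_numbers = "2.4.1.13",
    species = c("arabidopsis", "arabidopsis", "rice", "arabidopsis"),
    H = c(1, 0.5, 0.5, 1), F = c(1, 1, 1, 1), stringsAsFactors = FALSE)
  scored <- score_table(ev, score_config(5))
  pw <- build_pathway(toy_template(), scored)
  # pz and pm have MS 1 (id tie-break), pa has MS 0.5
  expect_identical(pw$assignments$R1$query_id, c("pm", "pz", "pa"))
})

test_that("stats: counts per sub-pathway and species; degenerate inputs", {
  ev <- data.frame(query_id = c("p1", "p2", "p3"),
                   function_label = "sucrose synthase",
                   ec_numbers = "2.4.1.13", species = "arabidopsis",
                   H = 1, F = 1, stringsAsFactors = FALSE)
  pw <- build_pathway(toy_template(), score_table(ev, score_config(5)))
  st <- pathway_stats(pw)
  suc <- st$sub_pathways[st$sub_pathways$sub_pathway == "sucrose_synthesis", ]
  expect_equal(suc$mean_proteins, 3)
  expect_equal(suc$n_gaps, 0)
  sta <- st$sub_pathways[st$sub_pathways$sub_pathway == "starch_synthesis", ]
  expect_equal(sta$n_gaps, 1)
  expect_equal(sta$mean_proteins, 0)  # no covered reaction, no NaN
  expect_equal(st$species$n_template_genes, 2)
  expect_equal(st$species$n_query_annotated, 3)

  # completely empty annotation set
  empty <- score_table(structure(list(), class = c("annotation_set", "data.frame")))
  pw0 <- build_pathway(toy_template(), empty)
  st0 <- pathway_stats(pw0)
  expect_equal(st0$n_proteins, 0)
  expect_equal(st0$n_gaps, 2)
  expect_true(all(st0$sub_pathways$mean_proteins == 0))
})

test_that("gaps and stats are invariant to annotation order", {
  scen <- small_scenario()
  ann <- as.data.frame(small_annotation())
  cfg <- score_config(n_templates = 3)
  pw1 <- build_pathway(scen$template, score_table(ann, cfg))
  set.seed(14)
  shuffled <- ann[sample(nrow(ann)), ]
  pw2 <- build_pathway(scen$template, score_table(shuffled, cfg))
  expect_identical(pw1$gaps, pw2$gaps)
  expect_identical(pathway_stats(pw1)$sub_pathways,
                   pathway_stats(pw2)$sub_pathways)
  expect_identical(pw1$assignments, pw2$assignments)
  # planted gaps are recovered exactly
  expect_identical(sort(pw1$gaps), sort(unlist(scen$manifest$expected_gaps)))
})

test_that("removing all annotations for one EC gaps exactly its reactions", {
  scen <- small_scenario()
  cfg <- score_config(n_templates = 3)
  ann <- as.data.frame(small_annotation())
  full <- build_pathway(scen$template, score_table(ann, cfg))
  ec_drop <- scen$manifest$families$ec[!scen$manifest$families$gap][1]
  pruned <- ann[!grepl(ec_drop, ann$ec_numbers, fixed = TRUE), ]
  part <- build_pathway(scen$template, score_table(pruned, cfg))
  only_that_ec <- scen$template$reactions$reaction_id[
    scen$template$reactions$ec_numbers == ec_drop]
  expect_identical(sort(part$gaps), sort(c(full$gaps, only_that_ec)))
})

test_that("known-gene validation matches planted genes and flags annotations", {
  scen <- small_scenario()
  scored <- score_table(small_annotation(), score_config(n_templates = 3))
  rep <- validate_against_known(scored, scen$known, scen$query_proteome)
  expect_equal(rep$matched_genes, nrow(scen$known))
  expect_identical(
    sort(rep$pairs$protein_id[rep$pairs$matched]),
    sort(scen$manifest$known$query_id))
  expect_true(all(rep$annotations$validated[
    rep$annotations$query_id %in% scen$manifest$known$query_id]))
  expect_true(rep$frac_validated_bc >= 0 && rep$frac_validated_bc <= 1)
})

test_that("validation identity threshold is inclusive at the best hit's value", {
  scen <- small_scenario()
  scored <- score_table(small_annotation(), score_config(n_templates = 3))
  set.seed(15)
  target <- scen$query_proteome[scen$query_proteome$id ==
                                  scen$manifest$known$query_id[1], ]
  diverged <- seq_set("kn1", mutate_residues(target$residues, 0.85, "protein"),
                      species = "known")
  rep85 <- validate_against_known(scored, diverged, scen$query_proteome)
  expect_equal(rep85$matched_genes, 0)  # ~85% identity fails the 90 floor
  best_pid <- rep85$pairs$pident[1]
  rep_at <- validate_against_known(scored, diverged, scen$query_proteome,
                                   min_pident = best_pid)
  expect_equal(rep_at$matched_genes, 1)  # inclusive at the exact value
  rep_above <- validate_against_known(scored, diverged, scen$query_proteome,
                                      min_pident = best_pid + 1e-6)
  expect_equal(rep_above$matched_genes, 0)
})

test_that("empty known set warns and returns an empty report", {
  scored <- mk_scored("p1", "sucrose synthase", "2.4.1.13")
  expect_warning(rep <- validate_against_known(scored, NULL, NULL), "empty")
  expect_equal(rep$n_known, 0)
  expect_true(is.na(rep$frac_validated_bc))
})
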