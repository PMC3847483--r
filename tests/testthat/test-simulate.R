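test_that("mutate_sequence hits the target identity exactly", {
  set.seed(21)
  p <- seq_set("anc", random_residues(200))
  expect_identical(mutate_sequence(p, 1.0)$residues, p$residues)
  m <- mutate_sequence(p, 0.9)
  same <- mapply(identical, strsplit(p$residues, "")[[1]],
                 strsplit(m$residues, "")[[1]])
  expect_identical(sum(same), 180L)  # exactly 180 of 200 positions kept
  expect_error(mutate_sequence(p, 1 / 500), "1/length")
  expect_error(mutate_sequence(p, 0), "\\(0, 1\\]")
})

test_that("engine-measured identity stays within 2 points of the target", {
  set.seed(22)
  sc <- scoring_scheme("protein")
  parent <- random_residues(150)
  targets <- runif(100, 0.7, 1)
  mutants <- vapply(targets, function(t) mutate_residues(parent, t, "protein"),
                    character(1))
  hits <- best_hits(make_seqs(mutants, prefix = "m"),
                    seq_set("parent", parent), sc)
  expect_identical(nrow(hits), 100L)
  realized <- hits$pident[match(paste0("m", seq_along(targets)), hits$query_id)]
  expect_true(all(realized >= 100 * targets - 2))
})

test_that("back-translation decodes to the original protein", {
  set.seed(23)
  res <- random_residues(80)
  nt <- back_translate(res)
  expect_identical(nchar(nt), 240L)
  decoded <- as.character(Biostrings::translate(Biostrings::DNAString(nt)))
  expect_identical(decoded, res)
  expect_error(back_translate("MKX"), "cannot back-translate")
})

test_that("scenario generation is byte-identical under a fixed seed", {
  cfg <- scenario_config(seed = 99, n_species = 2, n_families = 4,
                         n_decoys = 3, n_paralog_families = 1,
                         gap_families = 1, n_known = 2,
                         length_range = c(80L, 120L))
  d1 <- file.path(tempdir(), "orthopath-det-a")
  d2 <- file.path(tempdir(), "orthopath-det-b")
  s1 <- generate_scenario(cfg, d1)
  s2 <- generate_scenario(cfg, d2)
  f1 <- sort(list.files(d1))
  expect_identical(f1, sort(list.files(d2)))
  for (f in f1) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     info = f)
  }
})

test_that("invalid configurations fail before any file is written", {
  expect_error(scenario_config(decoy_identity_max = 0.9), "below the ortholog")
  expect_error(scenario_config(gap_families = 30, n_families = 30),
               "smaller than n_families")
  expect_error(scenario_config(n_known = 40, n_families = 30), "n_known")
  expect_error(scenario_config(ortholog_identity = c(0, 0.9)), "\\(0, 1\\]")
  expect_error(generate_scenario(scenario_config()), "directory")
})

test_that("manifest is complete and internally consistent with the bundle", {
  scen <- small_scenario()
  man <- scen$manifest
  fams <- man$families
  # every query record is an ortholog, a paralog or a decoy -- exactly once
  expected_ids <- c(fams$query_id[!is.na(fams$query_id)],
                    fams$paralog_id[!is.na(fams$paralog_id)],
                    grep("^9", scen$query_proteome$id, value = TRUE))
  expect_identical(sort(scen$query_proteome$id), sort(expected_ids))
  # gap bookkeeping
  expect_identical(sort(unlist(man$expected_gaps)),
                   sort(fams$reaction_id[fams$gap]))
  expect_identical(sum(fams$gap), 2L)
  expect_true(all(is.na(fams$query_id[fams$gap])))
  # template genes exist in their proteomes
  g <- scen$template$genes
  for (s in unique(g$species)) {
    expect_true(all(g$gene_id[g$species == s] %in%
                      scen$template_proteomes[[s]]$id))
  }
  # evidence H/F values are legal and expected candidates respect N_t
  ev <- man$expected_evidence
  expect_true(all(ev$H %in% c(1, 0.5) & ev$F %in% c(1, 0.5)))
  expect_true(all(man$expected_candidates$n_m <= 3))
  # files round-trip through the package readers
  q <- read_fasta(scen$paths$query, "protein", "query")
  expect_identical(q$residues, scen$query_proteome$residues)
  tpl <- read_pathway_template(scen$paths$template_file)
  expect_identical(tpl$reactions, scen$template$reactions)
})
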