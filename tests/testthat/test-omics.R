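test_that("expression reader validates shape and values", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("probe_id\tfibrous\tdeveloping\tmature",
               "p1\t10\t20\t30", "p2\t5\t5\t5"), f)
  tab <- read_expression(f)
  expect_s3_class(tab, "expression_table")
  expect_identical(names(tab), c("probe_id", "fibrous", "developing", "mature"))
  writeLines(c("probe_id\tc1\tc1", "p1\t1\t2"), f)
  expect_error(read_expression(f), "duplicate condition")
  writeLines(c("probe_id\tc1\tc2", "p1\t-1\t2"), f)
  expect_error(read_expression(f), "non-negative")
})

test_that("probes map to genes they are substrings of, not to decoys", {
  scen <- small_scenario()
  mapping <- map_probes(scen$genes_nt, scen$probes)
  exp_map <- scen$manifest$probe_map
  got <- mapping[, c("probe_id", "gene_id")]
  got <- got[order(got$probe_id, got$gene_id), ]
  rownames(got) <- NULL
  exp_map <- exp_map[order(exp_map$probe_id, exp_map$gene_id), ]
  rownames(exp_map) <- NULL
  expect_identical(got, exp_map)
  expect_true(all(mapping$pident == 100))  # planted probes are exact substrings
  expect_false(any(grepl("decoy", mapping$probe_id)))
  expect_error(map_probes(scen$query_proteome, scen$probes), "nucleotide")
})

test_that("probe mapping is monotone in thresholds and inclusive at them", {
  scen <- small_scenario()
  loose <- map_probes(scen$genes_nt, scen$probes, min_pident = 80)
  tight <- map_probes(scen$genes_nt, scen$probes, min_pident = 95)
  expect_true(all(paste(tight$probe_id, tight$gene_id) %in%
                    paste(loose$probe_id, loose$gene_id)))
  at <- map_probes(scen$genes_nt, scen$probes, min_pident = 100)
  expect_identical(nrow(at), nrow(tight))  # exact probes sit at pident 100
})

test_that("fold-change filter: ratio rule, floor clamp, probe averaging", {
  tab <- data.frame(probe_id = c("a1", "a2", "b1", "c1"),
                    f = c(8, 12, 10, 0), d = c(10, 10, 12, 0),
                    m = c(28, 32, 15, 5), stringsAsFactors = FALSE)
  mapping <- data.frame(probe_id = c("a1", "a2", "b1", "c1"),
                        gene_id = c("gA", "gA", "gB", "gC"),
                        stringsAsFactors = FALSE)
  ov <- fold_change_filter(tab, mapping, fold = 2)
  # gA: means (10, 10, 30) -> ratio 3 passes; gB: (10, 12, 15) ratio 1.5 fails
  expect_identical(sort(ov$gene_id), c("gA", "gC"))
  expect_equal(unlist(ov[ov$gene_id == "gA", c("f", "d", "m")],
                      use.names = FALSE), c(10, 10, 30))
  expect_equal(ov$n_probes[ov$gene_id == "gA"], 2L)
  # gC: min 0 clamped at floor 1 -> ratio 5 passes
  expect_equal(ov$fold_ratio[ov$gene_id == "gC"], 5)
  excluded <- attr(ov, "excluded")
  expect_identical(excluded$gene_id, "gB")
  # probe order does not change the means
  ov2 <- fold_change_filter(tab, mapping[c(3, 2, 4, 1), ], fold = 2)
  expect_equal(ov[order(ov$gene_id), c("f", "d", "m")],
               ov2[order(ov2$gene_id), c("f", "d", "m")], ignore_attr = TRUE)
})

test_that("planted monotone genes pass, flat controls fail", {
  scen <- small_scenario()
  mapping <- map_probes(scen$genes_nt, scen$probes)
  ov <- fold_change_filter(scen$expression, mapping)
  expect_identical(sort(ov$gene_id), sort(unlist(scen$manifest$expression_pass)))
  expect_true(all(ov$fold_ratio >= 2))
})

test_that("overlay attaches per-condition vectors only for passing genes", {
  scen <- small_scenario()
  scored <- score_table(small_annotation(), score_config(n_templates = 3))
  pw <- build_pathway(scen$template, scored)
  mapping <- map_probes(scen$genes_nt, scen$probes)
  ov <- fold_change_filter(scen$expression, mapping)
  pw <- attach_overlay(pw, ov)
  ex <- do.call(rbind, pw$expression)
  expect_true(all(ex$gene_id %in% ov$gene_id))
  expect_identical(sort(unique(ex$gene_id)), sort(ov$gene_id))
  expect_identical(setdiff(names(ex), c("protein_id", "gene_id")),
                   c("fibrous", "developing", "mature"))
})

test_that("graph export: structure, gap flag and parse-back oracle", {
  skip_if_not_installed("igraph")
  scored <- mk_scored("p1", "sucrose synthase", "2.4.1.13")
  pw <- build_pathway(toy_template(), scored)
  f <- withr::local_tempfile(fileext = ".graphml")
  write_pathway_graph(pw, f, "graphml")
  g <- igraph::read_graph(f, format = "graphml")
  # 4 metabolites + 2 reactions; 2 edges per reaction
  expect_equal(igraph::vcount(g), 6)
  expect_equal(igraph::ecount(g), 4)
  at <- igraph::vertex_attr(g)
  expect_identical(at$gap[at$id == "R2"], "true")
  expect_identical(at$gap[at$id == "R1"], "false")
  expect_identical(at$proteins[at$id == "R1"], "p1")
  expect_error(write_pathway_graph(pw, f, "dot"), "unknown graph format")

  fj <- withr::local_tempfile(fileext = ".json")
  write_pathway_graph(pw, fj, "json")
  j <- jsonlite::read_json(fj, simplifyVector = TRUE)
  expect_equal(nrow(j$nodes), 6)
  expect_equal(nrow(j$edges), 4)
})

test_that("expression vectors survive the GraphML round trip as strings", {
  skip_if_not_installed("igraph")
  scen <- small_scenario()
  scored <- score_table(small_annotation(), score_config(n_templates = 3))
  pw <- build_pathway(scen$template, scored)
  mapping <- map_probes(scen$genes_nt, scen$probes)
  ov <- fold_change_filter(scen$expression, mapping)
  pw <- attach_overlay(pw, ov)
  f <- withr::local_tempfile(fileext = ".graphml")
  write_pathway_graph(pw, f, "graphml")
  g <- igraph::read_graph(f, format = "graphml")
  at <- igraph::vertex_attr(g)
  carried <- which(nzchar(at$expr_proteins))
  expect_gt(length(carried), 0)
  for (i in carried) {
    rid <- at$id[i]
    ex <- pw$expression[[rid]]
    expect_identical(at$expr_fibrous[i],
                     paste(format(ex$fibrous, digits = 15), collapse = ";"))
  }
  # non-passing genes appear on no node
  failing <- attr(ov, "excluded")$gene_id
  if (length(failing)) {
    expect_false(any(vapply(strsplit(at$expr_proteins[carried], ";"),
                            function(p) any(substr(p, 1, 6) %in% failing),
                            logical(1))))
  }
})
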