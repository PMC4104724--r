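# Synthetic-data generators: planted structure, determinism, calibration.

test_that("generated cohort matches the requested design", {
  cohort <- generate_expression(100, 63, 20, n_de = 10, effect_size = 1.5,
                                noise_sd = 1, seed = 1)
  expect_equal(dim(cohort$expr), c(100L, 83L))
  expect_equal(sum(cohort$pheno == 1L), 63L)
  expect_equal(sum(cohort$pheno == 0L), 20L)
  expect_length(cohort$truth$de_probe_ids, 10L)
  expect_true(all(cohort$truth$de_probe_ids %in% rownames(cohort$expr)))
  expect_false(anyDuplicated(cohort$truth$de_probe_ids) > 0)
  # 50/50 direction split, extra probe positive when odd
  expect_equal(sum(cohort$truth$effect_sizes > 0), 5L)
  odd <- generate_expression(50, 5, 5, n_de = 7, effect_size = 1, noise_sd = 1,
                             seed = 2)
  expect_equal(sum(odd$truth$effect_sizes > 0), 4L)
})

test_that("generation is deterministic under a seed and varies across seeds", {
  a <- generate_expression(50, 6, 5, n_de = 4, effect_size = 1, noise_sd = 1, seed = 7)
  b <- generate_expression(50, 6, 5, n_de = 4, effect_size = 1, noise_sd = 1, seed = 7)
  c <- generate_expression(50, 6, 5, n_de = 4, effect_size = 1, noise_sd = 1, seed = 8)
  expect_identical(a, b)
  expect_false(identical(a$expr, c$expr))
})

test_that("null cohorts have no planted truth and calibrated group means", {
  cohort <- generate_expression(1000, 63, 20, n_de = 0, noise_sd = 1, seed = 3)
  expect_length(cohort$truth$de_probe_ids, 0L)
  diffs <- abs(rowMeans(cohort$expr[, cohort$pheno == 1]) -
               rowMeans(cohort$expr[, cohort$pheno == 0]))
  expect_gte(mean(diffs < 4 * 1 / sqrt(20)), 0.99)
})

test_that("vanishing noise isolates the planted shift", {
  cohort <- generate_expression(30, 4, 4, n_de = 2, effect_size = 1.5,
                                noise_sd = 1e-9, seed = 5)
  diffs <- rowMeans(cohort$expr[, cohort$pheno == 1]) -
           rowMeans(cohort$expr[, cohort$pheno == 0])
  de <- rownames(cohort$expr) %in% cohort$truth$de_probe_ids
  expect_equal(unname(abs(diffs[de])), rep(1.5, 2), tolerance = 1e-6)
  expect_lt(max(abs(diffs[!de])), 1e-6)
})

test_that("invalid generator parameters are rejected", {
  expect_error(generate_expression(10, 1, 5, seed = 1), "2 samples")
  expect_error(generate_expression(10, 5, 5, n_de = 11, seed = 1), "n_de")
  expect_error(generate_expression(10, 5, 5, noise_sd = 0, seed = 1), "noise_sd")
  expect_error(generate_expression(10, 5, 5, effect_size = -1, seed = 1),
               "effect_size")
})

test_that("annotation maps probes many-to-one onto full gene coverage", {
  ids <- sprintf("P%05d_at", 1:120)
  ann <- generate_annotation(ids, probes_per_gene = 1.2, seed = 1)
  expect_named(ann, ids)
  genes <- unique(ann[nzchar(ann)])
  expect_equal(length(genes), 100L)            # 120 / 1.2
  expect_true(all(table(ann) >= 1))
  ann2 <- generate_annotation(ids, unannotated_frac = 0.1, seed = 1)
  expect_equal(sum(!nzchar(ann2)), 12L)
})

test_that("planted enriched sets over-draw DE genes", {
  cohort <- small_cohort(n_probes = 300, n_de = 40)
  ann <- generate_annotation(rownames(cohort$expr), seed = 1)
  truth <- cohort$truth
  truth$enriched_set_ids <- "GS001"
  de_genes <- unique(ann[truth$de_probe_ids])

  # strength 1 with a small set: pure subset of DE genes
  sets1 <- generate_gene_sets(ann, 5, 10, 20, truth,
                              enrichment_strength = 1, seed = 2)
  expect_true(all(sets1$members$GS001 %in% de_genes))

  # strength 0: null collection, planted id treated like any other
  sets0 <- generate_gene_sets(ann, 5, 10, 20, truth,
                              enrichment_strength = 0, seed = 2)
  expect_false(all(sets0$members$GS001 %in% de_genes))

  # strength 0.5: planted set's DE overlap beats the null median, 20 seeds
  wins <- vapply(1:20, function(s) {
    sets <- generate_gene_sets(ann, 50, 10, 50, truth,
                               enrichment_strength = 0.5, seed = s)
    ov <- vapply(sets$members, function(m) length(intersect(m, de_genes)) /
                   length(m), numeric(1))
    ov[["GS001"]] > stats::median(ov[names(ov) != "GS001"])
  }, logical(1))
  expect_true(all(wins))
})

test_that("interaction generator plants hubs and keeps graphs simple", {
  genes <- sprintf("G%03d", 1:50)
  g <- generate_interactions(genes, mean_degree = 1, hub_ids = "G001",
                             hub_degree = 10, seed = 1)
  expect_true(igraph::is_simple(g))
  deg <- compute_degrees(g)
  expect_gte(deg[["G001"]], 10)
  expect_equal(sum(deg), 2L * igraph::ecount(g))

  # edgeless limit
  g0 <- generate_interactions(genes, mean_degree = 0, seed = 1)
  expect_equal(igraph::ecount(g0), 0L)

  # planted hubs dominate the degree ranking in nearly all seeds
  genes200 <- sprintf("G%03d", 1:200)
  hubs <- c("G005", "G050", "G150")
  hits <- vapply(1:20, function(s) {
    gg <- generate_interactions(genes200, mean_degree = 2, hub_ids = hubs,
                                hub_degree = 15, seed = s)
    d <- compute_degrees(gg)
    all(hubs %in% names(sort(d, decreasing = TRUE))[1:3])
  }, logical(1))
  expect_gte(sum(hits), 18)

  expect_error(generate_interactions(genes, 1, "G001", hub_degree = 50, seed = 1),
               "hub_degree")
  expect_error(generate_interactions(genes, 1, "NOPE", 5, seed = 1), "hub_ids")
})

test_that("synthetic bundles round-trip through the readers", {
  cohort <- small_cohort()
  ann <- generate_annotation(rownames(cohort$expr), seed = 1)
  truth <- cohort$truth
  truth$enriched_set_ids <- "GS001"
  sets <- generate_gene_sets(ann, 8, 5, 15, truth, 0.8, seed = 3)
  g <- generate_interactions(unique(ann), 2, seed = 4)
  dir <- withr::local_tempdir()
  paths <- write_synthetic_inputs(cohort, ann, sets, g, dir)
  expect_equal(read_expression(paths[["expression"]]), cohort$expr)
  expect_equal(read_phenotype(paths[["phenotype"]], cohort$expr), cohort$pheno)
  expect_equal(read_annotation(paths[["annotation"]]), ann)
  rt <- read_gene_sets(paths[["gene_sets"]])
  expect_equal(lapply(rt$members, sort), lapply(sets$members, sort))
  g2 <- read_edge_list(paths[["edges"]])
  expect_setequal(igraph::V(g2)$name, igraph::V(g)$name)
  d1 <- compute_degrees(g); d2 <- compute_degrees(g2)
  expect_equal(d2[sort(names(d2))], d1[sort(names(d1))])
  truth_json <- jsonlite::read_json(paths[["truth"]], simplifyVector = TRUE)
  expect_equal(truth_json$de_probe_ids, cohort$truth$de_probe_ids)
})
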