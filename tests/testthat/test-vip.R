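# VIP scoring, cross-validated h selection, permutation FDR, gene selection.

test_that("VIP reduces to 1 under uniform weights and keeps its identity", {
  p <- 16
  fake <- structure(list(h = 1L,
                         W = matrix(1 / sqrt(p), p, 1,
                                    dimnames = list(paste0("p", 1:p), NULL)),
                         T = matrix(c(rep(0, 4), rep(1, 4)) - 0.5, 8, 1),
                         probe_ids = paste0("p", 1:p)),
                    class = "pls_model")
  pheno <- setNames(c(rep(0L, 4), rep(1L, 4)), paste0("s", 1:8))
  vip <- compute_vip(fake, pheno)
  expect_equal(unname(vip), rep(1, p), tolerance = 1e-12)

  cohort <- small_cohort()
  fit <- nipals_fit(standardize(cohort$expr, cohort$pheno), 3)
  vip <- compute_vip(fit, cohort$pheno)
  expect_equal(sum(vip^2), length(vip), tolerance = 1e-6 * length(vip))
  expect_true(all(vip >= 0))
})

test_that("VIP matches a brute-force double-loop evaluation", {
  cohort <- small_cohort(n_probes = 30, n_cases = 12, n_controls = 8)
  fit <- nipals_fit(standardize(cohort$expr, cohort$pheno), 3)
  vip <- compute_vip(fit, cohort$pheno)
  r2 <- vapply(1:3, function(k) cor(as.numeric(cohort$pheno), fit$T[, k])^2,
               numeric(1))
  p <- length(fit$probe_ids)
  brute <- numeric(p)
  for (j in seq_len(p)) {
    num <- 0
    for (k in 1:3) {
      w_kj <- fit$W[j, k] / sqrt(sum(fit$W[, k]^2))
      num <- num + r2[k] * w_kj^2
    }
    brute[j] <- sqrt(p * num / sum(r2))
  }
  expect_equal(unname(vip), brute, tolerance = 1e-10)
})

test_that("cross-validation picks the smallest h at maximal accuracy", {
  cohort <- small_cohort(n_cases = 12, n_controls = 9)
  cv1 <- choose_h_cv(cohort$expr, cohort$pheno, h_max = 1, seed = 1)
  expect_equal(cv1$chosen_h, 1L)

  cv <- choose_h_cv(cohort$expr, cohort$pheno, h_max = 4, seed = 1)
  acc <- cv$curve$accuracy
  expect_equal(cv$chosen_h, which(acc >= max(acc) - 1e-12)[1])
  expect_true(all(acc >= 0 & acc <= 1))
  expect_identical(cv, choose_h_cv(cohort$expr, cohort$pheno, h_max = 4, seed = 1))

  tiny <- generate_expression(20, 3, 2, n_de = 0, seed = 1)
  expect_error(choose_h_cv(tiny$expr, tiny$pheno, h_max = 2, n_folds = 3, seed = 1),
               "fewer than 3 folds")
})

test_that("permutation FDR equals a direct evaluation of the pooled double sum", {
  # tiny instance: 3 probes, 6 samples, 2 permutations -- small enough that
  # the double sum can be checked by hand from the printed VIP values
  cohort <- generate_expression(3, 3, 3, n_de = 1, effect_size = 3,
                                noise_sd = 0.5, seed = 11)
  for (np in c(2L, 20L)) {
    res <- permutation_fdr(cohort$expr, cohort$pheno, h = 1, n_perm = np,
                           seed = 5)
    p <- length(res$probe_ids)
    # independent reconstruction: same canonical permutation stream, then a
    # literal double loop over permutations and probes
    ord <- order(names(cohort$pheno))
    set.seed(5)
    null_vip <- matrix(0, p, np)
    for (j in seq_len(np)) {
      perm <- sample(length(cohort$pheno))
      y_perm <- cohort$pheno
      y_perm[ord] <- cohort$pheno[ord][perm]
      f <- nipals_fit(standardize(cohort$expr, y_perm), 1)
      null_vip[, j] <- compute_vip(f, y_perm)
    }
    obs <- compute_vip(nipals_fit(standardize(cohort$expr, cohort$pheno), 1),
                       cohort$pheno)
    fdr_brute <- numeric(p)
    for (i in seq_len(p)) {
      count <- 0
      for (j in seq_len(np)) for (i2 in seq_len(p))
        if (null_vip[i2, j] > obs[i]) count <- count + 1
      fdr_brute[i] <- (count / np) / p
    }
    expect_equal(res$fdr, fdr_brute, tolerance = 1e-12)
    expect_equal(res$vip, unname(obs), tolerance = 1e-12)
  }
})

test_that("pooled FDR matches brute force on a larger random instance", {
  cohort <- generate_expression(10, 5, 4, n_de = 2, effect_size = 1,
                                noise_sd = 1, seed = 21)
  res <- permutation_fdr(cohort$expr, cohort$pheno, h = 2, n_perm = 20, seed = 9)
  ord <- order(names(cohort$pheno))
  set.seed(9)
  nulls <- c()
  for (j in 1:20) {
    perm <- sample(length(cohort$pheno))
    y_perm <- cohort$pheno
    y_perm[ord] <- cohort$pheno[ord][perm]
    f <- nipals_fit(standardize(cohort$expr, y_perm), 2)
    nulls <- c(nulls, compute_vip(f, y_perm))
  }
  obs <- res$vip
  brute <- vapply(obs, function(v) sum(nulls > v) / 20 / length(obs), numeric(1))
  expect_equal(res$fdr, unname(brute), tolerance = 1e-12)
})

test_that("pooled FDR is monotone non-increasing in VIP and bounded", {
  cohort <- small_cohort(n_probes = 40, n_de = 4, effect_size = 5,
                         noise_sd = 0.5)
  res <- permutation_fdr(cohort$expr, cohort$pheno, h = 1, n_perm = 50, seed = 3)
  ord <- order(res$vip, decreasing = TRUE)
  expect_true(all(diff(res$fdr[ord]) >= 0))
  expect_equal(min(res$fdr), res$fdr[which.max(res$vip)])
  expect_true(all(res$fdr >= 0 & res$fdr <= 1))
})

test_that("identically reordering samples leaves VIP and FDR unchanged", {
  cohort <- small_cohort(n_probes = 30)
  set.seed(7)
  sigma <- sample(ncol(cohort$expr))
  expr2 <- cohort$expr[, sigma]
  pheno2 <- cohort$pheno[sigma]
  a <- permutation_fdr(cohort$expr, cohort$pheno, h = 2, n_perm = 30, seed = 13)
  b <- permutation_fdr(expr2, pheno2, h = 2, n_perm = 30, seed = 13)
  expect_equal(a$vip, b$vip, tolerance = 1e-12)
  expect_equal(a$fdr, b$fdr, tolerance = 1e-12)
})

test_that("mean VIP of planted probes increases with effect size", {
  means <- vapply(c(0.5, 1, 2), function(es) {
    m <- vapply(1:3, function(s) {
      cohort <- generate_expression(200, 20, 15, n_de = 20, effect_size = es,
                                    noise_sd = 1, seed = s)
      fit <- nipals_fit(standardize(cohort$expr, cohort$pheno), 2)
      vip <- compute_vip(fit, cohort$pheno)
      mean(vip[cohort$truth$de_probe_ids])
    }, numeric(1))
    mean(m)
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("gene selection applies the strict FDR boundary and directions", {
  cohort <- small_cohort(n_probes = 30)
  fake <- structure(list(probe_ids = rownames(cohort$expr)[1:3],
                         vip = c(3, 2, 1), fdr = c(0.0, 0.01, 0.5),
                         h = 1L, n_perm = 10L, n_redrawn = 0L,
                         estimator = "pooled"),
                    class = "vip_fdr")
  tab <- select_genes(cohort$expr, cohort$pheno, fake, fdr_threshold = 0.01)
  expect_equal(tab$probe_id[tab$selected], fake$probe_ids[1])  # 0.01 not < 0.01

  tab_all <- select_genes(cohort$expr, cohort$pheno, fake, fdr_threshold = 1.0)
  expect_true(all(tab_all$selected))
  expect_equal(tab_all$fdr, sort(tab_all$fdr))                 # sorted output

  expect_error(select_genes(cohort$expr, cohort$pheno, fake, fdr_threshold = 0),
               "fdr_threshold")
  expect_error(select_genes(cohort$expr, cohort$pheno, fake, fdr_threshold = 1.5),
               "fdr_threshold")
})

test_that("selected probes recover the planted regulation direction", {
  cohort <- small_cohort(n_probes = 100, n_de = 10, effect_size = 2.5,
                         noise_sd = 0.8)
  res <- permutation_fdr(cohort$expr, cohort$pheno, h = 2, n_perm = 100, seed = 2)
  tab <- select_genes(cohort$expr, cohort$pheno, res)
  hits <- tab[tab$selected & tab$probe_id %in% cohort$truth$de_probe_ids, ]
  expect_gt(nrow(hits), 0)
  planted_up <- cohort$truth$effect_sizes[hits$probe_id] > 0
  expect_equal(hits$direction == "up", unname(planted_up))
})

test_that("probe-to-gene collapse keeps any gene with a selected probe", {
  ann <- c(p1 = "A", p2 = "A", p3 = "B", p4 = "")
  tab <- data.frame(probe_id = c("p1", "p2", "p3", "p4"),
                    selected = c(TRUE, FALSE, TRUE, TRUE),
                    gene = unname(ann), stringsAsFactors = FALSE)
  expect_setequal(selected_gene_symbols(tab), c("A", "B"))
})
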