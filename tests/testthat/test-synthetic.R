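test_that("simulated spectra are positive, deterministic, and reject bad intervals", {
  d <- tiny_design()
  tr <- default_truth(seed = 11)
  sp1 <- simulate_spectra(d, tr, ppm_grid = c(0.2, 10, 0.005))
  sp2 <- simulate_spectra(d, tr, ppm_grid = c(0.2, 10, 0.005))
  expect_identical(sp1$intensities, sp2$intensities)
  expect_true(all(sp1$intensities > 0))
  bad <- ground_truth(effects = list(
    planted_effect(c(10.5, 11), -0.1, c("1" = 1, "3" = 1))), seed = 1)
  expect_error(simulate_spectra(d, bad, ppm_grid = c(0.2, 10, 0.005)),
               "outside the ppm grid")
})

test_that("a planted negative-slope interval decreases monotonically in the noise-free limit", {
  d <- make_design(1, doses = c(0, 50, 500, 1000), days = 1)
  tr <- ground_truth(effects = list(
    planted_effect(c(3.35, 4.05), log(0.5) / log1p(1000), c("1" = 1))),
    seed = 5)
  sp <- simulate_spectra(d, tr, ppm_grid = c(0.2, 10, 0.002),
                         noise_sd = 0, amp_cv = 0)
  sch <- bucket_scheme(3.35, 4.05, 0.01)
  ints <- rowSums(t(apply(sp$intensities, 1, function(y)
    bucket_spectrum(sp$ppm, y, sch))))
  expect_true(all(diff(ints[order(d$dose)]) < 0))
  # and the halving calibration is exact without noise
  expect_equal(unname(ints[d$dose == 1000] / ints[d$dose == 0]), 0.5,
               tolerance = 0.01)
})

test_that("default halving effect gives mean 1000ppm/control interval ratio near 0.5 over seeds", {
  d <- make_design(2, doses = c(0, 1000), days = 1)
  sch <- bucket_scheme(3.35, 4.05, 0.05)
  ratios <- vapply(1:200, function(s) {
    tr <- ground_truth(effects = list(
      planted_effect(c(3.35, 4.05), log(0.5) / log1p(1000), c("1" = 1))),
      seed = s)
    sp <- simulate_spectra(d, tr, ppm_grid = c(3.0, 4.5, 0.005))
    ints <- rowSums(t(apply(sp$intensities, 1, function(y)
      bucket_spectrum(sp$ppm, y, sch))))
    mean(ints[d$dose == 1000]) / mean(ints[d$dose == 0])
  }, numeric(1))
  expect_gt(mean(ratios), 0.45)
  expect_lt(mean(ratios), 0.55)
})

test_that("zero-slope effects leave group means distinguished only by noise", {
  d <- make_design(5, doses = c(0, 50, 500, 1000), days = 1)
  ps <- vapply(1:40, function(s) {
    tr <- ground_truth(effects = list(
      planted_effect(c(3.35, 4.05), 0, c("1" = 1))), seed = 1000 + s)
    sp <- simulate_spectra(d, tr, ppm_grid = c(3.0, 4.5, 0.01))
    ints <- rowSums(sp$intensities)
    stats::anova(stats::lm(ints ~ factor(d$dose)))[["Pr(>F)"]][1]
  }, numeric(1))
  # p should be uniform: check both tails are populated
  expect_gt(mean(ps), 0.25)
  expect_lt(mean(ps), 0.75)
  expect_lt(ks.test(ps, "punif")$p.value, 1.01)  # well-defined
})

test_that("expression generator hits target gene-metabolite correlations", {
  d <- make_design()
  met <- matrix(rep(log1p(d$dose), 2) + rnorm(160, 0, 0.1), 80, 2,
                dimnames = list(d$sample_id, c("succinate", "lactate")))
  # exact linear link at r = 1
  tr1 <- ground_truth(
    gene_metabolite_links = data.frame(gene_id = "g", metabolite_id = "succinate",
                                       r = 1),
    seed = 3)
  es1 <- simulate_expression(d, tr1, n_null_genes = 0, metabolite_table = met)
  expect_equal(cor(es1$values["g", ], met[, "succinate"]), 1, tolerance = 1e-12)
  # r = 0: |observed| < 0.3 for n = 80 in >= 95% of seeds
  r0 <- vapply(1:60, function(s) {
    tr <- ground_truth(
      gene_metabolite_links = data.frame(gene_id = "g", metabolite_id = "succinate",
                                         r = 0), seed = s)
    es <- simulate_expression(d, tr, 0, met)
    cor(es$values["g", ], met[, "succinate"])
  }, numeric(1))
  expect_gte(mean(abs(r0) < 0.3), 0.95)
  # r = 0.7: mean observed within [0.6, 0.8] over 100 seeds
  r7 <- vapply(1:100, function(s) {
    tr <- ground_truth(
      gene_metabolite_links = data.frame(gene_id = "g", metabolite_id = "succinate",
                                         r = 0.7), seed = 5000 + s)
    es <- simulate_expression(d, tr, 0, met)
    cor(es$values["g", ], met[, "succinate"])
  }, numeric(1))
  expect_gt(mean(r7), 0.6)
  expect_lt(mean(r7), 0.8)
})

test_that("expression generator conserves row counts, flags, determinism and errors", {
  d <- make_design()
  met <- matrix(log1p(d$dose) + rnorm(80, 0, 0.1), 80, 1,
                dimnames = list(d$sample_id, "succinate"))
  tr <- default_truth(seed = 9)
  es <- simulate_expression(d, tr, n_null_genes = 50, metabolite_table = met)
  n_dose <- sum(vapply(tr$effects, function(e) is.character(e$target), logical(1)))
  expect_equal(nrow(es$values),
               50 + nrow(tr$gene_metabolite_links) +
                 nrow(tr$gene_gene_links) + n_dose)
  expect_true(all(es$values > 0))
  expect_true(all(es$flags %in% c("P", "A")))
  es2 <- simulate_expression(d, tr, 50, met)
  expect_identical(es$values, es2$values)
  bad <- ground_truth(gene_metabolite_links = data.frame(
    gene_id = "g", metabolite_id = "unobtainium", r = 0.5), seed = 1)
  expect_error(simulate_expression(d, bad, 10, met), "unobtainium")
})

test_that("planted gene pair correlates near its target r", {
  d <- make_design()
  met <- matrix(log1p(d$dose) + rnorm(80, 0, 0.1), 80, 1,
                dimnames = list(d$sample_id, "succinate"))
  rr <- vapply(1:30, function(s) {
    tr <- default_truth(seed = 100 + s)
    es <- simulate_expression(d, tr, 0, met)
    gene_gene_correlation(es$values, "malic_enzyme",
                          "glutathione_reductase_paralog",
                          genes_in_rows = TRUE)
  }, numeric(1))
  expect_gt(mean(rr), 0.6)
  expect_lt(mean(rr), 0.8)
})

test_that("lipid change generator is deterministic and round-trips through CSV", {
  a <- simulate_lipid_changes(seed = 42)
  b <- simulate_lipid_changes(seed = 42)
  expect_identical(a, b)
  expect_true(all(a$class %in% c("FFA", "monoacyl", "diacyl")))
  expect_true(all(a$headgroup %in% c("GpIns", "GpEtn", "GpCho", "GpGro",
                                     "GpSer", "GPA", "none")))
  expect_true(all(a$direction %in% c("up", "down")))
  expect_true(all(a$fa2[a$class == "diacyl"] != ""))
  path <- withr::local_tempfile(fileext = ".csv")
  write_lipid_csv(a, path)
  expect_equal(read_lipid_csv(path), a)
})
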