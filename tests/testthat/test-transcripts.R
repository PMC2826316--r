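make_es <- function(values, design, flags = NULL) {
  if (is.null(flags))
    flags <- matrix("P", nrow(values), ncol(values), dimnames = dimnames(values))
  expression_set(values, flags, design)
}

test_that("global normalization sets every array mean to 500", {
  withr::with_seed(1, m <- matrix(rexp(40, 1 / 600), 8, 5))
  g <- global_normalize(m)
  expect_equal(unname(colMeans(g)), rep(500, 5), tolerance = 1e-9)
  expect_equal(global_normalize(g), g, tolerance = 1e-12)
  m2 <- m; m2[, 2] <- m2[, 2] * 2
  expect_equal(global_normalize(m2)[, 2], g[, 2], tolerance = 1e-12)
})

test_that("flooring and per-gene median normalization", {
  m <- rbind(a = c(1, 2, 3), b = c(0.001, 2, 4), c = c(5, 5, 5))
  n <- floor_and_median_normalize(m)
  expect_equal(unname(n["a", ]), c(0.5, 1, 1.5))
  expect_equal(unname(n["b", 1]), 0.01 / 2)  # floored before division
  expect_equal(unname(n["c", ]), c(1, 1, 1))
  expect_equal(apply(n, 1, median), c(a = 1, b = 1, c = 1))
})

test_that("detection filter requires both flags and intensity", {
  d <- tiny_design(2, c(0, 1000), c(1, 3))  # 8 samples
  v <- matrix(1000, 3, 8, dimnames = list(c("flaggy", "dim", "dark"),
                                          d$sample_id))
  v["dim", ] <- c(95, 92, 91, 10, 10, 10, 10, 10)  # exactly 3 at >= 90
  f <- matrix("P", 3, 8, dimnames = dimnames(v))
  f["flaggy", ] <- c("P", "P", "A", "A", "A", "A", "A", "A")  # only 2 P
  f["dark", ] <- "A"
  keep <- filter_detected(make_es(v, d, f))
  expect_identical(keep, "dim")
})

test_that("fold-change filter is symmetric and cell-wise", {
  d <- make_design(3, c(0, 1000), c(1, 3))
  ctl <- d$dose == 0
  v <- matrix(1, 3, nrow(d), dimnames = list(c("flat", "up", "down"),
                                             d$sample_id))
  v["up", d$dose == 1000 & d$day == 1] <- 2       # r = 2 in one cell
  v["down", d$dose == 1000 & d$day == 3] <- 0.6   # 1/r ~ 1.67
  keep <- filter_foldchange(v, d, 1.5)
  expect_setequal(keep, c("up", "down"))
  d_noctl <- d[d$dose != 0 | d$day != 3, ]
  expect_error(filter_foldchange(v[, d_noctl$sample_id], d_noctl), "day")
})

test_that("two-way ANOVA matches lm() and flags extreme effects", {
  d <- make_design(3, c(0, 500, 1000), c(1, 3))
  withr::with_seed(2, {
    v <- matrix(exp(rnorm(5 * nrow(d), log(500), 0.3)), 5, nrow(d),
                dimnames = list(sprintf("g%d", 1:5), d$sample_id))
  })
  v["g5", ] <- v["g5", ] * ifelse(d$dose == 1000, 50, 1)
  a <- anova2_bh(v, d)
  for (i in c(1, 3, 5)) {
    tab <- stats::anova(stats::lm(log2(v[i, ]) ~ factor(d$day) * factor(d$dose)))
    expect_equal(a$p_dose[i], tab[2, "Pr(>F)"], tolerance = 1e-10)
    expect_equal(a$p_day[i], tab[1, "Pr(>F)"], tolerance = 1e-10)
    expect_equal(a$p_interaction[i], tab[3, "Pr(>F)"], tolerance = 1e-10)
  }
  expect_lt(a$padj_dose[5], 1e-6)
  expect_true(a$significant[5])
  expect_true(all(a$padj_dose >= a$p_dose - 1e-15))
})

test_that("BH adjustment agrees with the brute-force step-up rule", {
  step_up <- function(p) {
    m <- length(p); o <- order(p); q <- numeric(m)
    adj <- rev(cummin(rev(p[o] * m / seq_len(m))))
    q[o] <- pmin(adj, 1); q
  }
  expect_equal(p.adjust(c(0.01, 0.02, 0.03, 0.04), "BH"),
               step_up(c(0.01, 0.02, 0.03, 0.04)))
  expect_true(all(p.adjust(c(0.01, 0.02, 0.03, 0.04), "BH") < 0.05))
  for (s in 1:5) {
    withr::with_seed(s, p <- runif(1000)^(1 + s / 5))
    expect_equal(p.adjust(p, "BH"), step_up(p), tolerance = 1e-12)
  }
})

test_that("ANOVA false-positive fraction under the global null stays at or below alpha", {
  d <- make_design(3, c(0, 500, 1000), c(1, 3))
  frac <- vapply(1:10, function(s) {
    withr::with_seed(700 + s,
      v <- matrix(exp(rnorm(300 * nrow(d), log(500), 0.25)), 300, nrow(d),
                  dimnames = list(sprintf("g%03d", 1:300), d$sample_id)))
    mean(anova2_bh(v, d)$significant)
  }, numeric(1))
  expect_lte(mean(frac), 0.05)
})

test_that("ratios to time-matched control medians", {
  d <- make_design(3, c(0, 1000), 1)
  v <- matrix(c(1, 2, 3, 4, 2, 6), 1, 6,
              dimnames = list("g", d$sample_id))
  r <- ratios_to_control(v, d)  # control median = 2
  expect_equal(unname(r[1, ]), c(0.5, 1, 1.5, 2, 1, 3))
  expect_error(ratios_to_control(v * 0, d), "zero control median")
})

test_that("Pearson hierarchical clustering matches brute-force average linkage", {
  prof <- rbind(a = c(1, 2, 3, 4, 5),
                b = c(1, 2, 3, 4, 5) * 3 + 2,   # identical profile shape
                c = c(5, 4, 3, 2, 1),           # negation
                d = c(1, 3, 2, 5, 4),
                e = c(2, 1, 4, 3, 5),
                f = c(1, 1, 2, 1, 3))
  hc <- hcluster_pearson(prof)
  # identical profiles merge first at distance ~0; negation merges far away
  expect_equal(hc$hclust$height[1], 0, tolerance = 1e-12)
  expect_setequal(abs(hc$hclust$merge[1, ]), c(1, 2))
  heights <- oracle_average_linkage_heights(1 - cor(t(prof)))
  expect_equal(sort(hc$hclust$height), sort(heights), tolerance = 1e-12)
  expect_error(hcluster_pearson(rbind(a = c(1, 1, 1), b = c(1, 2, 3))), "a")
  # 3-gene set: profile + intermediate + negation, negation merges last
  hc3 <- hcluster_pearson(prof[c("a", "d", "c"), ])
  expect_equal(max(hc3$hclust$height), mean(c(1 - cor(prof["a", ], prof["c", ]),
                                              1 - cor(prof["d", ], prof["c", ]))),
               tolerance = 1e-12)
})

test_that("hypergeometric enrichment is exact and presets gate overlap", {
  universe <- sprintf("g%02d", 1:10)
  term_map <- list(T1 = universe[1:5])
  res <- enrich(universe[1:3], term_map, universe)
  expect_equal(res$p, 10 / 120, tolerance = 1e-12)
  expect_false(res$qualifies)  # p ~ 0.083 misses the 0.05 cutoff
  expect_true(enrich(universe[1:3], term_map, universe, alpha = 0.1)$qualifies)
  res_all <- enrich(universe, term_map, universe)
  expect_equal(res_all$p, 1)
  # KEGG preset: overlap 2 never qualifies
  res2 <- enrich(universe[1:2], term_map, universe, min_overlap = 3)
  expect_false(res2$qualifies)
  expect_error(enrich(c("nope"), term_map, universe), "outside the universe")
  expect_message(enrich(universe[1:2], list(T1 = universe[1:5], empty = "zz"),
                        universe), "skipped")
})

test_that("hypergeometric p equals exhaustive enumeration for small universes", {
  cases <- expand.grid(N = c(8, 12, 15), K = c(3, 5), n = c(3, 6))
  for (i in seq_len(nrow(cases))) {
    N <- cases$N[i]; K <- cases$K[i]; n <- cases$n[i]
    universe <- sprintf("u%02d", seq_len(N))
    for (k_obs in 1:min(K, n)) {
      want <- oracle_hyper(N, K, n, k_obs)
      got <- phyper(k_obs - 1, K, N - K, n, lower.tail = FALSE)
      expect_equal(got, want, tolerance = 1e-12)
    }
    # and through the user-facing function on one draw
    res <- enrich(universe[seq_len(n)], list(T = universe[seq_len(K)]), universe)
    expect_equal(res$p, oracle_hyper(N, K, n, min(n, K)), tolerance = 1e-12)
  }
})

test_that("pathway overlay flags only co-perturbed pathways", {
  defs <- list(
    glycogen_synthesis = list(genes = c("hexokinase_D", "gys2"),
                              metabolites = c("glycogen", "glucose")),
    gene_only = list(genes = "hexokinase_D", metabolites = "urea"),
    untouched = list(genes = "foo", metabolites = "bar"))
  rep <- pathway_overlay(c(hexokinase_D = "down"), c(glycogen = "down"), defs)
  expect_equal(rep$flagged, c(TRUE, FALSE, FALSE))
  expect_match(rep$genes[1], "hexokinase_D:down")
  rep0 <- pathway_overlay(character(), c(glycogen = "down"), defs)
  expect_false(any(rep0$flagged))
})

test_that("the cascade only removes probesets at each stage", {
  d <- make_design()
  met <- matrix(log1p(d$dose) + rnorm(80, 0, 0.1), 80, 1,
                dimnames = list(d$sample_id, "succinate"))
  es <- simulate_expression(d, default_truth(seed = 21), 200, met)
  casc <- de_cascade(es)
  expect_lte(length(casc$detected), nrow(es$values))
  expect_lte(length(casc$fold_changed), length(casc$detected))
  expect_lte(length(casc$significant), length(casc$fold_changed))
  expect_true(all(casc$fold_changed %in% casc$detected))
  expect_true(all(casc$significant %in% casc$fold_changed))
})
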