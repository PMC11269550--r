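# Statistics battery vs. independent brute-force implementations.

test_that("rm_anova gives exact zero F for null-by-construction designs", {
  # both group means are 2, constant across time -> group F = 0
  d <- expand.grid(subject_id = c("a1", "a2", "b1", "b2"),
                   timepoint = c("t1", "t2"), stringsAsFactors = FALSE)
  d$group <- substr(d$subject_id, 1, 1)
  d$value <- c(1, 3, 0, 4)[match(d$subject_id, c("a1", "a2", "b1", "b2"))]
  res <- rm_anova(d)
  expect_equal(res$effects$F[res$effects$effect == "group"], 0)
  # every subject constant across time -> time and interaction F = 0
  expect_equal(res$effects$F[res$effects$effect == "timepoint"], 0)
  expect_equal(res$effects$F[res$effects$effect == "group:timepoint"], 0)
  expect_equal(res$effects$p[res$effects$effect == "timepoint"], 1)
})

test_that("rm_anova matches the direct sums-of-squares oracle", {
  for (seed in c(7, 19, 52)) {
    d <- fixed_rm_dataset(seed = seed)
    res <- rm_anova(d)
    want <- oracle_rm_anova_F(d)
    expect_equal(res$effects$F[res$effects$effect == "group"],
                 unname(want["group"]), tolerance = 1e-10)
    expect_equal(res$effects$F[res$effects$effect == "timepoint"],
                 unname(want["timepoint"]), tolerance = 1e-10)
    expect_equal(res$effects$F[res$effects$effect == "group:timepoint"],
                 unname(want["interaction"]), tolerance = 1e-10)
    expect_true(all(res$effects$p >= 0 & res$effects$p <= 1))
    expect_true(all(res$effects$df1 >= 1 & res$effects$df2 >= 1))
  }
})

test_that("rm_anova rejects incomplete designs without imputation", {
  d <- fixed_rm_dataset()
  expect_error(rm_anova(d[-1, ]), class = "qdti_incomplete_design")
  expect_error(rm_anova(d[d$timepoint == "t1", ]), class = "qdti_incomplete_design")
})

test_that("bonferroni post hocs: null, extreme separation, and monotone decisions", {
  d <- fixed_rm_dataset(seed = 3)
  d$value <- rep(seq(0, 1, length.out = 8), 3)       # identical groups
  ph <- posthoc_bonferroni(d)
  expect_true(all(!ph$significant))

  d2 <- fixed_rm_dataset(seed = 3, n = 6)
  shift <- d2$group == "C"
  d2$value <- rnorm(nrow(d2), sd = 0.1)
  d2$value[shift] <- d2$value[shift] + 10 * 0.1 * 10  # 10 within-group SDs and then some
  ph2 <- posthoc_bonferroni(d2)
  withC <- grepl("C", ph2$contrast)
  expect_true(all(ph2$significant[withC]))

  # decisions monotone in raw p
  expect_true(all(ph2$p[ph2$significant] <
                    min(ph2$p[!ph2$significant], Inf)))
  # averaged mode runs and agrees on sign
  pha <- posthoc_bonferroni(d2, mode = "averaged")
  expect_equal(nrow(pha), 3)
  expect_true(all(pha$significant[grepl("C", pha$contrast)]))
})

test_that("tukey post hocs match the studentized-range integration oracle", {
  set.seed(23)
  d <- data.frame(group = rep(c("g1", "g2", "g3"), each = 4),
                  count = round(rnorm(12, mean = rep(c(100, 110, 125), each = 4),
                                      sd = 8)))
  res <- oneway_anova_tukey(d)
  for (i in seq_len(nrow(res$tukey))) {
    ab <- strsplit(res$tukey$contrast[i], " vs ")[[1]]
    expect_lt(abs(res$tukey$p_adj[i] -
                    oracle_tukey_p(d$count, d$group, ab[1], ab[2])), 1e-8)
  }
  # unequal n (Tukey-Kramer)
  d2 <- d[-c(1, 5), ]
  res2 <- oneway_anova_tukey(d2)
  for (i in seq_len(nrow(res2$tukey))) {
    ab <- strsplit(res2$tukey$contrast[i], " vs ")[[1]]
    expect_lt(abs(res2$tukey$p_adj[i] -
                    oracle_tukey_p(d2$count, d2$group, ab[1], ab[2])), 1e-8)
  }
})

test_that("one-way ANOVA edge behavior: identical groups and degeneracy", {
  d <- data.frame(group = rep(c("a", "b", "c"), each = 3),
                  count = rep(c(1, 2, 3), 3))
  res <- oneway_anova_tukey(d)
  expect_equal(res$F, 0)
  expect_equal(res$p, 1)

  set.seed(5)
  d2 <- data.frame(group = rep(c("a", "b", "c"), each = 3),
                   count = c(0, 0, 0, 0, 0, 0, 10, 10, 10) + rnorm(9, sd = 1e-3))
  res2 <- oneway_anova_tukey(d2)
  ord <- order(res2$tukey$p_adj)
  expect_true(all(grepl("c", res2$tukey$contrast[ord[1:2]])))

  d3 <- data.frame(group = rep(c("a", "b"), each = 3), count = rep(c(1, 2), each = 3))
  expect_error(oneway_anova_tukey(d3), class = "qdti_degenerate_variance")
  expect_error(oneway_anova_tukey(d3[1:3, ]), class = "qdti_insufficient_data")
})

test_that("pearson correlation and regression match hand evaluation", {
  r1 <- pearson_with_regression(c(1, 2, 3), c(2, 4, 6))
  expect_equal(r1$r, 1)
  expect_equal(r1$slope, 2)
  expect_equal(r1$intercept, 0)

  r2 <- pearson_with_regression(c(1, 2, 3, 4), -c(1, 2, 3, 4))
  expect_equal(r2$r, -1)

  r3 <- pearson_with_regression(c(1, 2, 3, 4), c(2, 1, 4, 3))
  expect_equal(r3$r, 0.6, tolerance = 1e-12)
  o <- oracle_pearson(c(1, 2, 3, 4), c(2, 1, 4, 3))
  expect_equal(r3$slope, o$slope, tolerance = 1e-12)
  expect_equal(r3$r^2, r3$r_squared, tolerance = 1e-12)

  expect_error(pearson_with_regression(c(1, 1, 1), c(1, 2, 3)),
               class = "qdti_undefined_correlation")
  expect_error(pearson_with_regression(c(1, 2), c(1, 2)),
               class = "qdti_insufficient_data")
})

test_that("the battery wrappers cover every ROI x metric and stain x ROI cell", {
  ph <- tiny_phantom()
  ch <- generate_cohort(ph, cohort_spec(n_per_group = 3, seed = 9), dwi = FALSE)
  tab <- truth_metric_table(ch)
  st <- run_group_stats(tab[tab$roi %in% c("EC", "CC"), ])
  # per cell: 3 rmANOVA effects + 2 timepoints x 3 contrasts
  expect_equal(nrow(st), 2 * 4 * (3 + 6))
  expect_true(all(st$p >= 0 & st$p <= 1))

  cnt <- generate_ihc_counts(ch)
  ist <- run_ihc_stats(cnt)
  expect_true(all(c("oneway_anova", "tukey_hsd") %in% ist$test))
  corr <- run_metric_ihc_correlations(tab, cnt)
  expect_equal(nrow(corr), 4)                       # EC/IC x GFAP/CD68
  expect_equal(corr$n, rep(sum(ch$cohort$histology_n), 4))
})
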