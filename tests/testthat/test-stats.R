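test_that("one-way ANOVA matches the definitional sums-of-squares oracle", {
  # hand-checkable toy: 3 groups x 3 values
  y <- c(1, 2, 3, 4, 5, 6, 10, 11, 12)
  g <- rep(c("a", "b", "c"), each = 3)
  res <- one_way_anova(data.frame(amount_ug_per_cm2 = y, formulation = g))
  ora <- anova_oracle(y, g)
  expect_equal(res$F, ora$F, tolerance = 1e-12)
  expect_equal(res$p, ora$p, tolerance = 1e-12)
  expect_equal(res$df_between, 2)
  expect_equal(res$df_within, 6)
  expect_equal(unname(res$group_means), c(2, 5, 11))

  # property: agreement on random small layouts (unbalanced included)
  set.seed(31)
  for (i in 1:25) {
    k <- sample(2:5, 1)
    n <- sample(2:6, k, replace = TRUE)
    g <- rep(letters[1:k], n)
    y <- rnorm(length(g), mean = as.integer(factor(g)))
    res <- one_way_anova(data.frame(amount_ug_per_cm2 = y, formulation = g))
    ora <- anova_oracle(y, g)
    expect_equal(res$F, ora$F, tolerance = 1e-12)
    expect_equal(res$p, ora$p, tolerance = 1e-12)
  }

  one <- data.frame(amount_ug_per_cm2 = rnorm(5), formulation = "a")
  expect_error(one_way_anova(one), "2 groups")
  flat <- data.frame(amount_ug_per_cm2 = rep(1, 6),
                     formulation = rep(c("a", "b"), 3))
  expect_error(one_way_anova(flat), "identical")
  expect_error(one_way_anova(data.frame(x = 1)), "column")
})

test_that("the null rejection rate of the ANOVA is at its nominal level", {
  set.seed(32)
  reject <- logical(2000)
  g <- rep(c("a", "b", "c"), each = 5)
  for (i in seq_along(reject)) {
    y <- rnorm(15)
    reject[i] <- one_way_anova(
      data.frame(amount_ug_per_cm2 = y, formulation = g))$p < 0.05
  }
  expect_gte(mean(reject), 0.03)
  expect_lte(mean(reject), 0.07)
})

test_that("Tukey comparisons find forced differences and reduce to the t-test at k = 2", {
  # two identical-distribution groups plus one far-shifted group
  set.seed(33)
  y <- c(rnorm(6), rnorm(6), rnorm(6, mean = 50))
  g <- rep(c("a", "b", "c"), each = 6)
  cmp <- multiple_comparisons(data.frame(amount_ug_per_cm2 = y, formulation = g))
  expect_equal(nrow(cmp), 3)
  far <- cmp$group1 == "c" | cmp$group2 == "c"
  expect_true(all(cmp$p_adj[far] < 0.01))
  expect_true(all(cmp$stars[far] == "**"))
  expect_gt(cmp$p_adj[!far], 0.05)
  expect_equal(cmp$stars[!far], "")

  # studentized-range equivalence with the pooled t-test at two groups
  for (i in 1:5) {
    y2 <- rnorm(12, mean = rep(c(0, runif(1, 0, 2)), each = 6))
    g2 <- rep(c("a", "b"), each = 6)
    cmp2 <- multiple_comparisons(data.frame(amount_ug_per_cm2 = y2,
                                            formulation = g2))
    tt <- t.test(y2[g2 == "a"], y2[g2 == "b"], var.equal = TRUE)
    expect_equal(cmp2$p_adj, tt$p.value, tolerance = 1e-6)
  }

  flat <- data.frame(amount_ug_per_cm2 = rep(c(1, 2), each = 3),
                     formulation = rep(c("a", "b"), each = 3))
  expect_error(multiple_comparisons(flat), "zero within-group variance")
})

test_that("Games-Howell agrees with Tukey under homoscedasticity and handles unequal variances", {
  set.seed(34)
  y <- rnorm(30, mean = rep(c(0, 0, 3), each = 10))
  g <- rep(c("a", "b", "c"), each = 10)
  d <- data.frame(amount_ug_per_cm2 = y, formulation = g)
  tk <- multiple_comparisons(d, method = "tukey")
  gh <- multiple_comparisons(d, method = "games_howell")
  expect_equal(gh$p_adj < 0.05, tk$p_adj < 0.05)
  expect_equal(gh$diff, tk$diff, tolerance = 1e-9)
})

test_that("overestimation ratios divide static by dynamic means per formulation", {
  stat <- data.frame(formulation = rep(c("A", "B"), each = 3),
                     amount_ug_per_cm2 = c(6, 6, 6, 4, 4, 4))
  dyn <- data.frame(formulation = rep(c("A", "B"), each = 2),
                    amount_ug_per_cm2 = c(1, 1, 2, 2))
  r <- overestimation_ratios(stat, dyn)
  expect_equal(r$ratio[r$formulation == "A"], 6)
  expect_equal(r$ratio[r$formulation == "B"], 2)
  expect_equal(overestimation_ratios(stat, stat)$ratio, c(1, 1))
  expect_error(overestimation_ratios(stat, dyn[dyn$formulation == "A", ]),
               "missing from one arm")
})

test_that("the end-to-end pipeline reports both arms, all pairs and all ratios, reproducibly", {
  rep1 <- run_pipeline(experiment_design(seed = 5))
  expect_named(rep1$anova, c("dynamic", "static"))
  expect_equal(nrow(rep1$pairwise$static), choose(7, 2))
  expect_equal(nrow(rep1$pairwise$dynamic), choose(7, 2))
  expect_equal(nrow(rep1$ratios), 7)
  expect_equal(rep1$seed, 5L)
  # same seed, identical report (including the serialized form)
  rep2 <- run_pipeline(experiment_design(seed = 5))
  p1 <- withr::local_tempfile(fileext = ".json")
  p2 <- withr::local_tempfile(fileext = ".json")
  write_report(rep1, p1); write_report(rep2, p2)
  expect_identical(readLines(p1), readLines(p2))
  # stars follow the two published tiers
  all_pairs <- rbind(rep1$pairwise$static, rep1$pairwise$dynamic)
  expect_true(all(all_pairs$stars[all_pairs$p_adj < 0.01] == "**"))
  expect_true(all(all_pairs$stars[all_pairs$p_adj >= 0.05] == ""))

  # a records file without the model column is a schema error naming it
  bad <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(formulation = "SOL", replicate = 1,
                       amount_ug_per_cm2 = 1), bad, row.names = FALSE)
  expect_error(run_pipeline(bad), "model")
})
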