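test_that("exact test reproduces hand-enumerable cases", {
  t1 <- mann_whitney(c(1, 2, 3), c(4, 5, 6), method = "exact")
  expect_equal(t1$U, 0)          # rank sum 6 minus 3*4/2
  expect_equal(t1$p_value, 0.1)  # 2 of the 20 assignments as extreme
  t2 <- mann_whitney(c(4, 5, 6), c(1, 2, 3), method = "exact")
  expect_equal(t2$U, 9)
  expect_equal(t2$p_value, 0.1)
  expect_equal(t2$Z, -t1$Z)      # swapping groups flips the sign only
})

test_that("identical and constant samples are null or degenerate", {
  x <- c(2, 4, 4, 7)
  t1 <- mann_whitney(x, x)
  expect_equal(t1$Z, 0)
  expect_equal(t1$p_value, 1)
  t2 <- mann_whitney(rep(3, 5), rep(3, 4))
  expect_true(t2$degenerate)
  expect_equal(t2$Z, 0)
  expect_equal(t2$p_value, 1)
})

test_that("exact p equals brute-force enumeration up to n1+n2 = 12", {
  set.seed(91)
  sizes <- list(c(3, 3), c(4, 4), c(5, 5), c(6, 6), c(4, 8), c(2, 10))
  for (sz in sizes) {
    for (rep in 1:5) {
      # draws from a small integer support so ties occur regularly
      a <- sample(1:6, sz[1], replace = TRUE)
      b <- sample(1:6, sz[2], replace = TRUE)
      got <- mann_whitney(a, b, method = "exact")
      expect_equal(got$p_value, min(1, brute_mw_p(a, b)),
                   info = paste(sz, collapse = "+"))
    }
  }
})

test_that("exact p matches the classical null distribution without ties", {
  set.seed(17)
  for (rep in 1:15) {
    a <- rnorm(sample(3:8, 1))
    b <- rnorm(sample(3:8, 1))
    expect_equal(mann_whitney(a, b, method = "exact")$p_value,
                 stats::wilcox.test(a, b, exact = TRUE)$p.value)
  }
})

test_that("asymptotic p matches the tie-corrected normal reference", {
  set.seed(18)
  for (rep in 1:10) {
    a <- sample(1:8, 25, replace = TRUE)
    b <- sample(1:8, 30, replace = TRUE)
    got <- mann_whitney(a, b, method = "asymptotic")
    ref <- stats::wilcox.test(a, b, exact = FALSE, correct = FALSE)
    expect_equal(got$p_value, ref$p.value)
    expect_equal(got$U, unname(ref$statistic))
  }
})

test_that("two-sided p is invariant under group swap", {
  set.seed(19)
  for (method in c("exact", "asymptotic")) {
    a <- sample(1:10, 6, replace = TRUE)
    b <- sample(1:10, 6, replace = TRUE)
    f <- mann_whitney(a, b, method = method)
    g <- mann_whitney(b, a, method = method)
    expect_equal(f$p_value, g$p_value)
    expect_equal(f$Z, -g$Z)
  }
})

test_that("effect size r recomputes from Z and falls in the stated bands", {
  expect_equal(effect_size_r(0, 10), 0)
  set.seed(20)
  a <- rnorm(12, 1); b <- rnorm(14)
  t1 <- mann_whitney(a, b)
  expect_equal(effect_size_r(t1$Z, 26), abs(t1$Z) / sqrt(26))
  expect_equal(classify_effect_size(c(0, 0.05, 0.1, 0.29, 0.3, 0.49, 0.5, 0.9)),
               c("negligible", "negligible", "small", "small",
                 "medium", "medium", "large", "large"))
  expect_equal(classify_effect_size(0.55), "large")
  expect_equal(classify_effect_size(0.33), "medium")
})

test_that("alpha adjustment divides the family alpha", {
  expect_identical(bonferroni_alpha(0.05, 4), 0.0125)
  expect_identical(bonferroni_alpha(0.05, 1), 0.05)
  expect_identical(bonferroni_alpha(0.01, 5), 0.002)
  expect_error(bonferroni_alpha(0.05, 0), "m")
  plan <- contrast_plan()
  expect_equal(plan$alpha_adjusted, 0.0125)
  expect_equal(plan$m, 4)
  expect_equal(nrow(plan$contrasts), 4)
})

test_that("the planned comparison grid has 12 tests with attached summaries", {
  cohort <- simulate_cohort(cohort_config(
    group_sizes = c(THI_AHI = 12, THI_ALO = 12, TLO_AHI = 12, TLO_ALO = 12),
    seed = 101))
  sc <- score_cohort(cohort$responses, cohort$manifest)
  cmp <- compare_groups(sc)
  expect_equal(nrow(cmp), 12)
  expect_equal(sort(unique(cmp$dv)),
               sort(c("n_clusters", "telling_together", "telling_apart")))
  expect_equal(cmp$significant, cmp$p_value < 0.0125)
  expect_equal(cmp$r, abs(cmp$Z) / sqrt(cmp$n_a + cmp$n_b))
  expect_equal(cmp$r_class, classify_effect_size(cmp$r))
  # medians/ranges attach per group
  grp <- group_code(sc$talker_familiarity, sc$accent_familiarity)
  row <- cmp[cmp$dv == "telling_together" & cmp$group_a == "THI_AHI" &
               cmp$group_b == "TLO_AHI", ]
  expect_equal(row$median_a, median(sc$telling_together[grp == "THI_AHI"]))
  expect_equal(row$max_b, max(sc$telling_together[grp == "TLO_AHI"]))
})

test_that("identical groups test null; empty groups are skipped with report", {
  same <- scores_frame(list(THI_AHI = c(1, 2, 3, 4, 5),
                            THI_ALO = c(1, 2, 3, 4, 5),
                            TLO_AHI = c(1, 2, 3, 4, 5),
                            TLO_ALO = c(1, 2, 3, 4, 5)))
  cmp <- compare_groups(same)
  expect_true(all(cmp$p_value == 1))
  expect_false(any(cmp$significant))

  three <- scores_frame(list(THI_AHI = 1:4, THI_ALO = 2:5, TLO_AHI = 3:6))
  expect_message(cmp2 <- compare_groups(three), "skipped")
  skipped <- cmp2[cmp2$group_b == "TLO_ALO", ]
  expect_true(all(is.na(skipped$p_value)))
  done <- cmp2[cmp2$group_a == "THI_AHI" & cmp2$group_b == "THI_ALO", ]
  expect_true(all(!is.na(done$p_value)))
})
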