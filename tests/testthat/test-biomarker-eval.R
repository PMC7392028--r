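test_that("group comparisons pick the right test and p-values", {
  coh <- data.frame(case_flag = rep(c(TRUE, FALSE), each = 3),
                    x = c(1, 2, 3, 1, 2, 3))
  out <- compare_groups(coh, "x")
  expect_equal(out$test_name, "wilcoxon")
  expect_equal(out$p_value, 1)

  # exact two-sided rank-sum p for (1,2) vs (10,20): 2/6 of the C(4,2)
  # rank assignments are at least as extreme
  coh2 <- data.frame(case_flag = c(TRUE, TRUE, FALSE, FALSE),
                     x = c(1, 2, 10, 20))
  expect_equal(compare_groups(coh2, "x")$p_value, 1 / 3)

  # above-median counts of the validation-phase shape: significance of a
  # 44.3% vs 55.4% imbalance by chi-square
  coh3 <- data.frame(
    case_flag = rep(c(FALSE, TRUE), c(185, 186)),
    above = factor(c(rep(c("no", "yes"), c(103, 82)),
                     rep(c("no", "yes"), c(83, 103)))))
  out3 <- compare_groups(coh3, "above")
  expect_equal(out3$test_name, "chi_square")
  expect_lt(out3$p_value, 0.05)
})

test_that("rank tests are invariant to monotone transforms", {
  set.seed(1)
  coh <- data.frame(case_flag = rep(c(TRUE, FALSE), each = 40),
                    x = rnorm(80, mean = rep(c(0.5, 0), each = 40)))
  p1 <- compare_groups(coh, "x")$p_value
  coh$x <- exp(coh$x)
  expect_equal(compare_groups(coh, "x")$p_value, p1)
})

test_that("constant variables are flagged instead of tested", {
  coh <- data.frame(case_flag = c(TRUE, FALSE), x = c(1, 1))
  out <- compare_groups(coh, "x")
  expect_equal(out$test_name, "none")
  expect_true(is.na(out$p_value))
})

test_that("small expected counts fall back to Fisher's exact test", {
  coh <- data.frame(case_flag = rep(c(TRUE, FALSE), each = 6),
                    g = factor(c(rep("a", 5), "b",
                                 "a", rep("b", 5))))
  expect_equal(compare_groups(coh, "g")$test_name, "fisher")
})

test_that("AUC equals the concordance count and respects symmetry", {
  expect_equal(roc_auc(c(1, 2, 3, 4), c(0, 0, 1, 1))$auc, 1)
  expect_equal(roc_auc(c(1, 2, 3, 4), c(0, 1, 0, 1))$auc, 0.75)
  set.seed(3)
  s <- rnorm(60); l <- rbinom(60, 1, 0.5)
  expect_equal(roc_auc(s, l)$auc + roc_auc(-s, l)$auc, 1)
  expect_error(roc_auc(1:3, c(1, 1, 1)), "both classes")
})

test_that("AUC and DeLong interval agree with pROC", {
  skip_if_not_installed("pROC")
  set.seed(8)
  s <- rnorm(120); l <- rbinom(120, 1, 0.4)
  mine <- roc_auc(s, l)
  ref <- pROC::roc(l, s, quiet = TRUE, direction = "<")
  ci <- as.numeric(pROC::ci.auc(ref, method = "delong"))
  expect_equal(mine$auc, as.numeric(pROC::auc(ref)), tolerance = 1e-10)
  expect_equal(mine$ci_low, ci[1], tolerance = 1e-6)
  expect_equal(mine$ci_high, ci[3], tolerance = 1e-6)
})

test_that("uninformative scores stay near AUC one half", {
  set.seed(9)
  out <- roc_auc(rnorm(400), rbinom(400, 1, 0.5))
  expect_gt(out$auc, 0.42); expect_lt(out$auc, 0.58)
  expect_gt(out$p_value, 0.01)
})

test_that("candidate screening enforces both cutoffs strictly", {
  tab <- data.frame(
    feature = c("m632", "a", "b", "down"),
    fold_change = c(2.9, 2.4, 3.0, 1 / 3),
    p_value = c(0.01, 0.001, 0.05, 0.02))
  sel <- screen_candidates(tab)
  expect_setequal(sel$feature, c("m632", "down"))   # 2.9-fold in, 2.4 out
  expect_equal(sel$feature[1], "m632")              # sorted by p
  expect_false("b" %in% sel$feature)                # p = 0.05 not < 0.05
  up_only <- screen_candidates(tab, two_sided = FALSE)
  expect_equal(up_only$feature, "m632")
  expect_error(screen_candidates(tab[, 1:2]), "lacks columns")
})
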