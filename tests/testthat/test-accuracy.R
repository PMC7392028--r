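test_that("integrated AUC is a trapezoidal average on the grid", {
  tr <- data.frame(time = seq(6, 36, by = 6), auc = 0.73)
  expect_equal(integrated_auc(tr), 0.73)
  tr2 <- data.frame(time = seq(0, 24, by = 6),
                    auc = seq(0.6, 0.8, length.out = 5))
  expect_equal(integrated_auc(tr2), 0.7)
  expect_equal(integrated_auc(tr2, horizon = 12),
               mean(c(0.6, 0.7)))          # linear piece up to 12
  expect_error(integrated_auc(tr2, horizon = 1), "fewer than 2")
  # bounded by the extremes of AUC(t)
  set.seed(1)
  tr3 <- data.frame(time = 1:20, auc = runif(20, 0.4, 0.9))
  ia <- integrated_auc(tr3)
  expect_gte(ia, min(tr3$auc)); expect_lte(ia, max(tr3$auc))
})

test_that("a perfectly ordering risk scores AUC one at every time", {
  set.seed(2)
  n <- 80
  te <- sort(rexp(n, 0.2) * 12)
  risk <- rev(seq_len(n))  # highest risk fails first
  for (t in quantile(te, c(0.2, 0.5, 0.8)))
    expect_equal(cd_auc(risk, te, rep(1, n), t), 1)
})

test_that("without censoring the estimator is the Mann-Whitney AUC", {
  for (s in 1:10) {
    set.seed(s)
    n <- 150
    risk <- rnorm(n)
    te <- rexp(n, exp(0.5 * risk) * 0.1) * 12
    t <- quantile(te, 0.4)
    expect_equal(cd_auc(risk, te, rep(1, n), t),
                 roc_auc(risk, te <= t)$auc, tolerance = 1e-10)
  }
})

test_that("light censoring stays close to the uncensored oracle", {
  set.seed(3)
  n <- 800
  risk <- rnorm(n)
  te <- rexp(n, exp(0.7 * risk) * 0.1) * 12
  tc <- rexp(n, 0.002) * 12   # ~2% censoring
  tt <- pmin(te, tc); ev <- as.integer(te <= tc)
  t <- quantile(te, 0.4)
  expect_equal(cd_auc(risk, tt, ev, t), roc_auc(risk, te <= t)$auc,
               tolerance = 0.02)
})

test_that("the time-dependent AUC is invariant to monotone rescoring", {
  coh <- generate_cohort(tree_spec(), 500, seed = 4)
  r <- predict_risk(fit_tree(coh, default_predictors()), coh)
  t <- 24
  expect_equal(cd_auc(r, coh$time, coh$event, t),
               cd_auc(rank(r), coh$time, coh$event, t), tolerance = 1e-12)
  expect_equal(cd_auc(r, coh$time, coh$event, t),
               cd_auc(exp(r / 10), coh$time, coh$event, t),
               tolerance = 1e-12)
})

test_that("undefined case or control sets yield NA", {
  tt <- c(10, 20, 30); ev <- c(0, 0, 1)
  expect_true(is.na(cd_auc(1:3, tt, ev, 5)))    # no case yet
  expect_true(is.na(cd_auc(1:3, tt, ev, 35)))   # nobody past t
})

test_that("the IRV definitions agree on worked two-leaf arithmetic", {
  lt <- data.frame(n = c(10, 10), events = c(5, 15),
                   person_years = c(10, 10))
  expect_equal(as.numeric(irv_index(lt, "wtd_abs_dev")), 50)
  expect_equal(as.numeric(irv_index(lt, "wtd_sd")), 50)
  expect_equal(as.numeric(irv_index(lt, "cv")), 0.5)
  hom <- data.frame(n = c(5, 9), events = c(2, 4),
                    person_years = c(4, 8))
  for (d in c("wtd_abs_dev", "wtd_sd", "cv"))
    expect_equal(as.numeric(irv_index(hom, d)), 0)
  expect_error(irv_index(lt, "nope"), "wtd_abs_dev")
})

test_that("IRV ignores leaf order and scales with the rates", {
  lt <- data.frame(n = c(10, 20, 30), events = c(2, 9, 30),
                   person_years = c(8, 15, 20))
  a <- as.numeric(irv_index(lt))
  expect_equal(as.numeric(irv_index(lt[c(3, 1, 2), ])), a)
  lt2 <- lt; lt2$events <- lt$events * 2      # all IRs double
  expect_equal(as.numeric(irv_index(lt2)), 2 * a, tolerance = 1e-10)
})

test_that("the fitted partition is more heterogeneous than random ones", {
  coh <- generate_cohort(tree_spec(), 4000, seed = 5)
  tree <- fit_tree(coh, default_predictors())
  lt <- node_summaries(tree, coh)
  irv_tree <- as.numeric(irv_index(lt))
  set.seed(5)
  worse <- replicate(50, {
    shuffle <- sample(rep(1:8, length.out = nrow(coh)))
    rl <- data.frame(
      n = as.vector(table(shuffle)),
      events = tapply(coh$event, shuffle, sum),
      person_years = tapply(coh$time / 12, shuffle, sum))
    as.numeric(irv_index(rl)) < irv_tree
  })
  expect_true(all(worse))
})

test_that("accuracy indices bundle iAUC and IRV consistently", {
  coh <- generate_cohort(tree_spec(), 1000, seed = 6)
  tree <- fit_tree(coh, default_predictors())
  acc <- accuracy_indices(tree, coh, horizon = 24)
  expect_gte(acc$iauc, 0.5); expect_lte(acc$iauc, 1)
  expect_equal(acc$iauc_horizon, 24)
  expect_equal(acc$definition_id, "wtd_abs_dev")
  expect_equal(acc$irv, as.numeric(irv_index(acc$leaf_table)))
  expect_equal(acc$iauc, integrated_auc(acc$time_roc, 24))
})
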