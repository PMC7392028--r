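test_that("generation is deterministic and validates its inputs", {
  sp <- tree_spec()
  a <- generate_cohort(sp, 100, seed = 3)
  b <- generate_cohort(sp, 100, seed = 3)
  expect_identical(a, b)
  expect_error(generate_cohort(sp, 10, seed = 1), "n must be")
  expect_error(tree_spec(leaf_ir = rep(10, 7)), "exactly 8")
  expect_error(tree_spec(leaf_ir = c(rep(10, 7), -1)), "> 0")
  expect_error(tree_spec(missing_rates = c(age = 0.1)), "missing_rates")
  bad <- default_splits(); bad$`1`$cutoff <- 95  # outside Uniform(50, 80)
  expect_error(tree_spec(splits = bad), "support")
})

test_that("pooled incidence rate recovers a common exponential hazard", {
  sp <- tree_spec(leaf_ir = rep(30, 8), dropout_rate = 0)
  coh <- generate_cohort(sp, 10000, seed = 7)
  est <- incidence_rate(sum(coh$event), sum(coh$time / 12))
  expect_lt(abs(est - 30) / 30, 0.05)
})

test_that("empirical leaf rates track the generative rates", {
  sp <- tree_spec()
  coh <- generate_cohort(sp, 4000, seed = 2)
  emp <- sapply(8:15, function(l) {
    sel <- coh$leaf_id == l
    incidence_rate(sum(coh$event[sel]), sum(coh$time[sel] / 12))
  })
  expect_equal(which.max(emp), which.max(sp$leaf_ir))  # leaf 11, 101.57
  expect_gt(cor(emp, sp$leaf_ir, method = "spearman"), 0.9)
})

test_that("event times follow the leaf exponential law (KM check)", {
  # KM survival at t vs exp(-lambda t) within a 95% envelope
  sp <- tree_spec(leaf_ir = rep(25, 8))
  coh <- generate_cohort(sp, 5000, seed = 9)
  sf <- survival::survfit(survival::Surv(time / 12, event) ~ 1,
                          data = coh)
  for (t in c(1, 2, 3)) {
    i <- max(which(sf$time <= t))
    expect_gt(exp(-0.25 * t), sf$lower[i])
    expect_lt(exp(-0.25 * t), sf$upper[i])
  }
})

test_that("matched draws pair nearest neighbours one case to one control", {
  coh <- data.frame(
    patient_id = paste0("p", 1:4), phase = "II",
    pair_id = NA_character_,
    case_flag = c(TRUE, TRUE, FALSE, FALSE),
    event = c(1, 1, 0, 0), time = c(10, 10, 20, 20),
    age = c(60, 70, 61, 80))
  cc <- draw_case_control(coh, 2, 2, matched = TRUE,
                          matching_vars = "age", seed = 1)
  expect_equal(cc$phase, rep("I", 4))
  expect_true(all(table(cc$pair_id) == 2))
  got <- lapply(split(cc$age, cc$pair_id), sort)
  expect_setequal(vapply(got, paste, character(1), collapse = "-"),
                  c("60-61", "70-80"))
  for (p in split(cc$event, cc$pair_id))
    expect_equal(sum(p), 1)  # never two cases or two controls
})

test_that("matching reduces the case/control age imbalance", {
  coh <- generate_cohort(tree_spec(), 3000, seed = 5)
  smd <- function(d) {
    abs(mean(d$age[d$event == 1]) - mean(d$age[d$event == 0])) /
      sd(coh$age)
  }
  better <- 0
  for (s in 1:100) {
    m <- draw_case_control(coh, 200, 200, matched = TRUE,
                           matching_vars = c("age", "bmi", "ktv"),
                           seed = s)
    u <- draw_case_control(coh, 200, 200, matched = FALSE, seed = s)
    if (smd(m) < smd(u)) better <- better + 1
  }
  expect_gt(better, 80)
})

test_that("insufficient cases are reported with the available count", {
  coh <- generate_cohort(tree_spec(), 100, seed = 1)
  n_cases <- sum(coh$event)
  expect_error(draw_case_control(coh, n_cases + 50, 10),
               paste0("only ", n_cases, " available"))
})

test_that("MCAR injection hits the configured rate and only allowed columns", {
  coh <- generate_cohort(tree_spec(), 5000, seed = 4)
  same <- inject_missingness(coh, c(hscrp = 0), seed = 1)
  expect_identical(same, coh)
  out <- inject_missingness(coh, c(hscrp = 0.2), seed = 1)
  frac <- mean(is.na(out$hscrp))
  expect_gt(frac, 0.17); expect_lt(frac, 0.23)
  expect_false(anyNA(out$bmi))
  expect_error(inject_missingness(coh, c(age = 0.1)), "refused")
})
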