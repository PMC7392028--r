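test_that("best split matches a brute-force cutpoint scan", {
  cfg <- tree_config(min_node_size = 2)
  for (s in 1:30) {
    i <- random_surv_instance(s)
    set.seed(s * 7)
    x <- round(rnorm(length(i$time)), 1)
    coh <- data.frame(time = i$time, event = i$event, x = x)
    if (sum(i$event) == 0 || length(unique(x)) < 2) next
    got <- best_split(coh, "x", cfg)
    # oracle: independent naive scan over all midpoints
    v <- sort(unique(x)); mids <- (v[-1] + v[-length(v)]) / 2
    stats <- sapply(mids, function(cut) {
      grp <- x <= cut
      if (min(sum(grp), sum(!grp)) < 2) return(-Inf)
      naive_grho(i$time, i$event, grp)
    })
    if (all(!is.finite(stats))) {
      expect_null(got)
    } else {
      best <- which(stats >= max(stats) - 1e-12)[1]  # lowest cutoff tie
      expect_equal(got$cutoff, mids[best])
      expect_equal(got$statistic, stats[best], tolerance = 1e-10)
    }
  }
})

test_that("a deterministic threshold effect is localized", {
  set.seed(1)
  x <- rep(1:10, each = 8)
  haz <- ifelse(x > 5, 2, 0.05)
  coh <- data.frame(time = rexp(80, haz) * 12, event = 1, x = x)
  sp <- best_split(coh, "x", tree_config(min_node_size = 5))
  expect_gt(sp$cutoff, 4); expect_lt(sp$cutoff, 6)
})

test_that("inadmissible splits return NULL", {
  coh <- data.frame(time = rexp(40) * 12, event = 1, x = 1)
  expect_null(best_split(coh, "x"))
  coh$x <- rnorm(40)
  expect_null(best_split(coh, "x", tree_config(min_node_size = 21)))
})

test_that("categorical splits scan binary level partitions", {
  set.seed(2)
  g <- sample(c("a", "b", "c"), 90, replace = TRUE)
  haz <- ifelse(g == "c", 1.5, 0.1)
  coh <- data.frame(time = rexp(90, haz) * 12, event = 1, g = g,
                    stringsAsFactors = FALSE)
  sp <- best_split(coh, "g", tree_config(min_node_size = 5))
  expect_equal(sp$type, "categorical")
  expect_true(setequal(sp$left_categories, c("a", "b")) ||
              setequal(sp$left_categories, "c"))
})

test_that("monotone transforms leave the selected partition unchanged", {
  coh <- generate_cohort(tree_spec(), 500, seed = 3)
  a <- best_split(coh, "hscrp", tree_config())
  coh2 <- coh; coh2$hscrp <- log(coh2$hscrp)
  b <- best_split(coh2, "hscrp", tree_config())
  expect_equal(coh$hscrp <= a$cutoff, coh2$hscrp <= b$cutoff)
  expect_equal(a$statistic, b$statistic, tolerance = 1e-10)
})

test_that("fitted trees partition the cohort exactly", {
  coh <- generate_cohort(tree_spec(), 1500, seed = 4)
  tree <- fit_tree(coh, default_predictors())
  leaf <- predict_leaf(tree, coh)
  expect_equal(length(leaf), nrow(coh))
  ls <- tree$leaf_summary
  expect_equal(sum(ls$events), sum(coh$event))
  expect_equal(sum(ls$n), nrow(coh))
  expect_equal(sum(ls$person_years), sum(coh$time / 12),
               tolerance = 1e-8)
  # hierarchization: strictly sorted by IR (ties by events)
  expect_true(all(diff(ls$ir) <= 0))
  expect_equal(ls$risk_rank, seq_len(nrow(ls)))
})

test_that("outcome-independent predictors give a single leaf", {
  set.seed(5)
  n <- 300
  coh <- data.frame(time = rexp(n, 0.2) * 12,
                    event = rbinom(n, 1, 0.7),
                    x = rbinom(n, 1, 0.5) == 1)
  single <- 0
  for (s in 1:20) {
    set.seed(s)
    coh$time <- rexp(n, 0.2) * 12
    coh$event <- rbinom(n, 1, 0.7)
    tr <- suppressWarnings(fit_tree(coh, "x"))
    if (length(tr$nodes) == 1) single <- single + 1
  }
  expect_gte(single, 16)
})

test_that("surrogates route patients with missing split values", {
  coh <- generate_cohort(tree_spec(), 1000, seed = 6)
  coh$age_twin <- coh$age + rnorm(1000, sd = 0.5)
  tree <- fit_tree(coh, c(default_predictors(), "age_twin"))
  expect_equal(tree$nodes[["1"]]$split$variable, "age")
  surr_vars <- sapply(tree$nodes[["1"]]$surrogates, `[[`, "variable")
  expect_true("age_twin" %in% surr_vars)
  ag <- sapply(tree$nodes[["1"]]$surrogates, `[[`, "agreement")
  expect_true(all(diff(ag) <= 0))       # ordered by agreement
  expect_true(all(ag >= 0 & ag <= 1))
  # blank the root variable: routing must still place everyone in a leaf
  holed <- coh; holed$age[1:200] <- NA
  leaf <- predict_leaf(tree, holed)
  expect_true(all(leaf %in% tree$leaf_summary$node_id))
  # with a near-duplicate surrogate, most missing-age patients keep
  # their original leaf
  expect_gt(mean(leaf[1:200] == predict_leaf(tree, coh)[1:200]), 0.8)
})

test_that("node summaries report IR, reference HR and KM per leaf", {
  coh <- generate_cohort(tree_spec(), 1500, seed = 7)
  tree <- fit_tree(coh, default_predictors())
  tab <- node_summaries(tree, coh)
  expect_equal(tab$ir, 100 * tab$events / tab$person_years)
  ref <- tab$node_id[which.min(tab$ir)]
  expect_equal(tab$hr[tab$node_id == ref], 1)
  expect_true(all(tab$hr[tab$node_id != ref] > 0))
  km <- attr(tab, "km")
  expect_setequal(names(km), as.character(tab$node_id))
  for (k in km) expect_true(all(diff(k$surv) <= 0))
})

test_that("incidence rate arithmetic follows person-time", {
  expect_equal(incidence_rate(2, 4), 50)
  # all events within the first year forces IR above 100
  d <- data.frame(time = runif(30, 1, 11), event = 1, x = rnorm(30))
  tr <- suppressWarnings(fit_tree(d, "x", tree_config(min_node_size = 15,
                                                      max_depth = 1)))
  expect_gt(tr$leaf_summary$ir[1], 100)
})

test_that("JSON serialization round-trips rules, summaries and ordering", {
  coh <- generate_cohort(tree_spec(), 800, seed = 8)
  tree <- fit_tree(coh, default_predictors())
  f <- tempfile(fileext = ".json")
  tree_to_json(tree, f)
  back <- tree_from_json(f)
  expect_equal(back$leaf_summary, tree$leaf_summary)
  expect_equal(predict_leaf(back, coh), predict_leaf(tree, coh))
  for (id in names(tree$nodes)) {
    a <- tree$nodes[[id]]; b <- back$nodes[[id]]
    expect_equal(b$is_leaf, a$is_leaf)
    if (!a$is_leaf) {
      expect_equal(b$split$variable, a$split$variable)
      expect_equal(b$split$cutoff, a$split$cutoff)
      expect_equal(length(b$surrogates), length(a$surrogates))
    }
  }
  unlink(f)
})
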