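test_that("confusion metrics match the formulas and flag degeneracies", {
  m <- confusion_metrics(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0), 0.5)
  expect_equal(unname(m["accuracy"]), 1)
  expect_equal(unname(m["f1"]), 1)
  # TP=3, FP=1, FN=1 setup
  m2 <- confusion_metrics(c(0.9, 0.9, 0.9, 0.9, 0.1),
                          c(1, 1, 1, 0, 1), 0.5)
  expect_equal(unname(m2["precision"]), 0.75)
  expect_equal(unname(m2["recall"]), 0.75)
  expect_equal(unname(m2["f1"]), 0.75)
  # all predicted negative: recall 0, precision undefined (NA, not 0)
  m3 <- confusion_metrics(c(0.1, 0.2), c(1, 0), 0.5)
  expect_equal(unname(m3["recall"]), 0)
  expect_true(is.na(m3["precision"]))
})

test_that("auroc equals Mann-Whitney with half-credit ties", {
  expect_equal(auroc(c(0.9, 0.2, 0.8), c(1, 1, 0)), 0.5)
  expect_equal(auroc(c(0.9, 0.8, 0.1), c(1, 1, 0)), 1.0)
  expect_equal(auroc(rep(0.4, 6), c(1, 0, 1, 0, 0, 1)), 0.5)
  expect_true(is.na(auroc(c(0.1, 0.9), c(1, 1))))
})

test_that("auprc equals known hand sweeps and the chance level", {
  expect_equal(auprc(c(0.2, 0.9), c(1, 0)), 0.5)
  expect_equal(auprc(c(0.9, 0.8, 0.1), c(1, 1, 0)), 1.0)
  # chance level approaches prevalence for random scores
  set.seed(4)
  y <- rbinom(20000, 1, 0.15)
  s <- runif(20000)
  expect_lt(abs(auprc(s, y) - 0.15), 0.02)
  expect_true(is.na(auprc(c(0.5, 0.2), c(0, 0))))
})

test_that("ranking metrics agree with brute-force oracles on fuzz", {
  set.seed(12)
  for (rep in 1:60) {
    n <- sample(5:120, 1)
    s <- round(runif(n), sample(c(1, 2, 6), 1)) # force ties sometimes
    y <- rbinom(n, 1, runif(1, 0.1, 0.9))
    if (length(unique(y)) < 2) next
    expect_equal(auroc(s, y), auroc_bruteforce(s, y), tolerance = 1e-12)
    expect_equal(auprc(s, y), auprc_bruteforce(s, y), tolerance = 1e-12)
  }
})

test_that("cluster bootstrap is seeded, contains the point estimate, and degenerates", {
  set.seed(6)
  n <- 300
  g <- sample(sprintf("s%02d", 1:30), n, replace = TRUE)
  y <- rbinom(n, 1, 0.3)
  s <- runif(n) + 0.4 * y
  ci <- bootstrap_ci(s, y, g, auroc, n_boot = 200, seed = 9)
  ci2 <- bootstrap_ci(s, y, g, auroc, n_boot = 200, seed = 9)
  expect_identical(ci, ci2)
  pt <- auroc(s, y)
  expect_lte(ci[["lower"]], pt)
  expect_gte(ci[["upper"]], pt)
  # single group: zero-width interval at the point estimate
  ci1 <- bootstrap_ci(s, y, rep("a", n), auroc, n_boot = 50, seed = 1)
  expect_equal(unname(ci1[["lower"]]), pt)
  expect_equal(unname(ci1[["upper"]]), pt)
  # replicates losing a class are dropped and counted
  y2 <- c(1, 0); s2 <- c(0.8, 0.1)
  ci3 <- bootstrap_ci(s2, y2, c("a", "b"), auroc, n_boot = 100, seed = 2)
  expect_gt(attr(ci3, "dropped"), 0)
})

test_that("CI endpoints stabilize as replicates grow", {
  set.seed(13)
  n <- 400
  g <- sample(sprintf("s%02d", 1:40), n, replace = TRUE)
  y <- rbinom(n, 1, 0.2); s <- runif(n) + 0.5 * y
  lo <- function(nb, sd) bootstrap_ci(s, y, g, auroc, nb, seed = sd)
  a <- lo(400, 3); b <- lo(4000, 4)
  c2 <- lo(4000, 5)
  # the two high-resolution CIs agree more closely than low vs high
  expect_lt(abs(b[["lower"]] - c2[["lower"]]),
            abs(a[["lower"]] - b[["lower"]]) + 0.01)
})

test_that("metric report rows are consistent with their interval bounds", {
  set.seed(7)
  y <- rbinom(200, 1, 0.3); s <- runif(200) + 0.6 * y
  rep <- metric_report(s, y, n_boot = 100, seed = 3)
  expect_setequal(rep$metric, c("auroc", "auprc", "accuracy", "recall",
                                "precision", "f1"))
  ok <- !is.na(rep$lower)
  expect_true(all(rep$lower[ok] <= rep$value[ok] + 1e-9))
  expect_true(all(rep$upper[ok] >= rep$value[ok] - 1e-9))
  expect_equal(attr(rep, "threshold"), 0.5)
})

test_that("temporal curve stratifies, flags, and partitions the examples", {
  pr <- data.frame(
    stay_id = rep(c("a", "b", "c", "d"), each = 4),
    trigger_h = rep(c(4, 8, 12, 16), 4),
    risk = runif(16),
    label = c(0, 0, 0, 0, 0, 0, 1, 1, 0, 0, 0, 1, 0, 0, 0, 0))
  pr$risk[pr$trigger_h >= 12] <- pr$label[pr$trigger_h >= 12] # separable
  tc <- temporal_curve(pr, stride = 4)
  expect_equal(tc$trigger_h, c(4, 8, 12, 16))
  expect_equal(sum(tc$n), nrow(pr))
  expect_false(tc$defined[tc$trigger_h == 4]) # no positives there
  expect_equal(tc$auroc[tc$trigger_h == 12], 1)
  expect_equal(tc$auroc[tc$trigger_h == 16], 1)
})

test_that("subgroup report covers strata and matches pooled metrics", {
  set.seed(8)
  meta <- data.frame(
    stay_id = sprintf("s%03d", 1:120),
    age_years = sample(c(40L, 70L), 120, TRUE),
    sex = sample(c("F", "M"), 120, TRUE),
    race = sample(c("white", "black"), 120, TRUE),
    stringsAsFactors = FALSE)
  pr <- data.frame(stay_id = meta$stay_id,
                   risk = runif(120),
                   label = rbinom(120, 1, 0.3))
  pr$risk <- pr$risk + 0.5 * pr$label
  sg <- subgroup_report(pr, meta, n_boot = 50, seed = 2)
  # stratum counts sum to the cohort count within each stratum family
  for (f in c("age", "sex", "race"))
    expect_equal(sum(sg$n[sg$stratum == f]), nrow(pr))
  # age boundary: 65 and over belongs to the >=65 group
  meta65 <- meta; meta65$age_years <- 65L
  sg65 <- subgroup_report(pr, meta65, n_boot = 0)
  expect_equal(sg65$group[sg65$stratum == "age"], ">=65")
  # a stratum equal to the whole set reproduces the pooled metric
  metaF <- meta; metaF$sex <- "F"
  sgF <- subgroup_report(pr, metaF, n_boot = 0)
  expect_equal(sgF$auroc[sgF$stratum == "sex"], auroc(pr$risk, pr$label))
  # identical distributions across two strata give overlapping CIs
  a <- sg[sg$stratum == "sex" & sg$group == "F", ]
  b <- sg[sg$stratum == "sex" & sg$group == "M", ]
  expect_true(a$auroc_lower <= b$auroc_upper &&
                b$auroc_lower <= a$auroc_upper)
})

test_that("transfer model uses exactly the common-variable channels", {
  mk <- function(seed) filter_eligible(suppressWarnings(
    simulate_cohort(sim_config(n_patients = 70, seed = seed)))$cohort)
  ca <- mk(61); cb <- mk(62)
  common <- c("num_01", "num_02", "num_03", "cat_01")
  task <- task_spec("static", horizon_h = Inf)
  cfg <- tbal_config(input_dim = 1, hidden_size = 4, seed = 2)
  tcfg <- train_config(task, batch_pos = 8, batch_neg = 8, lr = 1e-2,
                       max_epochs = 2, patience = 2, seed = 2)
  res <- cross_cohort(ca, cb, common, task, cfg, tcfg)
  parents <- unique(res$model$parent_var)
  expect_setequal(parents, common)
  expect_error(cross_cohort(ca, cb, character(0), task, cfg, tcfg),
               "non-empty")
  expect_error(cross_cohort(ca, cb, "bogus", task, cfg, tcfg),
               "missing from")
  # reports carry both directions
  expect_true(all(c("auroc", "auprc") %in% res$in_cohort$metric))
  expect_equal(nrow(res$predictions_b),
               sum(res$predictions_b$split == "test"))
})
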