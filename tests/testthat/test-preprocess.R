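spec3 <- tiny_dictionary()

test_that("hourly resampling aggregates within half-open bins", {
  ev <- data.frame(
    stay_id = "a",
    time_h = c(1.2, 1.4, 3.1, 3.2, 3.3, 2.5),
    variable = c("hr", "hr", "rhythm", "rhythm", "rhythm", "lactate"),
    value = c("80", "90", "sinus", "afib", "sinus", "3.0"),
    stringsAsFactors = FALSE)
  a <- resample_stay(ev, spec3, los_h = 6)
  expect_equal(a$grid_h, 0:6)
  # median of two observations in bin 1
  expect_equal(a$X$hr[2], 85)
  expect_equal(unname(a$M[2, "hr"]), 1)
  expect_true(all(a$M[-2, "hr"] == 0))
  # categorical mode (majority)
  expect_equal(a$X$rhythm[4], "sinus")
  # boundary: exactly 2.5 h lands in bin 3, not bin 2
  expect_true(is.na(a$X$lactate[3]))
  expect_equal(a$X$lactate[4], 3.0)
})

test_that("mode ties break toward the most recent observation", {
  ev <- data.frame(stay_id = "a", time_h = c(3.1, 3.2),
                   variable = "rhythm", value = c("sinus", "afib"),
                   stringsAsFactors = FALSE)
  a <- resample_stay(ev, spec3, los_h = 4)
  expect_equal(a$X$rhythm[4], "afib")
})

test_that("resampling matches a brute-force group-by-bin oracle", {
  set.seed(41)
  for (rep in 1:20) {
    ev <- random_stay_events("s", spec3, los_h = 10,
                             n_events = sample(5:40, 1),
                             cat_levels = c("sinus", "afib"))
    a <- resample_stay(ev, spec3, los_h = 10)
    bins <- floor(ev$time_h + 0.5)
    for (d in names(spec3)) {
      for (b in 0:10) {
        sel <- ev$variable == d & bins == b
        if (!any(sel)) {
          expect_equal(unname(a$M[b + 1, d]), 0)
          expect_true(is.na(a$X[[d]][b + 1]))
        } else {
          expect_equal(unname(a$M[b + 1, d]), 1)
          if (spec3[[d]]$vtype == "numeric")
            expect_equal(a$X[[d]][b + 1],
                         median(as.numeric(ev$value[sel])))
        }
      }
    }
  }
})

test_that("delta recursion matches hand-unrolled cases", {
  M <- matrix(c(1, 0, 0, 1), 4, 1)
  expect_equal(drop(compute_delta(M, 1:4)), c(0, 1, 2, 3))
  M2 <- matrix(1, 5, 1)
  expect_equal(drop(compute_delta(M2, 1:5)), c(0, 1, 1, 1, 1))
  # non-uniform grid with spacing (1, 3, 1) and mask 1,0,1,0
  M3 <- matrix(c(1, 0, 1, 0), 4, 1)
  expect_equal(drop(compute_delta(M3, c(0, 1, 4, 5))), c(0, 1, 4, 1))
})

test_that("delta equals a brute-force scan on random masks and grids", {
  set.seed(7)
  for (rep in 1:25) {
    T_ <- sample(2:12, 1); D <- sample(1:4, 1)
    M <- matrix(rbinom(T_ * D, 1, 0.5), T_, D)
    grid <- cumsum(c(0, sample(1:3, T_ - 1, replace = TRUE)))
    expect_equal(compute_delta(M, grid), delta_bruteforce(M, grid),
                 ignore_attr = TRUE)
  }
})

test_that("empty-bin removal keeps true times and recomputes delta", {
  ev <- data.frame(stay_id = "a", time_h = c(0.1, 2.2),
                   variable = c("hr", "hr"), value = c("70", "75"),
                   stringsAsFactors = FALSE)
  a <- resample_stay(ev, spec3, los_h = 3)
  pruned <- drop_empty_bins(a)
  expect_equal(pruned$grid_h, c(0, 2))
  expect_equal(pruned$dropped_bins, c(1, 3))
  expect_equal(unname(pruned$Delta[, "hr"]), c(0, 2))
  # all-empty stay is an error
  none <- resample_stay(ev[0, ], spec3, los_h = 3)
  none$stay_id <- "a"
  expect_error(drop_empty_bins(none), "empty stay")
  # no empty rows -> identity
  full <- resample_stay(data.frame(
    stay_id = "a", time_h = c(0.1, 1, 2, 3), variable = "hr",
    value = c("1", "2", "3", "4"), stringsAsFactors = FALSE),
    spec3, los_h = 3)
  expect_equal(drop_empty_bins(full)$grid_h, 0:3)
})

test_that("imputation cascade: head fill, interior interpolation, tails", {
  stats <- fit_normalization(list(), spec3[0])
  stats$fallback <- list(hr = 7.2, lactate = 2.0, rhythm = "sinus")
  grid <- 0:4
  a <- structure(list(
    stay_id = "a", grid_h = grid,
    X = data.frame(hr = c(NA, 10, NA, 20, NA),
                   lactate = NA_real_,
                   rhythm = c(NA, "afib", NA, NA, NA),
                   stringsAsFactors = FALSE),
    M = cbind(hr = c(0, 1, 0, 1, 0), lactate = rep(0, 5),
              rhythm = c(0, 1, 0, 0, 0)),
    Delta = NULL, dropped_bins = numeric(0)), class = "aligned_stay")
  a$Delta <- compute_delta(a$M, grid)
  out <- impute_stay(a, spec3, stats)
  expect_equal(out$X$hr, c(10, 10, 15, 20, 20))
  # never-observed numeric -> training median everywhere, mask untouched
  expect_equal(out$X$lactate, rep(2.0, 5))
  expect_equal(sum(out$M[, "lactate"]), 0)
  # categorical: head back-fill from earliest obs, "missing" elsewhere
  expect_equal(out$X$rhythm, c("afib", "afib", "missing", "missing",
                               "missing"))
})

test_that("imputation never alters observed entries", {
  set.seed(99)
  stats <- list(mean = c(hr = 0, lactate = 0), sd = c(hr = 1, lactate = 1),
                fallback = list(hr = 0, lactate = 0, rhythm = "missing"),
                interval_scale = 24)
  for (rep in 1:10) {
    ev <- random_stay_events("s", spec3, 8, sample(4:30, 1),
                             cat_levels = c("sinus", "afib"))
    a <- resample_stay(ev, spec3, los_h = 8)
    if (!any(a$M == 1)) next
    a <- drop_empty_bins(a)
    out <- impute_stay(a, spec3, stats)
    for (d in names(spec3)) {
      obs <- a$M[, d] == 1
      expect_equal(out$X[[d]][obs], a$X[[d]][obs])
      expect_false(anyNA(out$X[[d]]))
    }
  }
})

test_that("normalization statistics come from observed entries only", {
  ev <- data.frame(stay_id = "a", time_h = c(0.1, 1.1),
                   variable = "hr", value = c("10", "20"),
                   stringsAsFactors = FALSE)
  a <- drop_empty_bins(resample_stay(ev, spec3, los_h = 5))
  st <- suppressWarnings(fit_normalization(list(a), spec3))
  expect_equal(unname(st$mean["hr"]), 15)
  expect_equal(unname(st$sd["hr"]), sd(c(10, 20)))
  expect_equal(st$fallback$hr, 15)
  # degenerate: constant variable gets epsilon sd
  ev2 <- data.frame(stay_id = "a", time_h = c(0.1, 1.1), variable = "hr",
                    value = c("5", "5"), stringsAsFactors = FALSE)
  a2 <- drop_empty_bins(resample_stay(ev2, spec3, los_h = 2))
  expect_warning(st2 <- fit_normalization(list(a2), spec3["hr"]),
                 "degenerate")
  expect_equal(unname(st2$sd["hr"]), 1e-6)
})

test_that("training statistics change when test stays are added (leakage sentinel)", {
  set.seed(5)
  mk <- function(id, base) {
    ev <- data.frame(stay_id = id, time_h = c(0.1, 1.2, 2.4),
                     variable = "hr",
                     value = as.character(base + c(0, 5, 9)),
                     stringsAsFactors = FALSE)
    drop_empty_bins(resample_stay(ev, spec3["hr"], los_h = 3))
  }
  train <- list(mk("a", 60), mk("b", 70))
  test <- list(mk("c", 120))
  st_train <- fit_normalization(train, spec3["hr"])
  st_both <- fit_normalization(c(train, test), spec3["hr"])
  expect_false(isTRUE(all.equal(st_train$mean, st_both$mean)))
})

test_that("encoding layout, z-score identity and interval scaling", {
  dict <- list(
    n1 = variable_spec("n1", "numeric", "median", "linear"),
    n2 = variable_spec("n2", "numeric", "median", "linear"),
    c1 = variable_spec("c1", "categorical", "mode", "locf",
                       categories = c("a", "b")))
  ev <- data.frame(stay_id = "s", time_h = c(0.2, 1.2, 0.3),
                   variable = c("n1", "n2", "c1"),
                   value = c("15", "8", "a"), stringsAsFactors = FALSE)
  a <- drop_empty_bins(resample_stay(ev, dict, los_h = 1))
  stats <- list(mean = c(n1 = 15, n2 = 0), sd = c(n1 = 3, n2 = 1),
                fallback = list(n1 = 15, n2 = 0, c1 = "a"),
                interval_scale = 24)
  enc <- encode_stay(impute_stay(a, dict, stats), stats, dict)
  # F = 2 numeric + 3 one-hot levels + 3 masks + 3 intervals = 11
  expect_equal(ncol(enc$Z), 11)
  expect_equal(anyDuplicated(enc$feature_names), 0L)
  # value equal to the training mean encodes to 0
  expect_equal(unname(enc$Z[1, "n1"]), 0)
  # one-hot block sums to one per row
  oh <- enc$Z[, grep("^c1=", enc$feature_names), drop = FALSE]
  expect_true(all(rowSums(oh) == 1))
  # a 24-hour delta maps to interval channel 1.0
  a2 <- a
  a2$Delta[1, ] <- 24
  enc2 <- encode_stay(impute_stay(a2, dict, stats), stats, dict)
  expect_equal(unname(enc2$Z[1, "n1.delta"]), 1.0)
  # unseen category maps to "missing" with a warning
  a3 <- impute_stay(a, dict, stats)
  a3$X$c1[1] <- "zz"
  expect_warning(enc3 <- encode_stay(a3, stats, dict), "unseen")
  expect_equal(unname(enc3$Z[1, "c1=missing"]), 1)
})

test_that("preprocessing is deterministic given cohort and stats", {
  co <- suppressWarnings(
    simulate_cohort(sim_config(n_patients = 25, seed = 17)))$cohort
  p1 <- preprocess_cohort(co)
  p2 <- preprocess_cohort(co, stats = p1$stats)
  expect_equal(p1$encoded, p2$encoded)
})
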