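test_that("balance factor equals the negative-class proportion", {
  expect_equal(resolve_alpha(c(rep(1, 50), rep(0, 50))), 0.5)
  expect_equal(resolve_alpha(c(rep(1, 2), rep(0, 98))), 0.98)
  expect_equal(resolve_alpha(c(rep(1, 25), rep(0, 75))), 0.75)
  # and the stated rule: normalized inverse class proportions
  pi_pos <- 0.02
  expect_equal((1 / pi_pos) / (1 / pi_pos + 1 / (1 - pi_pos)),
               resolve_alpha(c(rep(1, 2), rep(0, 98))))
  expect_error(resolve_alpha(rep(1, 5)), "both classes")
  expect_error(resolve_alpha(c(0, 2)), "binary")
})

test_that("weighted cross-entropy closed forms and clamping", {
  expect_equal(weighted_bce(0.5, 1, 0.5), 0.5 * -log(0.5))
  expect_equal(weighted_bce(0.3, 0, 1), 0) # weight annihilates negatives
  expect_true(is.finite(weighted_bce(1, 0, 0.5))) # clamped at the edge
  # reduces to standard BCE at alpha = 0.5 up to the factor 1/2
  set.seed(2)
  p <- runif(50, 0.01, 0.99); y <- rbinom(50, 1, 0.5)
  plain <- -mean(y * log(p) + (1 - y) * log(1 - p))
  expect_equal(weighted_bce(p, y, 0.5), 0.5 * plain, tolerance = 1e-12)
})

test_that("loss gradient matches finite differences", {
  set.seed(3)
  for (alpha in c(0.2, 0.5, 0.98)) {
    p <- runif(6, 0.05, 0.95); y <- rbinom(6, 1, 0.5)
    # analytic d(mean loss)/dp_i
    ga <- ifelse(y == 1, -alpha / p, (1 - alpha) / (1 - p)) / length(p)
    eps <- 1e-7
    for (i in seq_along(p)) {
      pp <- p; pp[i] <- pp[i] + eps
      pm <- p; pm[i] <- pm[i] - eps
      gn <- (weighted_bce(pp, y, alpha) - weighted_bce(pm, y, alpha)) /
        (2 * eps)
      expect_equal(gn, ga[i], tolerance = 1e-5)
    }
  }
})

test_that("balanced batches hold exact class counts and cover the majority", {
  ex <- data.frame(label = c(rep(1L, 30), rep(0L, 1000)))
  bb <- balanced_batches(ex, batch_pos = 200, batch_neg = 200, seed = 4)
  expect_length(bb, 5) # ceiling(1000 / 200)
  for (b in bb) {
    expect_equal(sum(ex$label[b] == 1L), 200)
    expect_equal(sum(ex$label[b] == 0L), 200)
  }
  negs <- unlist(lapply(bb, function(b) b[ex$label[b] == 0L]))
  expect_setequal(unique(negs), which(ex$label == 0L)) # full coverage
  expect_identical(balanced_batches(ex, 200, 200, seed = 4), bb)
  expect_false(identical(balanced_batches(ex, 200, 200, seed = 5), bb))
  expect_error(balanced_batches(data.frame(label = rep(1L, 5)), 2, 2),
               "non-empty")
})

# shared toy problem: one feature separates the classes
make_toy <- function(n_stays = 60, T_ = 6, seed = 1) {
  set.seed(seed)
  encoded <- list(); examples <- NULL
  for (i in seq_len(n_stays)) {
    id <- sprintf("t%03d", i)
    y <- as.integer(i %% 3 == 0)
    Z <- matrix(rnorm(T_ * 4, 0, 0.3), T_, 4)
    Z[, 2] <- Z[, 2] + ifelse(y == 1, 2, -2)
    fn <- paste0("f", 1:4)
    colnames(Z) <- fn
    encoded[[id]] <- structure(
      list(stay_id = id, Z = Z, feature_names = fn,
           parent_var = stats::setNames(fn, fn), grid_h = seq_len(T_)),
      class = "encoded_stay")
    examples <- rbind(examples, data.frame(
      stay_id = id, trigger_h = T_, label = y,
      split = c("train", "val", "test")[1 + (i %% 10 == 1) +
                                          2 * (i %% 10 == 2)],
      stringsAsFactors = FALSE))
  }
  list(encoded = encoded, examples = examples)
}

test_that("a separable toy problem is learned to high training AUROC", {
  toy <- make_toy(90, seed = 6)
  cfg <- tbal_config(input_dim = 4, hidden_size = 8, seed = 2)
  tcfg <- train_config(task_spec("static"), batch_pos = 16,
                       batch_neg = 16, lr = 2e-2, max_epochs = 20,
                       patience = 20, seed = 2)
  fit <- tbal_fit(toy$examples, toy$encoded, cfg, tcfg)
  tr <- toy$examples[toy$examples$split == "train", ]
  pr <- predict(fit, toy$encoded, tr)
  expect_gt(auroc(pr$risk, pr$label), 0.99)
  expect_s3_class(fit, "tbal")
  expect_equal(nrow(fit$history), length(unique(fit$history$epoch)))
})

test_that("training is reproducible and early stopping respects patience", {
  toy <- make_toy(50, seed = 8)
  cfg <- tbal_config(input_dim = 4, hidden_size = 4, seed = 3)
  tcfg <- train_config(task_spec("static"), batch_pos = 8, batch_neg = 8,
                       lr = 1e-2, max_epochs = 30, patience = 2, seed = 3)
  f1 <- tbal_fit(toy$examples, toy$encoded, cfg, tcfg)
  f2 <- tbal_fit(toy$examples, toy$encoded, cfg, tcfg)
  expect_identical(f1$params, f2$params)
  expect_identical(f1$history, f2$history)
  # with patience 2 and a quickly saturating problem, stop before the cap
  expect_lt(nrow(f1$history), 30)
  expect_equal(f1$best_epoch, which.max(f1$history$val_auprc))
})

test_that("dynamic fitting resolves alpha from the labels it trains on", {
  toy <- make_toy(60, seed = 9)
  # re-badge the toy as a dynamic task with triggers at the stay end
  cfg <- tbal_config(input_dim = 4, hidden_size = 4, seed = 4)
  tcfg <- train_config(task_spec("dynamic"), lr = 1e-2, max_epochs = 3,
                       patience = 3, batch_size = 32, seed = 4)
  fit <- tbal_fit(toy$examples, toy$encoded, cfg, tcfg)
  tr <- toy$examples[toy$examples$split == "train", ]
  expect_equal(fit$alpha, resolve_alpha(tr$label), tolerance = 1e-12)
  expect_gt(fit$alpha, 0.5) # negatives dominate the toy
})

test_that("patient leakage between splits is refused", {
  toy <- make_toy(30, seed = 10)
  bad <- toy$examples
  bad$split[bad$stay_id == bad$stay_id[1]] <- "train"
  bad2 <- rbind(bad, transform(bad[1, ], split = "val"))
  cfg <- tbal_config(input_dim = 4, hidden_size = 4, seed = 1)
  tcfg <- train_config(task_spec("static"), batch_pos = 4, batch_neg = 4,
                       max_epochs = 1, seed = 1)
  expect_error(tbal_fit(bad2, toy$encoded, cfg, tcfg), "leakage")
})
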