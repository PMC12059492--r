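cfg5 <- tbal_config(input_dim = 5, hidden_size = 6, seed = 3)

test_that("attention weights are a proper distribution over the prefix", {
  enc <- random_encoded_stay(T_ = 9, Fd = 5, seed = 2)
  params <- init_params(cfg5)
  out <- tbal_forward(enc, trigger_h = 6, params, cfg5)
  expect_length(out$attention_weights, 6) # prefix rows only
  expect_true(all(out$attention_weights >= 0))
  expect_equal(sum(out$attention_weights), 1, tolerance = 1e-10)
  expect_gt(out$risk, 0); expect_lt(out$risk, 1)
  # single-step prefix: softmax over a singleton
  out1 <- tbal_forward(enc, trigger_h = 1, params, cfg5)
  expect_equal(out1$attention_weights, 1)
})

test_that("forward is deterministic and validates inputs", {
  enc <- random_encoded_stay(seed = 4)
  params <- init_params(cfg5)
  r1 <- tbal_forward(enc, 5, params, cfg5)
  r2 <- tbal_forward(enc, 5, params, cfg5)
  expect_identical(r1$risk, r2$risk)
  bad <- enc; bad$Z[2, 3] <- NA
  expect_error(tbal_forward(bad, 5, params, cfg5), "imputation contract")
  expect_error(tbal_forward(enc, 0.5, params, cfg5), "prefix shorter")
})

test_that("dynamic predictions equal prefix-wise forward passes", {
  enc <- random_encoded_stay(T_ = 10, Fd = 5, seed = 5)
  params <- init_params(cfg5)
  dyn <- tbal_forward_dynamic(enc, c(4, 8), params, cfg5)
  expect_equal(dyn$risk[1], tbal_forward(enc, 4, params, cfg5)$risk,
               tolerance = 1e-12)
  expect_equal(dyn$risk[2], tbal_forward(enc, 8, params, cfg5)$risk,
               tolerance = 1e-12)
  expect_error(tbal_forward_dynamic(enc, c(4.5), params, cfg5),
               "not on the grid")
})

test_that("predictions at trigger t ignore all later rows (causality)", {
  params <- init_params(cfg5)
  set.seed(88)
  for (rep in 1:20) {
    enc <- random_encoded_stay(T_ = 12, Fd = 5, seed = 100 + rep)
    trig <- sample(3:10, 1)
    base <- tbal_forward(enc, trig, params, cfg5)$risk
    mut <- enc
    later <- which(mut$grid_h > trig)
    mut$Z[later, ] <- matrix(rnorm(length(later) * 5) * 10,
                             length(later), 5)
    expect_identical(tbal_forward(mut, trig, params, cfg5)$risk, base)
  }
})

test_that("feature permutation with matching layout leaves output unchanged", {
  enc <- random_encoded_stay(T_ = 7, Fd = 5, seed = 6)
  params <- init_params(cfg5)
  base <- tbal_forward(enc, 7, params, cfg5)$risk
  perm <- sample(5)
  enc2 <- enc
  enc2$Z <- enc$Z[, perm]
  enc2$feature_names <- enc$feature_names[perm]
  params2 <- params # permute the first-layer input rows to match
  params2$layers[[1]]$fwd$W <- params$layers[[1]]$fwd$W[perm, ]
  params2$layers[[1]]$bwd$W <- params$layers[[1]]$bwd$W[perm, ]
  expect_equal(tbal_forward(enc2, 7, params2, cfg5)$risk, base,
               tolerance = 1e-12)
})

test_that("time-aware attention responds to grid spacing; plain attention does not", {
  cfg_ta <- tbal_config(input_dim = 4, hidden_size = 5, time_aware = TRUE,
                        seed = 9)
  cfg_pl <- tbal_config(input_dim = 4, hidden_size = 5,
                        time_aware = FALSE, seed = 9)
  p_ta <- init_params(cfg_ta); p_pl <- init_params(cfg_pl)
  enc_a <- random_encoded_stay(T_ = 6, Fd = 4, seed = 7, grid = 1:6)
  enc_b <- enc_a
  enc_b$grid_h <- c(1, 2, 3, 4, 5, 30) # same values, stretched spacing
  att_a <- tbal_forward(enc_a, 6, p_ta, cfg_ta)$attention_weights
  # same prefix against a much later trigger: tau differs
  att_b <- tbal_forward(enc_b, 30, p_ta, cfg_ta)$attention_weights
  expect_gt(max(abs(att_a - att_b)), 1e-6)
  # with the time term off, output is invariant to uniform time shifts
  r1 <- tbal_forward(enc_a, 6, p_pl, cfg_pl)$risk
  enc_sh <- enc_a; enc_sh$grid_h <- enc_a$grid_h + 50
  r2 <- tbal_forward(enc_sh, 56, p_pl, cfg_pl)$risk
  expect_equal(r1, r2, tolerance = 1e-12)
})

test_that("parameter counts follow the closed-form LSTM formula", {
  # unidirectional, hidden 1, input 1: 4(1*1 + 1*1 + 1) = 12 + head (1 + 1)
  c1 <- tbal_config(input_dim = 1, hidden_size = 1, bidirectional = FALSE)
  expect_equal(as.integer(count_parameters(c1)), 12 + 2)
  # closed form at larger sizes: 4H(F + H + 1) per direction
  H <- 7; Fd <- 5; A <- 4
  cb <- tbal_config(input_dim = Fd, hidden_size = H, attention_dim = A,
                    bidirectional = TRUE)
  expected <- 2 * 4 * H * (Fd + H + 1) + # encoder, both directions
    (2 * H * A + A + A + A) +            # attention: Wa, wt, ba, v
    (2 * H + 1)                          # head
  expect_equal(as.integer(count_parameters(cb)), expected)
  # monotone in hidden size; bidirectional doubles the encoder block
  c2 <- tbal_config(input_dim = 5, hidden_size = 14, attention_dim = 4)
  expect_gt(as.integer(count_parameters(c2)),
            as.integer(count_parameters(cb)))
  bd <- attr(count_parameters(cb), "breakdown")
  expect_equal(bd[["layer1_fwd"]], bd[["layer1_bwd"]])
})

test_that("checkpoints round-trip through save and load", {
  enc <- random_encoded_stay(T_ = 6, Fd = 5, seed = 11)
  fitlike <- structure(list(params = init_params(cfg5), config = cfg5,
                            feature_names = enc$feature_names,
                            stats = NULL),
                       class = "tbal")
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(fitlike, path)
  back <- load_checkpoint(path)
  expect_equal(back$params, fitlike$params)
  expect_equal(tbal_forward(enc, 6, back$params, back$config)$risk,
               tbal_forward(enc, 6, fitlike$params, cfg5)$risk)
})
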