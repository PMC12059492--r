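# Native implementation of the TBAL network and the LSTM baseline.
#
# The encoder is a (optionally stacked, optionally bidirectional) LSTM run
# over the encoded prefix only. The TBAL head applies additive attention
# with a time-aware term: scores e_t = v . tanh(W_a h_t + w_tau * g(tau_t)
# + b_a) with tau_t = trigger_time - s_t (hours to the prediction point)
# and g(tau) = log(1 + tau / 24); weights are a softmax over the prefix,
# the context is the attention-weighted sum of encoder states and the risk
# is sigmoid(linear(context)). The baseline LSTM (bidirectional = FALSE)
# classifies the final hidden state. Forward and backward passes are
# hand-derived and exercised by finite-difference tests.
#
# Batch container: 3D arrays (B, Tmax, F) with per-sequence lengths; padded
# steps are frozen (states carry through) and masked out of the attention
# softmax, so they contribute nothing to outputs or gradients.

# gate column blocks in the 4H-wide pre-activation: input, forget, output,
# cell candidate
gate_cols <- function(H) list(i = 1:H, f = H + 1:H, o = 2 * H + 1:H,
                              g = 3 * H + 1:H)

#' TBAL / LSTM architecture configuration
#'
#' @param input_dim encoded feature count F.
#' @param hidden_size LSTM hidden units per direction (512 at full scale;
#'   much smaller values are adequate for synthetic cohorts).
#' @param num_layers stacked encoder layers.
#' @param attention_dim width of the additive-attention projection.
#' @param dropout dropout probability applied to the context vector during
#'   training.
#' @param l2_weight L2 (weight-decay) coefficient on non-bias parameters.
#' @param bidirectional `TRUE` for the TBAL encoder; `FALSE` gives the
#'   unidirectional LSTM baseline with a last-hidden-state head (no
#'   attention).
#' @param time_aware include the elapsed-time term in the attention scores.
#' @param seed seed for parameter initialization.
#' @return object of class `tbal_config`.
#' @export
tbal_config <- function(input_dim, hidden_size = 32, num_layers = 1,
                        attention_dim = NULL, dropout = 0,
                        l2_weight = 1e-5, bidirectional = TRUE,
                        time_aware = TRUE, seed = 1L) {
  stopifnot(input_dim >= 1, hidden_size >= 1, num_layers >= 1,
            dropout >= 0, dropout < 1)
  attention_dim <- attention_dim %||% hidden_size
  structure(list(input_dim = as.integer(input_dim),
                 hidden_size = as.integer(hidden_size),
                 num_layers = as.integer(num_layers),
                 attention_dim = as.integer(attention_dim),
                 dropout = dropout, l2_weight = l2_weight,
                 bidirectional = isTRUE(bidirectional),
                 time_aware = isTRUE(time_aware),
                 seed = as.integer(seed)),
            class = "tbal_config")
}

#' @export
print.tbal_config <- function(x, ...) {
  cat(sprintf(
    "<tbal_config> %s, input %d, hidden %d x %d layer(s)%s%s\n",
    if (x$bidirectional) "TBAL (bidirectional + attention)"
    else "LSTM baseline",
    x$input_dim, x$hidden_size, x$num_layers,
    if (x$bidirectional) sprintf(", attention %d", x$attention_dim) else "",
    if (x$bidirectional && x$time_aware) ", time-aware" else ""))
  invisible(x)
}

# -- parameters ------------------------------------------------------------

#' Initialize model parameters
#'
#' Uniform initialization on +/- 1/sqrt(hidden) with forget-gate biases
#' at 1; the configuration seed fully determines the draw. Mostly useful
#' for low-level experimentation and testing — [tbal_fit()] calls this
#' internally.
#'
#' @param config a [tbal_config()].
#' @return nested list of parameter matrices (per-layer LSTM blocks,
#'   attention, classifier head).
#' @export
init_params <- function(config) {
  set.seed(config$seed)
  H <- config$hidden_size
  unif <- function(nr, nc, fan) {
    s <- 1 / sqrt(fan)
    matrix(stats::runif(nr * nc, -s, s), nr, nc)
  }
  layer <- function(Fin) {
    b <- stats::runif(4 * H, -1 / sqrt(H), 1 / sqrt(H))
    b[gate_cols(H)$f] <- 1 # forget-gate bias init
    list(W = unif(Fin, 4 * H, H), U = unif(H, 4 * H, H), b = b)
  }
  params <- list(layers = list())
  Fin <- config$input_dim
  for (l in seq_len(config$num_layers)) {
    params$layers[[l]] <- list(fwd = layer(Fin),
                               bwd = if (config$bidirectional) layer(Fin))
    Fin <- if (config$bidirectional) 2L * H else H
  }
  K <- Fin # encoder output width
  if (config$bidirectional) {
    A <- config$attention_dim
    params$att <- list(Wa = unif(K, A, K), wt = stats::runif(A, -0.1, 0.1),
                       ba = rep(0, A), v = unif(A, 1, A)[, 1])
  }
  params$head <- list(w = unif(K, 1, K)[, 1], b = 0)
  params
}

#' Count trainable parameters
#'
#' @param config a [tbal_config()].
#' @return integer total with a per-submodule breakdown in attribute
#'   `"breakdown"`.
#' @export
count_parameters <- function(config) {
  params <- init_params(config)
  breakdown <- integer(0)
  for (l in seq_along(params$layers)) {
    for (dir in c("fwd", "bwd")) {
      blk <- params$layers[[l]][[dir]]
      if (is.null(blk)) next
      breakdown[[paste0("layer", l, "_", dir)]] <-
        sum(vapply(blk, length, 0L))
    }
  }
  if (!is.null(params$att))
    breakdown[["attention"]] <- sum(vapply(params$att, length, 0L))
  breakdown[["head"]] <- sum(vapply(params$head, length, 0L))
  structure(sum(breakdown), breakdown = breakdown)
}

# -- batched LSTM ----------------------------------------------------------

# slice (B, Tmax, F) -> B x F matrix at step t
arr_t <- function(A, t) {
  d <- dim(A)
  matrix(A[, t, ], d[1], d[3])
}

# reverse the first `lens[i]` steps of each row sequence
reverse_arr <- function(A, lens) {
  out <- A
  for (i in seq_along(lens)) {
    L <- lens[i]
    if (L > 1) out[i, 1:L, ] <- A[i, L:1, ]
  }
  out
}

# One LSTM direction over the batch. `valid` is B x Tmax; after a
# sequence ends its states freeze (carry previous values) so reads at any
# t <= len are well-defined and padded steps are inert.
lstm_run <- function(X, valid, prm) {
  d <- dim(X); B <- d[1]; Tmax <- d[2]
  H <- ncol(prm$U) / 4L
  gc_ <- gate_cols(H)
  mk <- function() array(0, c(B, Tmax, H))
  ci <- mk(); cf <- mk(); co <- mk(); cg <- mk(); ctC <- mk()
  Cs <- mk(); Hs <- mk()
  Hprev <- matrix(0, B, H); Cprev <- matrix(0, B, H)
  bmat <- matrix(prm$b, B, 4 * H, byrow = TRUE)
  for (t in seq_len(Tmax)) {
    A <- arr_t(X, t) %*% prm$W + Hprev %*% prm$U + bmat
    i <- sigmoid(A[, gc_$i, drop = FALSE])
    f <- sigmoid(A[, gc_$f, drop = FALSE])
    o <- sigmoid(A[, gc_$o, drop = FALSE])
    g <- tanh(A[, gc_$g, drop = FALSE])
    Cn <- f * Cprev + i * g
    tC <- tanh(Cn)
    Hn <- o * tC
    v <- valid[, t]
    Cnow <- Cprev; Cnow[v, ] <- Cn[v, , drop = FALSE]
    Hnow <- Hprev; Hnow[v, ] <- Hn[v, , drop = FALSE]
    ci[, t, ] <- i; cf[, t, ] <- f; co[, t, ] <- o; cg[, t, ] <- g
    ctC[, t, ] <- tC; Cs[, t, ] <- Cnow; Hs[, t, ] <- Hnow
    Hprev <- Hnow; Cprev <- Cnow
  }
  list(H = Hs, cache = list(i = ci, f = cf, o = co, g = cg, tC = ctC,
                            C = Cs))
}

# Backward pass for one direction. dHext is (B, Tmax, H): external gradient
# on the (post-freeze) hidden state at each step. Returns parameter grads
# and the gradient on the inputs.
lstm_back <- function(X, valid, prm, run, dHext) {
  d <- dim(X); B <- d[1]; Tmax <- d[2]; Fin <- d[3]
  H <- ncol(prm$U) / 4L
  gc_ <- gate_cols(H)
  ch <- run$cache
  dW <- matrix(0, Fin, 4 * H); dU <- matrix(0, H, 4 * H)
  db <- numeric(4 * H)
  dX <- array(0, c(B, Tmax, Fin))
  dHn <- matrix(0, B, H); dCn <- matrix(0, B, H)
  for (t in rev(seq_len(Tmax))) {
    dH <- arr_t(dHext, t) + dHn
    dC <- dCn
    v <- valid[, t]
    # invalid rows pass gradients straight through to the previous step
    dHnew <- dH; dHnew[!v, ] <- 0
    dCnew <- dC; dCnew[!v, ] <- 0
    dHcar <- dH; dHcar[v, ] <- 0
    dCcar <- dC; dCcar[v, ] <- 0
    i <- arr_t(ch$i, t); f <- arr_t(ch$f, t); o <- arr_t(ch$o, t)
    g <- arr_t(ch$g, t); tC <- arr_t(ch$tC, t)
    Cprev <- if (t > 1) arr_t(ch$C, t - 1L) else matrix(0, B, H)
    Hprev <- if (t > 1) arr_t(run$H, t - 1L) else matrix(0, B, H)
    do <- dHnew * tC
    dCC <- dCnew + dHnew * o * (1 - tC^2)
    di <- dCC * g; df <- dCC * Cprev; dg <- dCC * i
    dA <- cbind(di * i * (1 - i), df * f * (1 - f), do * o * (1 - o),
                dg * (1 - g^2))
    xt <- arr_t(X, t)
    dW <- dW + crossprod(xt, dA)
    dU <- dU + crossprod(Hprev, dA)
    db <- db + colSums(dA)
    dX[, t, ] <- dA %*% t(prm$W)
    dHn <- dA %*% t(prm$U) + dHcar
    dCn <- dCC * f + dCcar
  }
  list(dW = dW, dU = dU, db = db, dX = dX)
}

# -- full model ------------------------------------------------------------

# Encoder over the batch: returns top-layer state array (B, Tmax, K) plus
# per-layer run caches (and reversed inputs for the backward directions).
encoder_forward <- function(X, valid, lens, params, config) {
  layers <- list()
  Ain <- X
  for (l in seq_len(config$num_layers)) {
    prm <- params$layers[[l]]
    runf <- lstm_run(Ain, valid, prm$fwd)
    if (config$bidirectional) {
      Arev <- reverse_arr(Ain, lens)
      runb <- lstm_run(Arev, valid, prm$bwd)
      Hb <- reverse_arr(runb$H, lens)
      Hcat <- array(0, c(dim(runf$H)[1], dim(runf$H)[2],
                         2L * dim(runf$H)[3]))
      Hcat[, , seq_len(dim(runf$H)[3])] <- runf$H
      Hcat[, , dim(runf$H)[3] + seq_len(dim(runf$H)[3])] <- Hb
    } else {
      runb <- NULL; Arev <- NULL
      Hcat <- runf$H
    }
    layers[[l]] <- list(input = Ain, input_rev = Arev, runf = runf,
                        runb = runb)
    Ain <- Hcat
  }
  list(top = Ain, layers = layers)
}

encoder_backward <- function(enc, valid, lens, params, config, dTop) {
  grads <- list(layers = vector("list", config$num_layers))
  dA <- dTop
  for (l in rev(seq_len(config$num_layers))) {
    st <- enc$layers[[l]]
    prm <- params$layers[[l]]
    H <- dim(st$runf$H)[3]
    if (config$bidirectional) {
      dHf <- dA[, , seq_len(H), drop = FALSE]
      dHb <- reverse_arr(dA[, , H + seq_len(H), drop = FALSE], lens)
      gf <- lstm_back(st$input, valid, prm$fwd, st$runf, dHf)
      gb <- lstm_back(st$input_rev, valid, prm$bwd, st$runb, dHb)
      dA <- gf$dX + reverse_arr(gb$dX, lens)
      grads$layers[[l]] <- list(
        fwd = list(W = gf$dW, U = gf$dU, b = gf$db),
        bwd = list(W = gb$dW, U = gb$dU, b = gb$db))
    } else {
      gf <- lstm_back(st$input, valid, prm$fwd, st$runf, dA)
      dA <- gf$dX
      grads$layers[[l]] <- list(
        fwd = list(W = gf$dW, U = gf$dU, b = gf$db))
    }
  }
  grads$dX <- dA
  grads
}

# Full batched forward. X (B, Tmax, F), lens (B), tau (B, Tmax) hours to
# the prediction point. Returns probabilities, attention weights and a
# cache for the backward pass.
model_forward <- function(X, lens, tau, params, config, train = FALSE,
                          drop_mask = NULL) {
  B <- dim(X)[1]; Tmax <- dim(X)[2]
  valid <- outer(seq_len(B), seq_len(Tmax),
                 function(i, t) t <= lens[i])
  enc <- encoder_forward(X, valid, lens, params, config)
  K <- dim(enc$top)[3]
  if (config$bidirectional) {
    A <- length(params$att$ba)
    gtau <- log1p(pmax(tau, 0) / 24)
    e <- matrix(-Inf, B, Tmax)
    Slist <- vector("list", Tmax)
    for (t in seq_len(Tmax)) {
      pre <- arr_t(enc$top, t) %*% params$att$Wa +
        matrix(params$att$ba, B, A, byrow = TRUE)
      if (config$time_aware)
        pre <- pre + outer(gtau[, t], params$att$wt)
      S <- tanh(pre)
      Slist[[t]] <- S
      e[, t] <- S %*% params$att$v
    }
    e[!valid] <- -Inf
    alpha <- softmax_rows(e)
    ctx <- matrix(0, B, K)
    for (t in seq_len(Tmax))
      ctx <- ctx + alpha[, t] * arr_t(enc$top, t)
  } else {
    alpha <- NULL; Slist <- NULL; gtau <- NULL
    ctx <- t(vapply(seq_len(B), function(i) enc$top[i, lens[i], ],
                    numeric(K)))
    if (K == 1) ctx <- matrix(ctx, B, 1) # vapply collapse guard
  }
  if (train && config$dropout > 0) {
    if (is.null(drop_mask))
      drop_mask <- matrix(
        stats::rbinom(B * K, 1, 1 - config$dropout) /
          (1 - config$dropout), B, K)
    ctx_used <- ctx * drop_mask
  } else {
    drop_mask <- NULL
    ctx_used <- ctx
  }
  logit <- drop(ctx_used %*% params$head$w) + params$head$b
  p <- sigmoid(logit)
  list(p = p, logit = logit, alpha = alpha, ctx = ctx,
       ctx_used = ctx_used, enc = enc, valid = valid, Slist = Slist,
       gtau = gtau, drop_mask = drop_mask, lens = lens)
}

# Backward from d(loss)/d(logit). Returns gradient pytree matching params
# plus (optionally) input gradients dX.
model_backward <- function(fw, X, tau, params, config, dlogit,
                           want_dx = FALSE) {
  B <- dim(X)[1]; Tmax <- dim(X)[2]
  K <- dim(fw$enc$top)[3]
  grads <- list(head = list(
    w = drop(crossprod(fw$ctx_used, dlogit)),
    b = sum(dlogit)))
  dctx <- outer(dlogit, params$head$w)
  if (!is.null(fw$drop_mask)) dctx <- dctx * fw$drop_mask
  dTop <- array(0, c(B, Tmax, K))
  if (config$bidirectional) {
    A <- length(params$att$ba)
    alpha <- fw$alpha
    # d alpha and softmax backprop
    dalpha <- matrix(0, B, Tmax)
    for (t in seq_len(Tmax))
      dalpha[, t] <- rowSums(dctx * arr_t(fw$enc$top, t))
    rs <- rowSums(alpha * dalpha)
    de <- alpha * (dalpha - rs)
    de[!fw$valid] <- 0
    dWa <- matrix(0, K, A); dwt <- numeric(A); dba <- numeric(A)
    dv <- numeric(A)
    for (t in seq_len(Tmax)) {
      S <- fw$Slist[[t]]
      det <- de[, t]
      if (!any(det != 0)) {
        dTop[, t, ] <- alpha[, t] * dctx
        next
      }
      dv <- dv + drop(crossprod(S, det))
      dS <- outer(det, params$att$v) * (1 - S^2)
      dWa <- dWa + crossprod(arr_t(fw$enc$top, t), dS)
      dba <- dba + colSums(dS)
      if (config$time_aware)
        dwt <- dwt + drop(crossprod(dS, fw$gtau[, t]))
      dTop[, t, ] <- alpha[, t] * dctx + dS %*% t(params$att$Wa)
    }
    grads$att <- list(Wa = dWa, wt = dwt, ba = dba, v = dv)
  } else {
    for (i in seq_len(B))
      dTop[i, fw$lens[i], ] <- dctx[i, ]
  }
  eb <- encoder_backward(fw$enc, fw$valid, fw$lens, params, config, dTop)
  grads$layers <- eb$layers
  if (want_dx) grads$dX <- eb$dX
  grads
}

# Pack a list of encoded prefixes into the batch container.
# Each element: list(Z = T x F matrix, trigger = numeric, grid = times).
pack_batch <- function(prefixes) {
  B <- length(prefixes)
  lens <- vapply(prefixes, function(p) nrow(p$Z), 0L)
  Fdim <- ncol(prefixes[[1]]$Z)
  Tmax <- max(lens)
  X <- array(0, c(B, Tmax, Fdim))
  tau <- matrix(0, B, Tmax)
  for (i in seq_len(B)) {
    L <- lens[i]
    X[i, 1:L, ] <- prefixes[[i]]$Z
    tau[i, 1:L] <- prefixes[[i]]$trigger - prefixes[[i]]$grid
  }
  list(X = X, lens = lens, tau = tau)
}
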