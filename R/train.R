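# Training: balanced sampling for static tasks, class-weighted loss for
# dynamic tasks, Adam with weight decay, early stopping on validation
# AUPRC.

#' Class-balance factor from label proportions
#'
#' The balance factor is the inverse of the class proportions followed by
#' normalization: `alpha = (1/pi_pos) / (1/pi_pos + 1/pi_neg)`, which
#' simplifies to the negative-class proportion `pi_neg`.
#'
#' @param labels binary label vector (both classes must be present).
#' @return `alpha` in (0, 1).
#' @export
resolve_alpha <- function(labels) {
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L))) stop("labels must be binary")
  n_pos <- sum(labels == 1L); n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L)
    stop("both classes must be present to resolve alpha")
  n_neg / (n_pos + n_neg)
}

#' Class-weighted binary cross-entropy
#'
#' `loss = -[alpha * y * log(p) + (1 - alpha) * (1 - y) * log(1 - p)]`,
#' averaged over the batch. Probabilities at exactly 0 or 1 are clamped at
#' `1e-12` before the logarithm.
#'
#' @param p predicted probabilities in (0, 1).
#' @param y binary labels.
#' @param alpha balance factor in `[0, 1]`; the positive-class weight.
#' @return mean loss (scalar).
#' @export
weighted_bce <- function(p, y, alpha) {
  stopifnot(length(p) == length(y), alpha >= 0, alpha <= 1)
  p <- clamp_prob(p)
  -mean(alpha * y * log(p) + (1 - alpha) * (1 - y) * log(1 - p))
}

#' Balanced minibatches for static tasks
#'
#' Every batch holds exactly `batch_pos` positives (sampled with
#' replacement when the minority class is smaller) and `batch_neg`
#' negatives; within one epoch the majority class is partitioned so every
#' majority example appears at least once.
#'
#' @param examples data.frame with columns including `label`.
#' @param batch_pos,batch_neg per-class counts per batch.
#' @param seed integer seed.
#' @return list of batches, each an integer row-index vector into
#'   `examples`.
#' @export
balanced_batches <- function(examples, batch_pos = 200, batch_neg = 200,
                             seed = 1L) {
  pos <- which(examples$label == 1L)
  neg <- which(examples$label == 0L)
  if (!length(pos) || !length(neg)) stop("both classes must be non-empty")
  set.seed(as.integer(seed))
  maj <- if (length(neg) >= length(pos)) "neg" else "pos"
  maj_idx <- sample(if (maj == "neg") neg else pos)
  maj_size <- if (maj == "neg") batch_neg else batch_pos
  min_idx <- if (maj == "neg") pos else neg
  min_size <- if (maj == "neg") batch_pos else batch_neg
  n_batches <- ceiling(length(maj_idx) / maj_size)
  lapply(seq_len(n_batches), function(k) {
    lo <- (k - 1L) * maj_size + 1L
    hi <- min(length(maj_idx), k * maj_size)
    m <- maj_idx[lo:hi]
    if (length(m) < maj_size) # top up the last partition cell
      m <- c(m, sample(maj_idx, maj_size - length(m),
                       replace = length(maj_idx) < maj_size))
    s <- sample(min_idx, min_size, replace = length(min_idx) < min_size)
    if (maj == "neg") c(s, m) else c(m, s)
  })
}

#' Training configuration
#'
#' @param task a [task_spec()] — decides the imbalance strategy: static
#'   tasks use balanced minibatch sampling with plain cross-entropy,
#'   dynamic tasks use all sampled triggers with the class-weighted loss.
#' @param batch_pos,batch_neg per-class counts for static balanced batches.
#' @param alpha balance factor for the dynamic loss, or `"auto"` (resolved
#'   from the labels trained on before the first step).
#' @param lr Adam learning rate.
#' @param max_epochs,patience early stopping: training stops when
#'   validation AUPRC fails to improve for `patience` consecutive epochs.
#' @param l2_weight weight decay on non-bias parameters.
#' @param batch_size sequences per dynamic-task batch.
#' @param examples_per_epoch cap on dynamic training triggers per epoch
#'   (all positives are kept; negatives are subsampled to fill).
#' @param val_cap cap on validation examples used for early stopping.
#' @param seed integer seed controlling sampling and initialization order.
#' @return object of class `train_config`.
#' @export
train_config <- function(task, batch_pos = 200, batch_neg = 200,
                         alpha = "auto", lr = 5e-3, max_epochs = 30,
                         patience = 5, l2_weight = 1e-5,
                         batch_size = 128L, examples_per_epoch = 4096L,
                         val_cap = 4096L, seed = 1L) {
  stopifnot(inherits(task, "task_spec"), patience >= 1, max_epochs >= 1)
  structure(list(task = task, batch_pos = batch_pos,
                 batch_neg = batch_neg, alpha = alpha, lr = lr,
                 max_epochs = max_epochs, patience = patience,
                 l2_weight = l2_weight, batch_size = as.integer(batch_size),
                 examples_per_epoch = as.integer(examples_per_epoch),
                 val_cap = as.integer(val_cap), seed = as.integer(seed)),
            class = "train_config")
}

# -- Adam with decoupled-ish L2 (decay added to the gradient) --------------

tree_leaves <- function(x, path = character(0)) {
  if (is.numeric(x)) return(stats::setNames(list(x),
                                            paste(path, collapse = ".")))
  if (is.null(x)) return(list())
  out <- list()
  for (nm in names(x))
    out <- c(out, tree_leaves(x[[nm]], c(path, nm)))
  out
}

# walk params/grads in lockstep, applying Adam in place
adam_update <- function(params, grads, state, lr, step, l2) {
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  walk <- function(p, g, m, v, nm) {
    if (is.numeric(p)) {
      if (!(nm %in% c("b", "ba"))) g <- g + l2 * p
      m <- b1 * m + (1 - b1) * g
      v <- b2 * v + (1 - b2) * g^2
      mh <- m / (1 - b1^step)
      vh <- v / (1 - b2^step)
      list(p = p - lr * mh / (sqrt(vh) + eps), m = m, v = v)
    } else if (is.null(p)) {
      list(p = NULL, m = NULL, v = NULL)
    } else {
      pm <- p; mm <- m; vv <- v
      for (k in names(p)) {
        r <- walk(p[[k]], g[[k]], m[[k]], v[[k]], k)
        pm[[k]] <- r$p; mm[[k]] <- r$m; vv[[k]] <- r$v
      }
      list(p = pm, m = mm, v = vv)
    }
  }
  walk(params, grads, state$m, state$v, "")
}

zeros_like <- function(x) {
  if (is.numeric(x)) return(x * 0)
  if (is.null(x)) return(NULL)
  lapply(x, zeros_like)
}

# -- the fitting function --------------------------------------------------

#' Fit a TBAL or baseline LSTM risk model
#'
#' The central model-fitting entry point. `examples` are labeled
#' (stay, trigger) pairs from [make_static_labels()] or
#' [make_dynamic_labels()] with a `split` column; training uses the
#' `train` rows, early stopping watches AUPRC on the `val` rows, and the
#' parameters from the best validation epoch are returned.
#'
#' @param examples data.frame `stay_id`, `trigger_h`, `label`, `split`.
#' @param encoded named list of `encoded_stay` objects (all stays
#'   referenced by `examples`).
#' @param config a [tbal_config()].
#' @param train_cfg a [train_config()].
#' @param stats optional [fit_normalization()] statistics stored in the
#'   returned object (makes the fit a self-describing checkpoint).
#' @param verbose print per-epoch progress.
#' @return object of class `tbal` with elements `params`, `config`,
#'   `train_cfg`, `alpha`, `history` (per-epoch losses and validation
#'   AUPRC), `best_epoch`, `feature_names`, `parent_var`, `stats`.
#' @export
tbal_fit <- function(examples, encoded, config, train_cfg, stats = NULL,
                     verbose = FALSE) {
  stopifnot(inherits(config, "tbal_config"),
            inherits(train_cfg, "train_config"))
  miss <- setdiff(unique(examples$stay_id), names(encoded))
  if (length(miss))
    stop("examples reference stays without encodings: ",
         paste(utils::head(miss, 5), collapse = ", "))
  fn <- encoded[[1]]$feature_names
  if (length(fn) != config$input_dim)
    stop("config input_dim (", config$input_dim,
         ") does not match encoded feature count (", length(fn), ")")
  tr <- examples[examples$split == "train", , drop = FALSE]
  va <- examples[examples$split == "val", , drop = FALSE]
  if (!nrow(tr)) stop("no training examples")
  # guard: patient-grouped splits must not share stays
  if (length(intersect(tr$stay_id, va$stay_id)))
    stop("train and val splits share stays (patient leakage)")
  dynamic <- train_cfg$task$kind == "dynamic"

  params <- init_params(config)
  state <- list(m = zeros_like(params), v = zeros_like(params))
  step <- 0L
  best <- list(auprc = -Inf, params = params, epoch = 0L)
  bad_epochs <- 0L
  history <- data.frame()
  alpha_used <- NA_real_

  # fixed validation subsample (all positives, capped negatives)
  set.seed(derive_seed(train_cfg$seed, "val-subsample"))
  if (nrow(va) > train_cfg$val_cap) {
    vp <- which(va$label == 1L); vn <- which(va$label == 0L)
    keep_n <- sample(vn, max(0L, train_cfg$val_cap - length(vp)))
    va <- va[sort(c(vp, keep_n)), , drop = FALSE]
  }

  for (epoch in seq_len(train_cfg$max_epochs)) {
    set.seed(derive_seed(train_cfg$seed, paste0("epoch", epoch)))
    if (dynamic) {
      pos <- which(tr$label == 1L); neg <- which(tr$label == 0L)
      if (!length(pos) || !length(neg))
        stop("dynamic training needs both classes")
      n_neg_epoch <- min(length(neg),
                         max(length(pos),
                             train_cfg$examples_per_epoch - length(pos)))
      idx <- c(pos, sample(neg, n_neg_epoch))
      ep <- tr[idx, , drop = FALSE]
      alpha_used <- if (identical(train_cfg$alpha, "auto"))
        resolve_alpha(ep$label) else train_cfg$alpha
      # batch by similar prefix length, then shuffle batch order
      ep <- ep[order(ep$trigger_h, sample.int(nrow(ep))), , drop = FALSE]
      nb <- ceiling(nrow(ep) / train_cfg$batch_size)
      batches <- split(seq_len(nrow(ep)),
                       rep(seq_len(nb), each = train_cfg$batch_size,
                           length.out = nrow(ep)))
      batches <- batches[sample.int(nb)]
      batch_rows <- lapply(batches, function(b) ep[b, , drop = FALSE])
    } else {
      bb <- balanced_batches(tr, train_cfg$batch_pos, train_cfg$batch_neg,
                             seed = derive_seed(train_cfg$seed,
                                                paste0("bb", epoch)))
      batch_rows <- lapply(bb, function(b) tr[b, , drop = FALSE])
      alpha_used <- 0.5 # balancing by sampling; loss itself unweighted
    }

    ep_loss <- 0; ep_n <- 0L
    for (bt in batch_rows) {
      prefixes <- lapply(seq_len(nrow(bt)), function(j) {
        enc <- encoded[[bt$stay_id[j]]]
        keep <- enc$grid_h <= bt$trigger_h[j]
        list(Z = enc$Z[keep, , drop = FALSE], trigger = bt$trigger_h[j],
             grid = enc$grid_h[keep])
      })
      pk <- pack_batch(prefixes)
      fw <- model_forward(pk$X, pk$lens, pk$tau, params, config,
                          train = TRUE)
      y <- bt$label
      p <- clamp_prob(fw$p)
      w <- if (dynamic) ifelse(y == 1L, alpha_used, 1 - alpha_used)
           else rep(0.5, length(y))
      loss <- -mean(ifelse(y == 1L, w * log(p), w * log(1 - p)))
      if (!is.finite(loss)) stop("divergence: non-finite training loss")
      dlogit <- w * (fw$p - y) / length(y)
      grads <- model_backward(fw, pk$X, pk$tau, params, config, dlogit)
      step <- step + 1L
      upd <- adam_update(params, grads, state, train_cfg$lr, step,
                         train_cfg$l2_weight)
      params <- upd$p; state <- list(m = upd$m, v = upd$v)
      ep_loss <- ep_loss + loss * length(y); ep_n <- ep_n + length(y)
    }

    val_auprc <- NA_real_
    if (nrow(va) && length(unique(va$label)) == 2L) {
      vp <- predict_examples(va, encoded, params, config)
      val_auprc <- auprc(vp, va$label)
    }
    history <- rbind(history, data.frame(
      epoch = epoch, train_loss = ep_loss / ep_n, val_auprc = val_auprc,
      alpha = alpha_used))
    if (verbose)
      message(sprintf("epoch %d  loss %.4f  val AUPRC %s", epoch,
                      ep_loss / ep_n,
                      ifelse(is.na(val_auprc), "NA",
                             sprintf("%.4f", val_auprc))))
    crit <- if (is.na(val_auprc)) -ep_loss / ep_n else val_auprc
    if (crit > best$auprc + 1e-6) {
      best <- list(auprc = crit, params = params, epoch = epoch)
      bad_epochs <- 0L
    } else {
      bad_epochs <- bad_epochs + 1L
      if (bad_epochs >= train_cfg$patience) break
    }
  }

  structure(list(params = best$params, config = config,
                 train_cfg = train_cfg, alpha = alpha_used,
                 history = history, best_epoch = best$epoch,
                 feature_names = fn,
                 parent_var = encoded[[1]]$parent_var,
                 stats = stats),
            class = "tbal")
}

#' @export
print.tbal <- function(x, ...) {
  print(x$config)
  cat(sprintf("  fitted: %d epoch(s), best epoch %d", nrow(x$history),
              x$best_epoch))
  va <- x$history$val_auprc[x$best_epoch]
  if (length(va) && !is.na(va))
    cat(sprintf(" (validation AUPRC %.3f)", va))
  cat("\n")
  invisible(x)
}

#' @export
summary.tbal <- function(object, ...) {
  cnt <- count_parameters(object$config)
  cat("Time-aware recurrent risk model\n")
  print(object$config)
  cat(sprintf("Parameters: %d\n", as.integer(cnt)))
  bd <- attr(cnt, "breakdown")
  for (nm in names(bd)) cat(sprintf("  %-12s %d\n", nm, bd[[nm]]))
  cat(sprintf("Task: %s; balance factor alpha = %.4f\n",
              object$train_cfg$task$kind, object$alpha))
  cat("Training history (last 5 epochs):\n")
  print(utils::tail(object$history, 5), row.names = FALSE)
  invisible(object)
}

#' @export
coef.tbal <- function(object, ...) object$params

#' @export
plot.tbal <- function(x, ...) {
  h <- x$history
  graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(mfrow = c(1, 1)))
  graphics::plot(h$epoch, h$train_loss, type = "b", xlab = "epoch",
                 ylab = "training loss", main = "Loss", ...)
  if (any(!is.na(h$val_auprc))) {
    graphics::plot(h$epoch, h$val_auprc, type = "b", xlab = "epoch",
                   ylab = "validation AUPRC", main = "Early stopping", ...)
    graphics::abline(v = x$best_epoch, lty = 2)
  }
  invisible(x)
}

#' Predict risks for labeled examples with a fitted model
#'
#' @param object a fitted [tbal_fit()] object.
#' @param encoded named list of `encoded_stay` objects.
#' @param examples data.frame `stay_id`, `trigger_h` (labels optional).
#' @param ... unused.
#' @return `examples` with a `risk` column appended.
#' @export
predict.tbal <- function(object, encoded, examples, ...) {
  if (!identical(encoded[[1]]$feature_names, object$feature_names))
    stop("feature layout of the encodings does not match the fit")
  examples$risk <- predict_examples(examples, encoded, object$params,
                                    object$config)
  examples
}

#' Response residuals for labeled examples
#' @param object a fitted [tbal_fit()] object.
#' @param encoded named list of `encoded_stay` objects.
#' @param examples labeled examples (`label` column required).
#' @param ... unused.
#' @return numeric vector `label - risk`.
#' @export
residuals.tbal <- function(object, encoded, examples, ...) {
  pr <- predict.tbal(object, encoded, examples)
  pr$label - pr$risk
}
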