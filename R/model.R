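# User-facing forward passes over encoded stays.

#' Risk prediction for one encoded prefix
#'
#' Runs the network over the prefix rows whose grid time is at most
#' `trigger_h` — never over later rows, so a prediction at `t` is a pure
#' function of data up to `t`.
#'
#' @param encoded an `encoded_stay` from [encode_stay()].
#' @param trigger_h prediction time point (hours from ICU admission); must
#'   be at least the first grid time.
#' @param params model parameters (from [init_params()] or a fitted
#'   [tbal_fit()] object's `$params`).
#' @param config the [tbal_config()].
#' @return list of class `model_output`: `risk` in (0,1),
#'   `attention_weights` (non-negative, summing to 1 over the prefix;
#'   `NULL` for the baseline LSTM), `prefix_len`.
#' @export
tbal_forward <- function(encoded, trigger_h, params, config) {
  keep <- encoded$grid_h <= trigger_h
  if (!any(keep)) stop("prefix shorter than 1 step at trigger ", trigger_h)
  Z <- encoded$Z[keep, , drop = FALSE]
  if (anyNA(Z) || any(!is.finite(Z)))
    stop("non-finite values in encoded input (imputation contract violated)")
  pk <- pack_batch(list(list(Z = Z, trigger = trigger_h,
                             grid = encoded$grid_h[keep])))
  fw <- model_forward(pk$X, pk$lens, pk$tau, params, config)
  structure(list(risk = unname(fw$p[1]),
                 attention_weights = if (!is.null(fw$alpha))
                   fw$alpha[1, seq_len(pk$lens[1])],
                 prefix_len = pk$lens[1]),
            class = "model_output")
}

#' Dynamic (multi-trigger) risk predictions for one stay
#'
#' Each trigger re-encodes its own prefix; the result at trigger `t` equals
#' [tbal_forward()] on the prefix ending at `t`, so no future information
#' leaks into earlier predictions.
#'
#' @param encoded an `encoded_stay`.
#' @param triggers grid times at which to predict (must lie on the grid).
#' @param params,config as in [tbal_forward()].
#' @return data.frame `trigger_h`, `risk`; attention weights per trigger in
#'   attribute `"attention"`.
#' @export
tbal_forward_dynamic <- function(encoded, triggers, params, config) {
  off <- setdiff(triggers, encoded$grid_h)
  if (length(off))
    stop("trigger(s) not on the grid: ", paste(off, collapse = ", "))
  prefixes <- lapply(triggers, function(tr) {
    keep <- encoded$grid_h <= tr
    list(Z = encoded$Z[keep, , drop = FALSE], trigger = tr,
         grid = encoded$grid_h[keep])
  })
  pk <- pack_batch(prefixes)
  fw <- model_forward(pk$X, pk$lens, pk$tau, params, config)
  out <- data.frame(trigger_h = triggers, risk = unname(fw$p))
  if (!is.null(fw$alpha))
    attr(out, "attention") <- lapply(seq_along(triggers), function(i)
      fw$alpha[i, seq_len(pk$lens[i])])
  out
}

# Batched risk over many (stay, trigger) examples; used by fit/predict.
# `examples`: data.frame stay_id, trigger_h. Returns numeric risks.
predict_examples <- function(examples, encoded_by_stay, params, config,
                             batch_size = 256L) {
  n <- nrow(examples)
  out <- numeric(n)
  ord <- order(examples$trigger_h) # similar lengths batch together
  for (start in seq(1L, n, by = batch_size)) {
    idx <- ord[start:min(n, start + batch_size - 1L)]
    prefixes <- lapply(idx, function(j) {
      enc <- encoded_by_stay[[examples$stay_id[j]]]
      keep <- enc$grid_h <= examples$trigger_h[j]
      list(Z = enc$Z[keep, , drop = FALSE],
           trigger = examples$trigger_h[j], grid = enc$grid_h[keep])
    })
    pk <- pack_batch(prefixes)
    fw <- model_forward(pk$X, pk$lens, pk$tau, params, config)
    out[idx] <- fw$p
  }
  out
}

#' Save / load a self-describing model checkpoint
#'
#' The checkpoint bundles the architecture configuration, the weights, the
#' training-set normalization statistics and the feature layout, so a model
#' can be reloaded and applied to new cohorts without the training data.
#'
#' @param fit a fitted [tbal_fit()] object.
#' @param path file path (`.rds`).
#' @export
save_checkpoint <- function(fit, path) {
  stopifnot(inherits(fit, "tbal"))
  saveRDS(fit, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  fit <- readRDS(path)
  stopifnot(inherits(fit, "tbal"))
  fit
}
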