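# Integrated-gradients attribution over sequence inputs.

#' Integrated gradients along a straight-line path
#'
#' Computes `IG_i = (x_i - x'_i) * (1/m) * sum_{k=1..m}
#' dF(x' + (k/m) (x - x')) / dx_i` — the right-Riemann approximation of the
#' path integral from the baseline `x'` to the input.
#'
#' @param model_fn function taking an input array and returning
#'   `list(value = scalar, grad = same-shape array)` — the model output and
#'   its gradient with respect to the input.
#' @param x input array.
#' @param baseline baseline array `x'`; default all zeros (the natural
#'   reference for z-scored inputs).
#' @param m_steps number of Riemann steps.
#' @return list: `IG` (same shape as `x`), `completeness_gap`
#'   (`|sum(IG) - (F(x) - F(x'))|`), `Fx`, `Fx0`, `m_steps`.
#' @export
integrated_gradients <- function(model_fn, x, baseline = NULL,
                                 m_steps = 50) {
  baseline <- baseline %||% (x * 0)
  stopifnot(identical(dim(x) %||% length(x),
                      dim(baseline) %||% length(baseline)),
            m_steps >= 1)
  diff_x <- x - baseline
  gsum <- x * 0
  for (k in seq_len(m_steps)) {
    r <- model_fn(baseline + (k / m_steps) * diff_x)
    if (any(!is.finite(r$grad)))
      stop("non-finite gradient at path step ", k)
    gsum <- gsum + r$grad
  }
  IG <- diff_x * gsum / m_steps
  Fx <- model_fn(x)$value
  Fx0 <- model_fn(baseline)$value
  list(IG = IG, completeness_gap = abs(sum(IG) - (Fx - Fx0)),
       Fx = Fx, Fx0 = Fx0, m_steps = m_steps)
}

# baseline matrix for an encoded prefix: all zeros, or zeros with the
# "missing" one-hot channels set (sensitivity-analysis alternative)
ig_baseline_matrix <- function(Z, feature_names, kind) {
  b <- Z * 0
  if (kind == "missing") {
    mcols <- grep("=missing$", feature_names)
    if (length(mcols)) b[, mcols] <- 1
  }
  b
}

#' Integrated-gradients attribution map for one prediction
#'
#' Attributions are computed on the encoded (z-scored / one-hot) prefix the
#' model actually saw at the trigger; the `m_steps` path points are
#' evaluated in one batched pass. The model output attributed is the risk
#' probability.
#'
#' @param object a fitted [tbal_fit()] object.
#' @param encoded an `encoded_stay`.
#' @param trigger_h prediction time point.
#' @param m_steps Riemann steps (default 50).
#' @param baseline `"zero"` (default) or `"missing"` (zeros with the
#'   categorical `"missing"` one-hot channels lit), or a custom matrix of
#'   the prefix shape.
#' @return object of class `attribution_map`: `stay_id`, `trigger_h`, `IG`
#'   (T x F matrix on the encoded-input scale), `risk`,
#'   `completeness_gap`, `m_steps`, `feature_names`, `grid_h`.
#' @export
attribute_stay <- function(object, encoded, trigger_h, m_steps = 50,
                           baseline = "zero") {
  stopifnot(inherits(object, "tbal"))
  keep <- encoded$grid_h <= trigger_h
  if (!any(keep)) stop("prefix shorter than 1 step at trigger ", trigger_h)
  Z <- encoded$Z[keep, , drop = FALSE]
  grid <- encoded$grid_h[keep]
  b <- if (is.matrix(baseline)) baseline
       else ig_baseline_matrix(Z, encoded$feature_names,
                               match.arg(baseline, c("zero", "missing")))
  diff_x <- Z - b
  T_ <- nrow(Z); Fd <- ncol(Z)
  # all m path points share length and tau: one batched forward/backward
  X <- array(0, c(m_steps, T_, Fd))
  for (k in seq_len(m_steps))
    X[k, , ] <- b + (k / m_steps) * diff_x
  tau <- matrix(trigger_h - grid, m_steps, T_, byrow = TRUE)
  lens <- rep(T_, m_steps)
  fw <- model_forward(X, lens, tau, object$params, object$config)
  dlogit <- fw$p * (1 - fw$p) # dF/dlogit for F = risk probability
  gr <- model_backward(fw, X, tau, object$params, object$config, dlogit,
                       want_dx = TRUE)
  if (any(!is.finite(gr$dX)))
    stop("non-finite gradient along the attribution path")
  gmean <- apply(gr$dX, c(2, 3), mean)
  IG <- diff_x * gmean
  # endpoint evaluations for the completeness gap
  Xe <- array(0, c(2L, T_, Fd)); Xe[1, , ] <- Z; Xe[2, , ] <- b
  fe <- model_forward(Xe, rep(T_, 2L), tau[1:2, , drop = FALSE],
                      object$params, object$config)
  structure(list(stay_id = encoded$stay_id, trigger_h = trigger_h,
                 IG = IG, risk = unname(fe$p[1]),
                 delta_risk = unname(fe$p[1] - fe$p[2]),
                 completeness_gap = abs(sum(IG) - (fe$p[1] - fe$p[2])),
                 m_steps = m_steps,
                 feature_names = encoded$feature_names, grid_h = grid),
            class = "attribution_map")
}

#' @export
print.attribution_map <- function(x, ...) {
  cat(sprintf(
    "<attribution_map> stay %s @ %g h: risk %.3f, %d x %d scores, gap %.2e (m = %d)\n",
    x$stay_id, x$trigger_h, x$risk, nrow(x$IG), ncol(x$IG),
    x$completeness_gap, x$m_steps))
  invisible(x)
}

#' Population feature ranking by mean absolute attribution
#'
#' The per-channel score is the mean of `|IG|` over all maps and all
#' prefix timesteps; one-hot levels, mask channels and interval channels
#' are then attributed to their parent clinical variable by summing member
#' scores. Sorted descending with deterministic (lexicographic) ties.
#'
#' @param maps list of `attribution_map` objects sharing a feature layout.
#' @param parent_var named character vector mapping feature name to owning
#'   variable (from an `encoded_stay`).
#' @return data.frame `variable`, `score`, `rank`.
#' @export
rank_features <- function(maps, parent_var) {
  stopifnot(length(maps) >= 1)
  fn <- maps[[1]]$feature_names
  tot <- numeric(length(fn)); names(tot) <- fn
  rows <- 0L
  for (m in maps) {
    if (!identical(m$feature_names, fn))
      stop("attribution maps have mismatched feature layouts")
    tot <- tot + colSums(abs(m$IG))
    rows <- rows + nrow(m$IG)
  }
  per_feature <- tot / rows
  grp <- tapply(per_feature, parent_var[fn], sum)
  out <- data.frame(variable = names(grp), score = as.numeric(grp),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$score, out$variable), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Per-stay interpretation report
#'
#' Three aligned tables for one stay: the predicted risk trajectory over
#' the triggers, the per-trigger attribution (IG summed over the prefix)
#' of the top-k channels, and the normalized values of those channels over
#' time — the ingredients of a bedside case review.
#'
#' @param maps list of `attribution_map` objects for one stay, trigger
#'   order ascending.
#' @param encoded the stay's `encoded_stay`.
#' @param top_k number of channels to report (clipped to F with a warning
#'   when larger).
#' @return object of class `stay_report`: `risk` (trigger_h, risk),
#'   `attributions` (top-k channel x trigger matrix), `values` (top-k
#'   channel x grid-time matrix), `top_features`.
#' @export
stay_report <- function(maps, encoded, top_k = 20) {
  stopifnot(length(maps) >= 1)
  ids <- unique(vapply(maps, `[[`, "", "stay_id"))
  if (length(ids) != 1L) stop("maps must belong to a single stay")
  trig <- vapply(maps, `[[`, 0, "trigger_h")
  stopifnot(!is.unsorted(trig))
  fn <- encoded$feature_names
  if (top_k > length(fn)) {
    warning("top_k clipped to the number of channels (", length(fn), ")")
    top_k <- length(fn)
  }
  per_feature <- rowMeans(vapply(maps, function(m)
    colSums(abs(m$IG)) / nrow(m$IG), numeric(length(fn))))
  ord <- order(-per_feature, fn)
  top <- fn[ord[seq_len(top_k)]]
  att <- vapply(maps, function(m) colSums(m$IG[, top, drop = FALSE]),
                numeric(top_k))
  att <- matrix(att, nrow = top_k,
                dimnames = list(top, paste0("t", trig)))
  vals <- t(encoded$Z[, top, drop = FALSE])
  colnames(vals) <- paste0("t", encoded$grid_h)
  structure(list(
    stay_id = ids, risk = data.frame(
      trigger_h = trig, risk = vapply(maps, `[[`, 0, "risk")),
    attributions = att, values = vals, top_features = top),
    class = "stay_report")
}

#' @export
print.stay_report <- function(x, ...) {
  cat(sprintf("<stay_report> stay %s: %d triggers, top %d channels\n",
              x$stay_id, nrow(x$risk), length(x$top_features)))
  cat("  risk range:", sprintf("%.3f-%.3f", min(x$risk$risk),
                               max(x$risk$risk)), "\n")
  cat("  top channels:", paste(utils::head(x$top_features, 5),
                               collapse = ", "), "...\n")
  invisible(x)
}

#' Write a stay report as delimited text
#' @param report a [stay_report()].
#' @param dir output directory.
#' @export
write_stay_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$risk,
                   file.path(dir, "risk_trajectory.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(report$attributions),
                   file.path(dir, "attributions.csv"))
  utils::write.csv(as.data.frame(report$values),
                   file.path(dir, "feature_values.csv"))
  invisible(dir)
}
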