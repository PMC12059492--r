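# Evaluation: ranking and thresholded metrics, cluster-bootstrap CIs,
# temporal and subgroup analyses, cross-cohort transfer harness.

#' Thresholded confusion-matrix metrics
#'
#' `score >= threshold` predicts positive. `accuracy = (TP + TN) / N`,
#' `recall = TP / (TP + FN)`, `precision = TP / (TP + FP)`,
#' `f1 = 2 * precision * recall / (precision + recall)`. A zero
#' denominator yields `NA` (undefined), never 0.
#'
#' @param scores numeric scores.
#' @param labels binary labels.
#' @param threshold decision threshold (default 0.5).
#' @return named numeric vector `accuracy`, `recall`, `precision`, `f1`.
#' @export
confusion_metrics <- function(scores, labels, threshold = 0.5) {
  stopifnot(length(scores) == length(labels))
  pred <- as.integer(scores >= threshold)
  y <- as.integer(labels)
  tp <- sum(pred == 1L & y == 1L); tn <- sum(pred == 0L & y == 0L)
  fp <- sum(pred == 1L & y == 0L); fn <- sum(pred == 0L & y == 1L)
  acc <- (tp + tn) / length(y)
  rec <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  f1 <- if (!is.na(rec) && !is.na(prec) && (prec + rec) > 0)
    2 * prec * rec / (prec + rec) else NA_real_
  c(accuracy = acc, recall = rec, precision = prec, f1 = f1)
}

#' Area under the ROC curve
#'
#' Mann-Whitney concordance probability with ties counted one half
#' (equivalent to trapezoidal ROC integration), computed from ranks.
#'
#' @param scores numeric scores.
#' @param labels binary labels (both classes required; otherwise `NA`).
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(scores, labels) {
  y <- as.integer(labels)
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve
#'
#' Average-precision formulation: walking thresholds downward through the
#' distinct score values, each increment of recall contributes the
#' precision at that threshold
#' (`sum over thresholds of (R_k - R_[k-1]) * P_k`).
#'
#' @param scores numeric scores.
#' @param labels binary labels (positives required; otherwise `NA`).
#' @return AUPRC in `(0, 1]`.
#' @export
auprc <- function(scores, labels) {
  y <- as.integer(labels)
  n1 <- sum(y == 1L)
  if (n1 == 0L) return(NA_real_)
  ord <- order(scores, decreasing = TRUE)
  y <- y[ord]; s <- scores[ord]
  tp <- cumsum(y)
  fp <- cumsum(1 - y)
  last <- !duplicated(s, fromLast = TRUE) # threshold boundaries
  tp <- tp[last]; fp <- fp[last]
  prec <- tp / (tp + fp)
  rec <- tp / n1
  sum(diff(c(0, rec)) * prec)
}

#' Cluster-bootstrap confidence interval for a metric
#'
#' Resamples groups (stays) with replacement — timepoints within a stay
#' are dependent, so whole stays are the exchangeable unit — recomputes the
#' metric on each replicate and returns the 2.5/97.5 percentiles.
#' Replicates where the metric is undefined (single class) are dropped and
#' counted.
#'
#' @param scores,labels pooled predictions and labels.
#' @param group_ids cluster identifier per element (stay id); independent
#'   examples may simply use distinct ids (ordinary case bootstrap).
#' @param metric_fn `function(scores, labels) -> scalar`.
#' @param n_boot bootstrap replicates (1000 by default).
#' @param seed integer seed.
#' @return named numeric `lower`, `upper`; attribute `"dropped"` counts
#'   degenerate replicates.
#' @export
bootstrap_ci <- function(scores, labels, group_ids, metric_fn,
                         n_boot = 1000, seed = 1L) {
  stopifnot(n_boot >= 2, length(scores) == length(labels),
            length(group_ids) == length(scores))
  idx_by_group <- split(seq_along(scores), group_ids)
  groups <- names(idx_by_group)
  set.seed(as.integer(seed))
  vals <- numeric(n_boot)
  for (b in seq_len(n_boot)) {
    g <- sample(groups, length(groups), replace = TRUE)
    idx <- unlist(idx_by_group[g], use.names = FALSE)
    vals[b] <- metric_fn(scores[idx], labels[idx])
  }
  dropped <- sum(is.na(vals))
  vals <- vals[!is.na(vals)]
  if (!length(vals)) {
    ci <- c(lower = NA_real_, upper = NA_real_)
  } else {
    q <- stats::quantile(vals, c(0.025, 0.975), names = FALSE, type = 7)
    ci <- c(lower = q[1], upper = q[2])
  }
  attr(ci, "dropped") <- dropped
  ci
}

#' Full metric report with bootstrap confidence intervals
#'
#' @param scores,labels pooled predictions and labels.
#' @param group_ids cluster id per element (see [bootstrap_ci()]).
#' @param threshold decision threshold for the confusion metrics.
#' @param n_boot bootstrap replicates; 0 skips the intervals.
#' @param seed integer seed.
#' @return data.frame with one row per metric: `metric`, `value`,
#'   `lower`, `upper`, plus counts `n_pos`/`n_neg`/`threshold` in
#'   attributes.
#' @export
metric_report <- function(scores, labels, group_ids = seq_along(scores),
                          threshold = 0.5, n_boot = 1000, seed = 1L) {
  fns <- list(
    auroc = auroc, auprc = auprc,
    accuracy = function(s, y) confusion_metrics(s, y, threshold)[["accuracy"]],
    recall = function(s, y) confusion_metrics(s, y, threshold)[["recall"]],
    precision = function(s, y)
      confusion_metrics(s, y, threshold)[["precision"]],
    f1 = function(s, y) confusion_metrics(s, y, threshold)[["f1"]])
  rows <- lapply(names(fns), function(nm) {
    v <- fns[[nm]](scores, labels)
    if (n_boot > 0) {
      ci <- bootstrap_ci(scores, labels, group_ids, fns[[nm]],
                         n_boot = n_boot,
                         seed = derive_seed(seed, paste0("ci-", nm)))
    } else ci <- c(lower = NA_real_, upper = NA_real_)
    data.frame(metric = nm, value = v, lower = ci[["lower"]],
               upper = ci[["upper"]], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "n_pos") <- sum(labels == 1)
  attr(out, "n_neg") <- sum(labels == 0)
  attr(out, "threshold") <- threshold
  out
}

#' Performance at successive trigger times
#'
#' Stratifies dynamic predictions by trigger time (4-hourly marks by
#' default) and reports the ranking metrics within each stratum; strata
#' with a single class are flagged undefined rather than dropped.
#'
#' @param predictions data.frame `stay_id`, `trigger_h`, `risk`, `label`.
#' @param stride report stride in hours.
#' @param n_boot bootstrap replicates per stratum (0 = none).
#' @param seed integer seed.
#' @return data.frame `trigger_h`, `n`, `n_pos`, `auroc`, `auprc`,
#'   bootstrap bounds, `defined`.
#' @export
temporal_curve <- function(predictions, stride = 4, n_boot = 0,
                           seed = 1L) {
  pr <- predictions[predictions$trigger_h %% stride == 0, , drop = FALSE]
  rows <- lapply(sort(unique(pr$trigger_h)), function(tt) {
    p <- pr[pr$trigger_h == tt, , drop = FALSE]
    defined <- length(unique(p$label)) == 2L
    a <- if (defined) auroc(p$risk, p$label) else NA_real_
    ap <- if (defined) auprc(p$risk, p$label) else NA_real_
    lo <- hi <- NA_real_
    if (defined && n_boot > 0) {
      ci <- bootstrap_ci(p$risk, p$label, p$stay_id, auroc, n_boot,
                         seed = derive_seed(seed, paste0("t", tt)))
      lo <- ci[["lower"]]; hi <- ci[["upper"]]
    }
    data.frame(trigger_h = tt, n = nrow(p), n_pos = sum(p$label),
               auroc = a, auprc = ap, auroc_lower = lo,
               auroc_upper = hi, defined = defined)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Subgroup performance analysis
#'
#' Metrics with cluster-bootstrap intervals per stratum of age
#' (< 65 vs >= 65 years), sex and race. Empty strata are omitted with a
#' note attribute.
#'
#' @param predictions data.frame `stay_id`, `risk`, `label`.
#' @param meta stays table (`stay_id`, `age_years`, `sex`, `race`).
#' @param n_boot bootstrap replicates.
#' @param seed integer seed.
#' @return data.frame `stratum`, `group`, `n`, `n_pos`, `auroc`, `auprc`
#'   with bootstrap bounds.
#' @export
subgroup_report <- function(predictions, meta, n_boot = 200, seed = 1L) {
  m <- meta[match(predictions$stay_id, meta$stay_id), , drop = FALSE]
  strata <- list(
    age = ifelse(m$age_years >= 65, ">=65", "<65"),
    sex = m$sex,
    race = m$race)
  rows <- list(); omitted <- character(0)
  for (snm in names(strata)) {
    for (g in sort(unique(strata[[snm]]))) {
      sel <- strata[[snm]] == g
      if (!any(sel)) { omitted <- c(omitted, paste(snm, g)); next }
      p <- predictions[sel, , drop = FALSE]
      defined <- length(unique(p$label)) == 2L
      a <- if (defined) auroc(p$risk, p$label) else NA_real_
      ap <- if (defined) auprc(p$risk, p$label) else NA_real_
      lo <- hi <- NA_real_
      if (defined && n_boot > 0) {
        ci <- bootstrap_ci(p$risk, p$label, p$stay_id, auroc, n_boot,
                           seed = derive_seed(seed, paste(snm, g)))
        lo <- ci[["lower"]]; hi <- ci[["upper"]]
      }
      rows[[length(rows) + 1L]] <- data.frame(
        stratum = snm, group = g, n = nrow(p), n_pos = sum(p$label),
        auroc = a, auprc = ap, auroc_lower = lo, auroc_upper = hi,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "omitted") <- omitted
  out
}

#' Cross-cohort transfer harness
#'
#' Trains a model on cohort A restricted at training time to the common
#' variable set (a model trained on the full feature set cannot consume a
#' reduced one), then evaluates it both on A's held-out test split and on
#' cohort B, applying A's normalization statistics to B's data throughout.
#'
#' @param cohort_a,cohort_b [icu_cohort()] objects (already
#'   eligibility-filtered).
#' @param common_vars variables present in both dictionaries.
#' @param task a [task_spec()].
#' @param config a [tbal_config()] (`input_dim` is overridden to match
#'   the common-variable encoding).
#' @param train_cfg a [train_config()].
#' @param split_seed seed for cohort A's patient split.
#' @return list: `in_cohort` / `transfer` metric reports, the fitted
#'   `model`, and the pooled prediction tables.
#' @export
cross_cohort <- function(cohort_a, cohort_b, common_vars, task, config,
                         train_cfg, split_seed = 1L) {
  if (!length(common_vars)) stop("common_vars must be non-empty")
  for (co in list(cohort_a, cohort_b)) {
    miss <- setdiff(common_vars, names(co$dictionary))
    if (length(miss))
      stop("common_vars missing from a cohort dictionary: ",
           paste(miss, collapse = ", "))
  }
  split_a <- split_by_patient(cohort_a, seed = split_seed)
  ss <- attr(split_a, "stay_split")
  prep_a <- preprocess_cohort(cohort_a,
                              train_ids = names(ss)[ss == "train"],
                              keep_vars = common_vars)
  ex_a <- build_examples(cohort_a, task, prep_a, ss)
  fit <- tbal_fit(ex_a, prep_a$encoded,
                  tbal_config(input_dim =
                                length(prep_a$encoded[[1]]$feature_names),
                              hidden_size = config$hidden_size,
                              num_layers = config$num_layers,
                              attention_dim = config$attention_dim,
                              dropout = config$dropout,
                              l2_weight = config$l2_weight,
                              bidirectional = config$bidirectional,
                              time_aware = config$time_aware,
                              seed = config$seed),
                  train_cfg, stats = prep_a$stats)
  te_a <- ex_a[ex_a$split == "test", , drop = FALSE]
  pr_a <- predict.tbal(fit, prep_a$encoded, te_a)
  # cohort B preprocessed with cohort A's statistics
  prep_b <- preprocess_cohort(cohort_b, stats = prep_a$stats,
                              keep_vars = common_vars)
  ex_b <- build_examples(cohort_b, task, prep_b,
                         split = NULL)
  pr_b <- predict.tbal(fit, prep_b$encoded, ex_b)
  list(in_cohort = metric_report(pr_a$risk, pr_a$label, pr_a$stay_id,
                                 n_boot = 0),
       transfer = metric_report(pr_b$risk, pr_b$label, pr_b$stay_id,
                                n_boot = 0),
       model = fit, predictions_a = pr_a, predictions_b = pr_b)
}

#' Labeled examples for a cohort under a task
#'
#' Builds the task's labeled (stay, trigger) examples from the
#' preprocessed grids and attaches the split assignment (every example is
#' marked `"test"` when `split` is `NULL`, the convention for external
#' validation cohorts). Static examples whose trigger precedes the first
#' observed grid row are dropped — the model would have no prefix to read.
#'
#' @param cohort an [icu_cohort()].
#' @param task a [task_spec()].
#' @param prep a [preprocess_cohort()] result.
#' @param split named character vector mapping stay id to split, or
#'   `NULL`.
#' @return data.frame `stay_id`, `trigger_h`, `label`, `prefix_end_h`,
#'   `split`.
#' @export
build_examples <- function(cohort, task, prep, split) {
  ex <- if (task$kind == "static") {
    make_static_labels(cohort, task)
  } else {
    grids <- lapply(prep$encoded, `[[`, "grid_h")
    make_dynamic_labels(cohort, task, grids)
  }
  ex <- ex[ex$stay_id %in% names(prep$encoded), , drop = FALSE]
  if (task$kind == "static") {
    # the trigger must be coverable by the grid: at least one row at or
    # before the trigger
    first_row <- vapply(prep$encoded[ex$stay_id],
                        function(e) e$grid_h[1], 0)
    ex <- ex[first_row <= ex$trigger_h, , drop = FALSE]
  }
  ex$split <- if (is.null(split)) "test" else unname(split[ex$stay_id])
  ex
}
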