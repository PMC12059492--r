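# Prediction task definitions, labels, and patient-grouped splits.

#' Define a prediction task
#'
#' Static tasks issue one prediction per stay at a fixed trigger time
#' (hour 12 after ICU admission by default); the mortality label window is
#' `(trigger_h, trigger_h + horizon_h]` hours, with `horizon_h = Inf`
#' meaning in-hospital mortality. Dynamic tasks re-issue a prediction at
#' each trigger on the grid for a rolling window (death within the next
#' `horizon_h = 24` hours).
#'
#' @param kind `"static"` or `"dynamic"`.
#' @param trigger_h trigger time (static, default 12) or trigger stride in
#'   hours (dynamic: 1 for training, 4 for evaluation reporting).
#' @param horizon_h label window length after the trigger; `Inf` =
#'   in-hospital mortality (static only).
#' @param outcome `"mortality"` or `"los_gt"` (ICU length of stay greater
#'   than `los_threshold_h`).
#' @param los_threshold_h threshold for the `los_gt` outcome (48 h).
#' @return object of class `task_spec`.
#' @export
task_spec <- function(kind = c("static", "dynamic"), trigger_h = NULL,
                      horizon_h = NULL, outcome = c("mortality", "los_gt"),
                      los_threshold_h = 48) {
  kind <- match.arg(kind)
  outcome <- match.arg(outcome)
  if (kind == "static") {
    trigger_h <- trigger_h %||% 12
    horizon_h <- horizon_h %||% Inf
  } else {
    trigger_h <- trigger_h %||% 1
    horizon_h <- horizon_h %||% 24
    if (!is.finite(horizon_h)) stop("dynamic tasks need a finite horizon")
    if (outcome != "mortality")
      stop("dynamic tasks are defined for the mortality outcome")
  }
  stopifnot(horizon_h > 0, trigger_h > 0)
  structure(list(kind = kind, trigger_h = trigger_h,
                 horizon_h = horizon_h, outcome = outcome,
                 los_threshold_h = los_threshold_h),
            class = "task_spec")
}

#' @export
print.task_spec <- function(x, ...) {
  if (x$kind == "static")
    cat(sprintf("<task_spec> static @ %g h, horizon %s h, outcome %s\n",
                x$trigger_h, format(x$horizon_h), x$outcome))
  else
    cat(sprintf(
      "<task_spec> dynamic, stride %g h, next-%g-hour mortality\n",
      x$trigger_h, x$horizon_h))
  invisible(x)
}

#' Static task labels
#'
#' Mortality: label 1 iff `death_time_h` falls in
#' `(trigger_h, trigger_h + horizon_h]`; the in-hospital variant
#' (`horizon_h = Inf`) labels 1 iff death occurs any time after the
#' trigger. Stays whose death precedes the trigger are excluded from the
#' example set. Length-of-stay: label 1 iff `icu_los_h` exceeds the
#' threshold.
#'
#' @param cohort an eligibility-filtered [icu_cohort()].
#' @param task a static [task_spec()].
#' @return data.frame of labeled examples: `stay_id`, `trigger_h`,
#'   `label`, `prefix_end_h`.
#' @export
make_static_labels <- function(cohort, task) {
  stopifnot(inherits(task, "task_spec"), task$kind == "static")
  st <- cohort$stays
  trig <- task$trigger_h
  if (task$outcome == "mortality") {
    keep <- is.na(st$death_time_h) | st$death_time_h > trig
    st <- st[keep, , drop = FALSE]
    lab <- as.integer(!is.na(st$death_time_h) &
                        st$death_time_h > trig &
                        st$death_time_h <= trig + task$horizon_h)
  } else {
    lab <- as.integer(st$icu_los_h > task$los_threshold_h)
  }
  data.frame(stay_id = st$stay_id, trigger_h = trig, label = lab,
             prefix_end_h = trig, stringsAsFactors = FALSE)
}

#' Dynamic (rolling next-24-hour) task labels
#'
#' For each stay, every surviving grid time `t >= trigger_h` (and at
#' multiples of the stride measured from the first trigger) yields an
#' example labeled 1 iff `death_time_h` is in `(t, t + horizon_h]`.
#' Triggers at or after the death time are not emitted. Survivors (to
#' hospital discharge) contribute label-0 triggers through ICU discharge —
#' the outcome is in-hospital mortality, so their status inside the last
#' 24 h of the ICU stay is known; post-ICU deaths still produce positives
#' at in-ICU triggers within the horizon of the death.
#'
#' @param cohort an [icu_cohort()].
#' @param task a dynamic [task_spec()] (`trigger_h` is the stride).
#' @param grid_by_stay named list of grid times (from preprocessing) per
#'   stay.
#' @return data.frame: `stay_id`, `trigger_h`, `label`, `prefix_end_h`.
#' @export
make_dynamic_labels <- function(cohort, task, grid_by_stay) {
  stopifnot(inherits(task, "task_spec"), task$kind == "dynamic")
  stride <- task$trigger_h
  horizon <- task$horizon_h
  st <- cohort$stays
  death <- stats::setNames(st$death_time_h, st$stay_id)
  out_id <- out_t <- out_lab <- vector("list", length(grid_by_stay))
  i <- 0L
  for (id in names(grid_by_stay)) {
    g <- grid_by_stay[[id]]
    trig <- g[g >= stride & (g %% stride) == 0]
    d <- death[[id]]
    if (!is.na(d)) trig <- trig[trig < d]
    if (!length(trig)) next
    lab <- if (is.na(d)) rep(0L, length(trig))
           else as.integer(d > trig & d <= trig + horizon)
    i <- i + 1L
    out_id[[i]] <- rep(id, length(trig))
    out_t[[i]] <- trig
    out_lab[[i]] <- lab
  }
  data.frame(stay_id = unlist(out_id), trigger_h = unlist(out_t),
             label = unlist(out_lab), prefix_end_h = unlist(out_t),
             stringsAsFactors = FALSE)
}

#' Patient-grouped train/validation/test split
#'
#' Patients (not stays) are shuffled with the given seed and apportioned to
#' the three splits with largest-remainder rounding, so every stay of a
#' patient shares a split and no patient leaks across splits.
#'
#' @param cohort an [icu_cohort()].
#' @param ratios train/test/validation fractions summing to 1
#'   (default 7:2:1).
#' @param seed integer seed.
#' @return data.frame `patient_id`, `split` (`train`/`test`/`val`), plus a
#'   `stay_split` attribute mapping `stay_id` to split.
#' @export
split_by_patient <- function(cohort, ratios = c(train = 0.7, test = 0.2,
                                                val = 0.1), seed = 1L) {
  stopifnot(abs(sum(ratios) - 1) < 1e-8)
  pats <- sort(unique(cohort$stays$patient_id))
  if (length(pats) < length(ratios))
    stop("fewer patients than splits")
  set.seed(as.integer(seed))
  pats <- sample(pats)
  sizes <- largest_remainder(length(pats), ratios)
  split <- rep(names(ratios), sizes)
  asg <- data.frame(patient_id = pats, split = split,
                    stringsAsFactors = FALSE)
  stay_split <- asg$split[match(cohort$stays$patient_id, asg$patient_id)]
  names(stay_split) <- cohort$stays$stay_id
  attr(asg, "stay_split") <- stay_split
  asg
}
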