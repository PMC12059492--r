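# Irregular event streams -> aligned tensors.
#
# Order of operations: resample (hourly bins + mask) -> drop_empty_bins ->
# compute_delta on the surviving grid -> impute -> encode. Removal precedes
# imputation so interpolation never runs through bins that carry no
# information at all.

#' Resample one stay's events onto the hourly grid
#'
#' The timeline is discretized into 1-hour bins at integer hours
#' `0..floor(los_h)`; bin `t` collects raw observations with time in
#' `[t - 0.5, t + 0.5)` (half-open, so an observation at exactly 2.5 h lands
#' in bin 3; bin 0 uses `[0, 0.5)`). Multiple observations in a bin are
#' aggregated with the rule the variable dictionary assigns (median, mode,
#' sum, max, min, last); mode ties are broken by recency. Empty bins are
#' marked absent with mask 0.
#'
#' @param events events data.frame for a single stay.
#' @param spec_by_var named list of [variable_spec()].
#' @param los_h stay length in hours.
#' @return an `aligned_stay` list: `stay_id`, `grid_h`, `X` (T x D
#'   data.frame; numeric or character columns), `M` (T x D 0/1 matrix),
#'   `Delta` (`NULL` until [compute_delta()]), `dropped_bins`.
#' @export
resample_stay <- function(events, spec_by_var, los_h) {
  stopifnot(length(unique(events$stay_id)) <= 1L, los_h >= 0)
  vars <- names(spec_by_var)
  grid <- 0:floor(los_h)
  T_ <- length(grid)
  D <- length(vars)
  M <- matrix(0, T_, D, dimnames = list(NULL, vars))
  X <- vector("list", D); names(X) <- vars
  for (d in vars) {
    X[[d]] <- if (spec_by_var[[d]]$vtype == "numeric")
      rep(NA_real_, T_) else rep(NA_character_, T_)
  }
  if (nrow(events)) {
    bin <- floor(events$time_h + 0.5)
    keep <- bin >= 0 & bin <= max(grid) & events$variable %in% vars
    ev <- events[keep, , drop = FALSE]
    bin <- bin[keep]
    if (nrow(ev)) {
      key <- split(seq_len(nrow(ev)), list(ev$variable, bin), drop = TRUE)
      for (g in key) {
        d <- ev$variable[g[1]]
        b <- floor(ev$time_h[g[1]] + 0.5) + 1L # row index
        spec <- spec_by_var[[d]]
        tv <- ev$time_h[g]
        if (spec$vtype == "numeric") {
          vv <- as.numeric(ev$value[g])
          X[[d]][b] <- switch(spec$aggregation,
            median = stats::median(vv),
            sum = sum(vv), max = max(vv), min = min(vv),
            last = vv[which.max(tv)],
            mode = as.numeric(mode_recency(vv, tv)))
        } else {
          vv <- ev$value[g]
          X[[d]][b] <- switch(spec$aggregation,
            mode = mode_recency(vv, tv),
            last = vv[which.max(tv)],
            vv[which.max(tv)]) # remaining tokens degrade to most recent
        }
        M[b, d] <- 1
      }
    }
  }
  structure(list(
    stay_id = if (nrow(events)) events$stay_id[1] else NA_character_,
    grid_h = as.numeric(grid),
    X = as.data.frame(X, stringsAsFactors = FALSE, optional = TRUE),
    M = M, Delta = NULL, dropped_bins = numeric(0)), class = "aligned_stay")
}

#' Time-since-last-observation matrix
#'
#' Per variable `d`: `delta[1, d] = 0`; for `t > 1`,
#' `delta[t, d] = (s_t - s_[t-1]) + (0 if m_[t-1, d] = 1 else
#' delta[t-1, d])` — elapsed time accumulates across unobserved bins and
#' resets the step after an observation, the convention used by
#' missing-data-aware recurrent models.
#'
#' @param M T x D binary mask matrix.
#' @param grid_h strictly increasing grid times (length T).
#' @return T x D matrix of hours since the last observation.
#' @export
compute_delta <- function(M, grid_h) {
  T_ <- nrow(M)
  stopifnot(length(grid_h) == T_, T_ >= 1,
            all(diff(grid_h) > 0), all(M %in% c(0, 1)))
  Delta <- matrix(0, T_, ncol(M), dimnames = dimnames(M))
  if (T_ > 1) {
    gaps <- diff(grid_h)
    for (t in 2:T_)
      Delta[t, ] <- gaps[t - 1L] + (1 - M[t - 1L, ]) * Delta[t - 1L, ]
  }
  Delta
}

#' Remove timepoints at which no variable was observed
#'
#' Bins whose mask row is all zero are removed; `grid_h` keeps the original
#' hour values (the grid becomes non-uniform) and `Delta` is recomputed on
#' the surviving grid so that elapsed time across a removed bin reflects
#' true hours.
#'
#' @param aligned an `aligned_stay` (imputation must not have run yet).
#' @return the pruned `aligned_stay` with `dropped_bins` filled in.
#' @export
drop_empty_bins <- function(aligned) {
  keep <- rowSums(aligned$M) > 0
  if (!any(keep))
    stop("empty stay: no variable observed in any bin (stay ",
         aligned$stay_id, ")")
  dropped <- aligned$grid_h[!keep]
  aligned$X <- aligned$X[keep, , drop = FALSE]
  rownames(aligned$X) <- NULL
  aligned$M <- aligned$M[keep, , drop = FALSE]
  aligned$grid_h <- aligned$grid_h[keep]
  aligned$dropped_bins <- c(aligned$dropped_bins, dropped)
  aligned$Delta <- compute_delta(aligned$M, aligned$grid_h)
  aligned
}

#' Fit normalization statistics on the training split
#'
#' Means and standard deviations of numeric variables are computed over
#' observed entries only (mask 1), as are the global fallbacks (median for
#' numeric, mode for categorical — the value used when a stay never observes
#' the variable). The interval channels are scaled by a fixed 24-hour
#' constant rather than z-scored. Statistics must come from the training
#' split only; applying them elsewhere is what keeps test data out of the
#' model.
#'
#' @param training_stays list of `aligned_stay` objects (training split).
#' @param spec_by_var named list of [variable_spec()].
#' @param epsilon replacement standard deviation for degenerate variables
#'   (constant, or observed fewer than twice).
#' @return `norm_stats` list: `mean`, `sd` (named numeric), `fallback`
#'   (named list), `interval_scale`, `n_obs`.
#' @export
fit_normalization <- function(training_stays, spec_by_var,
                              epsilon = 1e-6) {
  vars <- names(spec_by_var)
  mu <- sdv <- stats::setNames(rep(NA_real_, length(vars)), vars)
  fb <- stats::setNames(vector("list", length(vars)), vars)
  nobs <- stats::setNames(integer(length(vars)), vars)
  for (d in vars) {
    obs <- unlist(lapply(training_stays, function(a) {
      m <- a$M[, d] == 1
      a$X[[d]][m]
    }), use.names = FALSE)
    nobs[[d]] <- length(obs)
    if (spec_by_var[[d]]$vtype == "numeric") {
      obs <- as.numeric(obs)
      if (length(obs) == 0L) {
        warning("variable '", d, "' never observed in training set")
        mu[[d]] <- 0; sdv[[d]] <- epsilon; fb[[d]] <- 0
      } else {
        mu[[d]] <- mean(obs)
        s <- if (length(obs) >= 2L) stats::sd(obs) else NA_real_
        if (is.na(s) || s <= 0) {
          warning("degenerate spread for variable '", d,
                  "'; using epsilon sd")
          s <- epsilon
        }
        sdv[[d]] <- s
        fb[[d]] <- stats::median(obs)
      }
    } else {
      if (length(obs) == 0L) {
        warning("variable '", d, "' never observed in training set")
        fb[[d]] <- "missing"
      } else {
        tab <- table(obs)
        top <- sort(names(tab)[tab == max(tab)])[1] # lexicographic tie
        fb[[d]] <- top
      }
    }
  }
  structure(list(mean = mu, sd = sdv, fallback = fb,
                 interval_scale = 24, n_obs = nobs),
            class = "norm_stats")
}

#' Complete missing values on the aligned grid
#'
#' The cascade, per variable: (a) bins before the first observation are
#' back-filled with the stay's earliest observed value (the carried-forward
#' head); (b) a variable never observed during the stay takes the global
#' training-set fallback (median / mode); (c) interior gaps use linear
#' interpolation for numeric variables (or carry-forward when the
#' dictionary says `locf`) and the dedicated `"missing"` category for
#' categorical variables; (d) trailing numeric gaps carry the last
#' observation forward. The mask and delta matrices are untouched, so the
#' model still sees what was imputed.
#'
#' @param aligned an `aligned_stay` (after [drop_empty_bins()]).
#' @param spec_by_var named list of [variable_spec()].
#' @param stats [fit_normalization()] output (supplies fallbacks).
#' @return the `aligned_stay` with `X` completed.
#' @export
impute_stay <- function(aligned, spec_by_var, stats) {
  grid <- aligned$grid_h
  for (d in names(spec_by_var)) {
    spec <- spec_by_var[[d]]
    m <- aligned$M[, d] == 1
    x <- aligned$X[[d]]
    if (!any(m)) {
      fb <- stats$fallback[[d]]
      if (is.null(fb) || (spec$vtype == "numeric" && !is.finite(fb)))
        stop("no training fallback available for variable '", d, "'")
      aligned$X[[d]] <- rep(if (spec$vtype == "numeric") as.numeric(fb)
                            else as.character(fb), length(x))
      next
    }
    if (spec$vtype == "numeric") {
      obs_t <- grid[m]; obs_v <- x[m]
      method <- if (spec$imputation == "locf") "constant" else "linear"
      if (spec$imputation == "none") {
        x[!m] <- stats$fallback[[d]]
      } else if (sum(m) == 1L) {
        x[!m] <- obs_v # single anchor: constant everywhere
      } else {
        x <- stats::approx(obs_t, obs_v, xout = grid, method = method,
                           rule = 2, f = 0)$y
        x[m] <- obs_v # never alter observed entries
      }
    } else {
      first <- which(m)[1]
      x[!m] <- "missing"
      if (first > 1L) x[seq_len(first - 1L)] <- x[first] # head back-fill
      if (spec$imputation == "none" && first > 1L)
        x[seq_len(first - 1L)] <- "missing"
    }
    aligned$X[[d]] <- x
  }
  aligned
}

#' Encode an imputed stay as the model-input matrix
#'
#' Numeric variables are z-scored with training statistics; categorical
#' variables are one-hot encoded over their dictionary categories
#' (including `"missing"`; an unseen category maps to `"missing"` with a
#' warning); then one mask channel and one scaled time-interval channel
#' (delta / 24 h) are appended per variable. Feature order is
#' deterministic: numerics, categorical blocks, masks, intervals.
#'
#' @param aligned an imputed `aligned_stay` with `Delta` computed.
#' @param stats [fit_normalization()] output.
#' @param spec_by_var named list of [variable_spec()].
#' @return an `encoded_stay` list: `stay_id`, `Z` (T x F numeric matrix),
#'   `feature_names`, `parent_var` (per-feature owning variable), `grid_h`.
#' @export
encode_stay <- function(aligned, stats, spec_by_var) {
  stopifnot(!is.null(aligned$Delta))
  vars <- names(spec_by_var)
  vt <- vapply(spec_by_var, `[[`, "", "vtype")
  num_vars <- vars[vt == "numeric"]
  cat_vars <- vars[vt == "categorical"]
  T_ <- length(aligned$grid_h)
  cols <- list(); fn <- character(0); parent <- character(0)
  for (d in num_vars) {
    x <- aligned$X[[d]]
    if (anyNA(x)) stop("imputation left missing values in '", d, "'")
    cols[[length(cols) + 1L]] <- (x - stats$mean[[d]]) / stats$sd[[d]]
    fn <- c(fn, d); parent <- c(parent, d)
  }
  for (d in cat_vars) {
    lv <- spec_by_var[[d]]$categories
    x <- aligned$X[[d]]
    unseen <- !(x %in% lv)
    if (any(unseen)) {
      warning("unseen categor", if (sum(unseen) > 1) "ies" else "y",
              " for '", d, "' mapped to \"missing\"")
      x[unseen] <- "missing"
    }
    oh <- matrix(0, T_, length(lv))
    oh[cbind(seq_len(T_), match(x, lv))] <- 1
    for (j in seq_along(lv)) cols[[length(cols) + 1L]] <- oh[, j]
    fn <- c(fn, paste0(d, "=", lv)); parent <- c(parent, rep(d, length(lv)))
  }
  for (d in vars) {
    cols[[length(cols) + 1L]] <- aligned$M[, d]
    fn <- c(fn, paste0(d, ".mask")); parent <- c(parent, d)
  }
  for (d in vars) {
    cols[[length(cols) + 1L]] <- aligned$Delta[, d] / stats$interval_scale
    fn <- c(fn, paste0(d, ".delta")); parent <- c(parent, d)
  }
  Z <- do.call(cbind, cols)
  colnames(Z) <- fn
  structure(list(stay_id = aligned$stay_id, Z = Z, feature_names = fn,
                 parent_var = stats::setNames(parent, fn),
                 grid_h = aligned$grid_h), class = "encoded_stay")
}

#' Align, impute and encode every stay of a cohort
#'
#' Runs the full preprocessing chain per stay. When `stats` is `NULL` they
#' are fitted on the stays named in `train_ids` (training split only) and
#' returned alongside, so the same statistics can later be applied to other
#' cohorts.
#'
#' @param cohort an [icu_cohort()].
#' @param stats optional pre-fitted [fit_normalization()] statistics.
#' @param train_ids stay ids to fit statistics on (defaults to all stays).
#' @param keep_vars optional subset of dictionary variables to retain (used
#'   by the cross-cohort harness).
#' @return list: `encoded` (named list of `encoded_stay`), `aligned`
#'   (named list of imputed `aligned_stay`), `stats`, `skipped` (ids of
#'   stays with no observation at all).
#' @export
preprocess_cohort <- function(cohort, stats = NULL, train_ids = NULL,
                              keep_vars = NULL) {
  stopifnot(inherits(cohort, "icu_cohort"))
  spec_by_var <- cohort$dictionary
  if (!is.null(keep_vars)) {
    miss <- setdiff(keep_vars, names(spec_by_var))
    if (length(miss)) stop("keep_vars not in dictionary: ",
                           paste(miss, collapse = ", "))
    spec_by_var <- spec_by_var[keep_vars]
  }
  ids <- cohort$stays$stay_id
  los <- stats::setNames(cohort$stays$icu_los_h, ids)
  ev_by_stay <- split(cohort$events, cohort$events$stay_id)
  aligned <- list(); skipped <- character(0)
  empty_events <- cohort$events[0, , drop = FALSE]
  for (id in ids) {
    ev <- ev_by_stay[[id]]
    if (is.null(ev)) ev <- empty_events
    if (!is.null(keep_vars))
      ev <- ev[ev$variable %in% keep_vars, , drop = FALSE]
    a <- resample_stay(ev, spec_by_var, los[[id]])
    a$stay_id <- id
    if (!any(a$M == 1)) { skipped <- c(skipped, id); next }
    a <- drop_empty_bins(a)
    aligned[[id]] <- a
  }
  if (is.null(stats)) {
    fit_ids <- intersect(train_ids %||% names(aligned), names(aligned))
    if (!length(fit_ids)) stop("no stays available to fit statistics on")
    stats <- fit_normalization(aligned[fit_ids], spec_by_var)
  }
  encoded <- list()
  for (id in names(aligned)) {
    aligned[[id]] <- impute_stay(aligned[[id]], spec_by_var, stats)
    encoded[[id]] <- encode_stay(aligned[[id]], stats, spec_by_var)
  }
  list(encoded = encoded, aligned = aligned, stats = stats,
       skipped = skipped)
}

#' Read / write normalization statistics as structured text
#' @param stats a `norm_stats` object.
#' @param path file path (JSON).
#' @export
write_norm_stats <- function(stats, path) {
  jsonlite::write_json(
    list(mean = as.list(stats$mean), sd = as.list(stats$sd),
         fallback = stats$fallback,
         interval_scale = stats$interval_scale,
         n_obs = as.list(stats$n_obs)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_norm_stats
#' @export
read_norm_stats <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(mean = unlist(x$mean), sd = unlist(x$sd),
                 fallback = x$fallback,
                 interval_scale = x$interval_scale,
                 n_obs = unlist(x$n_obs)), class = "norm_stats")
}
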