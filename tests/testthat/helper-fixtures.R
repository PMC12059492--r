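# Shared fixture builders. Everything is generated in code; no data files.

# dictionary with two numerics and one categorical
tiny_dictionary <- function() {
  list(
    hr = variable_spec("hr", "numeric", "median", "linear"),
    lactate = variable_spec("lactate", "numeric", "median", "linear"),
    rhythm = variable_spec("rhythm", "categorical", "mode", "locf",
                           categories = c("sinus", "afib"))
  )
}

# three stays: one survivor, one ICU death, one post-ICU death
tiny_cohort <- function() {
  stays <- data.frame(
    stay_id = c("a", "b", "c"),
    patient_id = c("p1", "p1", "p2"),
    icu_los_h = c(48, 30.5, 24),
    death_time_h = c(NA, 30.5, 40),
    age_years = c(60L, 45L, 70L),
    sex = c("F", "M", "F"),
    race = c("white", "black", "asian"),
    stringsAsFactors = FALSE)
  events <- data.frame(
    stay_id = c("a", "a", "a", "b", "b", "c"),
    time_h = c(0.2, 1.2, 1.4, 2.1, 10.0, 5.5),
    variable = c("hr", "hr", "hr", "lactate", "rhythm", "hr"),
    value = c("80", "80", "90", "2.5", "afib", "100"),
    stringsAsFactors = FALSE)
  icu_cohort(stays, events, tiny_dictionary())
}

# random events for one stay over a small grid; used by oracle suites
random_stay_events <- function(stay_id, vars, los_h, n_events,
                               cat_levels = c("low", "mid", "high")) {
  v <- sample(names(vars), n_events, replace = TRUE)
  tt <- round(stats::runif(n_events, 0, los_h), 3)
  val <- ifelse(
    vapply(vars[v], `[[`, "", "vtype") == "numeric",
    as.character(round(stats::rnorm(n_events, 50, 10), 3)),
    sample(cat_levels, n_events, replace = TRUE))
  data.frame(stay_id = stay_id, time_h = tt, variable = v, value = val,
             stringsAsFactors = FALSE)
}

# small encoded stay with synthetic values, for model-level tests
random_encoded_stay <- function(T_ = 8L, Fd = 5L, seed = 1L,
                                grid = NULL) {
  set.seed(seed)
  Z <- matrix(stats::rnorm(T_ * Fd), T_, Fd)
  fn <- paste0("f", seq_len(Fd))
  colnames(Z) <- fn
  structure(list(stay_id = "fx", Z = Z, feature_names = fn,
                 parent_var = stats::setNames(fn, fn),
                 grid_h = grid %||% seq_len(T_)),
            class = "encoded_stay")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# brute-force reference for the delta recursion: hours since the most
# recent observed bin, scanned directly
delta_bruteforce <- function(M, grid_h) {
  D <- matrix(0, nrow(M), ncol(M))
  for (d in seq_len(ncol(M))) {
    for (t in seq_len(nrow(M))) {
      if (t == 1) { D[t, d] <- 0; next }
      obs <- which(M[seq_len(t - 1L), d] == 1)
      D[t, d] <- if (length(obs)) grid_h[t] - grid_h[max(obs)]
                 else grid_h[t] - grid_h[1]
    }
  }
  D
}

# brute-force AUROC by pair enumeration with half credit for ties
auroc_bruteforce <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  if (!length(pos) || !length(neg)) return(NA_real_)
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

# brute-force AUPRC by explicit threshold sweep over distinct scores
auprc_bruteforce <- function(scores, labels) {
  n1 <- sum(labels == 1)
  if (n1 == 0) return(NA_real_)
  th <- sort(unique(scores), decreasing = TRUE)
  prev_r <- 0; area <- 0
  for (s in th) {
    tp <- sum(scores >= s & labels == 1)
    fp <- sum(scores >= s & labels == 0)
    r <- tp / n1; p <- tp / (tp + fp)
    area <- area + (r - prev_r) * p
    prev_r <- r
  }
  area
}
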