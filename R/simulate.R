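# Synthetic EMR cohort simulator.
#
# Generative model (see the methods vignette for the full account):
# each stay carries a latent deterioration state z_t following a
# discrete-time AR(1) process on the hourly grid; numeric variables are
# affine functions of the latent state (causal variables) or of an
# independent AR(1) latent (non-causal), plus observation noise, observed at
# exponential inter-arrival gaps whose rate increases with severity
# (informative missingness); categorical variables threshold their driving
# latent; the per-hour death hazard is logistic(baseline + sum effect * z_t),
# and a fired death is either an in-ICU death or, with stated probability,
# deferred past ICU discharge to emulate post-ICU in-hospital death.

#' Configure the synthetic EMR simulator
#'
#' Defaults are set to emulate the structure of large ICU cohorts: mean age
#' near 59 with tails outside the 18-80 eligibility window, ICU stays of
#' roughly 1-10 days, per-variable mean sampling gaps of 1-6 hours,
#' in-hospital mortality near 8-9% and next-24-hour mortality near 2% of
#' timepoints.
#'
#' @param n_patients number of patients.
#' @param multi_stay_prob probability a patient has a second ICU stay.
#' @param n_numeric_vars,n_categorical_vars variable counts (named
#'   `num_01`..., `cat_01`...).
#' @param sampling_rate_h range of per-variable mean inter-observation gaps
#'   (hours); each variable draws its mean gap uniformly from this range.
#' @param causal_vars names of variables whose driving latent is the shared
#'   deterioration state (they carry the mortality signal). Default: the
#'   first three numeric variables.
#' @param effect_sizes per-causal-variable log-hazard coefficients.
#' @param baseline_hazard per-hour death probability at neutral severity
#'   (z = 0).
#' @param target_mortality intended in-hospital mortality fraction; a
#'   warning reports the achieved rate when it lands far from this.
#' @param los_range_h min/max planned stay length in hours (log-uniform).
#' @param post_icu_death_prob probability a fired death is deferred past ICU
#'   discharge (in-hospital, out-of-ICU death).
#' @param ar_rho hour-to-hour autocorrelation of the transient component
#'   of the latent state.
#' @param frailty_sd standard deviation of the stay-level frailty (the
#'   persistent component of severity); the transient AR(1) component is
#'   scaled so the marginal latent variance stays 1.
#' @param noise_sd observation noise, in units of the latent scale.
#' @param informative_k strength of informative sampling (rate multiplier
#'   `1 + informative_k * max(z, 0)`).
#' @param seed integer seed; fully determines the cohort.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_patients = 500,
                       multi_stay_prob = 0.12,
                       n_numeric_vars = 17,
                       n_categorical_vars = 3,
                       sampling_rate_h = c(1, 6),
                       causal_vars = NULL,
                       effect_sizes = c(1.5, 1.5, 1.5),
                       baseline_hazard = 5e-6,
                       target_mortality = 0.085,
                       los_range_h = c(16, 320),
                       post_icu_death_prob = 0.15,
                       ar_rho = 0.97,
                       frailty_sd = 0.6,
                       noise_sd = 0.6,
                       informative_k = 1,
                       seed = 1L) {
  num_names <- if (n_numeric_vars > 0)
    sprintf("num_%02d", seq_len(n_numeric_vars)) else character(0)
  cat_names <- if (n_categorical_vars > 0)
    sprintf("cat_%02d", seq_len(n_categorical_vars)) else character(0)
  if (is.null(causal_vars))
    causal_vars <- utils::head(num_names, min(3L, length(num_names)))
  if (!all(causal_vars %in% c(num_names, cat_names)))
    stop("causal_vars must be generated variable names")
  if (length(effect_sizes) != length(causal_vars))
    effect_sizes <- rep_len(effect_sizes, length(causal_vars))
  stopifnot(multi_stay_prob >= 0, multi_stay_prob <= 1,
            post_icu_death_prob >= 0, post_icu_death_prob <= 1,
            baseline_hazard > 0, baseline_hazard < 1,
            los_range_h[1] > 0, diff(los_range_h) >= 0,
            ar_rho >= 0, ar_rho < 1, frailty_sd >= 0, frailty_sd < 1)
  structure(list(
    n_patients = n_patients, multi_stay_prob = multi_stay_prob,
    n_numeric_vars = n_numeric_vars,
    n_categorical_vars = n_categorical_vars,
    num_names = num_names, cat_names = cat_names,
    sampling_rate_h = sampling_rate_h, causal_vars = causal_vars,
    effect_sizes = stats::setNames(effect_sizes, causal_vars),
    baseline_hazard = baseline_hazard,
    target_mortality = target_mortality, los_range_h = los_range_h,
    post_icu_death_prob = post_icu_death_prob, ar_rho = ar_rho,
    frailty_sd = frailty_sd, noise_sd = noise_sd,
    informative_k = informative_k,
    seed = as.integer(seed)), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "<sim_config> %d patients, %d numeric + %d categorical vars, seed %d\n",
    x$n_patients, x$n_numeric_vars, x$n_categorical_vars, x$seed))
  cat(sprintf("  causal: %s (effects %s)\n",
              paste(x$causal_vars, collapse = ", "),
              paste(format(x$effect_sizes), collapse = ", ")))
  invisible(x)
}

#' Simulate a synthetic ICU cohort with ground truth
#'
#' @param config a [sim_config()].
#' @return list with elements `cohort` (an [icu_cohort()]) and
#'   `ground_truth` (per-stay true event times and pathway flags, the causal
#'   variable set with effect sizes, and per-stay latent trajectories).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  vars <- c(config$num_names, config$cat_names)
  D <- length(vars)
  stopifnot(D > 0)
  gap_mean <- stats::setNames(
    stats::runif(D, config$sampling_rate_h[1], config$sampling_rate_h[2]),
    vars)
  # per-variable affine scale: deterministic in the variable index so two
  # cohorts from the same structural config share measurement scales
  idx <- seq_len(D)
  mu_d <- stats::setNames(50 + 7 * idx, vars)
  sd_d <- stats::setNames(5 + 0.8 * idx, vars)
  b0 <- stats::qlogis(config$baseline_hazard)
  beta_sum <- sum(config$effect_sizes)

  n_stays_per_pat <- 1L + stats::rbinom(config$n_patients, 1L,
                                        config$multi_stay_prob)
  n_stays <- sum(n_stays_per_pat)
  pat_ids <- sprintf("p%05d", seq_len(config$n_patients))
  stay_pat <- rep(pat_ids, n_stays_per_pat)
  stay_ids <- sprintf("s%05d", seq_len(n_stays))
  age_pat <- pmin(92L, pmax(16L, as.integer(round(
    stats::rnorm(config$n_patients, 60, 15)))))
  sex_pat <- sample(c("F", "M"), config$n_patients, TRUE,
                    prob = c(0.44, 0.56))
  race_pat <- sample(
    c("asian", "black", "hispanic", "white", "other"),
    config$n_patients, TRUE, prob = c(0.02, 0.12, 0.04, 0.72, 0.10))
  names(age_pat) <- names(sex_pat) <- names(race_pat) <- pat_ids

  ev_stay <- vector("list", n_stays); ev_time <- vector("list", n_stays)
  ev_var <- vector("list", n_stays); ev_val <- vector("list", n_stays)
  icu_los <- death_time <- numeric(n_stays)
  post_icu <- logical(n_stays)
  latents <- vector("list", n_stays)

  cat_cut <- c(-0.6, 0.6) # low / mid / high thresholds on the latent scale
  for (i in seq_len(n_stays)) {
    L <- exp(stats::runif(1, log(config$los_range_h[1]),
                          log(config$los_range_h[2])))
    H <- as.integer(ceiling(L))
    # latent deterioration state on the hourly grid: stay-level frailty
    # plus a stationary AR(1) transient, marginal variance 1
    a <- numeric(H + 1L)
    a[1] <- stats::rnorm(1)
    if (H > 0) {
      innov <- stats::rnorm(H, 0, sqrt(1 - config$ar_rho^2))
      for (t in seq_len(H)) a[t + 1L] <- config$ar_rho * a[t] + innov[t]
    }
    sa <- sqrt(1 - config$frailty_sd^2)
    z <- config$frailty_sd * stats::rnorm(1) + sa * a
    # death hazard per hour (hour t spans (t-1, t])
    haz <- sigmoid(b0 + beta_sum * z[-1L])
    fire <- which(stats::runif(H) < haz)
    end_h <- L; dth <- NA_real_; post <- FALSE
    if (length(fire) && fire[1] <= L) {
      moment <- fire[1] - stats::runif(1)
      if (stats::runif(1) < config$post_icu_death_prob) {
        post <- TRUE
        end_h <- moment
        dth <- moment + stats::rexp(1, 1 / 48)
      } else {
        end_h <- moment
        dth <- moment
      }
    }
    end_h <- max(end_h, 1) # degenerate guard: at least one hour observed
    icu_los[i] <- end_h; death_time[i] <- dth; post_icu[i] <- post
    latents[[i]] <- z[seq_len(min(length(z), as.integer(ceiling(end_h)) + 1L))]

    # independent latents for non-causal variables
    zi <- function(t) z[pmin(length(z), floor(t) + 1L)]
    st_t <- list(); st_v <- list(); st_x <- list()
    k <- 0L
    for (d in vars) {
      causal <- d %in% config$causal_vars
      # own AR(1) latent for non-causal variables, sampled lazily per obs
      tt <- numeric(0); t <- stats::runif(1, 0, min(gap_mean[[d]], end_h))
      while (t < end_h) {
        tt <- c(tt, t)
        rate <- (1 + config$informative_k * max(zi(t), 0)) / gap_mean[[d]]
        t <- t + stats::rexp(1, rate)
      }
      if (!length(tt)) next
      n_obs <- length(tt)
      if (causal) {
        sig <- zi(tt)
      } else {
        # independent AR(1) latent evaluated at the observation hours
        u <- numeric(length(z)); u[1] <- stats::rnorm(1)
        if (length(z) > 1) {
          inn <- stats::rnorm(length(z) - 1L, 0,
                              sqrt(1 - config$ar_rho^2))
          for (t2 in seq_len(length(z) - 1L))
            u[t2 + 1L] <- config$ar_rho * u[t2] + inn[t2]
        }
        sig <- u[pmin(length(u), floor(tt) + 1L)]
      }
      noisy <- sig + stats::rnorm(n_obs, 0, config$noise_sd)
      if (d %in% config$num_names) {
        val <- round(mu_d[[d]] + sd_d[[d]] * noisy, 4)
        val <- as.character(val)
      } else {
        val <- cut(noisy, c(-Inf, cat_cut, Inf),
                   labels = c("low", "mid", "high"))
        val <- as.character(val)
      }
      k <- k + 1L
      st_t[[k]] <- round(tt, 4); st_v[[k]] <- rep(d, n_obs)
      st_x[[k]] <- val
    }
    ev_time[[i]] <- unlist(st_t); ev_var[[i]] <- unlist(st_v)
    ev_val[[i]] <- unlist(st_x)
    ev_stay[[i]] <- rep(stay_ids[i], length(ev_time[[i]]))
  }

  stays <- data.frame(
    stay_id = stay_ids, patient_id = stay_pat,
    icu_los_h = round(icu_los, 4),
    death_time_h = round(death_time, 4),
    age_years = age_pat[stay_pat], sex = sex_pat[stay_pat],
    race = race_pat[stay_pat], stringsAsFactors = FALSE)
  events <- data.frame(
    stay_id = unlist(ev_stay), time_h = unlist(ev_time),
    variable = unlist(ev_var), value = unlist(ev_val),
    stringsAsFactors = FALSE)
  dict <- make_fixture_dictionary(config$n_numeric_vars,
                                  config$n_categorical_vars)
  cohort <- icu_cohort(stays, events, dict)

  achieved <- mean(!is.na(stays$death_time_h))
  if (abs(achieved - config$target_mortality) >
      max(0.5 * config$target_mortality, 3 * sqrt(
        config$target_mortality * (1 - config$target_mortality) /
          max(1, n_stays))))
    warning(sprintf(
      "achieved in-hospital mortality %.3f differs from target %.3f",
      achieved, config$target_mortality))

  ground_truth <- list(
    stays = data.frame(
      stay_id = stay_ids, patient_id = stay_pat,
      died = !is.na(stays$death_time_h),
      death_time_h = stays$death_time_h, icu_los_h = stays$icu_los_h,
      post_icu_death = post_icu, stringsAsFactors = FALSE),
    causal_vars = config$causal_vars,
    effect_sizes = config$effect_sizes,
    latent = stats::setNames(latents, stay_ids))
  list(cohort = cohort, ground_truth = ground_truth)
}

#' Write simulator ground truth as delimited text
#'
#' @param ground_truth the `ground_truth` element of [simulate_cohort()].
#' @param dir output directory.
#' @return invisibly, the file path.
#' @export
write_ground_truth <- function(ground_truth, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  gp <- file.path(dir, "ground_truth.csv")
  utils::write.csv(ground_truth$stays, gp, row.names = FALSE, na = "",
                   fileEncoding = "UTF-8")
  cp <- file.path(dir, "causal_vars.csv")
  utils::write.csv(
    data.frame(variable = ground_truth$causal_vars,
               effect_size = as.numeric(ground_truth$effect_sizes)),
    cp, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(c(stays = gp, causal = cp))
}
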