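# Cohort container: stay metadata + long-format observation events +
# variable dictionary, with validating readers/writers.

#' Assemble and validate a cohort
#'
#' A cohort bundles stay-level metadata, the long-format observation events
#' (one row per measurement: stay, hours since ICU admission, variable,
#' value) and the variable dictionary every downstream stage consults.
#'
#' @param stays data.frame with columns `stay_id`, `patient_id`,
#'   `icu_los_h`, `death_time_h` (`NA` = survived to hospital discharge),
#'   `age_years`, `sex`, `race`.
#' @param events data.frame with columns `stay_id`, `time_h`, `variable`,
#'   `value`.
#' @param dictionary named list of [variable_spec()].
#' @return object of class `icu_cohort`.
#' @export
icu_cohort <- function(stays, events, dictionary) {
  stays <- as.data.frame(stays, stringsAsFactors = FALSE)
  events <- as.data.frame(events, stringsAsFactors = FALSE)
  need_s <- c("stay_id", "patient_id", "icu_los_h", "death_time_h",
              "age_years", "sex", "race")
  need_e <- c("stay_id", "time_h", "variable", "value")
  if (!all(need_s %in% names(stays)))
    stop("stays table missing columns: ",
         paste(setdiff(need_s, names(stays)), collapse = ", "))
  if (!all(need_e %in% names(events)))
    stop("events table missing columns: ",
         paste(setdiff(need_e, names(events)), collapse = ", "))
  if (anyDuplicated(stays$stay_id))
    stop("duplicate stay_id in stays table")
  bad_death <- which(!is.na(stays$death_time_h) & stays$death_time_h <= 0)
  if (length(bad_death))
    stop("non-positive death_time_h for stay(s): ",
         paste(stays$stay_id[bad_death], collapse = ", "))

  # referential integrity: events -> stays, events -> dictionary
  orphan <- !(events$stay_id %in% stays$stay_id)
  if (any(orphan))
    stop("events reference unknown stay_id (rows ",
         paste(utils::head(which(orphan), 5L), collapse = ", "), ")")
  unknown <- !(events$variable %in% names(dictionary))
  if (any(unknown))
    stop("dictionary mismatch: variable(s) ",
         paste(unique(events$variable[unknown]), collapse = ", "),
         " not in dictionary (rows ",
         paste(utils::head(which(unknown), 5L), collapse = ", "), ")")
  if (any(events$time_h < 0))
    stop("negative time_h in events (rows ",
         paste(utils::head(which(events$time_h < 0), 5L), collapse = ", "),
         ")")

  # type check numeric variables
  vt <- vapply(dictionary, `[[`, "", "vtype")
  num_vars <- names(vt)[vt == "numeric"]
  is_num_ev <- events$variable %in% num_vars
  if (any(is_num_ev)) {
    vals <- suppressWarnings(as.numeric(events$value[is_num_ev]))
    bad <- which(is.na(vals) & !is.na(events$value[is_num_ev]))
    if (length(bad)) {
      i <- which(is_num_ev)[bad[1]]
      stop(sprintf(
        "non-numeric value '%s' for numeric variable '%s' (stay %s, t=%g h)",
        events$value[i], events$variable[i], events$stay_id[i],
        events$time_h[i]))
    }
  }

  ord <- order(events$stay_id, events$time_h, events$variable)
  events <- events[ord, , drop = FALSE]
  rownames(events) <- NULL
  stays <- stays[order(stays$stay_id), , drop = FALSE]
  rownames(stays) <- NULL
  structure(list(stays = stays, events = events, dictionary = dictionary),
            class = "icu_cohort")
}

#' @export
print.icu_cohort <- function(x, ...) {
  n_died <- sum(!is.na(x$stays$death_time_h))
  cat(sprintf(
    "<icu_cohort> %d stays / %d patients, %d events, %d variables\n",
    nrow(x$stays), length(unique(x$stays$patient_id)), nrow(x$events),
    length(x$dictionary)))
  cat(sprintf("  in-hospital mortality: %d (%.1f%%)\n", n_died,
              100 * n_died / max(1L, nrow(x$stays))))
  invisible(x)
}

#' Load a cohort from its three delimited-text files
#'
#' @param events_path events file (`stay_id,time_h,variable,value`).
#' @param stays_path stays file (`stay_id,patient_id,icu_los_h,
#'   death_time_h,age_years,sex,race`; empty `death_time_h` = survived).
#' @param dict_path dictionary file, see [read_dictionary()].
#' @return validated [icu_cohort()].
#' @export
load_cohort <- function(events_path, stays_path, dict_path) {
  for (p in c(events_path, stays_path, dict_path))
    if (!file.exists(p)) stop("file not found: ", p)
  dict <- read_dictionary(dict_path)
  stays <- utils::read.csv(stays_path, stringsAsFactors = FALSE,
                           colClasses = c(stay_id = "character",
                                          patient_id = "character",
                                          sex = "character",
                                          race = "character"))
  events <- utils::read.csv(events_path, stringsAsFactors = FALSE,
                            colClasses = c(stay_id = "character",
                                           variable = "character",
                                           value = "character"))
  icu_cohort(stays, events, dict)
}

#' Write a cohort to delimited-text files
#'
#' Writers emit UTF-8 with deterministic row order (stay_id, then time);
#' `write_cohort` followed by [load_cohort()] round-trips all fields.
#'
#' @param cohort an [icu_cohort()].
#' @param dir output directory (created if needed).
#' @return invisibly, the three file paths.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "icu_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ep <- file.path(dir, "events.csv")
  sp <- file.path(dir, "stays.csv")
  dp <- file.path(dir, "dictionary.csv")
  ev <- cohort$events
  ev <- ev[order(ev$stay_id, ev$time_h, ev$variable), , drop = FALSE]
  st <- cohort$stays[order(cohort$stays$stay_id), , drop = FALSE]
  utils::write.csv(ev, ep, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8", na = "")
  utils::write.csv(st, sp, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8", na = "")
  write_dictionary(cohort$dictionary, dp)
  invisible(c(events = ep, stays = sp, dictionary = dp))
}

#' Apply the cohort eligibility filter
#'
#' Retains stays with `min_los_h <= icu_los_h <= max_los_d * 24` and
#' `min_age <= age_years <= max_age` (all bounds inclusive); events of
#' removed stays are dropped. The attached exclusion tally counts, per
#' criterion, how many stays failed it (a stay can fail several).
#'
#' @param cohort an [icu_cohort()].
#' @param min_los_h minimum ICU length of stay in hours.
#' @param max_los_d maximum ICU length of stay in days.
#' @param min_age,max_age inclusive age bounds in years.
#' @return filtered `icu_cohort` with attribute `"exclusions"`: named
#'   integer vector (`too_short`, `too_long`, `too_young`, `too_old`,
#'   `removed`).
#' @export
filter_eligible <- function(cohort, min_los_h = 12, max_los_d = 30,
                            min_age = 18, max_age = 80) {
  stopifnot(inherits(cohort, "icu_cohort"))
  st <- cohort$stays
  too_short <- st$icu_los_h < min_los_h
  too_long <- st$icu_los_h > max_los_d * 24
  too_young <- st$age_years < min_age
  too_old <- st$age_years > max_age
  drop <- too_short | too_long | too_young | too_old
  tally <- c(too_short = sum(too_short), too_long = sum(too_long),
             too_young = sum(too_young), too_old = sum(too_old),
             removed = sum(drop))
  keep_ids <- st$stay_id[!drop]
  out <- icu_cohort(st[!drop, , drop = FALSE],
                    cohort$events[cohort$events$stay_id %in% keep_ids, ,
                                  drop = FALSE],
                    cohort$dictionary)
  attr(out, "exclusions") <- tally
  out
}
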