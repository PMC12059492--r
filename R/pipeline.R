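# End-to-end pipeline: simulate -> preprocess -> train -> predict ->
# attribute -> evaluate, with one config object, derived per-stage seeds
# and config-stamped artifacts.

#' Assemble a full pipeline configuration
#'
#' One global seed deterministically derives every stage's seed (see
#' [derive_seed()]), so a run is reproducible end to end and stages can be
#' re-executed in isolation.
#'
#' @param work_dir directory for all artifacts.
#' @param sim a [sim_config()] (its own seed is overridden by the derived
#'   simulate-stage seed).
#' @param task a [task_spec()].
#' @param hidden_size,bidirectional,time_aware,dropout,l2_weight model
#'   architecture settings (see [tbal_config()]).
#' @param train_overrides named list of [train_config()] arguments.
#' @param eval_stride reporting stride in hours for dynamic evaluation.
#' @param n_boot bootstrap replicates in evaluation reports.
#' @param attribute_stays number of test stays to attribute (0 disables
#'   the attribution stage artifacts).
#' @param ig_steps Riemann steps for integrated gradients.
#' @param seed global seed.
#' @return object of class `run_config`.
#' @export
run_config <- function(work_dir, sim = sim_config(), task = task_spec("dynamic"),
                       hidden_size = 32, bidirectional = TRUE,
                       time_aware = TRUE, dropout = 0, l2_weight = 1e-5,
                       train_overrides = list(), eval_stride = 4,
                       n_boot = 200, attribute_stays = 5, ig_steps = 32,
                       seed = 1L) {
  structure(list(work_dir = work_dir, sim = sim, task = task,
                 hidden_size = hidden_size, bidirectional = bidirectional,
                 time_aware = time_aware, dropout = dropout,
                 l2_weight = l2_weight, train_overrides = train_overrides,
                 eval_stride = eval_stride, n_boot = n_boot,
                 attribute_stays = attribute_stays, ig_steps = ig_steps,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Fingerprint of the semantically meaningful configuration fields
#'
#' @param config a [run_config()].
#' @return character hash; changes whenever a field that affects results
#'   changes (the work directory does not).
#' @export
config_hash <- function(config) {
  semantic <- config[setdiff(names(config), "work_dir")]
  semantic$sim <- unclass(semantic$sim)
  semantic$task <- unclass(semantic$task)
  js <- jsonlite::toJSON(semantic, auto_unbox = TRUE, digits = NA,
                         null = "null")
  sprintf("%08x", fnv1a(as.character(js)))
}

stage_file <- function(config, ...) file.path(config$work_dir, ...)

need_artifact <- function(path, stage_needed) {
  if (!file.exists(path))
    stop("missing prerequisite artifact '", basename(path),
         "'; run the '", stage_needed, "' stage first")
  invisible(path)
}

#' Run pipeline stages
#'
#' Executes the requested stages in canonical order. Every run writes a
#' `run_info.json` stamping the artifacts with the config hash and package
#' version; the log records per-stage timing and row counts.
#'
#' @param config a [run_config()].
#' @param stages subset of `c("simulate", "preprocess", "train",
#'   "predict", "attribute", "evaluate")`.
#' @param verbose print stage progress.
#' @return invisibly, a list of stage summaries.
#' @export
run_pipeline <- function(config,
                         stages = c("simulate", "preprocess", "train",
                                    "predict", "attribute", "evaluate"),
                         verbose = FALSE) {
  stopifnot(inherits(config, "run_config"))
  all_stages <- c("simulate", "preprocess", "train", "predict",
                  "attribute", "evaluate")
  stages <- all_stages[all_stages %in% stages]
  dir.create(config$work_dir, recursive = TRUE, showWarnings = FALSE)
  info <- list(config_hash = config_hash(config),
               package_version =
                 as.character(utils::packageVersion("icurisk")),
               stages = list())
  log <- list()
  tick <- function(stage, expr) {
    t0 <- Sys.time()
    res <- expr
    el <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    if (verbose) message(sprintf("[%s] %.1fs", stage, el))
    log[[stage]] <<- c(res, list(seconds = el))
    res
  }

  for (stage in stages) {
    if (stage == "simulate") {
      tick("simulate", {
        sim <- config$sim
        sim$seed <- derive_seed(config$seed, "simulate")
        out <- simulate_cohort(sim)
        cd <- stage_file(config, "cohort")
        write_cohort(out$cohort, cd)
        write_ground_truth(out$ground_truth, cd)
        list(stays = nrow(out$cohort$stays),
             events = nrow(out$cohort$events))
      })
    } else if (stage == "preprocess") {
      tick("preprocess", {
        cd <- stage_file(config, "cohort")
        need_artifact(file.path(cd, "events.csv"), "simulate")
        cohort <- load_cohort(file.path(cd, "events.csv"),
                              file.path(cd, "stays.csv"),
                              file.path(cd, "dictionary.csv"))
        cohort <- filter_eligible(cohort)
        split <- split_by_patient(cohort,
                                  seed = derive_seed(config$seed, "split"))
        ss <- attr(split, "stay_split")
        prep <- preprocess_cohort(cohort,
                                  train_ids = names(ss)[ss == "train"])
        saveRDS(list(cohort = cohort, prep = prep, stay_split = ss),
                stage_file(config, "prep.rds"))
        write_norm_stats(prep$stats, stage_file(config, "norm_stats.json"))
        list(stays = length(prep$encoded),
             skipped = length(prep$skipped),
             features = length(prep$encoded[[1]]$feature_names))
      })
    } else if (stage == "train") {
      tick("train", {
        pp <- need_artifact(stage_file(config, "prep.rds"), "preprocess")
        env <- readRDS(pp)
        ex <- build_examples(env$cohort, config$task, env$prep,
                             env$stay_split)
        mcfg <- tbal_config(
          input_dim = length(env$prep$encoded[[1]]$feature_names),
          hidden_size = config$hidden_size,
          dropout = config$dropout, l2_weight = config$l2_weight,
          bidirectional = config$bidirectional,
          time_aware = config$time_aware,
          seed = derive_seed(config$seed, "init"))
        targs <- utils::modifyList(
          list(task = config$task, l2_weight = config$l2_weight,
               seed = derive_seed(config$seed, "train")),
          config$train_overrides)
        tcfg <- do.call(train_config, targs)
        fit <- tbal_fit(ex, env$prep$encoded, mcfg, tcfg,
                        stats = env$prep$stats)
        save_checkpoint(fit, stage_file(config, "checkpoint.rds"))
        utils::write.csv(fit$history,
                         stage_file(config, "training_log.csv"),
                         row.names = FALSE)
        list(examples = nrow(ex), epochs = nrow(fit$history),
             best_epoch = fit$best_epoch)
      })
    } else if (stage == "predict") {
      tick("predict", {
        env <- readRDS(need_artifact(stage_file(config, "prep.rds"),
                                     "preprocess"))
        fit <- load_checkpoint(
          need_artifact(stage_file(config, "checkpoint.rds"), "train"))
        ex <- build_examples(env$cohort, config$task, env$prep,
                             env$stay_split)
        te <- ex[ex$split == "test", , drop = FALSE]
        if (config$task$kind == "dynamic")
          te <- te[te$trigger_h %% config$eval_stride == 0, ,
                   drop = FALSE]
        pr <- predict.tbal(fit, env$prep$encoded, te)
        utils::write.csv(pr, stage_file(config, "predictions.csv"),
                         row.names = FALSE)
        list(predictions = nrow(pr))
      })
    } else if (stage == "attribute") {
      if (config$attribute_stays > 0) tick("attribute", {
        env <- readRDS(need_artifact(stage_file(config, "prep.rds"),
                                     "preprocess"))
        fit <- load_checkpoint(
          need_artifact(stage_file(config, "checkpoint.rds"), "train"))
        pr <- utils::read.csv(
          need_artifact(stage_file(config, "predictions.csv"), "predict"),
          colClasses = c(stay_id = "character"))
        set.seed(derive_seed(config$seed, "attribute"))
        ids <- sample(unique(pr$stay_id),
                      min(config$attribute_stays,
                          length(unique(pr$stay_id))))
        maps <- list()
        for (id in ids) {
          trig <- sort(pr$trigger_h[pr$stay_id == id])
          for (tt in trig)
            maps[[length(maps) + 1L]] <- attribute_stay(
              fit, env$prep$encoded[[id]], tt, m_steps = config$ig_steps)
        }
        rk <- rank_features(maps, env$prep$encoded[[1]]$parent_var)
        utils::write.csv(rk, stage_file(config, "feature_ranking.csv"),
                         row.names = FALSE)
        list(maps = length(maps), top_variable = rk$variable[1])
      })
    } else if (stage == "evaluate") {
      tick("evaluate", {
        env <- readRDS(need_artifact(stage_file(config, "prep.rds"),
                                     "preprocess"))
        pr <- utils::read.csv(
          need_artifact(stage_file(config, "predictions.csv"), "predict"),
          colClasses = c(stay_id = "character"))
        rep <- metric_report(pr$risk, pr$label, pr$stay_id,
                             n_boot = config$n_boot,
                             seed = derive_seed(config$seed, "boot"))
        utils::write.csv(rep, stage_file(config, "metrics.csv"),
                         row.names = FALSE)
        if (config$task$kind == "dynamic") {
          tc <- temporal_curve(pr, stride = config$eval_stride)
          utils::write.csv(tc, stage_file(config, "temporal_curve.csv"),
                           row.names = FALSE)
        }
        sg <- subgroup_report(pr, env$cohort$stays, n_boot = 0)
        utils::write.csv(sg, stage_file(config, "subgroups.csv"),
                         row.names = FALSE)
        list(auroc = rep$value[rep$metric == "auroc"],
             auprc = rep$value[rep$metric == "auprc"])
      })
    }
  }
  info$stages <- log
  jsonlite::write_json(info, stage_file(config, "run_info.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(log)
}
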