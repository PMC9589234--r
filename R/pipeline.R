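#' Default pipeline configuration
#'
#' One nested list controls every stage; each stage derives its own seed
#' from the master seed and the stage name, so a single integer fully
#' determines all artifacts.
#'
#' @param out_dir run directory.
#' @param seed master seed.
#' @param generator list of [generator_config()] overrides.
#' @param preprocess list: low, high, notch, epoch_len_s, threshold_uv,
#'   min_effective.
#' @param featuremap list: win_s, size, clip_uv.
#' @param cnn list of [cnn_config_reduced()] overrides (the pilot-scale
#'   network is the pipeline default).
#' @param split_unit `"image"` or `"subject"`.
#' @param tasks tasks to evaluate (default both).
#' @param n_boot bootstrap resamples for AUC CIs.
#' @return validated `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir, seed = 1L, generator = list(),
                            preprocess = list(), featuremap = list(),
                            cnn = list(), split_unit = "image",
                            tasks = c("diagnosis", "severity"),
                            n_boot = 500) {
  pre <- utils::modifyList(
    list(low = 0.5, high = 50, notch = 50, epoch_len_s = 2,
         threshold_uv = 70, min_effective = 0.5), preprocess)
  fm <- utils::modifyList(list(win_s = 10, size = 100, clip_uv = 70),
                          featuremap)
  if (pre$min_effective < 0 || pre$min_effective > 1)
    stop("min_effective must be in [0, 1]")
  if (fm$win_s <= 0) stop("win_s must be positive")
  cfg <- list(out_dir = out_dir, seed = as.integer(seed),
              generator = generator, preprocess = pre, featuremap = fm,
              cnn = cnn, split_unit = match.arg(split_unit,
                                                c("image", "subject")),
              tasks = match.arg(tasks, c("diagnosis", "severity"),
                                several.ok = TRUE),
              n_boot = n_boot)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Load a pipeline configuration from YAML
#' @param path YAML file whose top-level keys match [pipeline_config()]
#'   arguments.
#' @param out_dir overrides the file's out_dir when given.
#' @export
read_pipeline_config <- function(path, out_dir = NULL) {
  y <- yaml::read_yaml(path)
  if (!is.null(out_dir)) y$out_dir <- out_dir
  do.call(pipeline_config, y)
}

log_stage <- function(log_path, fmt, ...) {
  msg <- sprintf(fmt, ...)
  message(msg)
  cat(msg, "\n", file = log_path, append = TRUE, sep = "")
  invisible(msg)
}

#' Run the full pipeline
#'
#' Stage order: synthesize cohort, preprocess/screen, render feature maps,
#' train and evaluate the CNN for each task, correlate subject AI scores
#' with the questionnaire scales. All artifacts (roster, screening reports,
#' manifest, per-task metrics, correlation tables, run log, summary JSON)
#' are written under `config$out_dir`.
#'
#' @param config a [pipeline_config()].
#' @return the summary list, invisibly; also written as `summary.json`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)
  log_path <- file.path(out, "run.log")
  if (file.exists(log_path)) file.remove(log_path)
  summary <- list(seed = config$seed)

  gen <- do.call(generator_config,
                 utils::modifyList(config$generator,
                                   list(seed = derive_seed(config$seed, "synth"))))
  log_stage(log_path, "[synth] %d/%d/%d subjects, %gs @ %g Hz",
            gen$n_healthy, gen$n_nonmajor, gen$n_major,
            gen$duration_s, gen$fs)
  cohort <- generate_cohort(gen, out_dir = NULL)
  write_roster(cohort$roster, file.path(out, "roster.csv"))
  summary$n_subjects <- nrow(cohort$roster)

  pre <- config$preprocess
  prep <- preprocess_cohort(cohort$recordings, out_dir = NULL,
                            seed = derive_seed(config$seed, "preprocess"),
                            threshold_uv = pre$threshold_uv,
                            min_effective = pre$min_effective,
                            low = pre$low, high = pre$high,
                            notch = pre$notch,
                            epoch_len_s = pre$epoch_len_s)
  utils::write.csv(prep$reports, file.path(out, "screening.csv"),
                   row.names = FALSE)
  summary$n_included <- sum(prep$reports$included)
  log_stage(log_path, "[preprocess] %d/%d recordings included",
            summary$n_included, nrow(prep$reports))
  if (summary$n_included == 0) stop("preprocess: no recording passed screening")

  fmc <- config$featuremap
  maps <- extract_cohort_maps(prep$clean, cohort$roster, out_dir = NULL,
                              win_s = fmc$win_s, size = fmc$size,
                              clip_uv = fmc$clip_uv)
  utils::write.csv(maps$manifest, file.path(out, "manifest.csv"),
                   row.names = FALSE)
  summary$n_images <- nrow(maps$manifest)
  log_stage(log_path, "[featurize] %d feature maps (%dx%d)",
            summary$n_images, fmc$size, fmc$size)

  cnn_cfg <- do.call(cnn_config_reduced,
                     utils::modifyList(config$cnn, list(input = fmc$size)))
  for (task in config$tasks) {
    ev <- evaluate_task(maps$manifest, maps$images, task = task,
                        config = cnn_cfg,
                        seed = derive_seed(config$seed, paste0("eval:", task)),
                        unit = config$split_unit, n_boot = config$n_boot)
    utils::write.csv(ev$per_fold,
                     file.path(out, sprintf("metrics_%s_folds.csv", task)),
                     row.names = FALSE)
    utils::write.csv(ev$scores,
                     file.path(out, sprintf("scores_%s.csv", task)),
                     row.names = FALSE)
    utils::write.csv(ev$roc, file.path(out, sprintf("roc_%s.csv", task)),
                     row.names = FALSE)
    pooled <- ev$pooled
    summary[[paste0(task, "_auc")]] <- pooled$auc
    summary[[paste0(task, "_auc_ci")]] <- pooled$auc_ci
    summary[[paste0(task, "_accuracy")]] <- pooled$accuracy
    summary[[paste0(task, "_f1")]] <- pooled$f1
    log_stage(log_path, "[evaluate:%s] pooled AUC %.3f accuracy %.3f",
              task, pooled$auc, pooled$accuracy)
    if (task == "severity") {
      subj <- subject_ai_scores(ev$scores, maps$manifest)
      cors <- correlate_scales(subj, cohort$roster)
      utils::write.csv(cors, file.path(out, "correlations.csv"),
                       row.names = FALSE)
      utils::write.csv(subj, file.path(out, "subject_ai_scores.csv"),
                       row.names = FALSE)
      sds_row <- cors[cors$scale == "sds", ]
      summary$rho_ai_sds <- sds_row$rho
      log_stage(log_path, "[correlate] rho(AI score, SDS) = %.3f", sds_row$rho)
    }
  }
  jsonlite::write_json(summary, file.path(out, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary)
}
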