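#' Run the end-to-end test-dose workflow
#'
#' Executes the full study pipeline from a single configuration:
#' \enumerate{
#'   \item calibrate the per-phenotype virtual populations to the PK
#'     targets;
#'   \item simulate the per-phenotype training cohorts (default 10 trials
#'     of 500 subjects each per phenotype) at the candidate sampling
#'     times;
#'   \item fit the Bayesian classifier at every candidate time and compute
#'     the per-phenotype ROC operating points (in-sample by default, the
#'     development-time view; \code{eval_mode = "held_out"} scores an
#'     independent mixed cohort instead);
#'   \item select the sampling time maximizing the target phenotype's
#'     Youden J;
#'   \item simulate a blinded mixed verification cohort (default 100
#'     subjects at the normalized 46/38/26 EM/IM/PM frequencies) and
#'     evaluate the optimal-time model on it, joining truths only for
#'     scoring;
#'   \item summarize PK on a dense-grid 10x30 cohort per phenotype.
#' }
#' When \code{out_dir} is given, the resolved configuration, cohort and
#' result CSVs, the model JSON and the two diagnostic figures (posterior
#' curve; concentration-time bands) are written there; outputs are a
#' deterministic function of the configuration and seed.
#'
#' @param config Configuration list, see [default_run_config()] /
#'   [read_run_config()].
#' @param out_dir Optional output directory (created if needed).
#' @param quiet Suppress stage messages.
#' @return An \code{efv_pipeline} list: \code{specs}, \code{models} (one
#'   per time), \code{roc}, \code{optimal_time}, \code{model} (at the
#'   optimal time), \code{verification} (cohort, truth, evaluation),
#'   \code{pk_summary}, \code{config}.
#' @export
run_pipeline <- function(config = default_run_config(), out_dir = NULL,
                         quiet = FALSE) {
  cfg <- validate_run_config(config)
  say <- function(...) if (!quiet) message("[efvphen] ", ...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  say("calibrating populations")
  specs <- stage("calibrate",
                 calibrate_population(cfg$targets, dose = cfg$dose,
                                      cv_v = cfg$cv_v, cv_ka = cfg$cv_ka,
                                      mean_ka = cfg$mean_ka))

  say("simulating training cohorts (", cfg$train_trials, " x ", cfg$train_n,
      " per phenotype)")
  training <- stage("simulate_training", {
    parts <- lapply(seq_along(phenotype_levels()), function(i)
      simulate_cohort(specs, dose = cfg$dose, times = cfg$sampling_times,
                      n_trials = cfg$train_trials, n_per_trial = cfg$train_n,
                      phenotype_mix = phenotype_levels()[i],
                      seed = child_seed(cfg$seed, 0, i)))
    for (i in seq_along(parts))
      parts[[i]]$subject_id <- paste0(phenotype_levels()[i], "_",
                                      parts[[i]]$subject_id)
    out <- do.call(rbind, parts)
    attr(out, "seed") <- cfg$seed
    class(out) <- c("efv_cohort", "data.frame")
    out
  })
  say("training records: ", nrow(training))

  models <- stage("fit_models",
                  lapply(stats::setNames(cfg$sampling_times,
                                         paste0("t", cfg$sampling_times)),
                         function(tt)
                           efv_bayes(training, time = tt,
                                     bin_width = cfg$bin_width,
                                     priors = cfg$priors,
                                     smoothing = cfg$smoothing)))

  say("computing ROC over times (", cfg$eval_mode, ")")
  roc_eval <- if (cfg$eval_mode == "in_sample") training else
    stage("simulate_roc_eval",
          simulate_cohort(specs, dose = cfg$dose, times = cfg$sampling_times,
                          n_trials = 1, n_per_trial = cfg$verify_n,
                          phenotype_mix = cfg$phenotype_freq,
                          seed = child_seed(cfg$seed, 0, 17)))
  roc <- stage("roc",
               roc_over_times(training, roc_eval, times = cfg$sampling_times,
                              bin_width = cfg$bin_width, priors = cfg$priors,
                              smoothing = cfg$smoothing))
  optimal_time <- stage("select_time",
                        select_optimal_time(roc, cfg$target_phenotype))
  say("optimal sampling time for ", cfg$target_phenotype, ": ",
      optimal_time, " h")
  model <- models[[paste0("t", optimal_time)]]

  say("simulating blinded verification cohort (", cfg$verify_trials, " x ",
      cfg$verify_n, ", mixed)")
  verification <- stage("simulate_verification",
                        simulate_cohort(specs, dose = cfg$dose,
                                        times = cfg$sampling_times,
                                        n_trials = cfg$verify_trials,
                                        n_per_trial = cfg$verify_n,
                                        phenotype_mix = cfg$phenotype_freq,
                                        seed = child_seed(cfg$seed, 0, 99)))
  truth <- unique(verification[, c("subject_id", "phenotype")])
  evaluation <- stage("evaluate",
                      evaluate_cohort(model, verification, truth))

  say("dense-grid PK summary (10 x 30 per phenotype)")
  dense_times <- seq(0, cfg$dense_end, by = cfg$dense_step)
  pk_summary <- stage("pk_summary", {
    parts <- lapply(seq_along(phenotype_levels()), function(i)
      simulate_cohort(specs, dose = cfg$dose, times = dense_times,
                      n_trials = 10, n_per_trial = 30,
                      phenotype_mix = phenotype_levels()[i],
                      seed = child_seed(cfg$seed, 0, 30 + i)))
    dense <- do.call(rbind, lapply(seq_along(parts), function(i) {
      parts[[i]]$subject_id <- paste0(phenotype_levels()[i], "_",
                                      parts[[i]]$subject_id)
      parts[[i]]
    }))
    attr(dense, "dose") <- cfg$dose
    class(dense) <- c("efv_cohort", "data.frame")
    list(summary = summarize_pk(dense, dose = cfg$dose), dense = dense)
  })

  result <- structure(
    list(specs = specs, models = models, roc = roc,
         optimal_time = optimal_time, model = model,
         verification = list(cohort = verification, truth = truth,
                             evaluation = evaluation),
         pk_summary = pk_summary$summary, config = cfg),
    class = "efv_pipeline")

  if (!is.null(out_dir)) {
    say("writing outputs to ", out_dir)
    stage("write_outputs",
          write_pipeline_outputs(result, pk_summary$dense, out_dir))
  }
  result
}

#' @keywords internal
write_pipeline_outputs <- function(result, dense, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- result$config
  cfg_out <- cfg
  cfg_out$targets <- split(cfg$targets[, -1], cfg$targets$phenotype)
  yaml::write_yaml(cfg_out, file.path(out_dir, "config.yaml"))

  fmt <- function(x, p = 4) formatC(round(x, p), format = "fg")
  roc <- result$roc
  roc$tpr <- round(roc$tpr, 4); roc$fpr <- round(roc$fpr, 4)
  roc$youden_j <- round(roc$youden_j, 4)
  utils::write.csv(roc, file.path(out_dir, "roc.csv"), row.names = FALSE,
                   quote = FALSE)

  write_cohort_csv(result$verification$cohort,
                   file.path(out_dir, "verification_cohort.csv"))
  utils::write.csv(result$verification$truth,
                   file.path(out_dir, "verification_truth.csv"),
                   row.names = FALSE, quote = FALSE)
  calls <- result$verification$evaluation$calls
  for (nm in c("p_EM", "p_IM", "p_PM")) calls[[nm]] <- round(calls[[nm]], 4)
  calls$conc_ng_ml <- round(calls$conc_ng_ml, 1)
  utils::write.csv(calls, file.path(out_dir, "calls.csv"),
                   row.names = FALSE, quote = FALSE)

  cm <- result$verification$evaluation$confusion
  conf <- data.frame(true = rownames(unclass(cm)),
                     round(attr(cm, "prob"), 4))
  utils::write.csv(conf, file.path(out_dir, "confusion.csv"),
                   row.names = FALSE, quote = FALSE)
  perf <- result$verification$evaluation$performance
  for (nm in c("tpr", "tnr", "fpr")) perf[[nm]] <- round(perf[[nm]], 4)
  utils::write.csv(perf, file.path(out_dir, "performance.csv"),
                   row.names = FALSE, quote = FALSE)

  pk <- result$pk_summary
  for (nm in c("mean", "lo", "hi")) pk[[nm]] <- round(pk[[nm]], 1)
  utils::write.csv(pk, file.path(out_dir, "pk_summary.csv"),
                   row.names = FALSE, quote = FALSE)

  write_efv_bayes(result$model, file.path(out_dir, "model.json"))

  grDevices::pdf(file.path(out_dir, "posterior_curve.pdf"), width = 7,
                 height = 5)
  plot(result$model)
  grDevices::dev.off()

  grDevices::pdf(file.path(out_dir, "concentration_time.pdf"), width = 7,
                 height = 5)
  plot_concentration_bands(dense)
  grDevices::dev.off()
  invisible(out_dir)
}

#' Concentration-time plot with 5th/95th percentile bands
#'
#' Per phenotype, the population mean profile with a 5-95 percentile band
#' across subjects — the visual-predictive-check style display used to
#' judge whether observed concentrations fall inside the simulated spread.
#'
#' @param cohort A labelled dense-grid \code{efv_cohort}.
#' @param log_y Plot the concentration axis on a log scale.
#' @export
plot_concentration_bands <- function(cohort, log_y = FALSE) {
  assert_cohort(cohort)
  times <- sort(unique(cohort$time_h))
  cols <- stats::setNames(c("#1b9e77", "#7570b3", "#d95f02"),
                          phenotype_levels())
  stats_ph <- lapply(phenotype_levels(), function(ph) {
    sub <- cohort[cohort$phenotype == ph, ]
    list(mean = tapply(sub$conc_ng_ml, sub$time_h, mean),
         lo = tapply(sub$conc_ng_ml, sub$time_h, stats::quantile, 0.05),
         hi = tapply(sub$conc_ng_ml, sub$time_h, stats::quantile, 0.95))
  })
  ymax <- max(unlist(lapply(stats_ph, `[[`, "hi")))
  graphics::plot(NA, xlim = range(times),
                 ylim = c(if (log_y) 1 else 0, ymax),
                 log = if (log_y) "y" else "",
                 xlab = "Time (h)", ylab = "Concentration (ng/mL)",
                 main = "Simulated efavirenz profiles (mean, 5-95% band)")
  for (i in seq_along(phenotype_levels())) {
    s <- stats_ph[[i]]; col <- cols[i]
    graphics::polygon(c(times, rev(times)), c(s$lo, rev(s$hi)),
                      col = grDevices::adjustcolor(col, 0.2), border = NA)
    graphics::lines(times, s$mean, col = col, lwd = 2)
  }
  graphics::legend("topright", legend = phenotype_levels(), lwd = 2,
                   col = cols, bty = "n")
  invisible(NULL)
}

#' @export
print.efv_pipeline <- function(x, ...) {
  cat("efavirenz test-dose pipeline\n")
  cat("  optimal sampling time (", x$config$target_phenotype, "): ",
      x$optimal_time, " h\n", sep = "")
  r <- x$roc[x$roc$phenotype == x$config$target_phenotype, ]
  cat("  ", x$config$target_phenotype, " Youden J by time: ",
      paste(sprintf("%gh=%.3f", r$time_h, r$youden_j), collapse = ", "),
      "\n", sep = "")
  cat("\nBlinded verification (n = ",
      length(unique(x$verification$cohort$subject_id)), "):\n", sep = "")
  print(x$verification$evaluation)
  invisible(x)
}
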