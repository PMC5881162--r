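#' Read and write cohort CSV files
#'
#' The interchange format for cohorts is a strict CSV with mandatory
#' header \code{subject_id,phenotype,time_h,conc_ng_ml}; phenotype is one
#' of EM/IM/PM or NA (unlabelled, e.g. a blinded cohort). Rows with
#' missing or negative concentrations, negative times, unknown phenotype
#' tokens or duplicated (subject, time) pairs are rejected with their row
#' number. Writing then reading a cohort reproduces it.
#'
#' @param path CSV file path.
#' @return \code{read_cohort_csv}: an \code{efv_cohort} data.frame.
#' @export
read_cohort_csv <- function(path) {
  header <- utils::read.csv(path, nrows = 1, header = FALSE,
                            colClasses = "character")
  need <- c("subject_id", "phenotype", "time_h", "conc_ng_ml")
  if (ncol(header) < 4 || !all(unlist(header[1, seq_len(4)]) == need))
    stop("cohort CSV must start with header ", paste(need, collapse = ","))
  x <- utils::read.csv(path, colClasses = c(subject_id = "character",
                                            phenotype = "character"))
  rown <- function(i) paste(i + 1, collapse = ", ")  # +1 for header line
  bad <- which(is.na(x$conc_ng_ml))
  if (length(bad)) stop("missing concentration at row(s) ", rown(bad))
  bad <- which(x$conc_ng_ml < 0)
  if (length(bad)) stop("negative concentration at row(s) ", rown(bad))
  bad <- which(is.na(x$time_h) | x$time_h < 0)
  if (length(bad)) stop("missing/negative time at row(s) ", rown(bad))
  bad <- which(!is.na(x$phenotype) & !x$phenotype %in% phenotype_levels())
  if (length(bad))
    stop("unknown phenotype token at row(s) ", rown(bad), ": ",
         paste(unique(x$phenotype[bad]), collapse = ", "))
  dup <- which(duplicated(paste(x$subject_id, x$time_h)))
  if (length(dup)) stop("duplicate (subject, time) at row(s) ", rown(dup))
  structure(x, class = c("efv_cohort", "data.frame"))
}

#' @rdname read_cohort_csv
#' @param cohort An \code{efv_cohort} or compatible data.frame.
#' @return \code{write_cohort_csv}: \code{path}, invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  assert_cohort(cohort)
  if (!"phenotype" %in% names(cohort)) cohort$phenotype <- NA_character_
  out <- data.frame(subject_id = cohort$subject_id,
                    phenotype = as.character(cohort$phenotype),
                    time_h = cohort$time_h,
                    conc_ng_ml = cohort$conc_ng_ml)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}

#' Default run configuration for the end-to-end pipeline
#'
#' All tunables of the workflow in one list: the 600 mg test dose, the
#' candidate sampling times, histogram bin width and smoothing, uniform
#' phenotype priors, the trial-replicate designs (10x500 per phenotype
#' for classifier development, one trial of 100 mixed subjects for
#' blinded verification), the Caucasian phenotype frequencies used for
#' the verification mix (46/38/26, normalized), the calibration targets,
#' between-subject CVs of volume and absorption, and the master seed.
#'
#' @return Named list of configuration values.
#' @export
default_run_config <- function() {
  list(
    dose = 600,
    sampling_times = c(2, 4, 8, 12, 24),
    bin_width = 100,
    smoothing = 0.5,
    priors = c(EM = 1, IM = 1, PM = 1) / 3,
    train_trials = 10, train_n = 500,
    verify_trials = 1, verify_n = 100,
    phenotype_freq = c(EM = 46, IM = 38, PM = 26),
    targets = efv_pk_targets(),
    cv_v = 0.25, cv_ka = 0.30, mean_ka = 0.6,
    dense_step = 0.5, dense_end = 72,
    eval_mode = "in_sample",
    target_phenotype = "PM",
    seed = 2018
  )
}

#' Read a run configuration from a YAML file
#'
#' Keys absent from the file keep their [default_run_config()] values;
#' the merged configuration is validated before use. \code{targets} may
#' be given as a list of per-phenotype \code{mean_cl}, \code{mean_auc},
#' \code{mean_cmax} entries.
#'
#' @param path YAML file.
#' @return Validated configuration list.
#' @export
read_run_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- default_run_config()
  for (nm in names(user)) {
    if (nm == "targets") {
      tg <- do.call(rbind, lapply(names(user$targets), function(ph)
        data.frame(phenotype = ph,
                   mean_cl = user$targets[[ph]]$mean_cl,
                   mean_auc = user$targets[[ph]]$mean_auc,
                   mean_cmax = user$targets[[ph]]$mean_cmax)))
      cfg$targets <- tg
    } else if (nm %in% c("priors", "phenotype_freq")) {
      cfg[[nm]] <- unlist(user[[nm]])
    } else cfg[[nm]] <- if (length(user[[nm]]) > 1) unlist(user[[nm]])
    else user[[nm]]
  }
  validate_run_config(cfg)
}

#' @keywords internal
validate_run_config <- function(cfg) {
  stopifnot(cfg$dose > 0, length(cfg$sampling_times) >= 1,
            cfg$bin_width > 0, cfg$smoothing >= 0,
            cfg$train_trials >= 1, cfg$train_n >= 1,
            cfg$verify_trials >= 1, cfg$verify_n >= 1,
            cfg$dense_step > 0, cfg$dense_end >= 72,
            cfg$eval_mode %in% c("in_sample", "held_out"),
            cfg$target_phenotype %in% phenotype_levels())
  cfg$priors <- normalize_priors(cfg$priors)
  if (is.null(names(cfg$phenotype_freq)) ||
      !all(names(cfg$phenotype_freq) %in% phenotype_levels()))
    stop("phenotype_freq must be named over EM/IM/PM")
  cfg
}
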