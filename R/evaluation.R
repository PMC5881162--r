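#' Confusion matrix of phenotype calls
#'
#' Tallies predicted against true phenotypes as a 3x3 count matrix (rows:
#' true EM/IM/PM, columns: predicted) with a row-normalized probability
#' view — the probability of each predicted phenotype given the true one.
#'
#' @param truth True phenotype per subject (EM/IM/PM).
#' @param predicted Predicted phenotype per subject, same length.
#' @return An \code{efv_confusion} object: the count matrix, with the
#'   row-normalized matrix as attribute \code{prob} (rows with zero count
#'   are NA and flagged in attribute \code{undefined_rows}).
#' @export
confusion_matrix <- function(truth, predicted) {
  if (length(truth) != length(predicted))
    stop("truth and predicted must have equal length")
  if (anyNA(truth))
    stop("missing truth for subject(s) at position(s): ",
         paste(which(is.na(truth)), collapse = ", "))
  counts <- table(true = as_phenotype(truth),
                  predicted = as_phenotype(predicted))
  counts <- unclass(counts)
  rs <- rowSums(counts)
  prob <- counts / ifelse(rs > 0, rs, NA)
  structure(counts, class = "efv_confusion", prob = prob,
            undefined_rows = rownames(counts)[rs == 0])
}

#' @export
print.efv_confusion <- function(x, ...) {
  cat("Confusion matrix (counts), true x predicted:\n")
  print(unclass(x)[, , drop = FALSE])
  cat("\nRow-normalized P(predicted | true):\n")
  print(round(attr(x, "prob"), 4))
  ud <- attr(x, "undefined_rows")
  if (length(ud))
    cat("rows with zero subjects (probabilities undefined):",
        paste(ud, collapse = ", "), "\n")
  invisible(x)
}

#' Per-phenotype sensitivity and specificity
#'
#' From a confusion matrix, computes for each phenotype the true-positive
#' probability P(+|+) (subjects of that phenotype called correctly / all
#' subjects of that phenotype), the true-negative probability P(-|-)
#' (subjects of other phenotypes not called as it / all subjects of other
#' phenotypes) and the false-positive probability P(+|-) = 1 - P(-|-).
#' Computed directly from integer counts, so the identities hold exactly.
#'
#' @param cm An [confusion_matrix()] result.
#' @return An \code{efv_performance} data.frame with columns
#'   \code{phenotype}, \code{n_true}, \code{n_not_true}, \code{tpr},
#'   \code{tnr}, \code{fpr}. Phenotypes with zero true subjects get
#'   \code{NA} sensitivity and are flagged in attribute
#'   \code{undefined}.
#' @export
sensitivity_specificity <- function(cm) {
  stopifnot(inherits(cm, "efv_confusion"))
  counts <- unclass(cm)
  n <- sum(counts)
  rows <- lapply(phenotype_levels(), function(ph) {
    n_true <- sum(counts[ph, ])
    n_not <- n - n_true
    tp <- counts[ph, ph]
    fp <- sum(counts[, ph]) - tp
    data.frame(phenotype = ph,
               n_true = n_true, n_not_true = n_not,
               tpr = if (n_true > 0) tp / n_true else NA_real_,
               tnr = if (n_not > 0) (n_not - fp) / n_not else NA_real_,
               # complement taken after the division so fpr + tnr is
               # exactly 1
               fpr = if (n_not > 0) 1 - (n_not - fp) / n_not else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  structure(out, class = c("efv_performance", "data.frame"),
            undefined = out$phenotype[out$n_true == 0])
}

#' @export
print.efv_performance <- function(x, digits = 4, ...) {
  cat("Per-phenotype performance: P(+|+) = tpr, P(-|-) = tnr,",
      "P(+|-) = fpr\n")
  print.data.frame(x, digits = digits, row.names = FALSE)
  ud <- attr(x, "undefined")
  if (length(ud))
    cat("sensitivity undefined (no true subjects):",
        paste(ud, collapse = ", "), "\n")
  invisible(x)
}

#' ROC operating points across candidate sampling times
#'
#' For each candidate sampling time, fits the classifier on the training
#' cohort at that time only, classifies the evaluation cohort's records at
#' the same time, and records each phenotype's true-positive and
#' false-positive probabilities plus Youden's J (tpr - fpr). Plotting
#' tpr against fpr per phenotype across times gives the ROC from which the
#' optimal sampling time is read.
#'
#' @param training Labelled training cohort containing all \code{times}.
#' @param eval_cohort Labelled evaluation cohort containing all
#'   \code{times} (pass the training cohort itself for in-sample,
#'   development-time probabilities).
#' @param times Candidate sampling times, h.
#' @param bin_width,priors,smoothing Classifier settings, see
#'   [efv_bayes()].
#' @return An \code{efv_roc} data.frame: \code{time_h}, \code{phenotype},
#'   \code{tpr}, \code{fpr}, \code{youden_j}.
#' @export
roc_over_times <- function(training, eval_cohort, times = c(2, 4, 8, 12, 24),
                           bin_width = 100,
                           priors = c(EM = 1, IM = 1, PM = 1) / 3,
                           smoothing = 0.5) {
  assert_cohort(training); assert_cohort(eval_cohort)
  for (nm in c("training", "eval_cohort")) {
    x <- get(nm)
    miss <- setdiff(times, unique(x$time_h))
    if (length(miss))
      stop(nm, " is missing sampling time(s): ", paste(miss, collapse = ", "))
  }
  rows <- lapply(times, function(tt) {
    fit <- efv_bayes(training, time = tt, bin_width = bin_width,
                     priors = priors, smoothing = smoothing)
    ev <- eval_cohort[eval_cohort$time_h == tt, , drop = FALSE]
    calls <- predict(fit, ev)
    perf <- sensitivity_specificity(
      confusion_matrix(ev$phenotype, calls$predicted))
    data.frame(time_h = tt, phenotype = perf$phenotype,
               tpr = perf$tpr, fpr = perf$fpr,
               youden_j = perf$tpr - perf$fpr,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  structure(out, class = c("efv_roc", "data.frame"))
}

#' Optimal sampling time for one phenotype
#'
#' Selects, among the ROC operating points of the target phenotype, the
#' sampling time maximizing Youden's J; exact ties go to the later time
#' (a later draw is logistically no harder and better separated upstream).
#'
#' @param roc An [roc_over_times()] result.
#' @param target_phenotype Phenotype whose identification is optimized
#'   (default PM, the clinically critical call).
#' @return Sampling time in h.
#' @export
select_optimal_time <- function(roc, target_phenotype = "PM") {
  stopifnot(is.data.frame(roc),
            all(c("time_h", "phenotype", "youden_j") %in% names(roc)))
  r <- roc[roc$phenotype == target_phenotype & !is.na(roc$youden_j), ]
  if (nrow(r) == 0) stop("no ROC points for phenotype ", target_phenotype)
  best <- r$youden_j >= max(r$youden_j) - 1e-12
  max(r$time_h[best])
}

#' Blinded evaluation of a fitted classifier on a cohort
#'
#' Classifies every subject of a cohort from its concentration at the
#' model's sampling time without consulting phenotype labels; truths,
#' supplied separately and keyed by subject, are joined only afterwards to
#' score the calls. The call table is therefore identical whether or not
#' truths exist — the blinding the verification procedure requires.
#'
#' @param object An [efv_bayes()] fit (or a path to a JSON model from
#'   [write_efv_bayes()]).
#' @param cohort Cohort to classify; phenotype labels, if present, are
#'   ignored.
#' @param truth data.frame with columns \code{subject_id} and
#'   \code{phenotype}.
#' @return An \code{efv_evaluation} list: \code{calls} (per-subject call
#'   table), \code{confusion}, \code{performance}.
#' @export
evaluate_cohort <- function(object, cohort, truth) {
  if (is.character(object)) object <- read_efv_bayes(object)
  stopifnot(inherits(object, "efv_bayes"))
  assert_cohort(cohort)
  blind <- cohort[, setdiff(names(cohort), "phenotype"), drop = FALSE]
  calls <- predict(object, blind)
  if (!all(c("subject_id", "phenotype") %in% names(truth)))
    stop("truth needs subject_id and phenotype columns")
  idx <- match(calls$subject_id, truth$subject_id)
  if (anyNA(idx))
    stop("subjects missing from truth file: ",
         paste(unique(calls$subject_id[is.na(idx)]), collapse = ", "))
  truths <- truth$phenotype[idx]
  cm <- confusion_matrix(truths, calls$predicted)
  structure(list(calls = calls, confusion = cm,
                 performance = sensitivity_specificity(cm)),
            class = "efv_evaluation")
}

#' @export
print.efv_evaluation <- function(x, ...) {
  print(x$confusion)
  cat("\n")
  print(x$performance)
  invisible(x)
}
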