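#' Noncompartmental PK summary of a dense-grid cohort
#'
#' Computes per-subject AUC(0-inf), Cmax and apparent clearance from a
#' cohort simulated (or observed) on a common dense time grid, then
#' summarizes per phenotype: the population mean over all subjects and a
#' 2.5-97.5 percentile interval of the per-trial means.
#'
#' Per subject: Cmax is the profile maximum; AUC(0-t_last) by linear
#' trapezoid; the terminal slope lambda_z by log-linear regression over
#' the tail of the grid (times at or beyond \code{lambda_z_from}); AUC to
#' infinity adds \code{C_last / lambda_z}; CL = dose / AUC(0-inf).
#'
#' When an \code{observed} reference table is supplied, predicted:observed
#' ratios are reported; a ratio within two-fold (0.5 to 2) is the accepted
#' prediction-error band.
#'
#' @param cohort An \code{efv_cohort} on a dense grid spanning at least
#'   0-72 h, with a \code{phenotype} column and at least two trials.
#' @param dose Dose in mg (taken from the cohort attribute by default).
#' @param observed Optional data.frame with columns \code{phenotype},
#'   \code{parameter} (one of \code{"auc_inf"}, \code{"cmax"},
#'   \code{"cl"}) and \code{observed} (mean reference value).
#' @param lambda_z_from Earliest time (h) entering the terminal-slope
#'   regression.
#' @return An \code{efv_pk_summary} data.frame: one row per phenotype and
#'   parameter (\code{auc_inf} in ug.h/mL, \code{cmax} in ng/mL, \code{cl}
#'   in L/h) with columns \code{mean}, \code{lo}, \code{hi}, and, when
#'   references are given, \code{observed}, \code{ratio},
#'   \code{acceptable}.
#' @export
summarize_pk <- function(cohort, dose = attr(cohort, "dose"),
                         observed = NULL, lambda_z_from = 48) {
  assert_cohort(cohort)
  if (!"phenotype" %in% names(cohort) || anyNA(cohort$phenotype))
    stop("summarize_pk needs labelled phenotypes")
  if (is.null(dose)) stop("dose is unknown; pass it explicitly")
  times <- sort(unique(cohort$time_h))
  if (min(times) > 0 || max(times) < 72)
    stop("dense grid must span 0-72 h; got ",
         min(times), "-", max(times), " h")
  if (!"trial" %in% names(cohort))
    cohort$trial <- 1L
  if (length(unique(cohort$trial)) < 2)
    stop("intervals need at least 2 trials")

  ord <- order(cohort$subject_id, cohort$time_h)
  x <- cohort[ord, ]
  n_t <- length(times)
  if (nrow(x) %% n_t != 0)
    stop("cohort is not a complete common time grid")
  n_subj <- nrow(x) / n_t
  if (!all(x$time_h == rep(times, times = n_subj)))
    stop("cohort is not a complete common time grid")

  conc <- matrix(x$conc_ng_ml, nrow = n_t)      # times x subjects
  subj_rows <- seq(1, nrow(x), by = n_t)
  pheno <- x$phenotype[subj_rows]
  trial <- x$trial[subj_rows]

  cmax <- apply(conc, 2, max)
  dt <- diff(times)
  auc_last <- as.vector(dt %*% (conc[-n_t, , drop = FALSE] +
                                  conc[-1, , drop = FALSE])) / 2

  # terminal slope by common-grid log-linear regression
  tail_idx <- which(times >= lambda_z_from)
  if (length(tail_idx) < 3)
    stop("need at least 3 grid points at or beyond ", lambda_z_from, " h")
  tt <- times[tail_idx]
  logc <- log(pmax(conc[tail_idx, , drop = FALSE], 1e-12))
  tc <- tt - mean(tt)
  lambda_z <- -as.vector(tc %*% logc) / sum(tc^2)
  if (any(lambda_z <= 0))
    stop("non-positive terminal slope for ", sum(lambda_z <= 0), " subject(s)")
  auc_inf <- (auc_last + conc[n_t, ] / lambda_z) / 1000  # ug.h/mL
  cl <- dose / auc_inf

  per_subj <- data.frame(subject_id = x$subject_id[subj_rows],
                         phenotype = pheno, trial = trial,
                         auc_inf = auc_inf, cmax = cmax, cl = cl,
                         stringsAsFactors = FALSE)

  rows <- list()
  for (ph in intersect(phenotype_levels(), unique(pheno))) {
    sub <- per_subj[per_subj$phenotype == ph, ]
    for (par in c("auc_inf", "cmax", "cl")) {
      trial_means <- tapply(sub[[par]], sub$trial, mean)
      ci <- stats::quantile(trial_means, c(0.025, 0.975), names = FALSE)
      rows[[length(rows) + 1]] <- data.frame(
        phenotype = ph, parameter = par,
        mean = mean(sub[[par]]), lo = ci[1], hi = ci[2],
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)

  if (!is.null(observed)) {
    key <- paste(out$phenotype, out$parameter)
    okey <- paste(observed$phenotype, observed$parameter)
    out$observed <- observed$observed[match(key, okey)]
    out$ratio <- out$mean / out$observed
    out$acceptable <- !is.na(out$ratio) & out$ratio >= 0.5 & out$ratio <= 2
  }
  structure(out, class = c("efv_pk_summary", "data.frame"),
            per_subject = per_subj)
}

#' @export
print.efv_pk_summary <- function(x, digits = 4, ...) {
  cat("PK summary (mean and 2.5-97.5% interval of trial means)\n")
  print.data.frame(x, digits = digits, row.names = FALSE)
  invisible(x)
}
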