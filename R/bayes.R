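#' Round a concentration to its histogram bin center
#'
#' Concentrations are discretized to the nearest multiple of
#' \code{bin_width} (default 100 ng/mL). Exact midpoints round up
#' (half-up), so 1250 with width 100 falls in the 1300 bin.
#'
#' @param concentration Concentration(s), ng/mL, non-negative.
#' @param bin_width Bin width, ng/mL, positive.
#' @return The bin center(s), a multiple of \code{bin_width}.
#' @export
#' @examples
#' bin_concentration(c(1234, 1250, 0))
bin_concentration <- function(concentration, bin_width = 100) {
  if (any(concentration < 0)) stop("concentration must be non-negative")
  if (bin_width <= 0) stop("bin_width must be positive")
  floor(concentration / bin_width + 0.5) * bin_width
}

#' Fit the empirical Bayesian phenotype classifier
#'
#' The central model of the package: at one sampling time, the conditional
#' probability of each binned concentration given each phenotype is the
#' empirical bin frequency in the training cohort,
#' \deqn{P(C \mid e_j) = \frac{\#\{\text{phenotype } e_j \text{ with binned
#'  concentration } C\}}{\#\{\text{phenotype } e_j\}},}
#' optionally smoothed with a pseudo-count spread over the union bin range
#' plus two guard bins at each end. Combined with phenotype priors via
#' Bayes' theorem this yields the posterior \eqn{P(e_j \mid C)} used for
#' maximum a posteriori phenotype calls.
#'
#' @param data Training data: a data.frame with columns \code{phenotype}
#'   and \code{conc_ng_ml} (and \code{time_h} when \code{time} is used to
#'   select records), e.g. an [simulate_cohort()] result.
#' @param time Sampling time (h) whose records are used; \code{NULL}
#'   takes all rows as-is.
#' @param bin_width Histogram bin width, ng/mL.
#' @param priors Named prior probabilities over EM/IM/PM; normalized
#'   internally. Default uniform: with equal-size training arms each
#'   phenotype is equally likely a priori.
#' @param smoothing Pseudo-count added to every bin of the grid (0.5 by
#'   default; 0 reproduces the raw count ratios exactly).
#' @return An object of class \code{efv_bayes} with components
#'   \code{sampling_time}, \code{bin_width}, \code{bins} (grid of bin
#'   centers incl. guard bins), \code{counts} and \code{likelihood}
#'   (bins x phenotypes matrices), \code{priors}, \code{smoothing},
#'   \code{n_train}, \code{provenance}.
#' @seealso [predict.efv_bayes()], [posterior_curve()],
#'   [phenotype_ranges()], [write_efv_bayes()]
#' @export
#' @examples
#' train <- data.frame(
#'   phenotype = rep(c("EM", "IM", "PM"), each = 3),
#'   conc_ng_ml = c(100, 240, 260, 420, 580, 600, 940, 1080, 1130))
#' fit <- efv_bayes(train, time = NULL, smoothing = 0)
#' predict(fit, 1100)
efv_bayes <- function(data, time = 24, bin_width = 100,
                      priors = c(EM = 1, IM = 1, PM = 1) / 3,
                      smoothing = 0.5) {
  stopifnot(is.data.frame(data), bin_width > 0, smoothing >= 0)
  if (!all(c("phenotype", "conc_ng_ml") %in% names(data)))
    stop("training data needs phenotype and conc_ng_ml columns")
  if (!is.null(time)) {
    if (!"time_h" %in% names(data))
      stop("time_h column required when selecting a sampling time")
    data <- data[data$time_h == time, , drop = FALSE]
    if (nrow(data) == 0) stop("no training records at time ", time, " h")
  }
  if (anyNA(data$phenotype))
    stop("unlabelled training records present")
  pheno <- as_phenotype(data$phenotype)
  missing_ph <- setdiff(phenotype_levels(), levels(droplevels(pheno)))
  if (length(missing_ph))
    stop("no training records for phenotype(s): ",
         paste(missing_ph, collapse = ", "),
         if (!is.null(time)) paste0(" at time ", time, " h"))

  priors <- normalize_priors(priors)
  binned <- bin_concentration(data$conc_ng_ml, bin_width)
  pop <- sort(unique(binned))
  # union bin range plus two guard bins each end (floored at 0)
  bins <- seq(max(0, min(pop) - 2 * bin_width), max(pop) + 2 * bin_width,
              by = bin_width)
  counts <- vapply(phenotype_levels(), function(ph) {
    tab <- tabulate(match(binned[pheno == ph], bins), nbins = length(bins))
    tab
  }, integer(length(bins)))
  rownames(counts) <- bins
  n_train <- colSums(counts)
  lik <- sweep(counts + smoothing, 2, n_train + smoothing * length(bins), "/")

  structure(list(sampling_time = time, bin_width = bin_width,
                 bins = bins, counts = counts, likelihood = lik,
                 priors = priors, smoothing = smoothing,
                 n_train = n_train,
                 provenance = list(seed = attr(data, "seed"),
                                   n_train = unname(sum(n_train)))),
            class = "efv_bayes")
}

#' @keywords internal
normalize_priors <- function(priors) {
  if (is.null(names(priors)) || !all(phenotype_levels() %in% names(priors)))
    stop("priors must be named over EM, IM, PM")
  priors <- priors[phenotype_levels()]
  if (any(priors < 0) || sum(priors) <= 0)
    stop("priors must be non-negative with positive sum")
  priors / sum(priors)
}

# Map concentrations to row indices of the model's bin grid; out-of-range
# values clamp to the bottom/top guard bin.
#' @keywords internal
bin_index <- function(object, concentration) {
  b <- bin_concentration(concentration, object$bin_width)
  b <- pmin(pmax(b, object$bins[1]), object$bins[length(object$bins)])
  match(b, object$bins)
}

#' Posterior phenotype probabilities and MAP calls
#'
#' Applies Bayes' theorem to one or more concentrations:
#' \eqn{P(e_j \mid C) \propto P(e_j) P(C \mid e_j)}, normalized over the
#' three phenotypes. \code{type = "class"} additionally takes the maximum
#' a posteriori call; exact posterior ties are broken toward the slower
#' metabolizer (PM over IM over EM) and flagged.
#'
#' With smoothing disabled a concentration can fall in a bin never seen in
#' training (all likelihoods zero, the posterior undefined); the call then
#' falls back to the nearest populated bin (distance in bins, ties toward
#' the higher concentration), so the classifier always returns a call.
#'
#' @param object An [efv_bayes()] fit.
#' @param newdata Numeric concentrations (ng/mL), or a data.frame with a
#'   \code{conc_ng_ml} column (records at the model's sampling time are
#'   selected when a \code{time_h} column is present).
#' @param type \code{"class"} for a call table, \code{"posterior"} for the
#'   bare posterior matrix.
#' @param ... Unused.
#' @return For \code{"class"}: a data.frame with \code{subject_id} (when
#'   available), \code{conc_ng_ml}, \code{predicted}, \code{p_EM},
#'   \code{p_IM}, \code{p_PM} and \code{tie_flag}. For
#'   \code{"posterior"}: an n x 3 matrix of posterior probabilities.
#' @export
predict.efv_bayes <- function(object, newdata, type = c("class", "posterior"),
                              ...) {
  type <- match.arg(type)
  subject_id <- NULL
  if (is.data.frame(newdata)) {
    if (!"conc_ng_ml" %in% names(newdata))
      stop("newdata needs a conc_ng_ml column")
    if ("time_h" %in% names(newdata) && !is.null(object$sampling_time)) {
      newdata <- newdata[newdata$time_h == object$sampling_time, ,
                         drop = FALSE]
      if (nrow(newdata) == 0)
        stop("no records at the model's sampling time ",
             object$sampling_time, " h")
    }
    if ("subject_id" %in% names(newdata)) subject_id <- newdata$subject_id
    conc <- newdata$conc_ng_ml
  } else conc <- as.numeric(newdata)
  if (any(is.na(conc))) stop("missing concentrations in newdata")

  idx <- bin_index(object, conc)
  lik <- object$likelihood[idx, , drop = FALSE]
  num <- sweep(lik, 2, object$priors, "*")
  tot <- rowSums(num)
  zero <- tot <= 0
  if (any(zero)) {
    populated <- which(rowSums(object$counts) > 0)
    for (i in which(zero)) {
      d <- abs(populated - idx[i])
      cand <- populated[d == min(d)]
      j <- max(cand)  # tie toward the higher concentration
      num[i, ] <- object$likelihood[j, ] * object$priors
      tot[i] <- sum(num[i, ])
    }
  }
  post <- num / tot
  colnames(post) <- phenotype_levels()
  if (type == "posterior") return(post)

  eps <- 1e-12
  is_max <- post >= apply(post, 1, max) - eps
  tie_flag <- rowSums(is_max) > 1
  # among tied maxima pick the slowest metabolizer: highest column index
  pick <- max.col(is_max, ties.method = "last")
  out <- data.frame(conc_ng_ml = conc,
                    predicted = phenotype_levels()[pick],
                    p_EM = post[, "EM"], p_IM = post[, "IM"],
                    p_PM = post[, "PM"], tie_flag = tie_flag,
                    stringsAsFactors = FALSE)
  if (!is.null(subject_id)) out <- cbind(subject_id = subject_id, out)
  rownames(out) <- NULL
  out
}

#' Posterior curve across the model's concentration bins
#'
#' Evaluates the posterior of each phenotype at every bin center of the
#' fitted grid — the model analogue of a posterior-probability-versus-
#' concentration figure.
#'
#' @param object An [efv_bayes()] fit.
#' @return An \code{efv_posterior_curve} data.frame: \code{bin} (center,
#'   ng/mL), \code{populated} (any training count in the bin), and
#'   posterior columns \code{p_EM}, \code{p_IM}, \code{p_PM} summing to 1
#'   per row.
#' @export
posterior_curve <- function(object) {
  stopifnot(inherits(object, "efv_bayes"))
  post <- predict(object, object$bins, type = "posterior")
  out <- data.frame(bin = object$bins,
                    populated = unname(rowSums(object$counts) > 0),
                    p_EM = unname(post[, "EM"]), p_IM = unname(post[, "IM"]),
                    p_PM = unname(post[, "PM"]))
  rownames(out) <- NULL
  structure(out, class = c("efv_posterior_curve", "data.frame"),
            sampling_time = object$sampling_time)
}

#' Concentration ranges assigned to each phenotype
#'
#' Partitions the fitted bin range into contiguous intervals by the MAP
#' call at each bin: the range of concentrations for which each phenotype
#' is the most likely call.
#'
#' @param object An [efv_bayes()] fit or an [posterior_curve()] result.
#' @return data.frame with columns \code{phenotype}, \code{from},
#'   \code{to} (bin centers, ng/mL), one row per contiguous run; every bin
#'   belongs to exactly one row.
#' @export
phenotype_ranges <- function(object) {
  if (inherits(object, "efv_bayes")) curve <- posterior_curve(object)
  else curve <- object
  if (!inherits(curve, "efv_posterior_curve") || nrow(curve) == 0)
    stop("need a non-empty posterior curve")
  post <- as.matrix(curve[, c("p_EM", "p_IM", "p_PM")])
  eps <- 1e-12
  call <- phenotype_levels()[max.col(post >= apply(post, 1, max) - eps,
                                     ties.method = "last")]
  r <- rle(call)
  hi <- cumsum(r$lengths)
  lo <- hi - r$lengths + 1
  data.frame(phenotype = r$values,
             from = curve$bin[lo], to = curve$bin[hi],
             stringsAsFactors = FALSE)
}

#' @export
print.efv_bayes <- function(x, ...) {
  cat("Empirical Bayesian phenotype classifier\n")
  cat("  sampling time:", if (is.null(x$sampling_time)) "(pooled)" else
    paste0(x$sampling_time, " h"), "\n")
  cat("  bin width:", x$bin_width, "ng/mL;",
      length(x$bins), "bins spanning", x$bins[1], "-",
      x$bins[length(x$bins)], "ng/mL\n")
  cat("  smoothing pseudo-count:", x$smoothing, "\n")
  cat("  priors:", paste(sprintf("%s=%.3f", names(x$priors), x$priors),
                         collapse = ", "), "\n")
  cat("  training counts:", paste(sprintf("%s=%d", names(x$n_train),
                                          x$n_train), collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.efv_bayes <- function(object, ...) {
  print(object)
  cat("\nMAP concentration ranges:\n")
  print(phenotype_ranges(object), row.names = FALSE)
  invisible(object)
}

#' @export
coef.efv_bayes <- function(object, ...) object$likelihood

#' Plot the posterior phenotype probabilities against concentration
#'
#' @param x An \code{efv_bayes} fit.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.efv_bayes <- function(x, ...) {
  curve <- posterior_curve(x)
  graphics::matplot(curve$bin, curve[, c("p_EM", "p_IM", "p_PM")],
                    type = "l", lty = 1, lwd = 2,
                    col = c("#1b9e77", "#7570b3", "#d95f02"),
                    xlab = "Concentration (ng/mL)",
                    ylab = "Posterior probability",
                    main = sprintf("Phenotype posterior at %s h",
                                   x$sampling_time), ...)
  graphics::legend("right", legend = phenotype_levels(), lty = 1, lwd = 2,
                   col = c("#1b9e77", "#7570b3", "#d95f02"), bty = "n")
  invisible(curve)
}

#' Simulate binned concentrations from the fitted conditional tables
#'
#' Draws concentrations (bin centers) from \eqn{P(C \mid e_j)} for a given
#' phenotype — useful for posterior-predictive style checks of the fitted
#' histogram model.
#'
#' @param object An \code{efv_bayes} fit.
#' @param nsim Number of draws.
#' @param seed Optional integer seed.
#' @param phenotype Which phenotype's conditional table to draw from.
#' @param ... Unused.
#' @return Numeric vector of bin centers, ng/mL.
#' @export
simulate.efv_bayes <- function(object, nsim = 1, seed = NULL,
                               phenotype = "PM", ...) {
  if (!is.null(seed)) set.seed(seed)
  p <- object$likelihood[, phenotype]
  sample(object$bins, nsim, replace = TRUE, prob = p)
}

#' Serialize / restore a fitted classifier as JSON
#'
#' The trained model is stored as plain JSON holding the bin grid, raw
#' counts, smoothed conditional probabilities, priors, smoothing,
#' sampling time, bin width and provenance, so a call made from a
#' restored model is bit-identical to one from the original.
#'
#' @param object An \code{efv_bayes} fit.
#' @param path File path for the JSON model.
#' @return \code{write_efv_bayes} returns \code{path} invisibly;
#'   \code{read_efv_bayes} returns the restored \code{efv_bayes} object.
#' @export
write_efv_bayes <- function(object, path) {
  stopifnot(inherits(object, "efv_bayes"))
  tables <- lapply(phenotype_levels(), function(ph)
    stats::setNames(as.list(object$likelihood[, ph]),
                    format(object$bins, scientific = FALSE, trim = TRUE)))
  names(tables) <- phenotype_levels()
  counts <- lapply(phenotype_levels(), function(ph)
    stats::setNames(as.list(object$counts[, ph]),
                    format(object$bins, scientific = FALSE, trim = TRUE)))
  names(counts) <- phenotype_levels()
  obj <- list(sampling_time_h = object$sampling_time,
              bin_width = object$bin_width,
              priors = as.list(object$priors),
              smoothing = object$smoothing,
              tables = tables, counts = counts,
              provenance = object$provenance)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_efv_bayes
#' @param path File path of a model written by \code{write_efv_bayes}.
#' @export
read_efv_bayes <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  bins <- as.numeric(names(obj$tables$EM))
  lik <- vapply(phenotype_levels(), function(ph)
    as.numeric(unlist(obj$tables[[ph]])), numeric(length(bins)))
  counts <- vapply(phenotype_levels(), function(ph)
    as.integer(unlist(obj$counts[[ph]])), integer(length(bins)))
  rownames(lik) <- rownames(counts) <- bins
  structure(list(sampling_time = obj$sampling_time_h,
                 bin_width = obj$bin_width,
                 bins = bins, counts = counts, likelihood = lik,
                 priors = normalize_priors(unlist(obj$priors)),
                 smoothing = obj$smoothing,
                 n_train = colSums(counts),
                 provenance = obj$provenance),
            class = "efv_bayes")
}
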