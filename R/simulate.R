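#' Plasma concentration of the one-compartment oral model
#'
#' Closed-form concentration after a single oral dose under first-order
#' absorption and elimination:
#' \deqn{C(t) = \frac{D k_a}{V (k_a - k)} (e^{-k t} - e^{-k_a t}), \quad
#'       k = CL/V,}
#' converted to ng/mL (dose in mg, volume in L). Vectorized over any
#' argument.
#'
#' @param dose Dose in mg.
#' @param cl Apparent oral clearance, L/h.
#' @param v Apparent volume of distribution, L.
#' @param ka First-order absorption rate constant, 1/h.
#' @param time Time after dose, h (non-negative).
#' @return Concentration(s) in ng/mL; 0 at \code{time = 0}.
#' @export
#' @examples
#' simulate_concentration(600, cl = 4.7, v = 250, ka = 0.6, time = 24)
simulate_concentration <- function(dose, cl, v, ka, time) {
  if (any(time < 0)) stop("time must be non-negative")
  if (any(cl <= 0) || any(v <= 0) || any(ka <= 0))
    stop("cl, v and ka must be strictly positive")
  k <- cl / v
  if (any(abs(ka - k) < 1e-9))
    stop("flip-flop degeneracy: ka equals cl/v")
  conc <- 1000 * dose * ka / (v * (ka - k)) * (exp(-k * time) - exp(-ka * time))
  pmax(conc, 0)
}

#' Draw individual PK parameters from a phenotype population spec
#'
#' Samples clearance, volume and absorption rate constant independently
#' from lognormal distributions with the spec's means and CVs. Draws for
#' which \code{cl/v} falls within 1e-6 of \code{ka} (the flip-flop
#' singularity of the closed form) are redrawn.
#'
#' @param spec One phenotype's element of an [calibrate_population()]
#'   result (a list with \code{mean_cl}, \code{cv_cl}, \code{mean_v},
#'   \code{cv_v}, \code{mean_ka}, \code{cv_ka}).
#' @param n Number of individuals.
#' @return data.frame with columns \code{cl}, \code{v}, \code{ka}.
#' @export
sample_individuals <- function(spec, n) {
  stopifnot(is.list(spec), n >= 1,
            spec$mean_cl > 0, spec$mean_v > 0, spec$mean_ka > 0,
            spec$cv_cl >= 0, spec$cv_v >= 0, spec$cv_ka >= 0)
  draw <- function(m) {
    pcl <- lognormal_pars(spec$mean_cl, spec$cv_cl)
    pv  <- lognormal_pars(spec$mean_v,  spec$cv_v)
    pka <- lognormal_pars(spec$mean_ka, spec$cv_ka)
    data.frame(cl = stats::rlnorm(m, pcl$meanlog, pcl$sdlog),
               v  = stats::rlnorm(m, pv$meanlog,  pv$sdlog),
               ka = stats::rlnorm(m, pka$meanlog, pka$sdlog))
  }
  out <- draw(n)
  bad <- abs(out$cl / out$v - out$ka) < 1e-6
  while (any(bad)) {
    out[bad, ] <- draw(sum(bad))
    bad <- abs(out$cl / out$v - out$ka) < 1e-6
  }
  out
}

# Deterministic child seed for (trial, phenotype-block) substreams, so
# adding trials never reshuffles earlier ones. Kept below 2^31.
#' @keywords internal
child_seed <- function(seed, trial, block = 0L) {
  (as.numeric(seed) + 100003 * trial + 7919 * block) %% 2147483629
}

# Largest-remainder allocation of n subjects to phenotype proportions.
#' @keywords internal
allocate_counts <- function(n, prop) {
  exact <- n * prop / sum(prop)
  base <- floor(exact)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(exact - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Simulate a multi-trial virtual cohort
#'
#' Generates \code{n_trials} replicate trials of \code{n_per_trial}
#' virtual subjects each, draws individual PK parameters from the
#' calibrated phenotype specs, and evaluates the plasma concentration at
#' every requested time. Phenotypes are either a single label (all
#' subjects share it) or a named proportion vector (normalized internally;
#' subjects allocated per trial by largest remainder, so the design is
#' reproducible). Sex is recorded as alternating F/M metadata (50\%
#' female designs); it does not enter the PK model.
#'
#' Each (trial, phenotype-mix) block uses a child RNG stream derived
#' deterministically from \code{seed}, so the same seed always yields the
#' identical cohort.
#'
#' @param specs An \code{efv_pop_spec} from [calibrate_population()].
#' @param dose Dose in mg.
#' @param times Sampling times in h (non-empty).
#' @param n_trials,n_per_trial Trial-replicate design.
#' @param phenotype_mix Either one of \code{"EM","IM","PM"} or a named
#'   numeric vector of proportions over the three phenotypes.
#' @param seed Integer master seed.
#' @return An \code{efv_cohort}: a data.frame with columns
#'   \code{subject_id}, \code{trial}, \code{phenotype}, \code{sex},
#'   \code{time_h}, \code{conc_ng_ml}, with the dose, design and seed as
#'   attributes.
#' @export
#' @examples
#' specs <- calibrate_population()
#' coh <- simulate_cohort(specs, times = c(2, 24), n_trials = 2,
#'                        n_per_trial = 10, phenotype_mix = "PM", seed = 1)
#' head(coh)
simulate_cohort <- function(specs, dose = attr(specs, "dose"),
                            times = c(2, 4, 8, 12, 24),
                            n_trials = 10, n_per_trial = 500,
                            phenotype_mix, seed) {
  stopifnot(inherits(specs, "efv_pop_spec"), length(times) >= 1,
            all(times >= 0), n_trials >= 1, n_per_trial >= 1)
  if (missing(phenotype_mix) || length(phenotype_mix) == 0)
    stop("phenotype_mix must be a phenotype label or a proportion vector")
  if (missing(seed)) stop("seed is required for reproducibility")

  if (is.character(phenotype_mix) && length(phenotype_mix) == 1) {
    prop <- stats::setNames(as.numeric(phenotype_levels() == phenotype_mix),
                            phenotype_levels())
    if (sum(prop) == 0) stop("unknown phenotype: ", phenotype_mix)
  } else {
    if (is.null(names(phenotype_mix)) ||
        !all(names(phenotype_mix) %in% phenotype_levels()))
      stop("phenotype_mix must be named with EM/IM/PM")
    prop <- stats::setNames(rep(0, 3), phenotype_levels())
    prop[names(phenotype_mix)] <- phenotype_mix
    if (any(prop < 0) || sum(prop) <= 0)
      stop("phenotype proportions must be non-negative and sum > 0")
  }

  trials <- lapply(seq_len(n_trials), function(tr) {
    counts <- allocate_counts(n_per_trial, prop)
    pheno <- rep(phenotype_levels(), counts)
    set.seed(child_seed(seed, tr))
    pars <- do.call(rbind, lapply(phenotype_levels()[counts > 0], function(ph)
      sample_individuals(specs[[ph]], sum(pheno == ph))))
    ids <- sprintf("T%02d_S%04d", tr, seq_len(n_per_trial))
    sex <- rep(c("F", "M"), length.out = n_per_trial)
    conc <- outer(seq_len(n_per_trial), seq_along(times),
                  function(i, j) simulate_concentration(
                    dose, pars$cl[i], pars$v[i], pars$ka[i], times[j]))
    data.frame(subject_id = rep(ids, times = length(times)),
               trial = tr,
               phenotype = rep(pheno, times = length(times)),
               sex = rep(sex, times = length(times)),
               time_h = rep(times, each = n_per_trial),
               conc_ng_ml = as.vector(conc),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, trials)
  rownames(out) <- NULL
  structure(out, class = c("efv_cohort", "data.frame"),
            dose = dose, design = c(trials = n_trials, n = n_per_trial),
            seed = seed)
}

#' @keywords internal
assert_cohort <- function(x) {
  need <- c("subject_id", "time_h", "conc_ng_ml")
  if (!all(need %in% names(x)))
    stop("cohort must have columns ", paste(need, collapse = ", "))
  invisible(x)
}
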