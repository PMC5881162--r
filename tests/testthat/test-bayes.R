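test_that("concentrations round to the nearest bin, midpoints up", {
  expect_equal(bin_concentration(1234), 1200)
  expect_equal(bin_concentration(1250), 1300)
  expect_equal(bin_concentration(0), 0)
  expect_equal(bin_concentration(49.999), 0)
  expect_equal(bin_concentration(c(75, 125), bin_width = 50), c(100, 150))
  expect_error(bin_concentration(-1), "non-negative")
})

test_that("unsmoothed tables reproduce the raw count ratios", {
  pm <- data.frame(phenotype = "PM", conc_ng_ml = c(1130, 1080, 940))
  train <- rbind(pm,
                 data.frame(phenotype = c("EM", "IM"),
                            conc_ng_ml = c(100, 500)))
  fit <- efv_bayes(train, time = NULL, smoothing = 0)
  expect_equal(unname(fit$likelihood["1100", "PM"]), 2 / 3)
  expect_equal(unname(fit$likelihood["900", "PM"]), 1 / 3)
  expect_equal(sum(fit$likelihood[, "PM"]), 1, tolerance = 1e-9)
})

test_that("fitted tables match independent brute-force counting", {
  set.seed(17)
  train <- data.frame(
    phenotype = sample(c("EM", "IM", "PM"), 50, replace = TRUE,
                       prob = c(0.4, 0.35, 0.25)),
    conc_ng_ml = round(runif(50, 0, 2500), 1))
  while (length(unique(train$phenotype)) < 3) {
    train$phenotype <- sample(c("EM", "IM", "PM"), 50, replace = TRUE)
  }
  fit <- efv_bayes(train, time = NULL, smoothing = 0)
  oracle <- brute_force_table(train)
  for (ph in names(oracle)) {
    got <- fit$likelihood[names(oracle[[ph]]), ph]
    expect_equal(unname(got), unname(oracle[[ph]]),
                 label = paste("table for", ph))
  }
  # rows (per phenotype) always normalize, with or without smoothing
  fit_s <- efv_bayes(train, time = NULL, smoothing = 0.5)
  expect_equal(unname(colSums(fit_s$likelihood)), rep(1, 3),
               tolerance = 1e-9)
})

test_that("identical training data per phenotype gives identical tables", {
  conc <- c(300, 700, 700, 1500)
  train <- data.frame(phenotype = rep(c("EM", "IM", "PM"), each = 4),
                      conc_ng_ml = rep(conc, 3))
  fit <- efv_bayes(train, time = NULL)
  expect_equal(fit$likelihood[, "EM"], fit$likelihood[, "IM"])
  expect_equal(fit$likelihood[, "IM"], fit$likelihood[, "PM"])
  post <- predict(fit, c(300, 1500), type = "posterior")
  expect_equal(unname(post), matrix(1 / 3, 2, 3), tolerance = 1e-12)
})

test_that("fitting errors on missing phenotypes or labels", {
  expect_error(efv_bayes(data.frame(phenotype = c("EM", "IM"),
                                    conc_ng_ml = c(1, 2)), time = NULL),
               "PM")
  train <- tiny_training()
  train$phenotype[2] <- NA
  expect_error(efv_bayes(train, time = NULL), "unlabelled")
})

test_that("posteriors follow Bayes' rule and are prior-scale invariant", {
  fit <- efv_bayes(tiny_training(), time = NULL, smoothing = 0)
  # hand evaluation: at 600 (bin 600), counts EM 0/3, IM 2/3, PM 0/3
  post <- predict(fit, 600, type = "posterior")
  expect_equal(unname(post[1, ]), c(0, 1, 0))
  # 1100: EM 0, IM 0, PM 2/3 -> PM
  expect_equal(predict(fit, 1100)$predicted, "PM")
  # scaling priors changes nothing
  f2 <- efv_bayes(tiny_training(), time = NULL, smoothing = 0,
                  priors = c(EM = 2, IM = 2, PM = 2) / 6)
  expect_equal(predict(f2, c(100, 600, 1100), type = "posterior"),
               predict(fit, c(100, 600, 1100), type = "posterior"))
  # arithmetic: equal priors, likelihoods (0.1, 0.1, 0.2) -> (.25,.25,.5)
  manual <- c(0.1, 0.1, 0.2) / 3
  expect_equal(unname(manual / sum(manual)), c(0.25, 0.25, 0.5))
})

test_that("degenerate priors force the favoured phenotype everywhere", {
  fit <- efv_bayes(tiny_training(), time = NULL,
                   priors = c(EM = 1, IM = 0, PM = 0))
  calls <- predict(fit, c(0, 500, 1100, 2000))
  expect_true(all(calls$predicted == "EM"))
})

test_that("MAP ties break toward the slower metabolizer and are flagged", {
  # two phenotypes share the max: EM and IM tie -> IM (slower of the two)
  train <- data.frame(phenotype = rep(c("EM", "IM", "PM"), each = 2),
                      conc_ng_ml = c(400, 400, 400, 400, 900, 900))
  fit <- efv_bayes(train, time = NULL, smoothing = 0)
  call <- predict(fit, 400)
  expect_equal(call$predicted, "IM")
  expect_true(call$tie_flag)
  # three-way tie -> PM
  call3 <- predict(efv_bayes(train, time = NULL), 2000)  # far guard bin
  expect_equal(call3$predicted[1], "PM")
})

test_that("label permutation in training permutes posteriors identically", {
  set.seed(23)
  train <- data.frame(
    phenotype = rep(c("EM", "IM", "PM"), times = c(12, 10, 8)),
    conc_ng_ml = round(rlnorm(30, log(800), 0.6)))
  perm <- c(EM = "PM", IM = "EM", PM = "IM")
  swapped <- train
  swapped$phenotype <- unname(perm[train$phenotype])
  f1 <- efv_bayes(train, time = NULL)
  f2 <- efv_bayes(swapped, time = NULL)
  conc <- c(100, 700, 1400)
  p1 <- predict(f1, conc, type = "posterior")
  p2 <- predict(f2, conc, type = "posterior")
  for (ph in phenotype_levels())
    expect_equal(p2[, perm[ph]], p1[, ph],
                 label = paste("posterior of relabelled", ph))
})

test_that("zero-evidence bins fall back to the nearest populated bin", {
  train <- data.frame(phenotype = rep(c("EM", "IM", "PM"), each = 2),
                      conc_ng_ml = c(100, 200, 600, 700, 1800, 1900))
  fit <- efv_bayes(train, time = NULL, smoothing = 0)
  # 1200 is unseen; nearest populated bins are 700 (5 away) vs 1800 (6) -> 700
  expect_equal(predict(fit, 1200)$predicted, "IM")
  # 1250 bins to 1300: 700 is 6 away, 1800 is 5 away -> PM
  expect_equal(predict(fit, 1250)$predicted, "PM")
  # equidistant unseen bin ties toward the higher concentration
  fit2 <- efv_bayes(data.frame(
    phenotype = rep(c("EM", "IM", "PM"), each = 2),
    conc_ng_ml = c(100, 200, 600, 700, 1300, 1400)), time = NULL,
    smoothing = 0)
  expect_equal(predict(fit2, 1000)$predicted, "PM")  # 700 vs 1300, tie -> up
})

test_that("out-of-range concentrations clamp to the guard bins", {
  fit <- efv_bayes(tiny_training(), time = NULL)
  hi <- predict(fit, 99999)
  expect_equal(hi$predicted, predict(fit, max(fit$bins))$predicted)
})

test_that("posterior curve normalizes and drives the range partition", {
  set.seed(29)
  specs <- calibrated_specs()
  train <- simulate_cohort(specs, times = 24, n_trials = 2, n_per_trial = 300,
                           phenotype_mix = c(EM = 1, IM = 1, PM = 1),
                           seed = 41)
  fit <- efv_bayes(train, time = 24)
  curve <- posterior_curve(fit)
  expect_equal(unname(rowSums(curve[, c("p_EM", "p_IM", "p_PM")])),
               rep(1, nrow(curve)), tolerance = 1e-9)
  ranges <- phenotype_ranges(fit)
  # intervals partition the bin grid contiguously
  expect_equal(ranges$from[1], fit$bins[1])
  expect_equal(ranges$to[nrow(ranges)], fit$bins[length(fit$bins)])
  expect_equal(ranges$from[-1], ranges$to[-nrow(ranges)] + fit$bin_width)
  # single-phenotype certainty covers the whole range in one interval
  sure <- efv_bayes(tiny_training(), time = NULL,
                    priors = c(EM = 0, IM = 0, PM = 1))
  expect_equal(nrow(phenotype_ranges(sure)), 1)
  expect_equal(phenotype_ranges(sure)$phenotype, "PM")
})

test_that("serialized models restore bit-identical predictions", {
  fit <- efv_bayes(tiny_training(), time = NULL)
  path <- tempfile(fileext = ".json")
  write_efv_bayes(fit, path)
  conc <- c(0, 123, 456, 789, 1100, 5000)
  # a fixed serialized model is bit-stable: two loads, identical calls
  expect_identical(predict(read_efv_bayes(path), conc),
                   predict(read_efv_bayes(path), conc))
  # and the restored model reproduces the original fit
  back <- read_efv_bayes(path)
  expect_equal(predict(fit, conc), predict(back, conc), tolerance = 1e-12)
  expect_identical(predict(fit, conc)$predicted, predict(back, conc)$predicted)
  expect_equal(back$priors, fit$priors)
  expect_equal(unname(back$counts), unname(fit$counts))
  unlink(path)
})

test_that("simulate() draws from the fitted conditional table", {
  fit <- efv_bayes(tiny_training(), time = NULL, smoothing = 0)
  draws <- simulate(fit, nsim = 500, seed = 4, phenotype = "PM")
  expect_true(all(draws %in% c(900, 1100)))
  expect_equal(mean(draws == 1100), 2 / 3, tolerance = 0.1)
})
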