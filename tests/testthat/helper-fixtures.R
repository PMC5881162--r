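# Calibrated specs are deterministic; compute once per test run.
calibrated_specs <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- calibrate_population()
    cache
  }
})

# Small labelled training set with clean hand-countable bins.
tiny_training <- function() {
  data.frame(
    phenotype = rep(c("EM", "IM", "PM"), each = 3),
    conc_ng_ml = c(100, 240, 260, 420, 580, 600, 940, 1080, 1130),
    stringsAsFactors = FALSE)
}

# Independent brute-force counting of the conditional table: loop over
# records, round each concentration, tally per phenotype.
brute_force_table <- function(data, bin_width = 100) {
  out <- list()
  for (ph in unique(data$phenotype)) {
    sub <- data[data$phenotype == ph, ]
    bins <- floor(sub$conc_ng_ml / bin_width + 0.5) * bin_width
    tab <- table(bins)
    out[[ph]] <- setNames(as.numeric(tab) / nrow(sub), names(tab))
  }
  out
}
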