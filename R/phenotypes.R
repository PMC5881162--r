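#' Metabolizer phenotype labels
#'
#' The three CYP2B6 metabolizer phenotypes handled throughout the package,
#' in canonical order: extensive (EM, 516 GG), intermediate (IM, 516 GT) and
#' poor (PM, 516 TT). PM is the slowest metabolizer; tie-breaks in
#' classification favour the slower phenotype (PM over IM over EM).
#'
#' @return Character vector \code{c("EM", "IM", "PM")}.
#' @export
phenotype_levels <- function() c("EM", "IM", "PM")

#' @keywords internal
as_phenotype <- function(x) {
  f <- factor(as.character(x), levels = phenotype_levels())
  if (anyNA(f) && !anyNA(x)) {
    bad <- unique(setdiff(as.character(x), phenotype_levels()))
    stop("unknown phenotype label(s): ", paste(bad, collapse = ", "))
  }
  f
}
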