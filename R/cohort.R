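# Published cohort composition of the source study (sample sizes per
# population and region), shipped as a plain-text table. Used for
# cohort bookkeeping checks: the Egyptian populations sum to 394
# genotyped individuals and the four regional totals to the 1,234
# individuals surviving sample QC.

#' Cohort sample sizes of the source study
#'
#' Sample sizes of the 30 sheep populations genotyped on the Ovine SNP50K
#' array across four regions (North Africa/Egypt, East Africa, western
#' Asia, North/Central Europe).
#'
#' @return a data.frame `region, country, population, type, n`.
#' @export
cohort_sizes <- function() {
  path <- system.file("extdata", "cohort_sizes.tsv", package = "sweepscan",
                      mustWork = TRUE)
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' Regional totals of the study cohort
#'
#' Sums [cohort_sizes()] per region; the grand total is the number of
#' individuals entering SNP quality control.
#'
#' @return a data.frame `region, n` plus attribute `total`.
#' @export
cohort_regional_totals <- function() {
  cs <- cohort_sizes()
  agg <- aggregate(n ~ region, data = cs, FUN = sum)
  attr(agg, "total") <- sum(agg$n)
  agg
}
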