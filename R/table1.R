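#' Published Kilkari differential-impact cells
#'
#' The printed cells (integer percent, numerator N, standard error) of
#' the published Table of differential Kilkari impact on family
#' planning, infant feeding and immunisation outcomes, per cluster and
#' exposure arm. The source prints two rows labelled "Sterilised"; the
#' second is transcribed as "Sterilised (since last birth)" to keep keys
#' unique. Cell denominators are not printed; they can be recovered
#' approximately with [recover_denominator()].
#'
#' @return data.frame with columns `outcome`, `group`, `cluster`, `arm`,
#'   `percent`, `numerator`, `se`.
#' @export
kilkari_table1 <- function() {
  path <- system.file("extdata", "kilkari_table1.csv", package = "coupleseg")
  read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Exposed-minus-unexposed differences from printed cells
#'
#' Computes, for every (outcome, cluster), the difference in printed
#' percent between the exposed and not-exposed arms.
#'
#' @param cells data.frame in the layout of [kilkari_table1()].
#' @return data.frame with `outcome`, `cluster`, `diff_percent`.
#' @export
impact_differences <- function(cells) {
  stopifnot(all(c("outcome", "cluster", "arm", "percent") %in% names(cells)))
  exp_ <- cells[cells$arm == "exposed", ]
  une <- cells[cells$arm == "not_exposed", ]
  key <- paste(exp_$outcome, exp_$cluster, sep = "\r")
  m <- match(key, paste(une$outcome, une$cluster, sep = "\r"))
  data.frame(outcome = exp_$outcome,
             cluster = exp_$cluster,
             diff_percent = exp_$percent - une$percent[m],
             stringsAsFactors = FALSE)
}

#' Binomial standard error of a proportion
#'
#' @param p proportion in \[0, 1\].
#' @param m denominator.
#' @return sqrt(p (1 - p) / m).
#' @export
binomial_se <- function(p, m) {
  stopifnot(p >= 0, p <= 1, m > 0)
  sqrt(p * (1 - p) / m)
}

#' Recover a cell denominator from printed percent and numerator
#'
#' Printed cells give the percent and the numerator count only; the
#' denominator is approximately numerator / (percent / 100), rounded to
#' the nearest integer.
#'
#' @param percent printed integer percent.
#' @param numerator printed count with the outcome.
#' @return Estimated denominator (integer).
#' @export
recover_denominator <- function(percent, numerator) {
  stopifnot(percent > 0)
  as.integer(round(numerator / (percent / 100)))
}
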