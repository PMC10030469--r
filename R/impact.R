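#' Proportion cell for an impact table
#'
#' Summarises a binary outcome vector the way the published
#' differential-impact table prints each cell: the integer-rounded
#' percent, the numerator count N of respondents with the outcome, and
#' the binomial standard error sqrt(p (1 - p) / m) of the proportion
#' (m = cell denominator), rounded to three decimals.
#'
#' @param values 0/1 vector (NAs dropped).
#' @return List with `percent`, `numerator`, `se`, `m` and `empty` flag.
#' @export
proportion_cell <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) == 0) {
    return(list(percent = NA_real_, numerator = NA_integer_, se = NA_real_,
                m = 0L, empty = TRUE))
  }
  stopifnot(all(values %in% c(0, 1)))
  m <- length(values)
  p <- mean(values)
  list(percent = round(100 * p),
       numerator = as.integer(sum(values)),
       se = round(sqrt(p * (1 - p) / m), 3),
       m = m,
       empty = FALSE)
}

#' Differential-impact table by cluster and exposure arm
#'
#' One cell per (outcome, cluster, arm) plus the exposed-minus-unexposed
#' differences per cluster, computed both on unrounded proportions and on
#' the rounded percents. Clusters where one arm is empty get flagged
#' cells and an omitted difference.
#'
#' @param outcomes data.frame of 0/1 outcome columns.
#' @param labels cluster labels aligned to rows.
#' @param exposure 0/1 exposure indicator aligned to rows.
#' @return List of class `impact_table` with data.frames `cells`
#'   (`outcome`, `cluster`, `arm`, `percent`, `numerator`, `se`, `m`,
#'   `empty`) and `differences` (`outcome`, `cluster`, `diff_percent`,
#'   `diff_unrounded`).
#' @export
impact_table <- function(outcomes, labels, exposure) {
  outcomes <- as.data.frame(outcomes)
  stopifnot(nrow(outcomes) == length(labels),
            length(exposure) == length(labels))
  if (anyNA(exposure)) stopf("exposure indicator contains missing values")
  ks <- sort(unique(labels))
  arms <- c("not_exposed", "exposed")
  cells <- list()
  diffs <- list()
  for (oc in names(outcomes)) {
    for (g in ks) {
      cell <- list()
      for (a in c(0, 1)) {
        v <- outcomes[[oc]][labels == g & exposure == a]
        pc <- proportion_cell(v)
        cell[[arms[a + 1]]] <- pc
        cells[[length(cells) + 1L]] <- data.frame(
          outcome = oc, cluster = g, arm = arms[a + 1],
          percent = pc$percent, numerator = pc$numerator, se = pc$se,
          m = pc$m, empty = pc$empty, stringsAsFactors = FALSE)
      }
      if (!cell$exposed$empty && !cell$not_exposed$empty) {
        diffs[[length(diffs) + 1L]] <- data.frame(
          outcome = oc, cluster = g,
          diff_percent = cell$exposed$percent - cell$not_exposed$percent,
          diff_unrounded =
            100 * (cell$exposed$numerator / cell$exposed$m -
                     cell$not_exposed$numerator / cell$not_exposed$m),
          stringsAsFactors = FALSE)
      }
    }
  }
  structure(
    list(cells = do.call(rbind, cells),
         differences = if (length(diffs)) do.call(rbind, diffs) else
           data.frame(outcome = character(), cluster = integer(),
                      diff_percent = numeric(), diff_unrounded = numeric())),
    class = "impact_table")
}

#' Cluster profile of strong-signal variables
#'
#' Per-cluster prevalence of each strong-signal variable, one row per
#' variable with a column per cluster, sorted by descending maximal gap —
#' the layout used to display the distribution of select characteristics
#' with strong signals by cluster.
#'
#' @param prevalence a [prevalence_table()].
#' @param signal_set a [detect_strong_signals()] result.
#' @return data.frame with `variable`, one `cluster_<g>` column per
#'   cluster, `qualifying_cluster` and `max_gap`. Empty signal set gives
#'   an empty profile with a warning.
#' @export
cluster_profile <- function(prevalence, signal_set) {
  stopifnot(inherits(prevalence, "prevalence_table"),
            inherits(signal_set, "strong_signal_set"))
  ks <- sort(unique(prevalence$cluster))
  if (nrow(signal_set) == 0) {
    warnf("empty strong-signal set: profile has no rows")
    out <- data.frame(variable = character(), stringsAsFactors = FALSE)
    for (g in ks) out[[paste0("cluster_", g)]] <- numeric()
    out$qualifying_cluster <- integer()
    out$max_gap <- numeric()
    return(out)
  }
  pv <- prevalence[prevalence$variable %in% signal_set$variable, , drop = FALSE]
  wide <- stats::reshape(
    pv[, c("variable", "cluster", "prevalence")],
    idvar = "variable", timevar = "cluster", direction = "wide")
  names(wide) <- sub("^prevalence\\.", "cluster_", names(wide))
  wide <- merge(wide,
                data.frame(variable = signal_set$variable,
                           qualifying_cluster = signal_set$cluster,
                           max_gap = signal_set$max_gap,
                           stringsAsFactors = FALSE),
                by = "variable")
  wide <- wide[order(-wide$max_gap), , drop = FALSE]
  rownames(wide) <- NULL
  wide
}
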