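#' Per-cluster prevalence table
#'
#' Prevalence of each 0/1 indicator column within each cluster, in
#' percent. Missing values are assumed to have been handled upstream
#' (the encoder imputes); non-indicator columns are rejected because
#' prevalence has no meaning for them.
#'
#' @param encoded numeric matrix of indicator (0/1) columns.
#' @param labels integer cluster labels aligned to the rows.
#' @return data.frame of class `prevalence_table` with columns
#'   `variable`, `cluster`, `prevalence` (percent) and `n` (cluster size).
#' @export
prevalence_table <- function(encoded, labels) {
  X <- as.matrix(encoded)
  labels <- as.integer(labels)
  stopifnot(nrow(X) == length(labels))
  bad <- colnames(X)[!apply(X, 2, is_indicator)]
  if (length(bad)) {
    stopf("non-indicator column(s): %s", paste(utils::head(bad, 3), collapse = ", "))
  }
  ks <- sort(unique(labels))
  out <- do.call(rbind, lapply(ks, function(g) {
    rows <- labels == g
    data.frame(variable = colnames(X),
               cluster = g,
               prevalence = 100 * colMeans(X[rows, , drop = FALSE]),
               n = sum(rows),
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  class(out) <- c("prevalence_table", class(out))
  out
}

#' Detect strong signals
#'
#' A variable carries a strong signal when some cluster c has prevalence
#' of at least `p_min` percent AND that same cluster's prevalence exceeds
#' some other cluster's by at least `d_min` percentage points. Both
#' thresholds are inclusive ("at least" / "or more"). The canonical
#' example: men's smartphone ownership of 6%, 88% and 75% across three
#' clusters qualifies through the 88% cluster.
#'
#' @param prev a [prevalence_table()].
#' @param p_min minimum prevalence, percent (default 70).
#' @param d_min minimum pairwise gap, percentage points (default 50).
#' @return data.frame of class `strong_signal_set` with one row per
#'   qualifying variable: `variable`, `cluster` (the qualifying,
#'   highest-prevalence cluster), `max_prevalence`, `max_gap`. Thresholds
#'   are attached as attributes.
#' @export
detect_strong_signals <- function(prev, p_min = 70, d_min = 50) {
  stopifnot(inherits(prev, "prevalence_table"))
  ks <- sort(unique(prev$cluster))
  if (length(ks) < 2) stopf("strong-signal detection requires at least two clusters")
  rows <- lapply(split(prev, prev$variable), function(pv) {
    p <- pv$prevalence[match(ks, pv$cluster)]
    # anchor both conditions on the same high-prevalence cluster
    ok <- p >= p_min & (p - min(p)) >= d_min
    if (!any(ok)) return(NULL)
    best <- which(ok)[which.max(p[ok])]
    data.frame(variable = pv$variable[1],
               cluster = ks[best],
               max_prevalence = p[best],
               max_gap = p[best] - min(p),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(variable = character(), cluster = integer(),
                      max_prevalence = numeric(), max_gap = numeric(),
                      stringsAsFactors = FALSE)
  }
  out <- out[order(-out$max_gap), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, p_min = p_min, d_min = d_min,
            class = c("strong_signal_set", "data.frame"))
}

#' Per-respondent signal-strength score
#'
#' The count of strong-signal indicators a respondent possesses: the row
#' sum of the qualifying 0/1 columns. This integer score is the target of
#' the L1-regularised regression in the refinement loop.
#'
#' @param encoded numeric indicator matrix containing the signal columns.
#' @param signal_set a [detect_strong_signals()] result (non-empty).
#' @return Integer vector, one score per row, in
#'   `0..nrow(signal_set)`.
#' @export
signal_strength_score <- function(encoded, signal_set) {
  stopifnot(inherits(signal_set, "strong_signal_set"))
  if (nrow(signal_set) == 0) {
    stopf("empty strong-signal set: no score can be built, stop the loop")
  }
  X <- as.matrix(encoded)
  missing_cols <- setdiff(signal_set$variable, colnames(X))
  if (length(missing_cols)) {
    stopf("signal columns absent from matrix: %s",
          paste(missing_cols, collapse = ", "))
  }
  as.integer(round(rowSums(X[, signal_set$variable, drop = FALSE])))
}
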