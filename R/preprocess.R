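#' Merge the men's and women's tables by couple
#'
#' Inner join on `couple_id`; only complete couples are analysed. Column
#' names (and their dictionary entries) are prefixed by the spouse role so
#' that the same survey item asked of both spouses stays distinguishable.
#'
#' @param men,women [survey_table] objects keyed by `couple_id`.
#' @return A merged [survey_table] with `man_`/`woman_` prefixed columns.
#' @export
merge_couples <- function(men, women) {
  stopifnot(inherits(men, "survey_table"), inherits(women, "survey_table"))
  prefix <- function(tab, role) {
    d <- tab$data
    vars <- setdiff(names(d), "couple_id")
    names(d)[match(vars, names(d))] <- paste0(role, "_", vars)
    dict <- tab$dictionary
    if (nrow(dict) > 0) {
      dict$name <- paste0(role, "_", dict$name)
      dict$role <- role
    }
    list(data = d, dict = dict)
  }
  m <- prefix(men, "man")
  w <- prefix(women, "woman")
  common <- intersect(m$data$couple_id, w$data$couple_id)
  if (length(common) == 0) stopf("no couple_id values are shared by the two tables")
  md <- m$data[match(common, m$data$couple_id), , drop = FALSE]
  wd <- w$data[match(common, w$data$couple_id), , drop = FALSE]
  merged <- cbind(md, wd[, setdiff(names(wd), "couple_id"), drop = FALSE])
  rownames(merged) <- NULL
  survey_table(merged, rbind(m$dict, w$dict))
}

#' Filter variables that may not enter clustering
#'
#' Drops every column whose dictionary entry has `domain = "health"` or
#' `clustering_eligible = FALSE` — health knowledge/practice items and
#' outcome/exposure columns never inform the segmentation. The retained
#' and dropped sets are recorded in the `"filter_log"` attribute.
#'
#' @param table a [survey_table].
#' @return The filtered [survey_table].
#' @export
filter_variables <- function(table) {
  stopifnot(inherits(table, "survey_table"))
  dict <- table$dictionary
  keep <- dict$name[dict$domain != "health" & dict$clustering_eligible]
  if (length(keep) == 0) stopf("all variables were filtered out; nothing left to cluster")
  dropped <- setdiff(dict$name, keep)
  out <- survey_table(
    table$data[, c("couple_id", keep), drop = FALSE],
    dict[dict$name %in% keep, , drop = FALSE])
  attr(out, "filter_log") <- list(retained = keep, dropped = dropped)
  out
}

#' Encode a survey table as a numeric matrix
#'
#' Binary variables become single 0/1 columns; a categorical variable
#' with L observed levels becomes L indicator columns (full one-hot, no
#' reference level dropped, so that each indicator keeps its prevalence
#' semantics); continuous variables are z-scored. Missing values are
#' imputed per column — mode for binary/categorical, mean for continuous
#' — under the default policy, or the incomplete rows are dropped under
#' `"drop_incomplete"`. Zero-variance columns are removed and logged.
#'
#' @param table a [survey_table].
#' @param missing_policy `"impute"` (default) or `"drop_incomplete"`.
#' @return A numeric matrix of class `encoded_matrix` with attributes
#'   `couple_id` (row alignment), `provenance` (data.frame mapping each
#'   encoded column to its source variable and level) and `encode_log`
#'   (dropped zero-variance columns, imputation counts).
#' @export
encode <- function(table, missing_policy = c("impute", "drop_incomplete")) {
  stopifnot(inherits(table, "survey_table"))
  missing_policy <- match.arg(missing_policy)
  dat <- table$data
  dict <- table$dictionary
  vars <- setdiff(names(dat), "couple_id")

  entirely_missing <- vars[vapply(dat[vars], function(x) all(is.na(x)), TRUE)]
  if (length(entirely_missing)) {
    stopf("column entirely missing: %s", entirely_missing[1])
  }
  if (missing_policy == "drop_incomplete") {
    complete <- stats::complete.cases(dat[vars])
    dat <- dat[complete, , drop = FALSE]
    if (nrow(dat) == 0) stopf("no complete rows left under drop_incomplete")
  }

  n_imputed <- 0L
  cols <- list()
  prov <- list()
  for (v in vars) {
    kind <- dict$kind[match(v, dict$name)]
    x <- dat[[v]]
    if (kind %in% c("binary", "categorical")) {
      if (anyNA(x)) {
        tab <- table(x)
        mode_val <- names(tab)[which.max(tab)]
        if (is.numeric(x)) mode_val <- as.numeric(mode_val)
        n_imputed <- n_imputed + sum(is.na(x))
        x[is.na(x)] <- mode_val
      }
      if (kind == "binary") {
        xv <- as.numeric(x)
        if (!all(xv %in% c(0, 1))) {
          stopf("binary column '%s' has values outside {0, 1}", v)
        }
        cols[[v]] <- xv
        prov[[v]] <- data.frame(column = v, source = v, level = NA_character_,
                                stringsAsFactors = FALSE)
      } else {
        levs <- sort(unique(as.character(x)))
        for (lv in levs) {
          nm <- paste0(v, ".", lv)
          cols[[nm]] <- as.numeric(as.character(x) == lv)
          prov[[nm]] <- data.frame(column = nm, source = v, level = lv,
                                   stringsAsFactors = FALSE)
        }
      }
    } else if (kind == "continuous") {
      xv <- as.numeric(x)
      if (anyNA(xv)) {
        n_imputed <- n_imputed + sum(is.na(xv))
        xv[is.na(xv)] <- mean(xv, na.rm = TRUE)
      }
      s <- sqrt(mean((xv - mean(xv))^2))
      cols[[v]] <- if (s > 0) (xv - mean(xv)) / s else xv * 0
      prov[[v]] <- data.frame(column = v, source = v, level = NA_character_,
                              stringsAsFactors = FALSE)
    } else {
      stopf("unknown kind '%s' for column '%s'", kind, v)
    }
  }

  X <- do.call(cbind, cols)
  provenance <- do.call(rbind, prov)
  rownames(provenance) <- NULL
  keep <- apply(X, 2, function(col) var(col) > 0)
  dropped <- colnames(X)[!keep]
  X <- X[, keep, drop = FALSE]
  provenance <- provenance[keep, , drop = FALSE]
  if (ncol(X) == 0) stopf("no non-constant columns left after encoding")

  structure(X,
            couple_id = dat$couple_id,
            provenance = provenance,
            encode_log = list(dropped_zero_variance = dropped,
                              n_imputed = n_imputed,
                              missing_policy = missing_policy),
            class = c("encoded_matrix", class(X)))
}
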