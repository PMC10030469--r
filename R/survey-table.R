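#' Construct a survey table
#'
#' A `survey_table` couples respondent-level data with a variable
#' dictionary. The dictionary drives everything downstream: which columns
#' may enter clustering, how each is encoded, and which domain
#' (sociodemographic, phone, health, design) a variable belongs to.
#'
#' @param data data.frame with a `couple_id` column plus survey variables.
#' @param dictionary data.frame with columns `name`, `role`, `kind`
#'   (`binary`, `categorical` or `continuous`), `domain`
#'   (`sociodemographic`, `phone`, `health` or `design`) and
#'   `clustering_eligible` (logical).
#' @return An object of class `survey_table`.
#' @export
survey_table <- function(data, dictionary) {
  if (!is.data.frame(data) || !"couple_id" %in% names(data)) {
    stopf("`data` must be a data.frame with a `couple_id` column")
  }
  if (anyDuplicated(data$couple_id)) {
    dup <- data$couple_id[duplicated(data$couple_id)][1]
    stopf("duplicate couple_id in table: %s", dup)
  }
  needed <- c("name", "kind", "domain", "clustering_eligible")
  if (!is.data.frame(dictionary) || !all(needed %in% names(dictionary))) {
    stopf("`dictionary` must have columns %s", paste(needed, collapse = ", "))
  }
  vars <- setdiff(names(data), "couple_id")
  missing_dict <- setdiff(vars, dictionary$name)
  if (length(missing_dict)) {
    stopf("columns absent from dictionary: %s",
          paste(missing_dict, collapse = ", "))
  }
  bad_kind <- setdiff(dictionary$kind, c("binary", "categorical", "continuous"))
  if (length(bad_kind)) stopf("unknown variable kind: %s", bad_kind[1])
  structure(
    list(data = data,
         dictionary = dictionary[dictionary$name %in% vars, , drop = FALSE]),
    class = "survey_table"
  )
}

#' @export
print.survey_table <- function(x, ...) {
  cat(sprintf("<survey_table> %d respondents x %d variables\n",
              nrow(x$data), ncol(x$data) - 1L))
  cat("  kinds: ",
      paste(sprintf("%s=%d", names(table(x$dictionary$kind)),
                    table(x$dictionary$kind)), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.survey_table <- function(x) c(nrow(x$data), ncol(x$data) - 1L)
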