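# CSV dialect: header row, comma delimiter, UTF-8, "" for missing.
read_csv_strict <- function(path) {
  if (!file.exists(path)) stopf("input file not found: %s", path)
  read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
           na.strings = "")
}

write_csv_strict <- function(x, path) {
  write.csv(x, path, row.names = FALSE, na = "")
}

run_info <- function(seed, config = NULL) {
  list(package = "coupleseg",
       version = as.character(utils::packageVersion("coupleseg")),
       seed = as.integer(seed),
       config_hash = rlang::hash(config))
}

write_json_stable <- function(x, path) {
  # stable key order and unboxed scalars keep outputs diffable
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
}

#' Write a synthetic couple survey to a directory
#'
#' Generates the survey for `config` and writes `men.csv`, `women.csv`,
#' `dictionary.csv` (both spouses' dictionaries, with a `role` column),
#' `truth.csv` and a `run_info.json` sidecar carrying the master seed
#' and a hash of the configuration.
#'
#' @param config a [generator_config()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the generated list from [generate_couple_survey()].
#' @export
simulate_survey_files <- function(config, dir) {
  validate_generator_config(config)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(dir)) stopf("cannot create output directory: %s", dir)
  sim <- generate_couple_survey(config)
  write_csv_strict(sim$men$data, file.path(dir, "men.csv"))
  write_csv_strict(sim$women$data, file.path(dir, "women.csv"))
  write_csv_strict(rbind(sim$men$dictionary, sim$women$dictionary),
                   file.path(dir, "dictionary.csv"))
  write_csv_strict(sim$truth, file.path(dir, "truth.csv"))
  write_json_stable(run_info(config$seed, config),
                    file.path(dir, "run_info.json"))
  invisible(sim)
}

#' Read a couple survey from a directory
#'
#' Counterpart of [simulate_survey_files()]; also accepts hand-prepared
#' data in the same layout. The dictionary's `role` column splits it
#' between the two tables.
#'
#' @param dir directory holding `men.csv`, `women.csv`, `dictionary.csv`
#'   and optionally `truth.csv`.
#' @return List with `men`, `women` ([survey_table]s) and `truth`
#'   (data.frame or `NULL`).
#' @export
read_survey_files <- function(dir) {
  dict <- read_csv_strict(file.path(dir, "dictionary.csv"))
  need <- c("name", "role", "kind", "domain", "clustering_eligible")
  missing_cols <- setdiff(need, names(dict))
  if (length(missing_cols)) {
    stopf("dictionary.csv lacks column(s): %s", paste(missing_cols, collapse = ", "))
  }
  dict$clustering_eligible <- as.logical(dict$clustering_eligible)
  men <- survey_table(read_csv_strict(file.path(dir, "men.csv")),
                      dict[dict$role == "man", , drop = FALSE])
  women <- survey_table(read_csv_strict(file.path(dir, "women.csv")),
                        dict[dict$role == "woman", , drop = FALSE])
  truth_path <- file.path(dir, "truth.csv")
  truth <- if (file.exists(truth_path)) read_csv_strict(truth_path) else NULL
  list(men = men, women = women, truth = truth)
}

#' Run the full segmentation pipeline
#'
#' Merges the spouses' tables, filters clustering-ineligible and health
#' variables, encodes to a numeric matrix, chooses K by the elbow on the
#' men's predefined step-1 subset (sociodemographic and phone
#' access/use) unless `k` is forced, and runs the iterative
#' K-Means/Lasso refinement loop.
#'
#' @param men,women [survey_table] objects.
#' @param k forced number of clusters, or `NULL` to take the elbow choice.
#' @param k_max largest K for the elbow curve.
#' @param p_min,d_min strong-signal thresholds.
#' @param seed master seed for every stochastic stage.
#' @param ... further arguments passed to [run_segmentation()].
#' @return List of class `pipeline_result`: `result`
#'   (a `segmentation_result`), `wcss_by_k`, `elbow_k`, `k`, `encoded`,
#'   `step1_columns`, `couple_id`, `prevalence` and `profile`.
#' @export
run_pipeline <- function(men, women, k = NULL, k_max = 6,
                         p_min = 70, d_min = 50, seed = 1L, ...) {
  merged <- merge_couples(men, women)
  filtered <- filter_variables(merged)
  enc <- encode(filtered)
  prov <- attr(enc, "provenance")
  dict <- filtered$dictionary
  dom <- dict$domain[match(prov$source, dict$name)]
  role <- dict$role[match(prov$source, dict$name)]
  step1_cols <- prov$column[role == "man" &
                              dom %in% c("sociodemographic", "phone")]
  if (length(step1_cols) == 0) stopf("no step-1 (men's) columns available")
  men_X <- enc[, step1_cols, drop = FALSE]

  wcss <- wcss_curve(men_X, k_max, seed = derive_seed(seed, 500L))
  elbow_k <- elbow_select(wcss)
  k_used <- k %||% as.integer(elbow_k)

  res <- run_segmentation(men_X, enc, k_used, p_min = p_min, d_min = d_min,
                          seed = seed, ...)
  indicator_cols <- colnames(enc)[apply(enc, 2, is_indicator)]
  prev <- prevalence_table(enc[, indicator_cols, drop = FALSE],
                           res$final_model$labels)
  profile <- if (nrow(res$final_signals) > 0) {
    cluster_profile(prev, res$final_signals)
  } else NULL

  structure(
    list(result = res,
         wcss_by_k = wcss,
         elbow_k = as.integer(elbow_k),
         k = k_used,
         encoded = enc,
         step1_columns = step1_cols,
         couple_id = attr(enc, "couple_id"),
         prevalence = prev,
         profile = profile,
         seed = as.integer(seed)),
    class = "pipeline_result")
}

#' Write pipeline outputs
#'
#' Writes `assignments.csv` (couple and final cluster), `trace.json`
#' (per-iteration feature sets, strong-signal sets and fit metrics),
#' `validity.json` (WCSS curve and elbow choice), `signals.csv`,
#' `profile.csv`, `wcss_curve.csv` and a `run_info.json` sidecar.
#'
#' @param pipeline a [run_pipeline()] result.
#' @param dir output directory.
#' @return Invisibly, the vector of files written.
#' @export
write_segmentation <- function(pipeline, dir) {
  stopifnot(inherits(pipeline, "pipeline_result"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  res <- pipeline$result

  assignments <- data.frame(couple_id = pipeline$couple_id,
                            cluster = res$final_model$labels,
                            stringsAsFactors = FALSE)
  write_csv_strict(assignments, file.path(dir, "assignments.csv"))

  trace <- lapply(res$trace, function(rec) {
    list(iteration = rec$iteration,
         n_features = length(rec$features),
         features = rec$features,
         inertia = rec$model$inertia,
         cluster_sizes = tabulate(rec$model$labels, res$k),
         signal_count = rec$signal_count,
         signals = rec$signals$variable)
  })
  write_json_stable(list(k = res$k, converged = res$converged,
                         final_iteration = res$final_iteration,
                         diagnostic = res$diagnostic, iterations = trace),
                    file.path(dir, "trace.json"))

  write_json_stable(list(wcss_by_k = as.list(pipeline$wcss_by_k),
                         elbow_k = pipeline$elbow_k,
                         k_used = pipeline$k),
                    file.path(dir, "validity.json"))
  write_csv_strict(data.frame(k = as.integer(names(pipeline$wcss_by_k)),
                              wcss = as.numeric(pipeline$wcss_by_k)),
                   file.path(dir, "wcss_curve.csv"))

  write_csv_strict(as.data.frame(res$final_signals),
                   file.path(dir, "signals.csv"))
  if (!is.null(pipeline$profile)) {
    write_csv_strict(pipeline$profile, file.path(dir, "profile.csv"))
  }
  write_json_stable(run_info(pipeline$seed), file.path(dir, "run_info.json"))
  invisible(list.files(dir, full.names = TRUE))
}

#' Write an impact table
#'
#' Writes the per-cell table (`impact.csv`, mirroring the published
#' percent/N/SE layout) and the per-cluster exposure differences
#' (`impact_differences.csv`).
#'
#' @param impact an [impact_table()] result.
#' @param dir output directory.
#' @param seed seed recorded in the sidecar.
#' @return Invisibly, the files written.
#' @export
impact_to_files <- function(impact, dir, seed = NA_integer_) {
  stopifnot(inherits(impact, "impact_table"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_csv_strict(impact$cells, file.path(dir, "impact.csv"))
  write_csv_strict(impact$differences, file.path(dir, "impact_differences.csv"))
  write_json_stable(run_info(seed), file.path(dir, "run_info.json"))
  invisible(file.path(dir, c("impact.csv", "impact_differences.csv")))
}
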