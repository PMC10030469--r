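#' Iterative segmentation loop
#'
#' Orchestrates the three-step refinement procedure. Step 1 clusters on
#' the predefined men's feature subset and detects strong signals on the
#' combined matrix. Each further iteration (a) builds the per-respondent
#' signal-strength score from the current strong-signal set, (b) fits an
#' L1-regularised regression of that score on the combined matrix with a
#' cross-validated penalty, (c) re-clusters on the selected features, and
#' (d) re-detects strong signals. The loop continues only while the
#' strong-signal count strictly increases; a tie or decrease, a repeated
#' signal set, an empty Lasso selection, or the iteration cap stops it.
#' The returned model is the iteration with the maximal signal count
#' (ties resolved toward the latest, i.e. most refined, iteration).
#'
#' @param men_encoded encoded matrix of the predefined step-1 subset
#'   (men's sociodemographic and phone access/use variables).
#' @param combined_encoded encoded matrix of the merged couples' data,
#'   health variables already excluded; indicator columns of this matrix
#'   are the universe for signal detection and Lasso selection.
#' @param k number of clusters, held fixed across iterations.
#' @param p_min,d_min strong-signal thresholds (percent / points).
#' @param max_iterations safety bound on loop passes.
#' @param n_init K-Means restarts per fit.
#' @param cv_folds,alpha_grid penalty-selection controls; see
#'   [select_alpha()].
#' @param seed master seed; every clustering restart and CV split uses a
#'   seed derived from it, so a rerun reproduces the full trace.
#' @return A `segmentation_result`: `trace` (list of per-iteration
#'   records: `iteration`, `features`, `model`, `signals`,
#'   `signal_count`), `final_model`, `final_signals`, `final_iteration`,
#'   `converged`, `k` and `diagnostic`.
#' @export
run_segmentation <- function(men_encoded, combined_encoded, k,
                             p_min = 70, d_min = 50,
                             max_iterations = 20, n_init = 10,
                             cv_folds = 5, alpha_grid = NULL, seed = 1L) {
  men_X <- as.matrix(men_encoded)
  comb_X <- as.matrix(combined_encoded)
  stopifnot(nrow(men_X) == nrow(comb_X))
  indicator_cols <- colnames(comb_X)[apply(comb_X, 2, is_indicator)]
  if (length(indicator_cols) == 0) {
    stopf("combined matrix has no indicator columns for signal detection")
  }

  detect <- function(labels) {
    detect_strong_signals(
      prevalence_table(comb_X[, indicator_cols, drop = FALSE], labels),
      p_min = p_min, d_min = d_min)
  }
  record <- function(iteration, features, model, signals) {
    list(iteration = iteration, features = features, model = model,
         signals = signals, signal_count = nrow(signals))
  }

  model <- kmeans_fit(men_X, k, n_init = n_init, seed = derive_seed(seed, 1L))
  signals <- detect(model$labels)
  trace <- list(record(1L, colnames(men_X), model, signals))
  converged <- FALSE
  diagnostic <- NULL

  if (nrow(signals) == 0) {
    diagnostic <- "no strong signals after step 1; loop not started"
  } else if (max_iterations >= 2) {
    for (it in seq.int(2L, max_iterations)) {
      prev_rec <- trace[[length(trace)]]
      y <- signal_strength_score(comb_X, prev_rec$signals)
      alpha <- select_alpha(comb_X, y, alpha_grid = alpha_grid,
                            folds = cv_folds,
                            seed = derive_seed(seed, 100L + it))
      fit <- lasso_fit(comb_X, y, alpha = as.numeric(alpha))
      feats <- selected_features(fit)
      if (length(feats) == 0) {
        diagnostic <- sprintf("iteration %d: Lasso selected no features", it)
        break
      }
      model <- kmeans_fit(comb_X[, feats, drop = FALSE], k, n_init = n_init,
                          seed = derive_seed(seed, it))
      signals <- detect(model$labels)
      trace[[length(trace) + 1L]] <- record(it, feats, model, signals)
      if (nrow(signals) <= prev_rec$signal_count) {
        converged <- TRUE
        diagnostic <- sprintf(
          "stopped at iteration %d: no gain in strong signals (%d vs %d)",
          it, nrow(signals), prev_rec$signal_count)
        break
      }
      if (setequal(signals$variable, prev_rec$signals$variable)) {
        converged <- TRUE
        diagnostic <- sprintf("stopped at iteration %d: signal set repeated", it)
        break
      }
      if (it == max_iterations) {
        diagnostic <- sprintf("iteration cap (%d) reached", max_iterations)
      }
    }
  }

  counts <- vapply(trace, `[[`, integer(1), "signal_count")
  best_i <- max(which(counts == max(counts)))  # ties -> latest iteration
  structure(
    list(trace = trace,
         final_model = trace[[best_i]]$model,
         final_signals = trace[[best_i]]$signals,
         final_iteration = trace[[best_i]]$iteration,
         converged = converged,
         k = k,
         seed = as.integer(seed),
         diagnostic = diagnostic %||% "completed"),
    class = "segmentation_result")
}

#' @export
print.segmentation_result <- function(x, ...) {
  counts <- vapply(x$trace, `[[`, integer(1), "signal_count")
  cat(sprintf("<segmentation_result> k = %d, %d iteration(s), converged = %s\n",
              x$k, length(x$trace), x$converged))
  cat("  strong-signal counts:", paste(counts, collapse = " -> "), "\n")
  cat(sprintf("  final model from iteration %d (%d strong signals)\n",
              x$final_iteration, nrow(x$final_signals)))
  cat(" ", x$diagnostic, "\n")
  invisible(x)
}
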