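#!/usr/bin/env Rscript

# Step 3: choose the number of clusters on the men's predefined step-1
# subset (sociodemographic + phone access/use): the elbow on the WCSS
# curve, cross-checked by silhouette, Calinski-Harabasz and Ray-Turi at
# the candidate K values.

library(coupleseg)

seed <- 1L
svy <- read_survey_files("results/data")
filtered <- filter_variables(merge_couples(svy$men, svy$women))
enc <- encode(filtered)
prov <- attr(enc, "provenance")
dict <- filtered$dictionary
men_cols <- prov$column[
  dict$role[match(prov$source, dict$name)] == "man" &
    dict$domain[match(prov$source, dict$name)] %in%
      c("sociodemographic", "phone")]
men_X <- enc[, men_cols, drop = FALSE]

wcss <- wcss_curve(men_X, 6, seed = seed)
elbow <- elbow_select(wcss)
cat("WCSS by K:\n")
print(round(wcss, 1))
cat("Elbow choice of K:", as.integer(elbow), "\n")

metrics <- do.call(rbind, lapply(2:5, function(k) {
  fit <- kmeans_fit(men_X, k, seed = seed + k)
  data.frame(k = k,
             wcss = fit$inertia,
             mean_silhouette = silhouette_widths(men_X, fit$labels)$mean,
             calinski_harabasz = calinski_harabasz(men_X, fit$labels),
             ray_turi = ray_turi(men_X, fit$labels))
}))
print(metrics, digits = 4)
cat(sprintf("Best K by silhouette/CH (max) and Ray-Turi (min): %d / %d / %d\n",
            metrics$k[which.max(metrics$mean_silhouette)],
            metrics$k[which.max(metrics$calinski_harabasz)],
            metrics$k[which.min(metrics$ray_turi)]))

dir.create("results/validity", showWarnings = FALSE, recursive = TRUE)
write.csv(data.frame(k = as.integer(names(wcss)), wcss = as.numeric(wcss)),
          "results/validity/wcss_curve.csv", row.names = FALSE)
write.csv(metrics, "results/validity/metrics_by_k.csv", row.names = FALSE)
jsonlite::write_json(list(elbow_k = as.integer(elbow)),
                     "results/validity/elbow.json", auto_unbox = TRUE)
cat("Wrote results/validity/\n")
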