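# Shared fixtures, built in code.

# two tight, well-separated 2-D clusters of three points each
six_points <- function() {
  matrix(c(0, 0, 0, 1, 1, 0, 10, 10, 10, 11, 11, 10),
         ncol = 2, byrow = TRUE)
}
six_labels <- c(1L, 1L, 1L, 2L, 2L, 2L)

# hand-built three-couple survey pair for the preprocessing tests
tiny_survey_pair <- function() {
  men <- survey_table(
    data.frame(couple_id = c("a", "b", "c"),
               owns_phone = c(1, 0, 1),
               caste = c("x", "y", "x"),
               stringsAsFactors = FALSE),
    data.frame(name = c("owns_phone", "caste"),
               role = "man",
               kind = c("binary", "categorical"),
               domain = c("phone", "sociodemographic"),
               clustering_eligible = TRUE,
               stringsAsFactors = FALSE))
  women <- survey_table(
    data.frame(couple_id = c("c", "a", "b"),
               owns_phone = c(0, 1, 0),
               knows_ors = c(1, 1, 0),
               stringsAsFactors = FALSE),
    data.frame(name = c("owns_phone", "knows_ors"),
               role = "woman",
               kind = "binary",
               domain = c("phone", "health"),
               clustering_eligible = TRUE,
               stringsAsFactors = FALSE))
  list(men = men, women = women)
}

planted_signal_columns <- function() {
  c(paste0("man_", c("owns_smartphone", "uses_whatsapp", "owns_feature_phone",
                     "phone_not_shared", "watches_youtube",
                     "daily_mobile_internet")),
    paste0("woman_", c("owns_phone", "owns_feature_phone",
                       "watches_shows_other_phone", "uses_whatsapp",
                       "internet_search", "five_digital_skills")))
}

# near-deterministic profiles: each cluster identified by two of six signals
crisp_signal_specs <- function(lo = 0.01, hi = 0.99) {
  prof <- list(c(hi, lo, lo), c(lo, hi, lo), c(lo, lo, hi))
  specs <- list()
  for (i in 1:3) {
    specs[[length(specs) + 1]] <-
      list(name = paste0("sig_m", i), role = "man", prev = prof[[i]])
    specs[[length(specs) + 1]] <-
      list(name = paste0("sig_w", i), role = "woman", prev = prof[[i]])
  }
  specs
}

# small noiseless configuration with crisp planted structure
crisp_config <- function(n = 400, seed = 1, ...) {
  generator_config(n_couples = n, k_true = 3,
                   cluster_proportions = c(0.4, 0.3, 0.3),
                   signal_specs = crisp_signal_specs(),
                   n_noise_binary = 0, n_noise_categorical = 0,
                   missing_rate = 0, seed = seed, ...)
}

# scaled-down version of the default fixture for unit tests
small_default_config <- function(n = 800, seed = 1,
                                 n_noise_binary = 40,
                                 n_noise_categorical = 10, ...) {
  generator_config(n_couples = n,
                   n_noise_binary = n_noise_binary,
                   n_noise_categorical = n_noise_categorical,
                   seed = seed, ...)
}

encode_survey_pair <- function(sim) {
  encode(filter_variables(merge_couples(sim$men, sim$women)))
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)
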