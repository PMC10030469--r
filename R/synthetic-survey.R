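#' Default planted signal profiles
#'
#' Twelve binary phone-access/use variables (six per spouse) with
#' per-cluster Bernoulli prevalences. Every profile satisfies the
#' strong-signal rule (at least 70% prevalence in one cluster and a gap of
#' at least 50 percentage points to another) with margin to spare at the
#' default sample size, and the men's six profiles jointly separate all
#' three cluster pairs by comparable centroid distances, so that the
#' men-only starting subset already carries three-way structure. The
#' smartphone profile (6%, 88%, 75%) mirrors the canonical worked example
#' of a strong signal.
#'
#' @return A list of signal specifications, each a list with elements
#'   `name`, `role` (`"man"` or `"woman"`) and `prev` (per-cluster
#'   prevalence vector).
#' @export
default_signal_specs <- function() {
  spec <- function(name, role, prev) list(name = name, role = role, prev = prev)
  list(
    spec("owns_smartphone",           "man",   c(0.06, 0.88, 0.75)),
    spec("uses_whatsapp",             "man",   c(0.05, 0.95, 0.15)),
    spec("owns_feature_phone",        "man",   c(0.90, 0.05, 0.85)),
    spec("phone_not_shared",          "man",   c(0.08, 0.20, 0.92)),
    spec("watches_youtube",           "man",   c(0.06, 0.90, 0.12)),
    spec("daily_mobile_internet",     "man",   c(0.10, 0.12, 0.90)),
    spec("owns_phone",                "woman", c(0.15, 0.40, 0.92)),
    spec("owns_feature_phone",        "woman", c(0.78, 0.10, 0.60)),
    spec("watches_shows_other_phone", "woman", c(0.18, 0.80, 0.70)),
    spec("uses_whatsapp",             "woman", c(0.06, 0.35, 0.78)),
    spec("internet_search",           "woman", c(0.08, 0.30, 0.76)),
    spec("five_digital_skills",       "woman", c(0.08, 0.20, 0.80))
  )
}

#' Default binary health outcomes
#'
#' Three outcomes with per-cluster baseline rates and additive exposure
#' effects (percentage-point changes among the exposed arm), echoing the
#' family-planning, immunisation and infant-feeding rows of the published
#' differential-impact table: the middle cluster carries the largest
#' planted effect.
#'
#' @return A list of outcome specifications (`name`, `baseline`, `effect`).
#' @export
default_outcome_specs <- function() {
  list(
    list(name = "reversible_methods",
         baseline = c(0.30, 0.30, 0.41), effect = c(0.00, 0.08, 0.03)),
    list(name = "immunisation_10wk",
         baseline = c(0.72, 0.72, 0.75), effect = c(0.04, 0.07, 0.01)),
    list(name = "complementary_feeding_decision",
         baseline = c(0.89, 0.82, 0.88), effect = c(0.03, 0.08, 0.00))
  )
}

#' Configuration for the synthetic couple-survey generator
#'
#' Defines the study conditions the generator emulates: couples sampled
#' from `k_true` latent clusters with fixed proportions, binary signal
#' variables whose prevalence depends on the cluster, irrelevant binary
#' and categorical noise variables independent of the cluster, completely
#' at random missingness, and binary health outcomes whose exposure
#' effect differs by cluster.
#'
#' @param n_couples number of couples to generate.
#' @param k_true number of planted clusters.
#' @param cluster_proportions simplex vector of length `k_true`; defaults
#'   echo the published cluster shares (40%, 19%, 41%).
#' @param signal_specs list of planted signal profiles; see
#'   [default_signal_specs()].
#' @param n_noise_binary count of irrelevant binary variables.
#' @param noise_binary_range range of the per-variable uniform draw of
#'   noise prevalences.
#' @param n_noise_categorical count of irrelevant categorical variables.
#' @param noise_categorical_levels candidate level counts for categorical
#'   noise; one is drawn per variable.
#' @param missing_rate fraction of survey cells set missing, completely
#'   at random.
#' @param outcome_specs list of outcome profiles; see
#'   [default_outcome_specs()].
#' @param exposure_prob probability a couple is in the exposed arm.
#' @param seed integer master seed.
#' @return A validated list of class `generator_config`.
#' @export
generator_config <- function(n_couples = 3000,
                             k_true = 3,
                             cluster_proportions = c(0.40, 0.19, 0.41),
                             signal_specs = default_signal_specs(),
                             n_noise_binary = 150,
                             noise_binary_range = c(0.1, 0.9),
                             n_noise_categorical = 50,
                             noise_categorical_levels = 3:5,
                             missing_rate = 0.02,
                             outcome_specs = default_outcome_specs(),
                             exposure_prob = 0.5,
                             seed = 1L) {
  config <- structure(
    list(n_couples = n_couples, k_true = k_true,
         cluster_proportions = cluster_proportions,
         signal_specs = signal_specs,
         n_noise_binary = n_noise_binary,
         noise_binary_range = noise_binary_range,
         n_noise_categorical = n_noise_categorical,
         noise_categorical_levels = noise_categorical_levels,
         missing_rate = missing_rate,
         outcome_specs = outcome_specs,
         exposure_prob = exposure_prob,
         seed = as.integer(seed)),
    class = "generator_config"
  )
  validate_generator_config(config)
  config
}

#' Validate a generator configuration
#'
#' Rejects invalid configurations with a message naming the offending
#' field: non-simplex cluster proportions, prevalences or rates outside
#' `[0, 1]`, exposure effects that push a rate outside `[0, 1]`, and
#' out-of-range missingness or exposure probabilities.
#'
#' @param config a `generator_config`.
#' @return `config`, invisibly, if valid.
#' @export
validate_generator_config <- function(config) {
  k <- config$k_true
  if (!is.numeric(config$n_couples) || config$n_couples < 1) {
    stopf("n_couples: must be a positive integer, got %s", config$n_couples)
  }
  if (!is.numeric(k) || k < 1) stopf("k_true: must be a positive integer")
  p <- config$cluster_proportions
  if (length(p) != k) {
    stopf("cluster_proportions: length %d does not match k_true = %d",
          length(p), k)
  }
  if (abs(sum(p) - 1) > 1e-9 || any(p <= 0)) {
    stopf("cluster_proportions: must be positive and sum to 1 (sum = %.10f)",
          sum(p))
  }
  for (s in config$signal_specs) {
    if (length(s$prev) != k) {
      stopf("signal_specs: '%s' has %d prevalences for k_true = %d",
            s$name, length(s$prev), k)
    }
    if (any(s$prev < 0 | s$prev > 1)) {
      stopf("signal_specs: '%s' prevalence outside [0, 1]", s$name)
    }
    if (!s$role %in% c("man", "woman")) {
      stopf("signal_specs: '%s' role must be 'man' or 'woman'", s$name)
    }
  }
  if (config$n_noise_binary < 0) stopf("n_noise_binary: must be >= 0")
  r <- config$noise_binary_range
  if (length(r) != 2 || any(r < 0 | r > 1) || r[1] > r[2]) {
    stopf("noise_binary_range: must be an increasing pair within [0, 1]")
  }
  if (config$n_noise_categorical < 0) stopf("n_noise_categorical: must be >= 0")
  if (any(config$noise_categorical_levels < 2)) {
    stopf("noise_categorical_levels: all level counts must be >= 2")
  }
  if (config$missing_rate < 0 || config$missing_rate >= 1) {
    stopf("missing_rate: must lie in [0, 1), got %s", config$missing_rate)
  }
  for (o in config$outcome_specs) {
    if (length(o$baseline) != k || length(o$effect) != k) {
      stopf("outcome_specs: '%s' baseline/effect length must equal k_true",
            o$name)
    }
    if (any(o$baseline < 0 | o$baseline > 1)) {
      stopf("outcome_specs: '%s' baseline outside [0, 1]", o$name)
    }
    rate <- o$baseline + o$effect
    if (any(rate < 0 | rate > 1)) {
      stopf("outcome_specs: '%s' baseline + effect outside [0, 1]", o$name)
    }
  }
  if (config$exposure_prob <= 0 || config$exposure_prob > 1) {
    stopf("exposure_prob: must lie in (0, 1], got %s", config$exposure_prob)
  }
  invisible(config)
}

#' Generate a synthetic couple survey
#'
#' Draws couples from the planted clusters, fills the spouses' tables
#' with cluster-dependent signal variables and cluster-independent noise
#' variables, applies completely-at-random missingness, and attaches
#' exposure plus binary health outcomes (tagged clustering-ineligible in
#' the dictionary) to the women's table.
#'
#' @param config a [generator_config()].
#' @return A list with elements `men` and `women` (both
#'   [survey_table] objects sharing `couple_id` keys 1:1) and `truth`
#'   (data.frame of `couple_id` and `true_cluster`).
#' @export
generate_couple_survey <- function(config) {
  validate_generator_config(config)
  n <- config$n_couples
  k <- config$k_true
  with_seed(config$seed, {
    cluster <- sample.int(k, n, replace = TRUE,
                          prob = config$cluster_proportions)
    couple_id <- sprintf("C%05d", seq_len(n))
    truth <- data.frame(couple_id = couple_id, true_cluster = cluster,
                        stringsAsFactors = FALSE)

    tables <- list(man = list(), woman = list())
    dicts <- list(man = list(), woman = list())
    add_var <- function(role, name, values, kind, domain, eligible = TRUE) {
      tables[[role]][[name]] <<- values
      dicts[[role]][[name]] <<- data.frame(
        name = name, role = role, kind = kind, domain = domain,
        clustering_eligible = eligible, stringsAsFactors = FALSE)
    }

    for (s in config$signal_specs) {
      add_var(s$role, s$name, rbinom(n, 1, s$prev[cluster]),
              kind = "binary", domain = "phone")
    }

    noise_domains <- c("sociodemographic", "phone", "health")
    noise_domain_prob <- c(0.60, 0.25, 0.15)
    if (config$n_noise_binary > 0) {
      for (i in seq_len(config$n_noise_binary)) {
        p <- runif(1, config$noise_binary_range[1], config$noise_binary_range[2])
        role <- if (i %% 2 == 1) "man" else "woman"
        domain <- sample(noise_domains, 1, prob = noise_domain_prob)
        add_var(role, sprintf("nb_%03d", i), rbinom(n, 1, p),
                kind = "binary", domain = domain)
      }
    }
    if (config$n_noise_categorical > 0) {
      for (i in seq_len(config$n_noise_categorical)) {
        L <- if (length(config$noise_categorical_levels) == 1) {
          config$noise_categorical_levels
        } else {
          sample(config$noise_categorical_levels, 1)
        }
        role <- if (i %% 2 == 1) "man" else "woman"
        domain <- sample(noise_domains, 1, prob = noise_domain_prob)
        add_var(role, sprintf("nc_%03d", i),
                paste0("l", sample.int(L, n, replace = TRUE)),
                kind = "categorical", domain = domain)
      }
    }

    # completely-at-random missingness on the survey variables
    if (config$missing_rate > 0) {
      for (role in c("man", "woman")) {
        for (nm in names(tables[[role]])) {
          miss <- runif(n) < config$missing_rate
          tables[[role]][[nm]][miss] <- NA
        }
      }
    }

    outcomes <- generate_outcomes(truth, config,
                                  seed = derive_seed(config$seed, 77L))

    as_table <- function(cols) {
      d <- data.frame(couple_id = couple_id, stringsAsFactors = FALSE)
      for (nm in names(cols)) d[[nm]] <- cols[[nm]]
      d
    }
    men_data <- as_table(tables$man)
    women_data <- as_table(tables$woman)
    stopifnot(identical(outcomes$couple_id, women_data$couple_id))
    women_data <- cbind(women_data, outcomes[, -1, drop = FALSE])

    empty_dict <- data.frame(name = character(), role = character(),
                             kind = character(), domain = character(),
                             clustering_eligible = logical(),
                             stringsAsFactors = FALSE)
    men_dict <- do.call(rbind, dicts$man) %||% empty_dict
    women_dict <- do.call(rbind, dicts$woman) %||% empty_dict
    outcome_dict <- data.frame(
      name = c("exposure", vapply(config$outcome_specs, `[[`, "", "name")),
      role = "woman",
      kind = "binary",
      domain = c("design", rep("health", length(config$outcome_specs))),
      clustering_eligible = FALSE, stringsAsFactors = FALSE)

    list(men = survey_table(men_data, men_dict),
         women = survey_table(women_data, rbind(women_dict, outcome_dict)),
         truth = truth)
  })
}

#' Generate exposure and binary outcomes for known cluster labels
#'
#' For each outcome, the rate among the unexposed in cluster `c` is the
#' cluster baseline and the rate among the exposed is baseline plus the
#' cluster's additive effect.
#'
#' @param truth data.frame with `couple_id` and `true_cluster`.
#' @param config a [generator_config()] carrying `outcome_specs` and
#'   `exposure_prob`.
#' @param seed seed for the outcome draws.
#' @return data.frame with `couple_id`, `exposure` (0/1) and one 0/1
#'   column per outcome.
#' @export
generate_outcomes <- function(truth, config, seed = config$seed) {
  validate_generator_config(config)
  if (!all(c("couple_id", "true_cluster") %in% names(truth))) {
    stopf("truth: must have couple_id and true_cluster columns")
  }
  cl <- truth$true_cluster
  if (any(cl < 1 | cl > config$k_true)) {
    stopf("truth: true_cluster outside 1..k_true")
  }
  n <- nrow(truth)
  with_seed(seed, {
    exposure <- rbinom(n, 1, config$exposure_prob)
    out <- data.frame(couple_id = truth$couple_id, exposure = exposure,
                      stringsAsFactors = FALSE)
    for (o in config$outcome_specs) {
      rate <- o$baseline[cl] + exposure * o$effect[cl]
      out[[o$name]] <- rbinom(n, 1, rate)
    }
    out
  })
}
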