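test_that("merge_couples inner-joins on couple_id with role prefixes", {
  pair <- tiny_survey_pair()
  merged <- merge_couples(pair$men, pair$women)
  expect_equal(nrow(merged$data), 3)
  expect_setequal(names(merged$data),
                  c("couple_id", "man_owns_phone", "man_caste",
                    "woman_owns_phone", "woman_knows_ors"))
  # women's rows were in a different key order; values must realign
  expect_equal(merged$data$woman_owns_phone[merged$data$couple_id == "a"], 1)
  expect_equal(merged$data$woman_owns_phone[merged$data$couple_id == "c"], 0)
})

test_that("merge with an empty-column table reproduces the other table", {
  pair <- tiny_survey_pair()
  empty_women <- survey_table(
    data.frame(couple_id = c("a", "b", "c"), stringsAsFactors = FALSE),
    data.frame(name = character(), role = character(), kind = character(),
               domain = character(), clustering_eligible = logical(),
               stringsAsFactors = FALSE))
  merged <- merge_couples(pair$men, empty_women)
  expect_setequal(names(merged$data), c("couple_id", "man_owns_phone", "man_caste"))
  expect_equal(merged$data$man_owns_phone, pair$men$data$owns_phone)
})

test_that("key violations are rejected by name", {
  expect_error(
    survey_table(data.frame(couple_id = c("a", "a"), x = 1:2),
                 data.frame(name = "x", role = "man", kind = "binary",
                            domain = "phone", clustering_eligible = TRUE)),
    "duplicate couple_id.*a")
  pair <- tiny_survey_pair()
  other <- survey_table(
    data.frame(couple_id = c("z1", "z2"), v = c(0, 1)),
    data.frame(name = "v", role = "woman", kind = "binary",
               domain = "phone", clustering_eligible = TRUE))
  expect_error(merge_couples(pair$men, other), "no couple_id")
})

test_that("filter_variables drops health and ineligible columns and logs", {
  pair <- tiny_survey_pair()
  merged <- merge_couples(pair$men, pair$women)
  filtered <- filter_variables(merged)
  expect_setequal(setdiff(names(filtered$data), "couple_id"),
                  c("man_owns_phone", "man_caste", "woman_owns_phone"))
  expect_equal(attr(filtered, "filter_log")$dropped, "woman_knows_ors")

  no_health <- filter_variables(pair$men)
  expect_identical(no_health$data, pair$men$data)

  all_health <- survey_table(
    data.frame(couple_id = "a", h = 1),
    data.frame(name = "h", role = "man", kind = "binary",
               domain = "health", clustering_eligible = TRUE))
  expect_error(filter_variables(all_health), "all variables")
})

test_that("encode one-hots categoricals with rows summing to one", {
  tab <- survey_table(
    data.frame(couple_id = c("a", "b", "c", "d"),
               grp = c("x", "y", "z", "x"), stringsAsFactors = FALSE),
    data.frame(name = "grp", role = "man", kind = "categorical",
               domain = "sociodemographic", clustering_eligible = TRUE))
  enc <- encode(tab)
  expect_equal(ncol(enc), 3)
  expect_true(all(rowSums(enc) == 1))
  expect_true(all(enc %in% c(0, 1)))
  prov <- attr(enc, "provenance")
  expect_equal(prov$source, rep("grp", 3))
  expect_setequal(prov$level, c("x", "y", "z"))
})

test_that("encode z-scores continuous columns", {
  tab <- survey_table(
    data.frame(couple_id = c("a", "b", "c"), age = c(1, 2, 3)),
    data.frame(name = "age", role = "man", kind = "continuous",
               domain = "sociodemographic", clustering_eligible = TRUE))
  enc <- encode(tab)
  expect_equal(as.numeric(enc[, "age"]), c(-1.2247, 0, 1.2247),
               tolerance = 1e-4)
})

test_that("constant columns are removed and logged", {
  tab <- survey_table(
    data.frame(couple_id = c("a", "b"), keep = c(0, 1), flat = c(1, 1)),
    data.frame(name = c("keep", "flat"), role = "man", kind = "binary",
               domain = "phone", clustering_eligible = TRUE))
  enc <- encode(tab)
  expect_equal(colnames(enc), "keep")
  expect_equal(attr(enc, "encode_log")$dropped_zero_variance, "flat")
})

test_that("encode is idempotent on already-encoded indicator data", {
  sim <- generate_couple_survey(crisp_config(n = 60, seed = 2))
  enc1 <- encode(sim$men)
  re <- survey_table(
    data.frame(couple_id = attr(enc1, "couple_id"),
               as.data.frame(unclass(enc1)), check.names = FALSE,
               stringsAsFactors = FALSE),
    data.frame(name = colnames(enc1), role = "man", kind = "binary",
               domain = "phone", clustering_eligible = TRUE))
  enc2 <- encode(re)
  expect_equal(unclass(enc2)[, colnames(enc1)], unclass(enc1),
               ignore_attr = TRUE)
})

test_that("missing values are imputed by mode or mean under the default policy", {
  tab <- survey_table(
    data.frame(couple_id = c("a", "b", "c", "d"),
               b = c(1, 1, 0, NA),
               g = c("x", "x", "y", NA),
               z = c(2, NA, 4, 6),
               stringsAsFactors = FALSE),
    data.frame(name = c("b", "g", "z"), role = "man",
               kind = c("binary", "categorical", "continuous"),
               domain = "sociodemographic", clustering_eligible = TRUE))
  enc <- encode(tab)
  expect_equal(enc[4, "b"], c(b = 1))          # mode
  expect_equal(enc[4, "g.x"], c(g.x = 1))      # modal level
  expect_equal(attr(enc, "encode_log")$n_imputed, 3L)
  # mean imputation leaves the imputed continuous value at z-score 0
  expect_equal(enc[2, "z"], c(z = 0))

  dropped <- encode(tab, missing_policy = "drop_incomplete")
  expect_equal(nrow(dropped), 2)
})

test_that("entirely-missing and unknown-kind columns are rejected", {
  tab <- survey_table(
    data.frame(couple_id = c("a", "b"), v = c(NA, NA)),
    data.frame(name = "v", role = "man", kind = "binary",
               domain = "phone", clustering_eligible = TRUE))
  expect_error(encode(tab), "entirely missing")
  expect_error(
    survey_table(data.frame(couple_id = "a", v = 1),
                 data.frame(name = "v", role = "man", kind = "text",
                            domain = "phone", clustering_eligible = TRUE)),
    "unknown variable kind")
})

test_that("row order and couple alignment survive merge, filter, encode", {
  sim <- generate_couple_survey(small_default_config(n = 150, seed = 4))
  enc <- encode_survey_pair(sim)
  expect_identical(attr(enc, "couple_id"), sim$truth$couple_id)
})
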