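# Cleaning rules, age grouping and stratified summarization.

make_records <- function(...) {
  base <- data.frame(age = 30, sex = "female", height = 165, weight = 65,
                     pregnant = FALSE, stratum = "rural",
                     study_id = "s1", sample_weight = 1,
                     stringsAsFactors = FALSE)
  rows <- list(...)
  if (!length(rows)) {
    return(base)
  }
  do.call(rbind, lapply(rows, function(r) {
    out <- base
    for (nm in names(r)) out[[nm]] <- r[[nm]]
    out
  }))
}

test_that("cleaning applies the plausibility and eligibility rules", {
  recs <- make_records(
    list(),                                        # kept
    list(height = 170, weight = 28),               # BMI 9.7 -> implausible
    list(height = 250, weight = 100),              # boundary kept
    list(age = 17),                                # under age
    list(pregnant = TRUE),
    list(weight = NA_real_),                       # missing
    list(height = 99),                             # implausible height
    list(weight = 310),                            # implausible weight
    list(stratum = "unknown")                      # study records residence
  )
  out <- clean_individual_records(recs)
  log <- setNames(out$exclusion_log$count, out$exclusion_log$reason)
  expect_equal(nrow(out$kept), 2)
  expect_equal(unname(log["implausible BMI"]), 1L)
  expect_equal(unname(log["age"]), 1L)
  expect_equal(unname(log["pregnant"]), 1L)
  expect_equal(unname(log["missing"]), 1L)
  expect_equal(unname(log["implausible height/weight"]), 2L)
  expect_equal(unname(log["unknown stratum"]), 1L)
  expect_equal(sum(log) + nrow(out$kept), nrow(recs))
})

test_that("unknown stratum is kept when the study never recorded residence", {
  recs <- make_records(list(stratum = "unknown"),
                       list(stratum = "unknown", age = 45))
  out <- clean_individual_records(recs)
  expect_equal(nrow(out$kept), 2)
})

test_that("cleaning is idempotent", {
  recs <- make_records(list(), list(age = 17), list(stratum = "unknown"),
                       list(height = 120, weight = 14))
  once <- clean_individual_records(recs)
  twice <- clean_individual_records(once$kept[, names(recs)])
  expect_equal(nrow(twice$kept), nrow(once$kept))
  expect_equal(sum(twice$exclusion_log$count), 0)
})

test_that("ages map to the canonical observation groups", {
  g <- assign_age_group(c(18, 19, 37, 80, 95, 20.9))
  expect_equal(g$age_lo, c(18, 19, 30, 80, 80, 20))
  expect_equal(g$age_hi, c(18, 19, 39, Inf, Inf, 29))
  expect_error(assign_age_group(17), "18")
})

test_that("stratified summaries reproduce weighted-mean arithmetic", {
  design <- list(study_id = "s1", country = "C01", mid_year = 2000,
                 coverage = "national")
  recs <- make_records(list(weight = 20 * 1.65^2),
                       list(weight = 22 * 1.65^2),
                       list(weight = 24 * 1.65^2))
  recs$bmi <- recs$weight / (recs$height / 100)^2
  out <- summarize_stratified(recs, design)
  expect_equal(nrow(out), 1)
  expect_equal(out$mean_bmi, 22, tolerance = 1e-9)
  expect_equal(out$n_eff, 3)

  recs2 <- make_records(list(weight = 20 * 1.65^2, sample_weight = 1),
                        list(weight = 30 * 1.65^2, sample_weight = 3))
  recs2$bmi <- recs2$weight / (recs2$height / 100)^2
  out2 <- summarize_stratified(recs2, design)
  expect_equal(out2$mean_bmi, 27.5, tolerance = 1e-9)
})

test_that("summaries are invariant to order and weight rescaling", {
  design <- list(study_id = "s1", country = "C01", mid_year = 2000,
                 coverage = "national")
  set.seed(1)
  recs <- do.call(make_records, lapply(1:30, function(i) {
    list(age = sample(18:79, 1), weight = runif(1, 50, 90),
         sample_weight = runif(1, 0.5, 3),
         stratum = sample(c("rural", "urban"), 1))
  }))
  recs$bmi <- recs$weight / (recs$height / 100)^2
  a <- summarize_stratified(recs, design)
  b <- summarize_stratified(recs[sample(nrow(recs)), ], design)
  recs3 <- recs
  recs3$sample_weight <- recs3$sample_weight * 17
  c3 <- summarize_stratified(recs3, design)
  expect_equal(a$mean_bmi, b$mean_bmi, tolerance = 1e-12)
  expect_equal(a$se, b$se, tolerance = 1e-12)
  expect_equal(a$mean_bmi, c3$mean_bmi, tolerance = 1e-12)
  expect_equal(a$se, c3$se, tolerance = 1e-12)
  expect_equal(a$n_eff, c3$n_eff, tolerance = 1e-12)
})

test_that("a study without residence info produces mixed rows", {
  design <- list(study_id = "s1", country = "C01", mid_year = 2000,
                 coverage = "subnational")
  recs <- make_records(list(stratum = "unknown"),
                       list(stratum = "unknown", weight = 70))
  recs$bmi <- recs$weight / (recs$height / 100)^2
  out <- summarize_stratified(recs, design)
  expect_true(all(out$stratum == "mixed"))
})

test_that("single-record cells are flagged and use a pooled variance", {
  design <- list(study_id = "s1", country = "C01", mid_year = 2000,
                 coverage = "national")
  recs <- make_records(list(age = 25), list(age = 26),
                       list(age = 26, weight = 70), list(age = 45))
  recs$bmi <- recs$weight / (recs$height / 100)^2
  out <- summarize_stratified(recs, design)
  small <- out[out$small_cell, ]
  expect_equal(nrow(small), 1)
  expect_true(is.finite(small$se) && small$se > 0)
})

test_that("weighted SE agrees with a bootstrap oracle", {
  set.seed(99)
  n <- 120
  recs <- data.frame(age = 35, sex = "female", height = 165,
                     weight = rnorm(n, 70, 9), pregnant = FALSE,
                     stratum = "rural", study_id = "s1",
                     sample_weight = runif(n, 0.5, 2))
  recs$bmi <- recs$weight / (recs$height / 100)^2
  design <- list(study_id = "s1", country = "C01", mid_year = 2000,
                 coverage = "national")
  out <- summarize_stratified(recs, design)
  boot <- replicate(500, {
    idx <- sample(n, replace = TRUE)
    sum(recs$sample_weight[idx] * recs$bmi[idx]) /
      sum(recs$sample_weight[idx])
  })
  expect_equal(out$se, sd(boot), tolerance = 0.15 * sd(boot))
})

test_that("schema violations are reported with rows", {
  w <- tiny_world()
  obs <- w$obs[1:5, ]
  obs$se[2] <- 0
  expect_error(validate_observations(obs), "non-positive standard error")
  obs2 <- w$obs[1:5, ]
  obs2$stratum[1] <- "suburban"
  expect_error(validate_observations(obs2), "unknown stratum")
  obs3 <- w$obs[1:5, ]
  obs3$mean_bmi[3] <- 9
  expect_error(validate_observations(obs3), "outside")
  # a mixed row is valid
  obs4 <- w$obs[w$obs$stratum == "mixed", ][1, ]
  expect_silent(validate_observations(obs4))
})
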