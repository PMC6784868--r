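# Synthetic-world generator: configuration validation, determinism,
# degenerate limits and the distributional properties the trend model
# relies on.

test_that("invalid configurations are rejected naming the field", {
  expect_error(world_config(rw2_innovation_sd = -1), "rw2_innovation_sd")
  expect_error(world_config(frac_prevalence_only = 1.5),
               "frac_prevalence_only")
  expect_error(world_config(years = integer()), "years")
  expect_error(world_config(age_groups = data.frame(age_lo = c(15, 30),
                                                    age_hi = c(29, 39))),
               "age_groups")
  expect_error(world_config(age_groups = data.frame(age_lo = c(20, 25),
                                                    age_hi = c(29, 34))),
               "non-overlapping")
})

test_that("a fully degenerate hierarchy collapses to one flat surface", {
  cfg <- world_config(trend_sd_hierarchy = c(0, 0, 0),
                      rw2_innovation_sd = 0, age_sd = 0,
                      urban_gap_base_sd = 0, urban_gap_trend_sd = 0,
                      mean_slope = 0, age_curve_scale = 0,
                      urban_gap_mean = 0, urban_gap_trend_mean = 0,
                      sexes = "female", seed = 3)
  truth <- generate_truth(cfg)
  expect_equal(max(truth$rural) - min(truth$rural), 0)
  expect_equal(unname(truth$rural[1, 1, 1, 1]), cfg$base_bmi[["female"]])
  expect_true(all(truth$gap == 0))
})

test_that("same config and seed give bitwise-identical worlds", {
  cfg <- world_config(seed = 42, sexes = "female",
                      countries_per_region = 2)
  t1 <- generate_truth(cfg)
  t2 <- generate_truth(cfg)
  expect_identical(t1$rural, t2$rural)
  expect_identical(t1$gap, t2$gap)
  p1 <- generate_population_table(cfg)
  p2 <- generate_population_table(cfg)
  expect_identical(p1, p2)
  o1 <- sample_observations(t1, p1, cfg)
  o2 <- sample_observations(t2, p2, cfg)
  expect_identical(o1, o2)
})

test_that("zero RW2 innovation gives exactly linear country time profiles", {
  cfg <- world_config(rw2_innovation_sd = 0, sexes = "female", seed = 9,
                      countries_per_region = 2)
  truth <- generate_truth(cfg)
  # per-country least-squares line through the (year, mean) profile must
  # have zero residual
  for (ci in seq_len(nrow(truth$hierarchy))) {
    prof <- truth$rural[ci, , 1, 1]
    fit <- lm(prof ~ seq_along(prof))
    expect_lt(max(abs(residuals(fit))), 1e-9)
  }
})

test_that("adding countries does not perturb existing countries' draws", {
  cfg_small <- world_config(countries_per_region = 2, sexes = "female",
                            seed = 13)
  cfg_big <- world_config(countries_per_region = 3, sexes = "female",
                          seed = 13)
  t_small <- generate_truth(cfg_small)
  t_big <- generate_truth(cfg_big)
  # country unit streams are keyed by country index, so shared indices
  # get identical RW2 and age draws; match profiles of the first country
  expect_identical(t_small$rural[1, , 1, ], t_big$rural[1, , 1, ])
})

test_that("urban shares stay in [0,1] and rise on average under defaults", {
  ends <- vapply(1:10, function(s) {
    cfg <- world_config(seed = s, countries_per_region = 2,
                        sexes = "female")
    pop <- generate_population_table(cfg)
    expect_true(all(pop$share_urban >= 0 & pop$share_urban <= 1))
    first <- pop$share_urban[pop$year == min(pop$year)]
    last <- pop$share_urban[pop$year == max(pop$year)]
    c(mean(first), mean(last))
  }, numeric(2))
  expect_gt(mean(ends[2, ]), mean(ends[1, ]))
})

test_that("zero logistic slope freezes the urban share", {
  cfg <- world_config(urban_slope_mean = 0, urban_slope_sd = 0,
                      countries_per_region = 2, sexes = "female",
                      seed = 4)
  pop <- generate_population_table(cfg)
  spread <- tapply(pop$share_urban, pop$country,
                   function(x) max(x) - min(x))
  expect_true(all(spread == 0))
})

test_that("noise-free observations equal the generating truth", {
  w <- tiny_world()
  cfg <- noise_free(w$cfg)
  truth <- generate_truth(cfg)
  pop <- generate_population_table(cfg)
  obs <- sample_observations(truth, pop, cfg)
  expect_gt(nrow(obs), 0)
  expect_lt(max(abs(obs$mean_bmi - obs$true_mean)), 1e-4)
})

test_that("mixed rows conserve the population-weighted rural/urban mean", {
  cfg <- noise_free(tiny_world()$cfg, frac_unstratified = 1)
  truth <- generate_truth(cfg)
  pop <- generate_population_table(cfg)
  obs <- sample_observations(truth, pop, cfg)
  expect_true(all(obs$stratum == "mixed"))
  for (i in seq_len(min(nrow(obs), 40))) {
    est_rows <- which(truth$est_ages$age_lo >= obs$age_lo[i] &
                        truth$est_ages$age_hi <= obs$age_hi[i])
    pl <- pop[pop$country == obs$country[i] & pop$year == obs$mid_year[i] &
                pop$sex == obs$sex[i], ]
    m <- match(truth$est_ages$age_lo[est_rows], pl$age_lo)
    w <- pl$population[m] / sum(pl$population[m])
    sh <- pl$share_urban[m][1]
    r <- bmitrend:::truth_stratum_mean(
      truth, obs$country[i], obs$mid_year[i], obs$sex[i], est_rows, "rural")
    u <- bmitrend:::truth_stratum_mean(
      truth, obs$country[i], obs$mid_year[i], obs$sex[i], est_rows, "urban")
    expected <- sum(w * (sh * u + (1 - sh) * r))
    expect_equal(obs$mean_bmi[i], expected, tolerance = 1e-4)
  }
})

test_that("reported standard errors scale as 1/sqrt(n)", {
  w <- tiny_world()
  obs <- w$obs
  fit <- lm(log(se) ~ log(n_eff), data = obs)
  expect_equal(unname(coef(fit)[2]), -0.5, tolerance = 0.02)
})

test_that("observation noise matches the reported standard error", {
  cfg <- noise_free(tiny_world()$cfg, surveys_per_country = 25,
                    n_eff_median = 250, seed = 8)
  truth <- generate_truth(cfg)
  pop <- generate_population_table(cfg)
  obs <- sample_observations(truth, pop, cfg)
  z <- (obs$mean_bmi - obs$true_mean) / obs$se
  expect_gt(length(z), 400)
  expect_equal(sd(z), 1, tolerance = 0.1)
})

test_that("hierarchy: countries cluster within regions when region SD dominates", {
  cfg <- world_config(n_super_regions = 1, regions_per_super = 40,
                      countries_per_region = 6,
                      trend_sd_hierarchy = c(0, 1.0, 0.3),
                      years = 2000:2002,
                      age_groups = data.frame(age_lo = 30, age_hi = 39),
                      sexes = "female", seed = 17)
  truth <- generate_truth(cfg)
  lev <- truth$rural[, 2, 1, 1]
  region <- truth$hierarchy$region
  within_var <- mean(tapply(lev, region, var))
  between_var <- var(tapply(lev, region, mean))
  expect_lt(within_var, between_var)
})

test_that("prevalence-only subset has the configured size and structure", {
  w <- tiny_world()
  cfg0 <- w$cfg
  cfg0$frac_prevalence_only <- 0
  split0 <- make_prevalence_only_subset(w$obs, cfg0)
  expect_equal(nrow(split0$prevalence), 0)
  expect_equal(nrow(split0$means), nrow(w$obs))

  # 2% of n rows converted, within binomial tolerance (4 sd)
  cfg2 <- w$cfg
  cfg2$frac_prevalence_only <- 0.02
  n <- nrow(w$obs)
  split2 <- make_prevalence_only_subset(w$obs, cfg2)
  expect_lt(abs(nrow(split2$prevalence) - 0.02 * n),
            4 * sqrt(n * 0.02 * 0.98) + 1)
  expect_equal(nrow(split2$prevalence) + nrow(split2$means), n)
  expect_false("mean_bmi" %in% names(split2$prevalence))

  cfg_bad <- w$cfg
  cfg_bad$frac_prevalence_only <- 2
  expect_error(make_prevalence_only_subset(w$obs, cfg_bad),
               "frac_prevalence_only")
})

test_that("category probabilities follow the Normal within-cell model", {
  # a cell distributed Normal(25, 4): P(BMI >= 30) = 1 - Phi(1.25)
  obs <- tiny_world()$obs[1, ]
  obs$mean_bmi <- 25
  obs$within_sd <- 4
  obs$n_eff <- 1e9   # essentially no binomial noise
  cfg <- tiny_world()$cfg
  cfg$frac_prevalence_only <- 1
  split <- make_prevalence_only_subset(obs, cfg)
  expect_equal(split$prevalence$prev_obesity, 1 - pnorm(1.25),
               tolerance = 1e-4)
  expect_equal(split$prevalence$prev_overweight, 0.5, tolerance = 1e-4)
})

test_that("observation CSV round-trips through write and load", {
  w <- tiny_world()
  path <- withr::local_tempfile(fileext = ".csv")
  write_observations(w$obs, path)
  back <- load_summary_file(path)
  keep <- c("study_id", "country", "mid_year", "sex", "age_lo", "age_hi",
            "stratum", "coverage", "mean_bmi", "se", "n_eff")
  expect_equal(back[, keep], w$obs[, keep], tolerance = 1e-12,
               ignore_attr = TRUE)
  ppath <- withr::local_tempfile(fileext = ".csv")
  write_population(w$pop, ppath)
  pback <- read_population(ppath)
  expect_equal(pback$population, w$pop$population, tolerance = 1e-12)
})
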