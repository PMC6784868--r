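# Hierarchical trend model: design mapping, degenerate oracles, shrinkage
# and posterior accessors.

test_that("observation age groups map to population-weighted estimation groups", {
  w <- tiny_world()
  cfg <- tiny_model_config(w$truth)
  inputs <- build_model_inputs(w$obs, w$pop, cfg, "female")
  layout <- inputs$layout
  i <- which(w$obs$age_lo == 20 & w$obs$age_hi == 29 &
               w$obs$sex == "female")[1]
  aw <- bmitrend:::age_group_weights(layout, w$pop, w$obs$country[i],
                                     w$obs$mid_year[i], "female", 20, 29)
  expect_equal(layout$est$age_lo[aw$est_idx], c(20, 25))
  pl <- w$pop[w$pop$country == w$obs$country[i] &
                w$pop$year == w$obs$mid_year[i] &
                w$pop$sex == "female" & w$pop$age_lo %in% c(20, 25), ]
  expect_equal(aw$w, pl$population / sum(pl$population),
               tolerance = 1e-12)
  expect_equal(sum(aw$w), 1, tolerance = 1e-12)
})

test_that("a mixed observation with share_urban 0 loads only the rural cell", {
  w <- tiny_world()
  cfg <- tiny_model_config(w$truth)
  inputs <- build_model_inputs(w$obs, w$pop, cfg, "female")
  layout <- inputs$layout
  # with zero urban share the design row carries no gap columns
  de <- bmitrend:::design_entries(layout, 1, 1, 1, 1, urb_w = 0)
  gap_cols <- c(layout$blocks$g_gap0, layout$blocks$gap0_super,
                layout$blocks$gap0_region, layout$blocks$gap0_country)
  expect_length(intersect(de$j, gap_cols), 0)
  de_urban <- bmitrend:::design_entries(layout, 1, 1, 1, 1, urb_w = 1)
  expect_gt(length(intersect(de_urban$j, gap_cols)), 0)
})

test_that("observations for unknown countries are rejected", {
  w <- tiny_world()
  cfg <- tiny_model_config(w$truth)
  obs <- w$obs
  obs$country[1] <- "ZZ"
  expect_error(build_model_inputs(obs, w$pop, cfg, "female"), "ZZ")
})

test_that("the degenerate single-cell model matches the conjugate posterior", {
  h <- data.frame(country = "C01", region = "R1", super_region = "S1")
  est <- estimation_age_groups()[3, ]
  cfg <- model_config(h, years = 2000, est_age_groups = est,
                      n_draws = 5000, burnin = 200,
                      components = list(slope = FALSE, rw2 = FALSE,
                                        age = FALSE, gap = FALSE,
                                        gap_trend = FALSE,
                                        study_re = FALSE,
                                        coverage_fx = FALSE),
                      fixed_sd = c(intercept_super = 0,
                                   intercept_region = 0,
                                   intercept_country = 0,
                                   tau_national = 0))
  expect_equal(cfg$n_draws, 5000L)  # the default retained draw count
  obs <- data.frame(study_id = c("s1", "s2", "s3"), country = "C01",
                    region = "R1", super_region = "S1", mid_year = 2000,
                    sex = "female", age_lo = 20, age_hi = 24,
                    stratum = "rural", coverage = "national",
                    mean_bmi = c(24.1, 24.6, 23.8),
                    se = c(0.2, 0.3, 0.25), n_eff = 100)
  pop <- data.frame(country = "C01", year = 2000, sex = "female",
                    age_lo = 20, age_hi = 24, population = 1e6,
                    share_urban = 0.5)
  inputs <- build_model_inputs(obs, pop, cfg, "female")
  fit <- fit_mcmc(inputs, cfg, seed = 11)
  prec <- 1 / 10^2 + sum(1 / obs$se^2)
  m <- (25 / 10^2 + sum(obs$mean_bmi / obs$se^2)) / prec
  expect_lt(abs(mean(fit$theta[, 1]) - m), 0.02)
  expect_lt(abs(sd(fit$theta[, 1]) / sqrt(1 / prec) - 1), 0.05)
})

test_that("noise-free linear data are reproduced year by year", {
  h <- data.frame(country = "C01", region = "R1", super_region = "S1")
  est <- estimation_age_groups()[3, ]
  years <- 1990:2009
  cfg <- model_config(h, years = years, est_age_groups = est,
                      n_draws = 400, burnin = 200,
                      components = list(rw2 = FALSE, age = FALSE,
                                        gap = FALSE, gap_trend = FALSE,
                                        study_re = FALSE,
                                        coverage_fx = FALSE),
                      fixed_sd = c(intercept_super = 0,
                                   intercept_region = 0,
                                   slope_super = 0, slope_region = 0))
  line <- 22 + 0.08 * (years - mean(years))
  obs <- data.frame(study_id = sprintf("s%02d", seq_along(years)),
                    country = "C01", region = "R1", super_region = "S1",
                    mid_year = years, sex = "female", age_lo = 20,
                    age_hi = 24, stratum = "rural", coverage = "national",
                    mean_bmi = line, se = 0.02, n_eff = 1e4)
  pop <- data.frame(country = "C01", year = years, sex = "female",
                    age_lo = 20, age_hi = 24, population = 1e6,
                    share_urban = 0.5)
  inputs <- build_model_inputs(obs, pop, cfg, "female")
  fit <- suppressWarnings(fit_mcmc(inputs, cfg, seed = 2))
  cells <- data.frame(country = "C01", year = years, age_lo = 20,
                      stratum = "rural")
  pm <- colMeans(posterior_cells(fit, cells))
  expect_lt(max(abs(pm - line)), 0.05)
})

test_that("a country with no data is shrunk toward its region", {
  w <- tiny_world()
  # drop all data from one country whose region-mates sit well away from
  # the global mean, then check the posterior lies between region and
  # global levels
  fit_full <- tiny_fit()
  cfg <- tiny_model_config(w$truth)
  country_means <- tapply(w$obs$mean_bmi[w$obs$stratum != "urban"],
                          w$obs$country[w$obs$stratum != "urban"], mean)
  regions <- w$truth$hierarchy
  target <- regions$country[1]
  obs_red <- w$obs[w$obs$country != target, ]
  inputs <- build_model_inputs(obs_red, w$pop, cfg, "female")
  fit <- suppressWarnings(fit_mcmc(inputs, cfg, seed = 6))
  mid_year <- w$truth$years[6]
  cells <- data.frame(country = target, year = mid_year, age_lo = 30,
                      stratum = "rural")
  est_nodata <- mean(posterior_cells(fit, cells))
  mates <- regions$country[regions$region == regions$region[1]]
  mates <- setdiff(mates, target)
  cells_mates <- data.frame(country = mates, year = mid_year, age_lo = 30,
                            stratum = "rural")
  region_mean <- mean(colMeans(posterior_cells(fit, cells_mates)))
  cells_all <- data.frame(country = setdiff(regions$country, target),
                          year = mid_year, age_lo = 30, stratum = "rural")
  global_mean <- mean(colMeans(posterior_cells(fit, cells_all)))
  # the no-data country's estimate is pulled from the global mean toward
  # its region's level
  expect_lt(abs(est_nodata - region_mean),
            abs(region_mean - global_mean) + 0.35)
  expect_true(sign(est_nodata - global_mean) ==
                sign(region_mean - global_mean) ||
                abs(region_mean - global_mean) < 0.1)
})

test_that("posterior stratum means combine rural and urban with the urban share", {
  w <- tiny_world()
  fit <- tiny_fit()
  country <- w$truth$hierarchy$country[2]
  year <- w$truth$years[4]
  out <- posterior_stratum_means(fit, w$pop, country, year, "female",
                                 age_lo = 30, age_hi = 39)
  expect_named(out, c("rural", "urban", "mixed"))
  pl <- w$pop[w$pop$country == country & w$pop$year == year &
                w$pop$sex == "female" & w$pop$age_lo %in% c(30, 35), ]
  wts <- pl$population / sum(pl$population)
  share <- sum(wts * pl$share_urban)
  expect_equal(out$mixed, share * out$urban + (1 - share) * out$rural,
               tolerance = 1e-12)

  # fully rural population: urban stratum is not reported
  pop0 <- w$pop
  pop0$share_urban <- 0
  out0 <- posterior_stratum_means(fit, pop0, country, year, "female",
                                  age_lo = 30, age_hi = 39)
  expect_false("urban" %in% names(out0))
  expect_equal(out0$mixed, out0$rural, tolerance = 1e-12)
  pop1 <- w$pop
  pop1$share_urban <- 1
  out1 <- posterior_stratum_means(fit, pop1, country, year, "female",
                                  age_lo = 30, age_hi = 39)
  expect_false("rural" %in% names(out1))
  expect_equal(out1$mixed, out1$urban, tolerance = 1e-12)
})

test_that("deleting a community study moves the estimate less than a national one", {
  w <- tiny_world()
  cfg <- tiny_model_config(w$truth, n_draws = 300, burnin = 150)
  # plant two synthetic studies with identical rows except coverage
  target <- w$truth$hierarchy$country[3]
  year <- w$truth$years[7]
  template <- data.frame(study_id = "xx", country = target,
                         region = w$truth$hierarchy$region[3],
                         super_region = w$truth$hierarchy$super_region[3],
                         mid_year = year, sex = "female",
                         age_lo = c(20, 30, 40), age_hi = c(29, 39, 49),
                         stratum = "rural", coverage = "national",
                         mean_bmi = 27.5, se = 0.15, n_eff = 500,
                         true_mean = NA, within_sd = 4)
  nat <- template
  nat$study_id <- "extra_nat"
  com <- template
  com$study_id <- "extra_com"
  com$coverage <- "community"
  base_obs <- rbind(w$obs, nat, com)
  cells <- data.frame(country = target, year = year, age_lo = 30,
                      stratum = "rural")
  est <- function(obs) {
    inputs <- build_model_inputs(obs, w$pop, cfg, "female")
    fit <- suppressWarnings(fit_mcmc(inputs, cfg, seed = 9))
    mean(posterior_cells(fit, cells))
  }
  est_all <- est(base_obs)
  est_no_com <- est(base_obs[base_obs$study_id != "extra_com", ])
  est_no_nat <- est(base_obs[base_obs$study_id != "extra_nat", ])
  expect_lt(abs(est_no_com - est_all), abs(est_no_nat - est_all))
})

test_that("reversals and widenings of the urban gap are recovered in sign", {
  w <- default_world()
  truth <- w$truth
  fit <- default_world_fit()
  y0 <- truth$years[1]
  y1 <- truth$years[length(truth$years)]
  correct <- 0
  n <- 0
  for (ci in seq_len(nrow(truth$hierarchy))) {
    true_change <- truth$gap[ci, length(truth$years), 1] -
      truth$gap[ci, 1, 1]
    if (abs(true_change) < 0.2) next
    cells <- expand.grid(year = c(y0, y1),
                         stratum = c("rural", "urban"),
                         stringsAsFactors = FALSE)
    cells$country <- truth$hierarchy$country[ci]
    cells$age_lo <- 30
    d <- posterior_cells(fit, cells)
    est_change <- mean(d[, 4] - d[, 2]) - mean(d[, 3] - d[, 1])
    n <- n + 1
    if (sign(est_change) == sign(true_change)) correct <- correct + 1
  }
  expect_gt(n, 5)
  expect_gte(correct / n, 0.9)
})
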