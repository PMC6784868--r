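# Synthetic-world generator: ground-truth rural/urban BMI surfaces,
# population tables with logistic urbanization, and survey-like stratified
# observations carrying the heterogeneity the trend model is built for
# (coverage offsets, study effects, unstratified sources, prevalence-only
# sources).

# purpose codes for deterministic RNG sub-streams
.P_TREND <- 1L
.P_AGE <- 2L
.P_GAP <- 3L
.P_RW2 <- 4L
.P_POP <- 5L
.P_SURVEY <- 6L
.P_PREV <- 7L

#' Configuration of a synthetic world
#'
#' All standard-deviation and rate fields must be non-negative, proportions
#' must lie in \code{[0, 1]}, and age groups must be ascending,
#' non-overlapping intervals starting at 18 or above.  Under the default
#' configuration the world has 3 super-regions x 2 regions x 4 countries
#' (24 countries), years 1985-2017, two sexes and about 8 surveys per
#' country.
#'
#' @param n_super_regions,regions_per_super,countries_per_region geography.
#' @param years integer year grid (default 1985:2017).
#' @param age_groups data.frame of observation age intervals
#'   (\code{age_lo}, \code{age_hi}); default \code{\link{observation_age_groups}}.
#' @param base_bmi named per-sex global intercept, kg/m2.
#' @param mean_slope global mean BMI trend, kg/m2 per year.
#' @param trend_sd_hierarchy SDs of intercept deviations at the
#'   super-region, region and country levels, kg/m2.  Slope deviations use
#'   these values divided by 60 (per year).
#' @param rw2_innovation_sd SD of second-order random-walk innovations,
#'   kg/m2; 0 yields exactly linear country trends.
#' @param age_curve_scale multiplier on the global age pattern.
#' @param age_sd SD of country perturbations on age-spline coefficients.
#' @param urban_gap_mean global mean urban-minus-rural difference, kg/m2.
#' @param urban_gap_base_sd SD of gap intercept deviations (region level;
#'   half this value at country level), kg/m2.
#' @param urban_gap_trend_mean,urban_gap_trend_sd mean and SD of the gap
#'   time trend, kg/m2 per year (regions may narrow, reverse or widen).
#' @param coverage_offsets systematic offsets for subnational and community
#'   sources, kg/m2 (national is 0 by definition).
#' @param coverage_extra_sd extra residual SD by coverage level, kg/m2.
#' @param study_sd SD of study random effects by coverage level, kg/m2.
#' @param coverage_probs sampling probabilities of coverage levels.
#' @param frac_unstratified proportion of surveys reporting no rural/urban
#'   stratification ("mixed" rows).
#' @param frac_prevalence_only proportion of rows reporting only
#'   BMI-category prevalences (default 0.02).
#' @param surveys_per_country Poisson rate of surveys per country.
#' @param within_sd named per-sex within-cell BMI SD, kg/m2 (4.0 women,
#'   3.5 men), used for sampling noise and prevalence synthesis.
#' @param n_eff_median median effective sample size per summary row.
#' @param sparse_early if TRUE, surveys before 2000 are thinned by half.
#' @param urban_mid_range,urban_slope_mean,urban_slope_sd logistic
#'   urbanization curve parameters (midpoint year range; per-year slope,
#'   truncated at 0 so urban shares never decline).
#' @param sexes character vector, subset of \code{c("female", "male")}.
#' @param seed integer base seed; every draw is taken from a sub-stream
#'   keyed by (country, purpose) so results are reproducible and stable
#'   under the addition of countries.
#' @return object of class \code{bmi_world_config}.
#' @export
world_config <- function(n_super_regions = 3,
                         regions_per_super = 2,
                         countries_per_region = 4,
                         years = 1985:2017,
                         age_groups = observation_age_groups(),
                         base_bmi = c(female = 24.0, male = 23.5),
                         mean_slope = 0.055,
                         trend_sd_hierarchy = c(super = 0.8, region = 0.5,
                                                country = 0.4),
                         rw2_innovation_sd = 0.03,
                         age_curve_scale = 1.0,
                         age_sd = 0.15,
                         urban_gap_mean = 1.5,
                         urban_gap_base_sd = 0.5,
                         urban_gap_trend_mean = -0.01,
                         urban_gap_trend_sd = 0.02,
                         coverage_offsets = c(subnational = -0.15,
                                              community = -0.3),
                         coverage_extra_sd = c(national = 0.05,
                                               subnational = 0.15,
                                               community = 0.25),
                         study_sd = c(national = 0.1, subnational = 0.2,
                                      community = 0.3),
                         coverage_probs = c(national = 0.6,
                                            subnational = 0.25,
                                            community = 0.15),
                         frac_unstratified = 0.3,
                         frac_prevalence_only = 0.02,
                         surveys_per_country = 8,
                         within_sd = c(female = 4.0, male = 3.5),
                         n_eff_median = 250,
                         sparse_early = FALSE,
                         urban_mid_range = c(1975, 2035),
                         urban_slope_mean = 0.07,
                         urban_slope_sd = 0.03,
                         sexes = c("female", "male"),
                         seed = 1L) {
  cfg <- list(n_super_regions = n_super_regions,
              regions_per_super = regions_per_super,
              countries_per_region = countries_per_region,
              years = as.integer(years),
              age_groups = age_groups,
              base_bmi = base_bmi, mean_slope = mean_slope,
              trend_sd_hierarchy = trend_sd_hierarchy,
              rw2_innovation_sd = rw2_innovation_sd,
              age_curve_scale = age_curve_scale, age_sd = age_sd,
              urban_gap_mean = urban_gap_mean,
              urban_gap_base_sd = urban_gap_base_sd,
              urban_gap_trend_mean = urban_gap_trend_mean,
              urban_gap_trend_sd = urban_gap_trend_sd,
              coverage_offsets = coverage_offsets,
              coverage_extra_sd = coverage_extra_sd,
              study_sd = study_sd, coverage_probs = coverage_probs,
              frac_unstratified = frac_unstratified,
              frac_prevalence_only = frac_prevalence_only,
              surveys_per_country = surveys_per_country,
              within_sd = within_sd, n_eff_median = n_eff_median,
              sparse_early = sparse_early,
              urban_mid_range = urban_mid_range,
              urban_slope_mean = urban_slope_mean,
              urban_slope_sd = urban_slope_sd,
              sexes = sexes, seed = as.integer(seed))
  class(cfg) <- "bmi_world_config"
  validate_world_config(cfg)
  cfg
}

validate_world_config <- function(cfg) {
  err <- function(field, msg) {
    stop(sprintf("invalid world configuration: field '%s' %s", field, msg),
         call. = FALSE)
  }
  counts <- c("n_super_regions", "regions_per_super", "countries_per_region")
  for (f in counts) {
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1 || cfg[[f]] < 1 ||
        cfg[[f]] != round(cfg[[f]])) {
      err(f, "must be a positive integer")
    }
  }
  if (length(cfg$years) < 1) err("years", "must be non-empty")
  sd_fields <- c("trend_sd_hierarchy", "rw2_innovation_sd", "age_sd",
                 "urban_gap_base_sd", "urban_gap_trend_sd",
                 "coverage_extra_sd", "study_sd", "within_sd",
                 "surveys_per_country", "urban_slope_sd")
  for (f in sd_fields) {
    if (any(!is.finite(cfg[[f]])) || any(cfg[[f]] < 0)) {
      err(f, "must be non-negative and finite")
    }
  }
  prop_fields <- c("frac_unstratified", "frac_prevalence_only")
  for (f in prop_fields) {
    if (!is.finite(cfg[[f]]) || cfg[[f]] < 0 || cfg[[f]] > 1) {
      err(f, "must be a proportion in [0, 1]")
    }
  }
  ag <- cfg$age_groups
  if (!all(c("age_lo", "age_hi") %in% names(ag)) || nrow(ag) < 1) {
    err("age_groups", "must have columns age_lo, age_hi")
  }
  if (ag$age_lo[1] < 18) err("age_groups", "must start at age 18 or above")
  if (any(ag$age_hi < ag$age_lo)) err("age_groups", "intervals must be valid")
  if (nrow(ag) > 1 && any(diff(ag$age_lo) <= 0)) {
    err("age_groups", "must be ascending")
  }
  if (nrow(ag) > 1 &&
      any(ag$age_lo[-1] <= ag$age_hi[-nrow(ag)])) {
    err("age_groups", "must be non-overlapping")
  }
  if (!all(cfg$sexes %in% c("female", "male"))) {
    err("sexes", "must be a subset of female/male")
  }
  invisible(cfg)
}

#' Country hierarchy of a synthetic world
#'
#' @param config a \code{\link{world_config}}.
#' @return data.frame with columns \code{country}, \code{region},
#'   \code{super_region}.
#' @export
world_hierarchy <- function(config) {
  ns <- config$n_super_regions
  nr <- config$regions_per_super
  nc <- config$countries_per_region
  supers <- sprintf("S%d", seq_len(ns))
  out <- expand.grid(ci = seq_len(nc), ri = seq_len(nr), si = seq_len(ns))
  out$super_region <- supers[out$si]
  out$region <- sprintf("S%dR%d", out$si, out$ri)
  out$country <- sprintf("C%02d", seq_len(nrow(out)))
  out[, c("country", "region", "super_region")]
}

# second-order random-walk path with sum-to-zero and zero-linear-trend
# constraints; innovations are second differences
rw2_path <- function(n, sd) {
  if (n < 3 || sd == 0) {
    return(rep(0, n))
  }
  e <- rnorm(n - 2, 0, sd)
  u <- cumsum(cumsum(c(0, 0, e)))
  t <- seq_len(n)
  unname(stats::lm.fit(cbind(1, t), u)$residuals)
}

# unit ids for RNG streams
.unit_country <- function(i) 1000L + i
.unit_region <- function(i) 500L + i
.unit_super <- function(i) 100L + i

#' Generate ground-truth BMI surfaces
#'
#' Country intercepts and slopes are drawn hierarchically (global ->
#' super-region -> region -> country), a per-country second-order
#' random-walk deviation is added, the age pattern comes from a fixed cubic
#' spline basis with country-level coefficient perturbations, and the
#' urban-minus-rural difference is linear in time with hierarchically drawn
#' intercept and trend.  Deterministic given the config seed.
#'
#' @param config a \code{\link{world_config}}.
#' @return object of class \code{bmi_truth} with arrays
#'   \code{rural[country, year, sex, age]} (mean rural BMI, kg/m2) and
#'   \code{gap[country, year, sex]} (urban minus rural, kg/m2), plus the
#'   hierarchy and estimation age grid.
#' @export
generate_truth <- function(config) {
  validate_world_config(config)
  h <- world_hierarchy(config)
  years <- config$years
  t0 <- mean(years)
  est_all <- estimation_age_groups()
  est_idx <- sort(unique(unlist(lapply(seq_len(nrow(config$age_groups)),
    function(i) estimation_groups_within(config$age_groups$age_lo[i],
                                         config$age_groups$age_hi[i])))))
  est <- est_all[est_idx, , drop = FALSE]
  B <- bmi_age_basis(est$age_mid)
  gamma0 <- bmi_age_curve_coefs() * config$age_curve_scale
  sexes <- config$sexes
  nC <- nrow(h); nT <- length(years); nS <- length(sexes); nA <- nrow(est)
  rural <- array(NA_real_, dim = c(nC, nT, nS, nA),
                 dimnames = list(h$country, years, sexes, est$label))
  gap <- array(NA_real_, dim = c(nC, nT, nS),
               dimnames = list(h$country, years, sexes))
  sds <- config$trend_sd_hierarchy
  slope_sds <- sds / 60
  supers <- unique(h$super_region)
  regions <- unique(h$region)
  for (si in seq_along(sexes)) {
    pt <- .P_TREND + 100L * si
    pg <- .P_GAP + 100L * si
    sup_dev <- vapply(seq_along(supers), function(i) {
      with_stream(config$seed, .unit_super(i), pt,
                  rnorm(2, 0, c(sds[[1]], slope_sds[[1]])))
    }, numeric(2))
    reg_dev <- vapply(seq_along(regions), function(i) {
      with_stream(config$seed, .unit_region(i), pt,
                  rnorm(2, 0, c(sds[[2]], slope_sds[[2]])))
    }, numeric(2))
    reg_gap <- vapply(seq_along(regions), function(i) {
      with_stream(config$seed, .unit_region(i), pg,
                  rnorm(2, c(config$urban_gap_mean,
                             config$urban_gap_trend_mean),
                        c(config$urban_gap_base_sd,
                          config$urban_gap_trend_sd)))
    }, numeric(2))
    for (ci in seq_len(nC)) {
      sidx <- match(h$super_region[ci], supers)
      ridx <- match(h$region[ci], regions)
      cdev <- with_stream(config$seed, .unit_country(ci), pt,
                          rnorm(2, 0, c(sds[[3]], slope_sds[[3]])))
      u <- with_stream(config$seed, .unit_country(ci), .P_RW2 + 100L * si,
                       rw2_path(nT, config$rw2_innovation_sd))
      gamma_c <- with_stream(config$seed, .unit_country(ci),
                             .P_AGE + 100L * si,
                             gamma0 + rnorm(length(gamma0), 0, config$age_sd))
      cgap <- with_stream(config$seed, .unit_country(ci), pg,
                          rnorm(2, 0, c(config$urban_gap_base_sd / 2,
                                        config$urban_gap_trend_sd / 2)))
      a_c <- config$base_bmi[[sexes[si]]] + sup_dev[1, sidx] +
        reg_dev[1, ridx] + cdev[1]
      b_c <- config$mean_slope + sup_dev[2, sidx] + reg_dev[2, ridx] + cdev[2]
      age_eff <- as.numeric(B %*% gamma_c)
      trend <- a_c + b_c * (years - t0) + u
      rural[ci, , si, ] <- outer(trend, age_eff, `+`)
      gap[ci, , si] <- (reg_gap[1, ridx] + cgap[1]) +
        (reg_gap[2, ridx] + cgap[2]) * (years - t0)
    }
  }
  if (any(!is.finite(rural)) || any(!is.finite(gap))) {
    stop("generated truth surface contains non-finite values", call. = FALSE)
  }
  structure(list(config = config, hierarchy = h, years = years, t0 = t0,
                 sexes = sexes, est_ages = est, rural = rural, gap = gap),
            class = "bmi_truth")
}

#' @export
print.bmi_truth <- function(x, ...) {
  cat(sprintf("synthetic BMI truth: %d countries x %d years x %d sex(es) x %d age groups\n",
              dim(x$rural)[1], dim(x$rural)[2], dim(x$rural)[3],
              dim(x$rural)[4]))
  invisible(x)
}

# mean BMI of one stratum at estimation-age resolution (vectorised over ages)
truth_stratum_mean <- function(truth, country, year, sex, est_rows,
                               stratum, share_urban = NULL) {
  ci <- match(country, truth$hierarchy$country)
  ti <- match(year, truth$years)
  si <- match(sex, truth$sexes)
  if (any(is.na(c(ci, ti, si)))) {
    stop("truth_stratum_mean: cell outside the generated index sets",
         call. = FALSE)
  }
  r <- truth$rural[ci, ti, si, est_rows]
  if (stratum == "rural") {
    return(r)
  }
  u <- r + truth$gap[ci, ti, si]
  if (stratum == "urban") {
    return(u)
  }
  if (is.null(share_urban)) {
    stop("share_urban required for mixed stratum", call. = FALSE)
  }
  share_urban * u + (1 - share_urban) * r
}

#' Convert a truth surface to a long data frame
#'
#' @param truth a \code{bmi_truth}.
#' @return data.frame keyed by country/year/sex/age_lo/stratum with
#'   \code{mean_bmi}.
#' @export
truth_as_data_frame <- function(truth) {
  grid <- expand.grid(age = seq_len(nrow(truth$est_ages)),
                      sex = seq_along(truth$sexes),
                      year = seq_along(truth$years),
                      country = seq_len(nrow(truth$hierarchy)))
  r <- truth$rural[cbind(grid$country, grid$year, grid$sex, grid$age)]
  g <- truth$gap[cbind(grid$country, grid$year, grid$sex)]
  base <- data.frame(country = truth$hierarchy$country[grid$country],
                     year = truth$years[grid$year],
                     sex = truth$sexes[grid$sex],
                     age_lo = truth$est_ages$age_lo[grid$age],
                     age_hi = truth$est_ages$age_hi[grid$age],
                     stringsAsFactors = FALSE)
  rbind(cbind(base, stratum = "rural", mean_bmi = r),
        cbind(base, stratum = "urban", mean_bmi = r + g))
}

#' Generate a population table with logistic urbanization
#'
#' Each country gets a logistic urban-share curve with a random midpoint
#' and non-negative slope (so shares are monotone non-decreasing), a random
#' total population, a common declining adult age structure and an equal
#' sex split.  Deterministic given the config seed.
#'
#' @param config a \code{\link{world_config}}.
#' @return data.frame of class \code{bmi_population} with columns
#'   \code{country}, \code{year}, \code{sex}, \code{age_lo}, \code{age_hi},
#'   \code{population}, \code{share_urban}.
#' @export
generate_population_table <- function(config) {
  validate_world_config(config)
  h <- world_hierarchy(config)
  years <- config$years
  est_all <- estimation_age_groups()
  est_idx <- sort(unique(unlist(lapply(seq_len(nrow(config$age_groups)),
    function(i) estimation_groups_within(config$age_groups$age_lo[i],
                                         config$age_groups$age_hi[i])))))
  est <- est_all[est_idx, , drop = FALSE]
  age_w <- exp(-0.03 * (est$age_mid - 18))
  age_w <- age_w / sum(age_w)
  out <- vector("list", nrow(h))
  for (ci in seq_len(nrow(h))) {
    prm <- with_stream(config$seed, .unit_country(ci), .P_POP, {
      list(total0 = rlnorm(1, log(1e7), 1),
           mid = runif(1, config$urban_mid_range[1],
                       config$urban_mid_range[2]),
           slope = max(0, rnorm(1, config$urban_slope_mean,
                                config$urban_slope_sd)))
    })
    share <- plogis(prm$slope * (years - prm$mid))
    grid <- expand.grid(age = seq_len(nrow(est)), sex = config$sexes,
                        year = years, stringsAsFactors = FALSE)
    grid$population <- prm$total0 * 1.015^(grid$year - min(years)) *
      0.5 * age_w[grid$age]
    grid$share_urban <- share[match(grid$year, years)]
    out[[ci]] <- data.frame(country = h$country[ci], year = grid$year,
                            sex = grid$sex, age_lo = est$age_lo[grid$age],
                            age_hi = est$age_hi[grid$age],
                            population = grid$population,
                            share_urban = grid$share_urban,
                            stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  class(res) <- c("bmi_population", "data.frame")
  res
}

# population lookup: rows of pop for one (country, year, sex) in the order
# of requested estimation rows
pop_lookup <- function(pop, country, year, sex, age_lo) {
  sel <- pop[pop$country == country & pop$year == year & pop$sex == sex, ]
  idx <- match(age_lo, sel$age_lo)
  if (any(is.na(idx))) {
    stop(sprintf("population table lacks ages for %s/%d/%s", country,
                 year, sex), call. = FALSE)
  }
  sel[idx, ]
}

#' Sample survey-like stratified observations from a truth surface
#'
#' Surveys are placed at random country-years; each yields one summary row
#' per sex x observation age group x stratum, with observed mean equal to
#' the truth plus a coverage offset, a study random effect and sampling
#' noise.  A fraction of surveys report no stratification ("mixed" rows
#' whose truth is the population-weighted rural/urban mean).  Hidden
#' columns \code{true_mean} and \code{within_sd} carry the generating truth
#' for testing; \code{\link{write_observations}} drops them.
#'
#' @param truth a \code{bmi_truth}.
#' @param pop a population table from
#'   \code{\link{generate_population_table}}.
#' @param config the \code{\link{world_config}} used for both.
#' @return data.frame of stratified observations (see
#'   \code{\link{load_summary_file}} for the schema).
#' @export
sample_observations <- function(truth, pop, config) {
  if (!inherits(truth, "bmi_truth") || length(truth$rural) == 0) {
    stop("sample_observations: empty or invalid truth surface",
         call. = FALSE)
  }
  validate_world_config(config)
  h <- truth$hierarchy
  years <- truth$years
  est <- truth$est_ages
  ag <- config$age_groups
  cov_levels <- names(config$coverage_probs)
  offsets <- c(national = 0, config$coverage_offsets)
  rows <- list()
  for (ci in seq_len(nrow(h))) {
    country <- h$country[ci]
    srows <- with_stream(config$seed, .unit_country(ci), .P_SURVEY, {
      n_surv <- rpois(1, config$surveys_per_country)
      out <- list()
      for (j in seq_len(n_surv)) {
        mid_year <- sample(years, 1)
        if (config$sparse_early && mid_year < 2000 && runif(1) < 0.5) {
          mid_year <- sample(years[years >= 2000], 1)
        }
        coverage <- sample(cov_levels, 1, prob = config$coverage_probs)
        stratified <- runif(1) >= config$frac_unstratified
        strata <- if (stratified) c("rural", "urban") else "mixed"
        study_id <- sprintf("%s_s%02d", country, j)
        nu <- rnorm(length(config$sexes), 0, config$study_sd[[coverage]])
        for (si in seq_along(config$sexes)) {
          sex <- config$sexes[si]
          pl <- pop_lookup(pop, country, mid_year, sex, est$age_lo)
          for (gi in seq_len(nrow(ag))) {
            est_rows <- which(est$age_lo >= ag$age_lo[gi] &
                                (est$age_hi <= ag$age_hi[gi] |
                                   (!is.finite(est$age_hi) &
                                      !is.finite(ag$age_hi[gi]))))
            w <- pl$population[est_rows]
            w <- w / sum(w)
            for (stratum in strata) {
              m_a <- truth_stratum_mean(truth, country, mid_year, sex,
                                        est_rows, stratum,
                                        share_urban = pl$share_urban[est_rows[1]])
              cell_truth <- sum(w * m_a)
              n_eff <- max(20, round(rlnorm(1, log(config$n_eff_median),
                                            0.5)))
              wsd <- config$within_sd[[sex]]
              se <- wsd / sqrt(n_eff)
              noise_sd <- sqrt(se^2 + config$coverage_extra_sd[[coverage]]^2)
              obs <- cell_truth + offsets[[coverage]] + nu[si] +
                rnorm(1, 0, noise_sd)
              out[[length(out) + 1]] <- data.frame(
                study_id = study_id, country = country,
                region = h$region[ci], super_region = h$super_region[ci],
                mid_year = mid_year, sex = sex,
                age_lo = ag$age_lo[gi], age_hi = ag$age_hi[gi],
                stratum = stratum, coverage = coverage,
                mean_bmi = obs, se = se, n_eff = n_eff,
                true_mean = cell_truth, within_sd = wsd,
                stringsAsFactors = FALSE)
            }
          }
        }
      }
      out
    })
    rows <- c(rows, srows)
  }
  if (!length(rows)) {
    return(empty_observations())
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

empty_observations <- function() {
  data.frame(study_id = character(), country = character(),
             region = character(), super_region = character(),
             mid_year = integer(), sex = character(), age_lo = numeric(),
             age_hi = numeric(), stratum = character(),
             coverage = character(), mean_bmi = numeric(), se = numeric(),
             n_eff = numeric(), true_mean = numeric(),
             within_sd = numeric(), stringsAsFactors = FALSE)
}

#' Strip a fraction of rows down to BMI-category prevalences
#'
#' A deterministic (seeded) fraction of observation rows loses its
#' mean/standard error and instead reports the prevalence of
#' BMI >= 25 kg/m2 (overweight incl. obesity), BMI >= 30 kg/m2 (obesity)
#' and BMI < 18.5 kg/m2 (underweight), with binomial sampling and binomial
#' standard errors.  The within-cell BMI distribution is Normal(mean,
#' within_sd).
#'
#' @param observations rows from \code{\link{sample_observations}} (must
#'   carry \code{within_sd}).
#' @param config the \code{\link{world_config}}; uses
#'   \code{frac_prevalence_only} and \code{seed}.
#' @return list with elements \code{means} (rows keeping mean/SE) and
#'   \code{prevalence} (converted rows with columns
#'   \code{prev_overweight}/\code{se_overweight},
#'   \code{prev_obesity}/\code{se_obesity},
#'   \code{prev_underweight}/\code{se_underweight} and \code{source_mean},
#'   the stripped mean kept for recovery testing).
#' @export
make_prevalence_only_subset <- function(observations, config) {
  frac <- config$frac_prevalence_only
  if (!is.finite(frac) || frac < 0 || frac > 1) {
    stop("invalid world configuration: field 'frac_prevalence_only' must be a proportion in [0, 1]",
         call. = FALSE)
  }
  n <- nrow(observations)
  sel <- with_stream(config$seed, 0L, .P_PREV, runif(n) < frac)
  if (!any(sel)) {
    return(list(means = observations,
                prevalence = observations[integer(0), ]))
  }
  conv <- observations[sel, ]
  prevs <- with_stream(config$seed, 1L, .P_PREV, {
    lapply(seq_len(nrow(conv)), function(i) {
      mu <- conv$mean_bmi[i]
      sigma <- conv$within_sd[i]
      ne <- conv$n_eff[i]
      p <- c(overweight = 1 - pnorm(25, mu, sigma),
             obesity = 1 - pnorm(30, mu, sigma),
             underweight = pnorm(18.5, mu, sigma))
      phat <- rbinom(3, ne, p) / ne
      pse <- pmax(phat, 1 / (2 * ne))
      pse <- pmin(pse, 1 - 1 / (2 * ne))
      se <- sqrt(pse * (1 - pse) / ne)
      c(phat, se)
    })
  })
  pm <- do.call(rbind, prevs)
  keys <- c("study_id", "country", "region", "super_region", "mid_year",
            "sex", "age_lo", "age_hi", "stratum", "coverage", "n_eff")
  prevalence <- cbind(conv[, keys],
                      data.frame(prev_overweight = pm[, 1],
                                 prev_obesity = pm[, 2],
                                 prev_underweight = pm[, 3],
                                 se_overweight = pm[, 4],
                                 se_obesity = pm[, 5],
                                 se_underweight = pm[, 6],
                                 source_mean = conv$mean_bmi,
                                 within_sd = conv$within_sd,
                                 stringsAsFactors = FALSE))
  rownames(prevalence) <- NULL
  list(means = observations[!sel, ], prevalence = prevalence)
}

#' Paired training cells for the prevalence crosswalk
#'
#' Augments observation rows with synthetic BMI-category prevalences
#' (binomially sampled from the within-cell Normal distribution) while
#' keeping the observed mean, yielding the paired data on which
#' \code{\link{fit_crosswalk}} is estimated.
#'
#' @param observations rows from \code{\link{sample_observations}}.
#' @param config the \code{\link{world_config}}.
#' @param metrics which prevalence metrics to synthesize (default all
#'   three).
#' @return data.frame with both \code{mean_bmi} and prevalence columns.
#' @export
crosswalk_training_pairs <- function(observations, config,
                                     metrics = c("overweight", "obesity",
                                                 "underweight")) {
  obs <- observations
  pm <- with_stream(config$seed, 2L, .P_PREV, {
    t(vapply(seq_len(nrow(obs)), function(i) {
      mu <- obs$mean_bmi[i]
      sigma <- obs$within_sd[i]
      ne <- obs$n_eff[i]
      p <- c(overweight = 1 - pnorm(25, mu, sigma),
             obesity = 1 - pnorm(30, mu, sigma),
             underweight = pnorm(18.5, mu, sigma))
      phat <- rbinom(3, ne, p) / ne
      pse <- pmin(pmax(phat, 1 / (2 * ne)), 1 - 1 / (2 * ne))
      c(phat, sqrt(pse * (1 - pse) / ne))
    }, numeric(6)))
  })
  colnames(pm) <- c(paste0("prev_", .prev_metrics),
                    paste0("se_", .prev_metrics))
  drop <- setdiff(.prev_metrics, metrics)
  for (m in drop) {
    pm[, paste0("prev_", m)] <- NA_real_
    pm[, paste0("se_", m)] <- NA_real_
  }
  cbind(obs, as.data.frame(pm))
}

#' Write observations to CSV
#'
#' Writes the documented summary schema (study_id, country, region,
#' super_region, mid_year, sex, age_lo, age_hi, stratum, coverage,
#' mean_bmi, se, n_eff), dropping the hidden ground-truth columns.
#'
#' @param observations observation data.frame.
#' @param path output CSV path.
#' @export
write_observations <- function(observations, path) {
  keep <- c("study_id", "country", "region", "super_region", "mid_year",
            "sex", "age_lo", "age_hi", "stratum", "coverage", "mean_bmi",
            "se", "n_eff")
  write.csv(observations[, keep], path, row.names = FALSE)
}

#' Write a population table to CSV
#' @param pop population table.
#' @param path output CSV path.
#' @export
write_population <- function(pop, path) {
  write.csv(as.data.frame(pop), path, row.names = FALSE)
}

#' Read a population table from CSV
#' @param path CSV path with columns country, year, sex, age_lo, age_hi,
#'   population, share_urban.
#' @return \code{bmi_population} data.frame.
#' @export
read_population <- function(path) {
  pop <- read.csv(path, stringsAsFactors = FALSE)
  stopifnot_fields(pop, c("country", "year", "sex", "age_lo", "age_hi",
                          "population", "share_urban"), "population table")
  if (any(pop$share_urban < 0 | pop$share_urban > 1)) {
    stop("population table: share_urban outside [0, 1]", call. = FALSE)
  }
  if (any(pop$population < 0)) {
    stop("population table: negative population", call. = FALSE)
  }
  class(pop) <- c("bmi_population", "data.frame")
  pop
}
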