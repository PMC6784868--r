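# Held-out cross-validation designs and error metrics.
#
# Two designs: (1) hold out all data from ~10% of countries with data,
# sampled within data-richness strata; (2) hold out ~10% of data sources,
# per selected country either a random third of its sources or all of its
# post-2000 sources.  Errors are posterior-mean prediction minus held-out
# observed mean; interval coverage is assessed on the posterior
# predictive distribution of the held-out observation (the held-out value
# is itself a noisy measurement, so its sampling noise, the study-effect
# variance of its coverage level and the extra residual variance all
# contribute).

#' Count data sources per country
#'
#' A data source is a distinct study_id contributing at least one row for
#' the given sex.
#'
#' @param observations observation rows.
#' @param sex sex.
#' @return named integer vector (country -> source count).
#' @export
count_sources <- function(observations, sex) {
  obs <- observations[observations$sex == sex, ]
  tab <- tapply(obs$study_id, obs$country,
                function(s) length(unique(s)))
  out <- as.integer(tab)
  names(out) <- names(tab)
  out
}

# sex-specific data-richness thresholds
classify_availability <- function(n_sources, sex) {
  if (sex == "female") {
    cut_points <- c(rich = 8, avg_lo = 4, poor_hi = 3)
  } else {
    cut_points <- c(rich = 7, avg_lo = 3, poor_hi = 2)
  }
  ifelse(n_sources >= cut_points["rich"], "data-rich",
         ifelse(n_sources >= cut_points["avg_lo"], "average",
                ifelse(n_sources >= 1, "data-poor", "no-data")))
}

#' Hold out all data from a fraction of countries
#'
#' Countries with data are classified by sex-specific source counts into
#' data-rich (>= 8 sources for women, >= 7 for men), data-poor (1-3 for
#' women, 1-2 for men) and average availability; about \code{frac} of
#' each non-empty stratum (at least one country) is sampled and all its
#' data withheld.  Deterministic given the seed.
#'
#' @param observations observation rows.
#' @param sex sex whose source counts drive the classification.
#' @param frac fraction per stratum (default 0.10).
#' @param seed integer seed.
#' @return object of class \code{bmi_holdout_plan}.
#' @export
split_holdout_countries <- function(observations, sex, frac = 0.10, seed) {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  counts <- count_sources(observations, sex)
  strata <- classify_availability(counts, sex)
  withheld <- character()
  set.seed(stream_seed(seed, 0L, 21L))
  for (s in c("data-rich", "average", "data-poor")) {
    members <- names(counts)[strata == s]
    if (!length(members)) {
      warning(sprintf("availability stratum '%s' has no countries; skipped", s))
      next
    }
    k <- max(1L, ceiling(frac * length(members)))
    withheld <- c(withheld, sample(members, k))
  }
  sel <- observations$country %in% withheld & observations$sex == sex
  structure(list(design = "countries", sex = sex, frac = frac,
                 seed = seed, withheld_countries = sort(withheld),
                 withheld_studies = sort(unique(observations$study_id[sel])),
                 strata = data.frame(country = names(counts),
                                     sources = counts,
                                     stratum = strata, row.names = NULL),
                 notes = character()),
            class = "bmi_holdout_plan")
}

#' Hold out a fraction of data sources
#'
#' Selects countries (from a mix of data-rich, average and data-poor) and
#' withholds, per selected country, either a random one third of its
#' sources or all of its sources with mid-year >= 2000 (scheme chosen at
#' random), until about \code{frac} of all sources are withheld.  A
#' selected country whose data all predate 2000 falls back to the
#' one-third scheme (logged in \code{notes}).  Deterministic given the
#' seed.
#'
#' @inheritParams split_holdout_countries
#' @return object of class \code{bmi_holdout_plan}.
#' @export
split_holdout_sources <- function(observations, sex, frac = 0.10, seed) {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  obs <- observations[observations$sex == sex, ]
  counts <- count_sources(observations, sex)
  strata <- classify_availability(counts, sex)
  total_sources <- sum(counts)
  target <- ceiling(frac * total_sources)
  set.seed(stream_seed(seed, 0L, 22L))
  candidates <- sample(names(counts))
  withheld <- character()
  notes <- character()
  schemes <- character()
  for (country in candidates) {
    if (length(withheld) >= target) break
    sources <- unique(obs$study_id[obs$country == country])
    scheme <- sample(c("third", "post2000"), 1)
    if (scheme == "post2000") {
      years <- tapply(obs$mid_year[obs$country == country],
                      obs$study_id[obs$country == country], min)
      post <- names(years)[years >= 2000]
      if (!length(post)) {
        notes <- c(notes, sprintf(
          "%s: all data pre-2000; fell back to one-third scheme", country))
        scheme <- "third"
      } else {
        w <- post
      }
    }
    if (scheme == "third") {
      k <- max(1L, round(length(sources) / 3))
      w <- sample(sources, k)
    }
    withheld <- c(withheld, w)
    schemes <- c(schemes, setNames(scheme, country))
  }
  structure(list(design = "sources", sex = sex, frac = frac, seed = seed,
                 withheld_countries = character(),
                 withheld_studies = sort(unique(withheld)),
                 schemes = schemes,
                 strata = data.frame(country = names(counts),
                                     sources = counts,
                                     stratum = strata, row.names = NULL),
                 notes = notes),
            class = "bmi_holdout_plan")
}

#' Apply a holdout plan
#'
#' @param observations observation rows (one or both sexes).
#' @param plan a \code{bmi_holdout_plan}.
#' @return list with \code{retained} and \code{withheld} observation
#'   tables (partitioning the rows of the plan's sex).
#' @export
apply_holdout <- function(observations, plan) {
  sex_rows <- observations$sex == plan$sex
  held <- sex_rows & (observations$study_id %in% plan$withheld_studies)
  list(retained = observations[sex_rows & !held, , drop = FALSE],
       withheld = observations[held, , drop = FALSE])
}

#' Score held-out observations against a refitted model
#'
#' For each held-out row, the posterior predictive distribution of the
#' observation is constructed from the refit: the linked cell prediction
#' (with the row's age-group/stratum mapping and its coverage fixed
#' effect) convolved, per draw, with Normal noise from the study-effect
#' SD of its coverage level, the extra residual SD and the row's
#' sampling SE.  The error is the posterior-mean prediction minus the
#' observed mean (estimate 25 vs observation 24 gives +1).  Interval
#' coverage is evaluated through the predictive CDF at the observed
#' value (a mixture of Normal CDFs over draws, so scoring is a
#' deterministic function of the draws): the value lies inside the
#' central 95\% predictive interval when its CDF falls in
#' (0.025, 0.975).  The report gives the median error, the median
#' absolute error and the coverage percentage, pooled and stratified by
#' period and by the country's data-availability stratum.
#'
#' @param withheld held-out observation rows.
#' @param fit a \code{bmi_fit} on the retained data.
#' @param plan the \code{bmi_holdout_plan} (for stratification labels).
#' @param seed unused; kept for interface stability.
#' @return object of class \code{bmi_validation_report}: data.frame with
#'   one row per subset plus \code{"pooled"}.
#' @export
score_predictions <- function(withheld, fit, plan = NULL, seed = 1L) {
  if (!nrow(withheld)) {
    stop("score_predictions: no held-out cells", call. = FALSE)
  }
  layout <- fit$layout
  pop <- fit$inputs$pop
  n_draws <- nrow(fit$theta)
  err <- numeric(nrow(withheld))
  inside <- logical(nrow(withheld))
  for (i in seq_len(nrow(withheld))) {
    row <- withheld[i, ]
    aw <- age_group_weights(layout, pop, row$country, row$mid_year,
                            row$sex, row$age_lo, row$age_hi)
    urb_w <- switch(row$stratum, rural = rep(0, length(aw$est_idx)),
                    urban = rep(1, length(aw$est_idx)), mixed = aw$share)
    ci <- match(row$country, layout$hierarchy$country)
    ti <- match(row$mid_year, layout$years)
    de <- design_entries(layout, ci, ti, aw$est_idx, aw$w, urb_w)
    jx <- de$j
    xx <- de$x
    if (layout$comp$coverage_fx && row$coverage != "national") {
      jx <- c(jx, layout$blocks$coverage[match(row$coverage,
                                               c("subnational",
                                                 "community"))])
      xx <- c(xx, 1)
    }
    pred <- as.numeric(fit$theta[, jx, drop = FALSE] %*% xx)
    phi_name <- paste0("study_", row$coverage)
    phi <- if (phi_name %in% colnames(fit$hyper)) {
      fit$hyper[, phi_name]
    } else {
      rep(0, n_draws)
    }
    tau_name <- paste0("tau_", row$coverage)
    tau <- if (tau_name %in% colnames(fit$hyper)) {
      fit$hyper[, tau_name]
    } else {
      rep(0, n_draws)
    }
    err[i] <- mean(pred) - row$mean_bmi
    sd_i <- pmax(sqrt(row$se^2 + phi^2 + tau^2), 1e-12)
    cdf <- mean(pnorm(row$mean_bmi, pred, sd_i))
    inside[i] <- cdf > 0.025 && cdf < 0.975
  }
  strat_label <- if (!is.null(plan)) {
    plan$strata$stratum[match(withheld$country, plan$strata$country)]
  } else {
    rep("all", nrow(withheld))
  }
  period <- ifelse(withheld$mid_year < 2000, "1985-1999", "2000-2017")
  summarize <- function(idx, label) {
    data.frame(subset = label, n = length(idx),
               median_error = median(err[idx]),
               median_abs_error = median(abs(err[idx])),
               coverage95 = 100 * mean(inside[idx]))
  }
  subsets <- c(split(seq_along(err), period),
               split(seq_along(err), strat_label))
  out <- do.call(rbind, c(list(summarize(seq_along(err), "pooled")),
                          lapply(names(subsets), function(nm) {
                            summarize(subsets[[nm]], nm)
                          })))
  rownames(out) <- NULL
  structure(list(table = out, errors = err, inside = inside),
            class = "bmi_validation_report")
}

#' @export
print.bmi_validation_report <- function(x, ...) {
  cat("held-out validation report\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Run a repeated holdout validation
#'
#' Draws \code{reps} holdout plans (different sub-seeds), refits the
#' model on each retained set and scores the withheld rows; pools errors
#' and coverage across repetitions.
#'
#' @param observations observation rows.
#' @param pop population table.
#' @param config a \code{\link{model_config}}.
#' @param sex sex to validate.
#' @param design \code{"countries"} or \code{"sources"}.
#' @param reps repetitions (default 5).
#' @param frac holdout fraction (default 0.10).
#' @param seed integer seed.
#' @return list with per-rep reports and a pooled summary row.
#' @export
run_holdout_validation <- function(observations, pop, config, sex,
                                   design = c("sources", "countries"),
                                   reps = 5, frac = 0.10, seed) {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  design <- match.arg(design)
  reports <- vector("list", reps)
  err <- numeric()
  inside <- logical()
  for (r in seq_len(reps)) {
    plan <- if (design == "countries") {
      split_holdout_countries(observations, sex, frac,
                              seed = stream_seed(seed, r, 31L))
    } else {
      split_holdout_sources(observations, sex, frac,
                            seed = stream_seed(seed, r, 32L))
    }
    parts <- apply_holdout(observations, plan)
    if (!nrow(parts$withheld)) next
    inputs <- build_model_inputs(parts$retained, pop, config, sex)
    fit <- fit_mcmc(inputs, config, seed = stream_seed(seed, r, 33L))
    rep_report <- score_predictions(parts$withheld, fit, plan,
                                    seed = stream_seed(seed, r, 34L))
    reports[[r]] <- rep_report
    err <- c(err, rep_report$errors)
    inside <- c(inside, rep_report$inside)
  }
  pooled <- data.frame(subset = "pooled-all-reps", n = length(err),
                       median_error = median(err),
                       median_abs_error = median(abs(err)),
                       coverage95 = 100 * mean(inside))
  list(reports = reports, pooled = pooled)
}
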