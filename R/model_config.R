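# Model configuration for the hierarchical rural/urban BMI trend model.

#' Configure the hierarchical BMI trend model
#'
#' The model, fitted separately by sex, describes the mean BMI of the
#' rural stratum of country \eqn{c} in year \eqn{t} and estimation age
#' group \eqn{a} as
#' \deqn{\mu_{rural}(c,t,a) = a_c + b_c (t - t_0) + u_c(t) + \gamma_c(a)}
#' with the urban stratum offset by a country- and year-varying difference
#' \deqn{\mu_{urban} = \mu_{rural} + \delta_{0c} + \delta_{1c} (t - t_0).}
#' Country intercepts, slopes and gap parameters are shrunk hierarchically
#' (country toward region, region toward super-region, super-region toward
#' global); \eqn{u_c} is a second-order random walk with sum-to-zero and
#' zero-linear-trend constraints (identifiable against \eqn{a_c, b_c});
#' \eqn{\gamma_c} is a cubic B-spline age pattern (global coefficients
#' plus hierarchically shrunk country deviations).  Observations enter as
#' \deqn{y_i \sim N(\mathrm{linked\ prediction} + \beta_{cov(i)} + \nu_{s(i)},
#'   se_i^2 + \tau_{cov(i)}^2)}
#' where the linked prediction maps observed 10-year age groups and
#' unstratified ("mixed") rows to population-weighted combinations of the
#' estimation cells, \eqn{\beta} are fixed effects for subnational and
#' community coverage (national is the reference), \eqn{\nu_s} are study
#' random effects with coverage-specific SDs ordered
#' \eqn{\phi_{nat} \le \phi_{subnat} \le \phi_{comm}}, and
#' \eqn{\tau} are coverage-level-specific extra residual SDs.
#' All SD hyperparameters get half-Normal priors with configurable scales.
#'
#' @param hierarchy data.frame with columns \code{country}, \code{region},
#'   \code{super_region}; every observed country must appear.
#' @param years integer estimation year grid.
#' @param est_age_groups estimation age grid (default
#'   \code{\link{estimation_age_groups}}: 1-year groups at 18 and 19,
#'   5-year groups from 20 up).
#' @param n_draws posterior draws retained after burn-in (default 5000).
#' @param burnin burn-in iterations (default 500).
#' @param components named list of logical switches:
#'   \code{slope}, \code{rw2}, \code{age}, \code{gap}, \code{gap_trend},
#'   \code{study_re}, \code{coverage_fx}.  Disabling a component removes
#'   its parameters (used for degenerate-model oracles).
#' @param prior_scales named list of half-Normal scales for the SD
#'   hyperparameters: \code{intercept}, \code{slope}, \code{gap0},
#'   \code{gap1}, \code{age}, \code{rw2}, \code{study}, \code{tau}.
#' @param global_priors named list of Normal priors for global-level
#'   coefficients: \code{intercept_mean}, \code{intercept_sd},
#'   \code{slope_sd}, \code{gap0_sd}, \code{gap1_sd}, \code{age_sd},
#'   \code{coverage_sd}.
#' @param fixed_sd named numeric vector fixing selected SD hyperparameters
#'   instead of sampling them (names as in the hyperparameter table, e.g.
#'   \code{c(rw2 = 0)}); a value of 0 removes the block entirely.
#' @return object of class \code{bmi_model_config}.
#' @export
model_config <- function(hierarchy, years,
                         est_age_groups = estimation_age_groups(),
                         n_draws = 5000, burnin = 500,
                         components = list(),
                         prior_scales = list(),
                         global_priors = list(),
                         fixed_sd = numeric()) {
  stopifnot_fields(hierarchy, c("country", "region", "super_region"),
                   "hierarchy")
  if (n_draws < 1) stop("n_draws must be >= 1", call. = FALSE)
  comp <- utils::modifyList(list(slope = TRUE, rw2 = TRUE, age = TRUE,
                                 gap = TRUE, gap_trend = TRUE,
                                 study_re = TRUE, coverage_fx = TRUE),
                            components)
  ps <- utils::modifyList(list(intercept = 1, slope = 0.05, gap0 = 1,
                               gap1 = 0.05, age = 0.5, rw2 = 0.2,
                               study = 1, tau = 0.5),
                          prior_scales)
  if (any(unlist(ps) <= 0)) {
    stop("prior scales must be positive", call. = FALSE)
  }
  gp <- utils::modifyList(list(intercept_mean = 25, intercept_sd = 10,
                               slope_sd = 0.5, gap0_sd = 2, gap1_sd = 0.1,
                               age_sd = 5, coverage_sd = 1),
                          global_priors)
  structure(list(hierarchy = hierarchy, years = as.integer(years),
                 est_age_groups = est_age_groups,
                 n_draws = as.integer(n_draws),
                 burnin = as.integer(burnin), components = comp,
                 prior_scales = ps, global_priors = gp,
                 fixed_sd = fixed_sd),
            class = "bmi_model_config")
}
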