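# Decomposition of the change in population mean BMI between two years
# into rural-change, urban-change and urbanization components.
#
# With endpoint stratum means (rural0, rural1, urban0, urban1) and urban
# population shares (share0, share1), the change in the share-weighted
# population mean decomposes exactly as
#   rural component        = (rural1 - rural0) * (1 - share0)
#   urban component        = (urban1 - urban0) * share0
#   urbanization component = (share1 - share0) * (urban1 - rural1)
# whose sum equals the total change
#   [share1*urban1 + (1-share1)*rural1] - [share0*urban0 + (1-share0)*rural0].

#' Decompose the change in population mean BMI
#'
#' All arguments may be vectors of posterior draws (of equal length) or
#' scalars; the identity with the total change holds per draw.
#'
#' @param rural0,rural1 rural mean BMI at the first and last year, kg/m2.
#' @param urban0,urban1 urban mean BMI at the first and last year, kg/m2.
#' @param share0,share1 proportion of the population living in urban
#'   areas at the first and last year.
#' @return data.frame with per-draw columns \code{rural}, \code{urban},
#'   \code{urbanization} and \code{total} (kg/m2).
#' @export
decompose_change <- function(rural0, rural1, urban0, urban1,
                             share0, share1) {
  if (any(c(share0, share1) < 0) || any(c(share0, share1) > 1)) {
    stop("urban shares must lie in [0, 1]", call. = FALSE)
  }
  rural_c <- (rural1 - rural0) * (1 - share0)
  urban_c <- (urban1 - urban0) * share0
  urb_c <- (share1 - share0) * (urban1 - rural1)
  data.frame(rural = rural_c, urban = urban_c, urbanization = urb_c,
             total = rural_c + urban_c + urb_c)
}

#' Percentage contributions with the NR suppression rule
#'
#' In draws mode (a multi-row decomposition), each draw's percentage is
#' \code{100 * component / total}, summarized by the posterior mean and
#' the 2.5th/97.5th percentiles.  In point mode (one row), percentages
#' are deterministic ratios of the point components.  If the (posterior
#' mean) total change is smaller than \code{nr_threshold} in magnitude,
#' all three percentages are flagged NR (not reported), because the small
#' denominator makes the ratios unstable.  Unrounded point percentages
#' always sum to 100.
#'
#' @param decomp data.frame from \code{\link{decompose_change}} (per-draw
#'   rows, or a single point row).
#' @param nr_threshold NR suppression threshold on the magnitude of the
#'   total change, kg/m2 (default 0.5).
#' @param digits rounding for reported percentages (default 0, i.e.
#'   integers, rounding half away from zero); use \code{NULL} for
#'   unrounded values.
#' @return data.frame with one row per component: absolute contribution
#'   (posterior mean and 95\% CrI in draws mode), percentage contribution
#'   (with CrI in draws mode) and \code{nr} flag.
#' @export
percent_contributions <- function(decomp, nr_threshold = 0.5,
                                  digits = 0) {
  comps <- c("rural", "urban", "urbanization")
  point_mode <- nrow(decomp) == 1
  total_mean <- mean(decomp$total)
  nr <- abs(total_mean) < nr_threshold || total_mean == 0
  rnd <- function(x) if (is.null(digits)) x else round_half_away(x, digits)
  if (point_mode) {
    abs_mean <- unlist(decomp[1, comps])
    pct <- if (nr) rep(NA_real_, 3) else
      rnd(100 * abs_mean / decomp$total[1])
    return(data.frame(component = comps, absolute = as.numeric(abs_mean),
                      absolute_l95 = NA_real_, absolute_u95 = NA_real_,
                      percent = as.numeric(pct),
                      percent_l95 = NA_real_, percent_u95 = NA_real_,
                      nr = nr, row.names = NULL))
  }
  out <- lapply(comps, function(cc) {
    ci_abs <- credible_interval(decomp[[cc]])
    if (nr) {
      pct <- c(NA_real_, NA_real_, NA_real_)
    } else {
      pd <- 100 * decomp[[cc]] / decomp$total
      ci_pct <- credible_interval(pd)
      pct <- rnd(c(ci_pct$mean, ci_pct$l95, ci_pct$u95))
    }
    data.frame(component = cc, absolute = ci_abs$mean,
               absolute_l95 = ci_abs$l95, absolute_u95 = ci_abs$u95,
               percent = pct[1], percent_l95 = pct[2],
               percent_u95 = pct[3], nr = nr)
  })
  do.call(rbind, out)
}

#' Reference decomposition table for worked examples
#'
#' Posterior-mean absolute contributions (kg/m2) of rural BMI change,
#' urban BMI change and urbanization to the 1985-2017 rise in regional
#' mean BMI, by region and sex, together with the reported integer
#' percentage contributions (NA where the reported total change was below
#' the NR threshold).  The \code{exact} flag marks rows whose percentages
#' are reproduced exactly by \code{\link{percent_contributions}} in point
#' mode from the 2-decimal absolute contributions; the remaining rows
#' differ by at most one percentage point, attributable to the reference
#' percentages having been computed from unrounded draws.
#'
#' @return data.frame with columns region, sex, rural, urban,
#'   urbanization, pct_rural, pct_urban, pct_urbanization, exact.
#' @export
load_decomposition_reference <- function() {
  read.csv(system.file("extdata", "decomposition_reference.csv",
                       package = "bmitrend"), stringsAsFactors = FALSE)
}

#' Decomposition inputs from posterior draws at the region or world level
#'
#' Builds per-draw endpoint stratum means by population-weighted
#' aggregation of country-level age-standardized draws, plus the matching
#' population-weighted urban shares, and decomposes the change.
#'
#' @param draws_by_stratum list with \code{cells} (country, year,
#'   stratum; age-standardized) and \code{draws} for the two endpoint
#'   years.
#' @param pop population table.
#' @param sex sex.
#' @param year0,year1 endpoint years.
#' @param countries countries making up the aggregate.
#' @return data.frame of per-draw decomposition rows.
#' @export
decompose_aggregate <- function(draws_by_stratum, pop, sex, year0, year1,
                                countries) {
  cells <- draws_by_stratum$cells
  draws <- draws_by_stratum$draws
  sel_c <- cells$country %in% countries
  pop_sel <- pop[pop$sex == sex & pop$country %in% countries, ]
  endpoint <- function(year, stratum) {
    idx <- which(sel_c & cells$year == year & cells$stratum == stratum)
    if (!length(idx)) {
      stop(sprintf("no draws for %s/%d", stratum, year), call. = FALSE)
    }
    sub <- pop_sel[pop_sel$year == year, ]
    tot <- tapply(sub$population, sub$country, sum)
    sh <- tapply(sub$share_urban, sub$country, mean)
    w <- tot * if (stratum == "urban") sh else (1 - sh)
    w <- as.numeric(w[cells$country[idx]])
    w <- w / sum(w)
    as.numeric(draws[, idx, drop = FALSE] %*% w)
  }
  share_at <- function(year) {
    sub <- pop_sel[pop_sel$year == year, ]
    sum(sub$population * sub$share_urban) / sum(sub$population)
  }
  decompose_change(rural0 = endpoint(year0, "rural"),
                   rural1 = endpoint(year1, "rural"),
                   urban0 = endpoint(year0, "urban"),
                   urban1 = endpoint(year1, "urban"),
                   share0 = share_at(year0), share1 = share_at(year1))
}
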