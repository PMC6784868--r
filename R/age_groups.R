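# Canonical age groupings.
#
# Input (observation) groups: single years 18 and 19, then 10-year groups
# 20-29 ... 70-79 and an open-ended 80+ group.  Estimation groups: single
# years 18 and 19, then 5-year groups from 20-24 upward with an open-ended
# 80+ group.  The open-ended group is treated as 80-84 when a numeric
# midpoint is needed.

#' Canonical observation age groups
#'
#' @return data.frame with columns \code{age_lo}, \code{age_hi}
#'   (\code{Inf} for the open-ended 80+ group) and \code{label}.
#' @export
observation_age_groups <- function() {
  lo <- c(18, 19, seq(20, 70, by = 10), 80)
  hi <- c(18, 19, seq(29, 79, by = 10), Inf)
  data.frame(age_lo = lo, age_hi = hi, label = age_group_label(lo, hi),
             stringsAsFactors = FALSE)
}

#' Canonical estimation age groups
#'
#' Posterior estimates are made on 1-year groups for ages 18 and 19 and
#' 5-year groups for ages 20 and older.
#'
#' @return data.frame with columns \code{age_lo}, \code{age_hi},
#'   \code{label} and \code{age_mid} (midpoint used for spline evaluation;
#'   82.5 for the open-ended group).
#' @export
estimation_age_groups <- function() {
  lo <- c(18, 19, seq(20, 80, by = 5))
  hi <- c(18, 19, seq(24, 79, by = 5), Inf)
  mid <- ifelse(is.finite(hi), (lo + hi + 1) / 2, 82.5)
  data.frame(age_lo = lo, age_hi = hi, label = age_group_label(lo, hi),
             age_mid = mid, stringsAsFactors = FALSE)
}

age_group_label <- function(lo, hi) {
  ifelse(is.finite(hi),
         ifelse(lo == hi, as.character(lo), paste0(lo, "-", hi)),
         paste0(lo, "+"))
}

age_group_mid <- function(age_lo, age_hi) {
  ifelse(is.finite(age_hi), (age_lo + age_hi + 1) / 2, age_lo + 2.5)
}

#' Assign an adult age to its observation age group
#'
#' @param age numeric vector of ages in years (floored to integers if
#'   fractional); all must be >= 18.
#' @return data.frame with one row per input age: \code{age_lo},
#'   \code{age_hi}, \code{label}.
#' @examples
#' assign_age_group(c(18, 37, 80))
#' @export
assign_age_group <- function(age) {
  age <- floor(age)
  if (any(is.na(age)) || any(age < 18)) {
    stop("assign_age_group: all ages must be >= 18 and non-missing",
         call. = FALSE)
  }
  groups <- observation_age_groups()
  idx <- vapply(age, function(a) {
    which(a >= groups$age_lo & a <= groups$age_hi)[1]
  }, integer(1))
  groups[idx, c("age_lo", "age_hi", "label")]
}

# Which estimation groups does an observation group [lo, hi] span?
estimation_groups_within <- function(age_lo, age_hi) {
  est <- estimation_age_groups()
  which(est$age_lo >= age_lo & (est$age_hi <= age_hi |
                                  (!is.finite(est$age_hi) & !is.finite(age_hi))))
}
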