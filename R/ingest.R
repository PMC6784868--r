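# Cleaning of individual survey records and computation of the stratified
# summary rows the trend model consumes; reading/validation of summary
# CSVs.

#' Clean individual survey records
#'
#' Keeps adult (age >= 18), non-pregnant participants with plausible
#' anthropometry: 100 cm <= height <= 250 cm, 12 kg <= weight <= 300 kg
#' and 10 kg/m2 <= BMI <= 80 kg/m2 (BMI computed as weight over squared
#' height in metres).  Records with unknown rural/urban status are dropped
#' only in studies that recorded place of residence (i.e. studies where at
#' least one record has a known stratum).  Records with missing height,
#' weight or age are excluded with reason \code{"missing"}, not treated as
#' an error.
#'
#' @param records data.frame with columns \code{age} (years), \code{sex},
#'   \code{height} (cm), \code{weight} (kg), \code{pregnant} (logical; NA
#'   treated as not pregnant), \code{stratum}
#'   (\code{"rural"}/\code{"urban"}/\code{"unknown"}), \code{study_id} and
#'   optionally \code{sample_weight}.
#' @return list with \code{kept} (cleaned records plus a \code{bmi}
#'   column) and \code{exclusion_log} (data.frame of reason, count;
#'   counts plus kept rows add up to the input rows).
#' @export
clean_individual_records <- function(records) {
  stopifnot_fields(records, c("age", "sex", "height", "weight", "pregnant",
                              "stratum", "study_id"),
                   "individual record table")
  n <- nrow(records)
  reason <- rep(NA_character_, n)
  mark <- function(cond, why) {
    cond[is.na(cond)] <- FALSE
    reason[is.na(reason) & cond] <<- why
  }
  mark(is.na(records$height) | is.na(records$weight) | is.na(records$age),
       "missing")
  mark(records$age < 18, "age")
  preg <- records$pregnant
  preg[is.na(preg)] <- FALSE
  mark(preg, "pregnant")
  mark(records$height < 100 | records$height > 250 |
         records$weight < 12 | records$weight > 300,
       "implausible height/weight")
  bmi <- records$weight / (records$height / 100)^2
  mark(bmi < 10 | bmi > 80, "implausible BMI")
  # unknown stratum dropped only where the study recorded residence
  study_records_residence <- tapply(records$stratum %in% c("rural", "urban"),
                                    records$study_id, any)
  has_res <- study_records_residence[records$study_id]
  mark(!(records$stratum %in% c("rural", "urban")) & has_res,
       "unknown stratum")
  kept <- records[is.na(reason), , drop = FALSE]
  kept$bmi <- bmi[is.na(reason)]
  excluded <- reason[!is.na(reason)]
  log_levels <- c("missing", "age", "pregnant", "implausible height/weight",
                  "implausible BMI", "unknown stratum")
  counts <- table(factor(excluded, levels = log_levels))
  list(kept = kept,
       exclusion_log = data.frame(reason = log_levels,
                                  count = as.integer(counts),
                                  stringsAsFactors = FALSE))
}

#' Summarize cleaned records into stratified observation rows
#'
#' Computes, per sex x observation age group x stratum, the sample-weighted
#' mean BMI, its standard error from the weighted variance (with an
#' optional scalar design-effect multiplier) and the effective sample size
#' \eqn{(\sum w)^2 / \sum w^2}.  Studies that did not record place of
#' residence contribute \code{"mixed"} rows computed over the entire
#' sample.  Cells with fewer than 2 records are emitted with
#' \code{small_cell = TRUE} and a standard error from the study's pooled
#' within-cell variance.
#'
#' @param records cleaned records from
#'   \code{\link{clean_individual_records}} (one study).
#' @param design list with fields \code{study_id}, \code{country},
#'   \code{region}, \code{super_region}, \code{mid_year}, \code{coverage}
#'   and optionally \code{deff} (scalar design-effect multiplier on the SE,
#'   default 1).
#' @return data.frame of stratified observations.
#' @export
summarize_stratified <- function(records, design) {
  stopifnot_fields(design, c("study_id", "country", "mid_year", "coverage"),
                   "design info")
  deff <- design$deff %||% 1
  if (!nrow(records)) {
    return(empty_observations()[, setdiff(names(empty_observations()),
                                          c("true_mean", "within_sd"))])
  }
  w <- records$sample_weight %||% rep(1, nrow(records))
  if (is.null(records$sample_weight)) records$sample_weight <- w
  if (any(records$sample_weight <= 0)) {
    stop("summarize_stratified: sample weights must be positive",
         call. = FALSE)
  }
  has_res <- any(records$stratum %in% c("rural", "urban"))
  strat <- if (has_res) records$stratum else rep("mixed", nrow(records))
  grp <- assign_age_group(records$age)
  key <- interaction(records$sex, grp$label, strat, drop = TRUE)
  pooled_var <- weighted_var(records$bmi, records$sample_weight)
  out <- lapply(split(seq_len(nrow(records)), key), function(idx) {
    x <- records$bmi[idx]
    wi <- records$sample_weight[idx]
    m <- sum(wi * x) / sum(wi)
    n_eff <- sum(wi)^2 / sum(wi^2)
    small <- length(idx) < 2
    v <- if (small) pooled_var else weighted_var(x, wi)
    se <- deff * sqrt(v / n_eff)
    data.frame(study_id = design$study_id, country = design$country,
               region = design$region %||% NA_character_,
               super_region = design$super_region %||% NA_character_,
               mid_year = design$mid_year, sex = records$sex[idx[1]],
               age_lo = grp$age_lo[idx[1]], age_hi = grp$age_hi[idx[1]],
               stratum = strat[idx[1]], coverage = design$coverage,
               mean_bmi = m, se = se, n_eff = n_eff, small_cell = small,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$sex, res$age_lo, res$stratum), ]
}

# weighted variance with reliability weights (unbiased under w_i = k)
weighted_var <- function(x, w) {
  if (length(x) < 2) {
    return(NA_real_)
  }
  sw <- sum(w)
  m <- sum(w * x) / sw
  denom <- sw - sum(w^2) / sw
  if (denom <= 0) {
    return(var(x))
  }
  sum(w * (x - m)^2) / denom
}

.strata_levels <- c("rural", "urban", "mixed")
.coverage_levels <- c("national", "subnational", "community")

#' Load and validate a summary observation CSV
#'
#' Validates the documented schema: stratum in rural/urban/mixed, coverage
#' in national/subnational/community, positive SE, mean BMI strictly
#' inside (10, 80) kg/m2 and effective sample size >= 1.  Violations are
#' reported with their row numbers.
#'
#' @param path CSV path.
#' @return validated observation data.frame.
#' @export
load_summary_file <- function(path) {
  obs <- read.csv(path, stringsAsFactors = FALSE)
  validate_observations(obs)
}

#' Validate an observation data.frame against the schema
#' @param obs observation data.frame.
#' @return the validated data.frame (invisibly unchanged).
#' @export
validate_observations <- function(obs) {
  stopifnot_fields(obs, c("study_id", "country", "mid_year", "sex",
                          "age_lo", "age_hi", "stratum", "coverage",
                          "mean_bmi", "se", "n_eff"), "observation table")
  bad <- list()
  note <- function(cond, msg) {
    cond[is.na(cond)] <- TRUE
    if (any(cond)) {
      bad[[length(bad) + 1]] <<- sprintf("%s (rows %s)", msg,
        paste(utils::head(which(cond), 10), collapse = ", "))
    }
  }
  note(!(obs$stratum %in% .strata_levels), "unknown stratum label")
  note(!(obs$coverage %in% .coverage_levels), "unknown coverage label")
  note(obs$se <= 0, "non-positive standard error")
  note(obs$mean_bmi <= 10 | obs$mean_bmi >= 80,
       "mean BMI outside (10, 80)")
  note(obs$n_eff < 1, "effective sample size below 1")
  note(!(obs$sex %in% c("female", "male")), "unknown sex label")
  if (length(bad)) {
    stop(paste0("invalid observation table:\n  ",
                paste(unlist(bad), collapse = "\n  ")), call. = FALSE)
  }
  obs
}
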