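# Postprocessing of posterior draws: age-standardization,
# population-weighted aggregation, credible intervals and posterior
# direction probabilities.  All operations are deterministic functions of
# the draws (no fresh randomness) and linear ones are implemented as
# draws-matrix x sparse-weight-matrix products.

#' Load an age-standard weight table
#'
#' The packaged default is the WHO world standard population restricted to
#' the adult estimation age groups and renormalized to sum to 1.
#'
#' @param path CSV with columns \code{age_lo}, \code{age_hi},
#'   \code{weight}; default the packaged standard.
#' @return data.frame of class \code{bmi_age_standard}.
#' @export
load_age_standard <- function(path = system.file("extdata",
                                                 "who_standard.csv",
                                                 package = "bmitrend")) {
  std <- read.csv(path, stringsAsFactors = FALSE)
  stopifnot_fields(std, c("age_lo", "age_hi", "weight"), "age standard")
  if (any(std$weight < 0)) {
    stop("age standard weights must be non-negative", call. = FALSE)
  }
  class(std) <- c("bmi_age_standard", "data.frame")
  std
}

standard_weights_for <- function(standard, age_lo) {
  idx <- match(age_lo, standard$age_lo)
  if (any(is.na(idx))) {
    stop("age standard does not cover every estimation age group",
         call. = FALSE)
  }
  standard$weight[idx]
}

#' Age-standardize per-draw estimates
#'
#' Collapses the age dimension of a draws x cells matrix by taking, per
#' draw and per remaining key (country/year/stratum/...), the weighted
#' mean of age-specific values with the standard's weights.  Weights must
#' sum to 1 over the age groups present (within 1e-9) after subsetting,
#' otherwise a normalization error is raised.
#'
#' @param draws matrix draws x cells.
#' @param cells data.frame describing the columns of \code{draws}; must
#'   contain \code{age_lo}; all other columns are treated as keys.
#' @param standard an age-standard table covering every age group.
#' @return list with \code{draws} (draws x collapsed cells) and
#'   \code{cells} (collapsed keys).
#' @export
age_standardize <- function(draws, cells, standard) {
  if (!"age_lo" %in% names(cells)) {
    stop("cells must contain an age_lo column", call. = FALSE)
  }
  w <- standard_weights_for(standard, cells$age_lo)
  keys <- setdiff(names(cells), c("age_lo", "age_hi", "age_mid", "label"))
  key <- interaction(cells[keys], drop = TRUE, lex.order = TRUE)
  groups <- split(seq_len(nrow(cells)), key)
  for (g in groups) {
    if (abs(sum(w[g]) - 1) > 1e-9) {
      stop(sprintf("age-standard weights sum to %.6f (not 1) for a cell group",
                   sum(w[g])), call. = FALSE)
    }
  }
  W <- Matrix::sparseMatrix(
    i = unlist(groups),
    j = rep(seq_along(groups), lengths(groups)),
    x = w[unlist(groups)],
    dims = c(nrow(cells), length(groups)))
  out_cells <- do.call(rbind, lapply(groups, function(g) {
    cells[g[1], keys, drop = FALSE]
  }))
  rownames(out_cells) <- NULL
  list(draws = as.matrix(draws %*% W), cells = out_cells)
}

#' Population-weighted aggregation of per-draw estimates
#'
#' National level: combines the rural and urban strata of each country
#' with the year-specific urban share.  Regional/global level: combines
#' constituent countries with population weights by age group and sex.
#' Cells missing population rows raise an error listing the members.
#'
#' @param draws matrix draws x cells.
#' @param cells data.frame with columns \code{country}, \code{year},
#'   \code{stratum}, optionally \code{age_lo}.
#' @param pop population table.
#' @param level \code{"national"}, \code{"regional"} or \code{"global"}.
#' @param sex sex of the draws (population lookup key).
#' @param hierarchy needed for \code{level = "regional"}: data.frame
#'   mapping country to region.
#' @return list with \code{draws} and collapsed \code{cells}.
#' @export
aggregate_weighted <- function(draws, cells, pop, level, sex,
                               hierarchy = NULL) {
  level <- match.arg(level, c("national", "regional", "global"))
  pc <- pop_for_cells(cells, pop, sex)
  if (level == "national") {
    wt <- ifelse(cells$stratum == "urban", pc$share_urban,
                 ifelse(cells$stratum == "rural", 1 - pc$share_urban,
                        NA_real_))
    if (any(is.na(wt))) {
      stop("national aggregation requires rural/urban strata",
           call. = FALSE)
    }
    keys <- setdiff(names(cells), "stratum")
    return(collapse_weighted(draws, cells, keys, wt, normalize = FALSE))
  }
  if (level == "regional") {
    if (is.null(hierarchy)) {
      stop("regional aggregation needs a hierarchy", call. = FALSE)
    }
    cells$region <- hierarchy$region[match(cells$country,
                                           hierarchy$country)]
  }
  # within a stratum, weight by the stratum's population
  wt <- pc$population * ifelse(cells$stratum == "urban", pc$share_urban,
                               ifelse(cells$stratum == "rural",
                                      1 - pc$share_urban, 1))
  keys <- setdiff(names(cells), c("country", "region"))
  keys <- c(if (level == "regional") "region", keys)
  collapse_weighted(draws, cells, keys, wt, normalize = TRUE)
}

# population and urban share aligned to cells (summed over age when the
# cells carry no age dimension)
pop_for_cells <- function(cells, pop, sex) {
  pop_sel <- pop[pop$sex == sex, ]
  has_age <- "age_lo" %in% names(cells)
  if (!has_age) {
    tot <- aggregate(population ~ country + year, pop_sel, sum)
    sh <- aggregate(share_urban ~ country + year, pop_sel, mean)
    pop_sel <- merge(tot, sh, by = c("country", "year"))
  }
  key_cells <- paste(cells$country, cells$year,
                     if (has_age) cells$age_lo else "")
  key_pop <- paste(pop_sel$country, pop_sel$year,
                   if (has_age) pop_sel$age_lo else "")
  m <- match(key_cells, key_pop)
  if (any(is.na(m))) {
    stop(sprintf("population missing for: %s",
                 paste(unique(key_cells[is.na(m)]), collapse = "; ")),
         call. = FALSE)
  }
  pop_sel[m, c("population", "share_urban")]
}

collapse_weighted <- function(draws, cells, keys, wt, normalize) {
  key <- interaction(cells[keys], drop = TRUE, lex.order = TRUE)
  groups <- split(seq_len(nrow(cells)), key)
  ww <- wt
  if (normalize) {
    for (g in groups) ww[g] <- wt[g] / sum(wt[g])
  } else {
    for (g in groups) {
      if (abs(sum(wt[g]) - 1) > 1e-6) {
        stop("aggregation weights do not sum to 1 within a group",
             call. = FALSE)
      }
    }
  }
  W <- Matrix::sparseMatrix(
    i = unlist(groups),
    j = rep(seq_along(groups), lengths(groups)),
    x = ww[unlist(groups)],
    dims = c(nrow(cells), length(groups)))
  out_cells <- do.call(rbind, lapply(groups, function(g) {
    cells[g[1], keys, drop = FALSE]
  }))
  rownames(out_cells) <- NULL
  list(draws = as.matrix(draws %*% W), cells = out_cells)
}

#' Posterior mean and 95\% credible interval
#'
#' The interval is the empirical 2.5th and 97.5th percentiles of the
#' draws, computed with linear interpolation between order statistics
#' (quantile type 7).
#'
#' @param x numeric vector of draws, or a draws x cells matrix.
#' @return data.frame with columns \code{mean}, \code{l95}, \code{u95}.
#' @export
credible_interval <- function(x) {
  if (is.matrix(x)) {
    out <- do.call(rbind, lapply(seq_len(ncol(x)), function(j) {
      credible_interval(x[, j])
    }))
    rownames(out) <- colnames(x)
    return(out)
  }
  if (length(x) < 2) {
    stop("credible_interval needs at least 2 draws", call. = FALSE)
  }
  if (length(x) < 40) {
    warning("fewer than 40 draws: percentile resolution is limited")
  }
  q <- quantile(x, c(0.025, 0.975), names = FALSE, type = 7)
  data.frame(mean = mean(x), l95 = q[1], u95 = q[2])
}

#' Posterior probability of direction
#'
#' Fraction of draws sharing the sign of the posterior mean; by
#' convention this lies in [0.5, 1].  If the posterior mean is exactly
#' zero the function returns 0.5 with attribute \code{undirected = TRUE}.
#'
#' @param x numeric vector of per-draw differences.
#' @return proportion in [0.5, 1].
#' @export
direction_probability <- function(x) {
  if (length(x) < 2) {
    stop("direction_probability needs at least 2 draws", call. = FALSE)
  }
  m <- mean(x)
  if (m == 0) {
    return(structure(0.5, undirected = TRUE))
  }
  mean(sign(x) == sign(m)) + 0.5 * mean(x == 0)
}
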