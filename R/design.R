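# Parameter layout and design-matrix construction for the trend model.
# The parameter vector theta collects, per sex fit:
#   global intercept/slope, super-region/region/country deviations,
#   global + per-country age-spline coefficients, per-country RW2 weights
#   (in the eigenbasis of the second-difference penalty, which enforces
#   the sum-to-zero and zero-linear-trend constraints), urban-gap
#   intercept/trend at all hierarchy levels, coverage fixed effects and
#   study random effects.  Every observation is a sparse linear
#   functional of theta, so the full conditional of theta is Gaussian.

rw2_eigen <- function(n) {
  D <- diff(diag(n), differences = 2)
  K <- crossprod(D)
  e <- eigen(K, symmetric = TRUE)
  keep <- e$values > 1e-8
  list(Z = e$vectors[, keep, drop = FALSE], lambda = e$values[keep])
}

# allocate columns for one block; returns updated state
.alloc <- function(state, block, n, group, prior_sd = NA_real_,
                   prior_mean = 0, lambda = rep(1, n)) {
  if (n == 0) {
    return(state)
  }
  cols <- state$p + seq_len(n)
  state$p <- state$p + n
  state$blocks[[block]] <- cols
  state$par[[length(state$par) + 1]] <-
    data.frame(col = cols, block = block, group = group,
               prior_sd = prior_sd, prior_mean = prior_mean,
               lambda = lambda, stringsAsFactors = FALSE)
  state
}

build_parameter_layout <- function(config, studies) {
  h <- config$hierarchy
  comp <- config$components
  ps <- config$prior_scales
  gp <- config$global_priors
  fixed_sd <- config$fixed_sd
  years <- config$years
  nT <- length(years)
  est <- config$est_age_groups
  B <- bmi_age_basis(est$age_mid)
  K <- ncol(B)
  supers <- unique(h$super_region)
  regions <- unique(h$region)
  nC <- nrow(h)
  nS <- length(supers)
  nR <- length(regions)
  # a block whose SD hyperparameter is fixed at 0 is dropped entirely
  dropped <- names(fixed_sd)[fixed_sd == 0]
  on_ <- function(name) !(name %in% dropped)
  st <- list(p = 0L, blocks = list(), par = list())
  st <- .alloc(st, "g_intercept", 1L, "fixed", gp$intercept_sd,
               gp$intercept_mean)
  lv <- c("super", "region", "country")
  sizes <- c(nS, nR, nC)
  for (i in 1:3) {
    g <- paste0("intercept_", lv[i])
    if (on_(g)) st <- .alloc(st, g, sizes[i], g)
  }
  if (comp$slope) {
    st <- .alloc(st, "g_slope", 1L, "fixed", gp$slope_sd)
    for (i in 1:3) {
      g <- paste0("slope_", lv[i])
      if (on_(g)) st <- .alloc(st, g, sizes[i], g)
    }
  }
  if (comp$age) {
    st <- .alloc(st, "g_age", K, "fixed", gp$age_sd)
    if (on_("age_country")) {
      st <- .alloc(st, "age_country", nC * K, "age_country")
    }
  }
  rw2 <- NULL
  if (comp$rw2 && nT >= 3 && on_("rw2")) {
    rw2 <- rw2_eigen(nT)
    m <- length(rw2$lambda)
    st <- .alloc(st, "rw2", nC * m, "rw2",
                 lambda = rep(rw2$lambda, nC))
  }
  if (comp$gap) {
    st <- .alloc(st, "g_gap0", 1L, "fixed", gp$gap0_sd)
    for (i in 1:3) {
      g <- paste0("gap0_", lv[i])
      if (on_(g)) st <- .alloc(st, g, sizes[i], g)
    }
    if (comp$gap_trend) {
      st <- .alloc(st, "g_gap1", 1L, "fixed", gp$gap1_sd)
      for (i in 1:3) {
        g <- paste0("gap1_", lv[i])
        if (on_(g)) st <- .alloc(st, g, sizes[i], g)
      }
    }
  }
  if (comp$coverage_fx) {
    st <- .alloc(st, "coverage", 2L, "fixed", gp$coverage_sd)
  }
  if (comp$study_re && length(studies$study_id)) {
    for (lev in .coverage_levels) {
      g <- paste0("study_", lev)
      idx <- which(studies$coverage == lev)
      if (length(idx) && on_(g)) {
        st <- .alloc(st, paste0("study_", lev), length(idx), g)
      }
    }
  }
  par <- do.call(rbind, st$par)
  # fix non-zero SDs requested via fixed_sd by converting to fixed priors
  for (g in names(fixed_sd)) {
    if (fixed_sd[[g]] > 0) {
      sel <- par$group == g
      par$prior_sd[sel] <- fixed_sd[[g]] / sqrt(par$lambda[sel])
      par$group[sel] <- "fixed"
    }
  }
  # map each study to its column
  study_col <- rep(NA_integer_, length(studies$study_id))
  if (comp$study_re) {
    for (lev in .coverage_levels) {
      blk <- st$blocks[[paste0("study_", lev)]]
      idx <- which(studies$coverage == lev)
      if (length(idx) && !is.null(blk)) study_col[idx] <- blk
    }
  }
  list(p = st$p, blocks = st$blocks, par = par,
       hierarchy = h, supers = supers, regions = regions,
       sup_of = match(h$super_region, supers),
       reg_of = match(h$region, regions),
       years = years, t0 = mean(years), est = est, B = B, K = K,
       rw2 = rw2, comp = config$components,
       studies = studies, study_col = study_col,
       prior_scales = config$prior_scales)
}

# sparse design entries for a population-weighted combination of
# estimation cells of one country-year.  w: weights over est rows
# (sum 1); urb_w: per-est-row urban weight (0 rural, 1 urban, share for
# mixed).
design_entries <- function(layout, ci, tidx, est_idx, w, urb_w) {
  bl <- layout$blocks
  dt <- layout$years[tidx] - layout$t0
  j <- c(bl$g_intercept,
         bl$intercept_super[layout$sup_of[ci]],
         bl$intercept_region[layout$reg_of[ci]],
         bl$intercept_country[ci])
  x <- rep(1, length(j))
  add <- function(jj, xx) {
    keep <- !vapply(jj, is.null, logical(1))
    j <<- c(j, unlist(jj[keep]))
    x <<- c(x, xx[keep])
  }
  if (layout$comp$slope) {
    add(list(bl$g_slope, bl$slope_super[layout$sup_of[ci]],
             bl$slope_region[layout$reg_of[ci]], bl$slope_country[ci]),
        rep(dt, 4))
  }
  if (layout$comp$age && !is.null(bl$g_age)) {
    bk <- as.numeric(w %*% layout$B[est_idx, , drop = FALSE])
    j <- c(j, bl$g_age)
    x <- c(x, bk)
    if (!is.null(bl$age_country)) {
      j <- c(j, bl$age_country[(ci - 1) * layout$K + seq_len(layout$K)])
      x <- c(x, bk)
    }
  }
  if (!is.null(layout$rw2) && !is.null(bl$rw2)) {
    m <- length(layout$rw2$lambda)
    j <- c(j, bl$rw2[(ci - 1) * m + seq_len(m)])
    x <- c(x, layout$rw2$Z[tidx, ])
  }
  ubar <- sum(w * urb_w)
  if (layout$comp$gap && ubar != 0) {
    add(list(bl$g_gap0, bl$gap0_super[layout$sup_of[ci]],
             bl$gap0_region[layout$reg_of[ci]], bl$gap0_country[ci]),
        rep(ubar, 4))
    if (layout$comp$gap_trend) {
      add(list(bl$g_gap1, bl$gap1_super[layout$sup_of[ci]],
               bl$gap1_region[layout$reg_of[ci]], bl$gap1_country[ci]),
          rep(ubar * dt, 4))
    }
  }
  list(j = j, x = x)
}

# population weights of the estimation groups inside an observation age
# group, and their urban shares
age_group_weights <- function(layout, pop, country, year, sex,
                              age_lo, age_hi) {
  est <- layout$est
  est_idx <- which(est$age_lo >= age_lo &
                     (est$age_hi <= age_hi |
                        (!is.finite(est$age_hi) & !is.finite(age_hi))))
  if (!length(est_idx)) {
    stop(sprintf("observation age group [%s, %s] maps to no estimation group",
                 age_lo, age_hi), call. = FALSE)
  }
  if (length(est_idx) == 1L) {
    sel <- pop[pop$country == country & pop$year == year &
                 pop$sex == sex & pop$age_lo == est$age_lo[est_idx], ]
    share <- if (nrow(sel)) sel$share_urban[1] else NA_real_
    return(list(est_idx = est_idx, w = 1, share = share))
  }
  sel <- pop[pop$country == country & pop$year == year & pop$sex == sex, ]
  m <- match(est$age_lo[est_idx], sel$age_lo)
  if (any(is.na(m))) {
    stop(sprintf("population missing for %s/%s/%s ages [%s, %s]", country,
                 year, sex, age_lo, age_hi), call. = FALSE)
  }
  w <- sel$population[m]
  list(est_idx = est_idx, w = w / sum(w), share = sel$share_urban[m])
}

#' Build model inputs from observations and a population table
#'
#' Maps each observation to the estimation cells it measures: an observed
#' 10-year age group links to the population-weighted combination of the
#' 5-year estimation groups it spans, and an unstratified ("mixed") row
#' links to \code{share_urban * mu_urban + (1 - share_urban) * mu_rural}.
#' Returns the sparse design, observation variances and parameter layout
#' consumed by \code{\link{fit_mcmc}}.
#'
#' @param observations validated observation rows (one sex; use
#'   \code{sex} to filter a mixed table).
#' @param pop population table (needed for mixed rows and multi-group age
#'   mapping).
#' @param config a \code{\link{model_config}}.
#' @param sex which sex to model (\code{"female"} or \code{"male"}).
#' @return object of class \code{bmi_model_inputs}.
#' @export
build_model_inputs <- function(observations, pop, config, sex) {
  obs <- observations[observations$sex == sex, , drop = FALSE]
  if (!nrow(obs)) stop("no observations for the requested sex",
                       call. = FALSE)
  unknown <- setdiff(unique(obs$country), config$hierarchy$country)
  if (length(unknown)) {
    stop(sprintf("observations for countries absent from hierarchy: %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  studies <- unique(obs[, c("study_id", "coverage")])
  studies <- studies[order(studies$study_id), ]
  layout <- build_parameter_layout(config, studies)
  n <- nrow(obs)
  trip_i <- vector("list", n)
  trip_j <- vector("list", n)
  trip_x <- vector("list", n)
  cty <- match(obs$country, config$hierarchy$country)
  tidx <- match(obs$mid_year, layout$years)
  if (any(is.na(tidx))) {
    stop("observation mid-years outside the model year grid",
         call. = FALSE)
  }
  stud_idx <- match(obs$study_id, studies$study_id)
  for (i in seq_len(n)) {
    aw <- age_group_weights(layout, pop, obs$country[i], obs$mid_year[i],
                            sex, obs$age_lo[i], obs$age_hi[i])
    urb_w <- switch(obs$stratum[i],
                    rural = rep(0, length(aw$est_idx)),
                    urban = rep(1, length(aw$est_idx)),
                    mixed = {
                      if (any(is.na(aw$share))) {
                        stop(sprintf("population (share_urban) missing for mixed observation %s/%s",
                                     obs$country[i], obs$mid_year[i]),
                             call. = FALSE)
                      }
                      aw$share
                    },
                    stop(sprintf("unknown stratum '%s'", obs$stratum[i]),
                         call. = FALSE))
    de <- design_entries(layout, cty[i], tidx[i], aw$est_idx, aw$w, urb_w)
    j <- de$j
    x <- de$x
    if (layout$comp$coverage_fx && obs$coverage[i] != "national") {
      j <- c(j, layout$blocks$coverage[match(obs$coverage[i],
                                             c("subnational", "community"))])
      x <- c(x, 1)
    }
    if (layout$comp$study_re && !is.na(layout$study_col[stud_idx[i]])) {
      j <- c(j, layout$study_col[stud_idx[i]])
      x <- c(x, 1)
    }
    trip_i[[i]] <- rep(i, length(j))
    trip_j[[i]] <- j
    trip_x[[i]] <- x
  }
  X <- Matrix::sparseMatrix(i = unlist(trip_i), j = unlist(trip_j),
                            x = unlist(trip_x), dims = c(n, layout$p))
  structure(list(X = X, y = obs$mean_bmi, se2 = obs$se^2,
                 level = obs$coverage, layout = layout, obs = obs,
                 sex = sex, config = config, pop = pop),
            class = "bmi_model_inputs")
}

# design matrix for prediction cells on the estimation grid
prediction_design <- function(layout, cells, pop = NULL, sex = NULL) {
  n <- nrow(cells)
  trip_i <- vector("list", n)
  trip_j <- vector("list", n)
  trip_x <- vector("list", n)
  cty <- match(cells$country, layout$hierarchy$country)
  tidx <- match(cells$year, layout$years)
  aidx <- match(cells$age_lo, layout$est$age_lo)
  if (any(is.na(cty)) || any(is.na(tidx)) || any(is.na(aidx))) {
    stop("prediction cells outside the estimated index sets",
         call. = FALSE)
  }
  for (i in seq_len(n)) {
    urb_w <- switch(cells$stratum[i], rural = 0, urban = 1,
                    stop("prediction cells must be rural or urban",
                         call. = FALSE))
    de <- design_entries(layout, cty[i], tidx[i], aidx[i], 1, urb_w)
    trip_i[[i]] <- rep(i, length(de$j))
    trip_j[[i]] <- de$j
    trip_x[[i]] <- de$x
  }
  Matrix::sparseMatrix(i = unlist(trip_i), j = unlist(trip_j),
                       x = unlist(trip_x), dims = c(n, layout$p))
}
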