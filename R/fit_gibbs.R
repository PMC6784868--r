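# Block Gibbs sampler for the hierarchical trend model.  Conditional on
# the SD hyperparameters the model is linear-Gaussian, so all regression
# effects (theta) are updated jointly from their multivariate-normal full
# conditional via a sparse Cholesky factorization; SD hyperparameters
# (half-Normal priors) are updated by univariate slice sampling.  The
# joint theta update makes the chain mix quickly relative to single-site
# samplers.

hyper_scale_for <- function(group, ps) {
  if (grepl("^intercept_", group)) return(ps$intercept)
  if (grepl("^slope_", group)) return(ps$slope)
  if (grepl("^gap0_", group)) return(ps$gap0)
  if (grepl("^gap1_", group)) return(ps$gap1)
  if (group == "age_country") return(ps$age)
  if (group == "rw2") return(ps$rw2)
  if (grepl("^study_", group)) return(ps$study)
  stop("unknown hyperparameter group: ", group)
}

#' Fit the hierarchical BMI trend model by MCMC
#'
#' Runs a block Gibbs sampler: a joint sparse multivariate-normal update
#' of all regression effects, followed by slice-sampling updates of the SD
#' hyperparameters (with the study-effect SDs constrained to the ordering
#' national <= subnational <= community) and of the coverage-level
#' extra residual SDs.  After burn-in, \code{n_draws} draws
#' are retained.  Split-Rhat and effective sample sizes are computed for
#' a set of monitored scalars; if any Rhat exceeds 1.05 the fit is flagged
#' (with a warning), not silently returned.
#'
#' @param inputs design bundle from \code{\link{build_model_inputs}}.
#' @param config the \code{\link{model_config}} (defaults to the one
#'   stored in \code{inputs}).
#' @param seed integer seed (required).
#' @return object of class \code{bmi_fit} with elements \code{theta}
#'   (draws x parameters), \code{hyper} (draws x SD hyperparameters),
#'   \code{layout}, \code{diagnostics} and \code{converged}.
#' @export
fit_mcmc <- function(inputs, config = inputs$config, seed) {
  if (missing(seed)) stop("fit_mcmc: seed is required", call. = FALSE)
  if (!inherits(inputs, "bmi_model_inputs")) {
    stop("inputs must come from build_model_inputs", call. = FALSE)
  }
  set.seed(stream_seed(seed, 0L, 42L))
  layout <- inputs$layout
  par <- layout$par
  ps <- layout$prior_scales
  X <- inputs$X
  Xt <- Matrix::t(X)
  y <- inputs$y
  se2 <- inputs$se2
  n <- length(y)
  p <- layout$p
  level <- inputs$level
  # hyperparameter groups
  coef_groups <- setdiff(unique(par$group), "fixed")
  grp <- lapply(coef_groups, function(g) {
    sel <- par$group == g
    list(name = g, cols = par$col[sel], lambda = par$lambda[sel],
         scale = hyper_scale_for(g, ps))
  })
  names(grp) <- coef_groups
  tau_levels <- intersect(.coverage_levels, unique(level))
  tau_fixed <- vapply(paste0("tau_", tau_levels), function(nm) {
    if (nm %in% names(config$fixed_sd)) config$fixed_sd[[nm]] else NA_real_
  }, numeric(1))
  # state
  sigma <- vapply(grp, function(g) g$scale / 2, numeric(1))
  tau <- setNames(ifelse(is.na(tau_fixed), 0.1, tau_fixed), tau_levels)
  theta <- par$prior_mean
  m0 <- par$prior_mean
  prior_sd_fixed <- par$prior_sd
  lam <- par$lambda
  tau2_of_obs <- function() {
    out <- numeric(n)
    for (lv in tau_levels) out[level == lv] <- tau[[lv]]^2
    out
  }
  pdiag <- function() {
    pr <- numeric(p)
    fixed <- par$group == "fixed"
    pr[par$col[fixed]] <- 1 / prior_sd_fixed[fixed]^2
    for (g in grp) pr[g$cols] <- g$lambda / sigma[[g$name]]^2
    pr
  }
  n_iter <- config$burnin + config$n_draws
  theta_draws <- matrix(NA_real_, config$n_draws, p)
  hyper_names <- c(names(sigma), if (length(tau_levels))
    paste0("tau_", tau_levels))
  hyper_draws <- matrix(NA_real_, config$n_draws, length(hyper_names),
                        dimnames = list(NULL, hyper_names))
  mon_names <- c("g_intercept",
                 if (!is.null(layout$blocks$g_slope)) "g_slope",
                 if (!is.null(layout$blocks$g_gap0)) "g_gap0",
                 hyper_names)
  monitors <- matrix(NA_real_, n_iter, length(mon_names),
                     dimnames = list(NULL, mon_names))
  ch <- NULL
  half_norm_log <- function(s, scale) -s^2 / (2 * scale^2)
  for (it in seq_len(n_iter)) {
    v <- se2 + tau2_of_obs()
    winv <- 1 / v
    Pd <- pdiag()
    Q <- Matrix::forceSymmetric(Xt %*% (winv * X)) +
      Matrix::Diagonal(p, Pd)
    Q <- methods::as(Q, "dsCMatrix")
    if (is.null(ch)) {
      ch <- Matrix::Cholesky(Q, LDL = FALSE, perm = TRUE)
    } else {
      ch <- Matrix::update(ch, Q)
    }
    b <- as.numeric(Xt %*% (winv * y)) + Pd * m0
    mu <- as.numeric(Matrix::solve(ch, b))
    z <- rnorm(p)
    u <- Matrix::solve(ch, z, system = "Lt")
    theta <- mu + as.numeric(Matrix::solve(ch, u, system = "Pt"))
    # --- SD hyperparameters (slice sampling, half-Normal priors) ---
    study_groups <- intersect(paste0("study_", .coverage_levels),
                              names(grp))
    for (gname in names(grp)) {
      g <- grp[[gname]]
      S <- sum(g$lambda * theta[g$cols]^2)
      ng <- length(g$cols)
      lower <- 1e-4
      upper <- Inf
      if (gname %in% study_groups) {
        # enforce phi_national <= phi_subnational <= phi_community
        pos <- match(gname, paste0("study_", .coverage_levels))
        below <- paste0("study_", .coverage_levels)[seq_len(pos - 1)]
        above <- paste0("study_", .coverage_levels)[-seq_len(pos)]
        below <- intersect(below, names(sigma))
        above <- intersect(above, names(sigma))
        if (length(below)) lower <- max(lower, max(sigma[below]))
        if (length(above)) upper <- min(upper, min(sigma[above]))
      }
      logf <- function(s) {
        -ng * log(s) - S / (2 * s^2) + half_norm_log(s, g$scale)
      }
      s0 <- min(max(sigma[[gname]], lower + 1e-6), if (is.finite(upper))
        upper - 1e-6 else sigma[[gname]])
      sigma[[gname]] <- slice_sample1(s0, logf, w = g$scale / 4,
                                      lower = lower, upper = upper)
    }
    # --- interweaving (ancillarity-sufficiency) rescaling step ---
    # In the non-centered parameterization theta_g = sigma_g * w_g the
    # conditional of sigma_g is Gaussian, which breaks the funnel-shaped
    # coupling between a block and its scale (important for the RW2
    # smoothing SD on sparse data).  Sign ambiguity is absorbed into w_g,
    # so the half-Normal prior on sigma_g corresponds to a Normal on the
    # signed scale.
    Xtheta <- as.numeric(X %*% theta)
    for (gname in setdiff(names(grp), study_groups)) {
      g <- grp[[gname]]
      sg <- sigma[[gname]]
      tg <- theta[g$cols]
      if (sg < 1e-8 || all(tg == 0)) next
      u <- as.numeric(X[, g$cols, drop = FALSE] %*% (tg / sg))
      r <- y - Xtheta + u * sg
      prec <- sum(u^2 * winv) + 1 / g$scale^2
      mn <- sum(u * r * winv) / prec
      s_new <- rnorm(1, mn, sqrt(1 / prec))
      if (abs(s_new) < 1e-4) s_new <- sign(s_new + 1e-12) * 1e-4
      theta[g$cols] <- tg * (s_new / sg)
      sigma[[gname]] <- abs(s_new)
      Xtheta <- Xtheta + u * (s_new - sg)
    }
    if (length(tau_levels)) {
      r <- y - Xtheta
      for (lv in tau_levels) {
        if (!is.na(tau_fixed[[paste0("tau_", lv)]])) next
        ridx <- which(level == lv)
        rl <- r[ridx]
        sl <- se2[ridx]
        logf <- function(tt) {
          vv <- sl + tt^2
          -0.5 * sum(log(vv)) - sum(rl^2 / (2 * vv)) +
            half_norm_log(tt, ps$tau)
        }
        tau[[lv]] <- slice_sample1(max(tau[[lv]], 1e-4), logf,
                                   w = ps$tau / 4, lower = 0, upper = Inf)
      }
    }
    mon <- c(theta[layout$blocks$g_intercept],
             if (!is.null(layout$blocks$g_slope))
               theta[layout$blocks$g_slope],
             if (!is.null(layout$blocks$g_gap0))
               theta[layout$blocks$g_gap0],
             sigma, if (length(tau_levels)) tau)
    monitors[it, ] <- mon
    if (it > config$burnin) {
      k <- it - config$burnin
      theta_draws[k, ] <- theta
      hyper_draws[k, ] <- c(sigma, if (length(tau_levels)) tau)
    }
  }
  post <- monitors[seq.int(config$burnin + 1, n_iter), , drop = FALSE]
  rhat <- apply(post, 2, split_rhat)
  ess <- apply(post, 2, ess_basic)
  converged <- all(is.na(rhat) | rhat < 1.05)
  if (!converged) {
    warning(sprintf("possible non-convergence: max split-Rhat %.3f (%s)",
                    max(rhat, na.rm = TRUE),
                    names(which.max(rhat))))
  }
  structure(list(theta = theta_draws, hyper = hyper_draws,
                 layout = layout, inputs = inputs, config = config,
                 sex = inputs$sex, seed = seed,
                 diagnostics = data.frame(parameter = colnames(post),
                                          rhat = rhat, ess = ess),
                 converged = converged),
            class = "bmi_fit")
}

#' @export
print.bmi_fit <- function(x, ...) {
  cat(sprintf("hierarchical BMI trend fit (%s): %d draws, %d parameters, %d observations\n",
              x$sex, nrow(x$theta), ncol(x$theta), nrow(x$inputs$obs)))
  cat(sprintf("  converged: %s (max split-Rhat %.3f)\n", x$converged,
              max(x$diagnostics$rhat, na.rm = TRUE)))
  invisible(x)
}

#' Posterior draws of stratum mean BMI at estimation cells
#'
#' @param fit a \code{bmi_fit}.
#' @param cells data.frame with columns \code{country}, \code{year},
#'   \code{age_lo} (estimation group) and \code{stratum}
#'   (\code{"rural"} or \code{"urban"}).
#' @return matrix draws x cells of mean BMI, kg/m2.
#' @export
posterior_cells <- function(fit, cells) {
  Xg <- prediction_design(fit$layout, cells)
  as.matrix(fit$theta %*% Matrix::t(Xg))
}

#' Full posterior grid for one country
#'
#' @param fit a \code{bmi_fit}.
#' @param country country code.
#' @return list with \code{cells} (data.frame country/year/age_lo/stratum)
#'   and \code{draws} (matrix draws x cells).
#' @export
posterior_country_grid <- function(fit, country) {
  layout <- fit$layout
  cells <- expand.grid(age_lo = layout$est$age_lo, year = layout$years,
                       stratum = c("rural", "urban"),
                       stringsAsFactors = FALSE)
  cells$country <- country
  cells <- cells[, c("country", "year", "age_lo", "stratum")]
  list(cells = cells, draws = posterior_cells(fit, cells))
}

#' Per-draw rural, urban and mixed means for one cell
#'
#' The mixed (whole-population) mean is
#' \code{share_urban * urban + (1 - share_urban) * rural}, per draw, with
#' the urban share taken from the population table for the requested
#' country-year.  For a country-year whose population is entirely urban
#' or entirely rural, only the populated stratum (and the mixed series,
#' which then equals it) is returned.
#'
#' @param fit a \code{bmi_fit}.
#' @param pop population table.
#' @param country,year,sex,age_lo,age_hi requested cell; the age group may
#'   be an observation group spanning several estimation groups, in which
#'   case strata are population-weighted across them.
#' @return list of per-draw vectors: \code{rural}, \code{urban} (present
#'   when populated) and \code{mixed}.
#' @export
posterior_stratum_means <- function(fit, pop, country, year, sex,
                                    age_lo, age_hi = age_lo) {
  layout <- fit$layout
  aw <- age_group_weights(layout, pop, country, year, sex, age_lo, age_hi)
  if (any(is.na(aw$share))) {
    stop("population table lacks share_urban for the requested cell",
         call. = FALSE)
  }
  est <- layout$est
  mk <- function(stratum) {
    cells <- data.frame(country = country, year = year,
                        age_lo = est$age_lo[aw$est_idx],
                        stratum = stratum, stringsAsFactors = FALSE)
    posterior_cells(fit, cells) %*% aw$w
  }
  rural <- as.numeric(mk("rural"))
  urban <- as.numeric(mk("urban"))
  share <- sum(aw$w * aw$share)
  mixed <- share * urban + (1 - share) * rural
  out <- list(mixed = mixed)
  if (share < 1) out$rural <- rural
  if (share > 0) out$urban <- urban
  out[c(intersect(c("rural", "urban"), names(out)), "mixed")]
}
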