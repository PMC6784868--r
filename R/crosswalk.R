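# Conversion of BMI-category prevalences to mean BMI: regression of mean
# BMI on logit-transformed prevalences with sex and age covariates and a
# study-level random intercept, applied with full uncertainty propagation
# via joint draws of prevalence, coefficients, random effect and residual.

.prev_metrics <- c("overweight", "obesity", "underweight")

# availability pattern of a prevalence row, e.g. "obesity" or
# "overweight+obesity"
prevalence_pattern <- function(row) {
  avail <- .prev_metrics[!is.na(unlist(row[paste0("prev_", .prev_metrics)]))]
  paste(avail, collapse = "+")
}

crosswalk_age_basis <- function(age_mid) {
  splines::ns(age_mid, knots = c(35, 55), Boundary.knots = c(18, 85))
}

clamp_prevalence <- function(p, n) {
  lo <- 1 / (2 * n)
  pmin(pmax(p, lo), 1 - lo)
}

build_crosswalk_design <- function(df, metrics) {
  X <- cbind(intercept = rep(1, nrow(df)))
  for (m in metrics) {
    p <- clamp_prevalence(df[[paste0("prev_", m)]], df$n_eff)
    X <- cbind(X, logit(p))
    colnames(X)[ncol(X)] <- paste0("lg_", m)
  }
  X <- cbind(X, sex_male = as.numeric(df$sex == "male"))
  age_mid <- age_group_mid(df$age_lo, df$age_hi)
  NB <- unclass(crosswalk_age_basis(age_mid))
  colnames(NB) <- paste0("age_ns", seq_len(ncol(NB)))
  cbind(X, NB)
}

#' Fit prevalence-to-mean conversion regressions
#'
#' For each availability pattern (which of the overweight / obesity /
#' underweight prevalences a row reports) with at least \code{min_pairs}
#' paired cells, fits a linear mixed model of mean BMI on the
#' logit-transformed prevalences with sex and a natural-spline age
#' covariate and a study-level random intercept (via \code{lme4::lmer}).
#'
#' @param paired data.frame of cells reporting both \code{mean_bmi} and
#'   prevalence columns (\code{prev_overweight}, \code{prev_obesity},
#'   \code{prev_underweight}, any subset non-NA) plus \code{sex},
#'   \code{age_lo}, \code{age_hi}, \code{n_eff}, \code{study_id}.
#' @param min_pairs minimum paired cells per pattern (default 50).
#' @return object of class \code{bmi_crosswalk}: per-pattern coefficient
#'   vectors, coefficient covariance, random-effect SD and residual SD.
#' @export
fit_crosswalk <- function(paired, min_pairs = 50) {
  stopifnot_fields(paired, c("mean_bmi", "sex", "age_lo", "age_hi",
                             "n_eff", "study_id"), "paired crosswalk data")
  pat <- vapply(seq_len(nrow(paired)), function(i) {
    prevalence_pattern(paired[i, ])
  }, character(1))
  models <- list()
  for (p in unique(pat[pat != ""])) {
    idx <- which(pat == p)
    if (length(idx) < min_pairs) {
      stop(sprintf("fit_crosswalk: only %d paired cells for metric subset '%s' (need >= %d)",
                   length(idx), p, min_pairs), call. = FALSE)
    }
    df <- paired[idx, ]
    metrics <- strsplit(p, "+", fixed = TRUE)[[1]]
    X <- build_crosswalk_design(df, metrics)
    dat <- data.frame(y = df$mean_bmi, study = df$study_id, X[, -1])
    form <- stats::as.formula(paste("y ~", paste(colnames(X)[-1],
                                                 collapse = " + "),
                                    "+ (1 | study)"))
    fit <- suppressMessages(lme4::lmer(form, data = dat, REML = TRUE))
    vc <- as.data.frame(lme4::VarCorr(fit))
    re_sd <- vc$sdcor[vc$grp == "study"]
    resid_sd <- vc$sdcor[vc$grp == "Residual"]
    # align to the full design: columns dropped by lmer for rank
    # deficiency (e.g. a constant sex term in single-sex data) get
    # coefficient 0 and zero covariance
    full_names <- c("(Intercept)", colnames(X)[-1])
    beta_fit <- lme4::fixef(fit)
    V_fit <- as.matrix(vcov(fit))
    beta <- setNames(numeric(length(full_names)), full_names)
    V <- matrix(0, length(full_names), length(full_names),
                dimnames = list(full_names, full_names))
    keep <- intersect(full_names, names(beta_fit))
    beta[keep] <- beta_fit[keep]
    V[keep, keep] <- V_fit[keep, keep]
    if (resid_sd <= 0) resid_sd <- 1e-8
    models[[p]] <- list(pattern = p, metrics = metrics, coef = beta,
                        vcov = V, re_sd = re_sd, resid_sd = resid_sd,
                        n = length(idx))
  }
  structure(list(models = models), class = "bmi_crosswalk")
}

#' @export
print.bmi_crosswalk <- function(x, ...) {
  cat("BMI prevalence-to-mean crosswalk\n")
  for (m in x$models) {
    cat(sprintf("  pattern %-30s n=%5d resid SD %.3f study SD %.3f\n",
                m$pattern, m$n, m$resid_sd, m$re_sd))
  }
  invisible(x)
}

#' Point prediction of mean BMI from prevalences
#'
#' Deterministic prediction from the fitted fixed effects (no uncertainty
#' propagation); used for diagnostics and monotonicity checks.
#'
#' @param model a \code{bmi_crosswalk}.
#' @param newdata prevalence rows (same columns as conversion input).
#' @return numeric vector of predicted mean BMI, kg/m2.
#' @export
predict_crosswalk <- function(model, newdata) {
  vapply(seq_len(nrow(newdata)), function(i) {
    row <- newdata[i, , drop = FALSE]
    p <- prevalence_pattern(row)
    sub <- model$models[[p]]
    if (is.null(sub)) {
      stop(sprintf("no fitted crosswalk for metric subset '%s'", p),
           call. = FALSE)
    }
    X <- build_crosswalk_design(row, sub$metrics)
    as.numeric(X %*% sub$coef)
  }, numeric(1))
}

#' Convert prevalence-only observations to mean-BMI observations
#'
#' Per draw: prevalences are drawn from their sampling distributions
#' (clamped to \code{[1/(2n), 1 - 1/(2n)]} before the logit, with a
#' warning when boundary values are clamped), regression coefficients from
#' their joint covariance, a study random effect from its variance and a
#' residual from the residual SD.  The converted mean is the draw average
#' and the converted SE the draw SD, so all conversion uncertainty is
#' carried forward.  Deterministic given \code{seed}.
#'
#' @param obs prevalence-only observation rows (see
#'   \code{\link{make_prevalence_only_subset}}).
#' @param model a fitted \code{bmi_crosswalk}.
#' @param n_draws number of joint draws (default 1000).
#' @param seed integer seed (required for reproducibility).
#' @return data.frame of stratified observations with \code{converted =
#'   TRUE}; downstream summaries can report the converted fraction.
#' @export
convert_prevalence_to_mean <- function(obs, model, n_draws = 1000, seed) {
  if (missing(seed)) stop("convert_prevalence_to_mean: seed is required",
                          call. = FALSE)
  out <- vector("list", nrow(obs))
  clamped_any <- FALSE
  for (i in seq_len(nrow(obs))) {
    row <- obs[i, , drop = FALSE]
    p <- prevalence_pattern(row)
    sub <- model$models[[p]]
    if (is.null(sub)) {
      stop(sprintf("no fitted crosswalk for metric subset '%s'", p),
           call. = FALSE)
    }
    set.seed(stream_seed(seed, i, 1L))
    n <- row$n_eff
    lg <- matrix(0, n_draws, length(sub$metrics))
    for (k in seq_along(sub$metrics)) {
      m <- sub$metrics[k]
      phat <- row[[paste0("prev_", m)]]
      pse <- row[[paste0("se_", m)]]
      if (phat <= 0 || phat >= 1) clamped_any <- TRUE
      pd <- clamp_prevalence(rnorm(n_draws, phat, pse), n)
      lg[, k] <- logit(pd)
    }
    Xf <- build_crosswalk_design(row, sub$metrics)
    # indices of the logit columns inside the design
    lg_cols <- match(paste0("lg_", sub$metrics), colnames(Xf))
    Xd <- matrix(rep(as.numeric(Xf), each = n_draws), n_draws,
                 ncol(Xf))
    Xd[, lg_cols] <- lg
    V <- sub$vcov
    cholV <- tryCatch(chol(V), error = function(e) NULL)
    beta_draws <- if (is.null(cholV) || sum(abs(V)) == 0) {
      matrix(rep(sub$coef, each = n_draws), n_draws)
    } else {
      matrix(rep(sub$coef, each = n_draws), n_draws) +
        matrix(rnorm(n_draws * length(sub$coef)), n_draws) %*% cholV
    }
    pred <- rowSums(Xd * beta_draws) +
      rnorm(n_draws, 0, sub$re_sd) + rnorm(n_draws, 0, sub$resid_sd)
    keys <- c("study_id", "country", "region", "super_region", "mid_year",
              "sex", "age_lo", "age_hi", "stratum", "coverage")
    keys <- intersect(keys, names(row))
    out[[i]] <- cbind(row[, keys, drop = FALSE],
                      data.frame(mean_bmi = mean(pred),
                                 se = sd(pred),
                                 n_eff = n, converted = TRUE,
                                 stringsAsFactors = FALSE))
  }
  if (clamped_any) {
    warning("prevalence of exactly 0 or 1 clamped to [1/(2n), 1 - 1/(2n)] before logit")
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
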