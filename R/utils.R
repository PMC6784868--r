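# Small shared helpers: rounding, logit, deterministic RNG streams,
# slice sampling, and MCMC diagnostics.

#' Round half away from zero
#'
#' Standard reporting rounding for decomposition percentages: ties are
#' rounded away from zero (so 0.5 -> 1 and -0.5 -> -1), unlike base
#' \code{round()} which rounds half to even.
#'
#' @param x numeric vector.
#' @param digits number of decimal digits.
#' @return rounded numeric vector.
#' @export
round_half_away <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

logit <- function(p) qlogis(p)
inv_logit <- function(x) plogis(x)

# Deterministic sub-stream seeds so that, e.g., adding countries to a
# synthetic world does not perturb the draws of existing countries.
# All values stay below 2^31 - 1.
stream_seed <- function(seed, unit = 0L, purpose = 0L) {
  s <- (as.numeric(seed) %% 1e6) * 1009 + as.numeric(unit) * 101 +
    as.numeric(purpose) * 7919
  as.integer(s %% 2147483646) + 1L
}

with_stream <- function(seed, unit, purpose, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  set.seed(stream_seed(seed, unit, purpose))
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  force(expr)
}

# Univariate slice sampler (stepping out + shrinkage; Neal 2003), used for
# the SD hyperparameters whose half-Normal full conditionals are
# non-conjugate. log_f must be a vectorised-free scalar log-density.
slice_sample1 <- function(x0, log_f, w = 1, lower = -Inf, upper = Inf,
                          max_steps = 50L) {
  f0 <- log_f(x0)
  if (!is.finite(f0)) stop("slice sampler started at zero-density point")
  z <- f0 - stats::rexp(1)
  u <- runif(1)
  L <- x0 - w * u
  R <- L + w
  j <- floor(max_steps * runif(1))
  k <- max_steps - 1 - j
  while (j > 0 && L > lower && log_f(L) > z) {
    L <- L - w
    j <- j - 1
  }
  while (k > 0 && R < upper && log_f(R) > z) {
    R <- R + w
    k <- k - 1
  }
  L <- max(L, lower)
  R <- min(R, upper)
  repeat {
    x1 <- runif(1, L, R)
    if (log_f(x1) >= z) {
      return(x1)
    }
    if (x1 < x0) L <- x1 else R <- x1
    if (R - L < 1e-12) {
      return(x0)
    }
  }
}

# Split-Rhat on a single chain (split into two halves) and a basic
# effective-sample-size estimate via Geyer's initial positive sequence.
split_rhat <- function(x) {
  n <- length(x)
  if (n < 4) {
    return(NA_real_)
  }
  half <- floor(n / 2)
  chains <- cbind(x[seq_len(half)], x[seq.int(n - half + 1, n)])
  m <- ncol(chains)
  nn <- nrow(chains)
  means <- colMeans(chains)
  vars <- apply(chains, 2, var)
  W <- mean(vars)
  B <- nn * var(means)
  if (W <= 0) {
    return(1)
  }
  sqrt(((nn - 1) / nn * W + B / nn) / W)
}

ess_basic <- function(x) {
  n <- length(x)
  if (n < 8 || sd(x) == 0) {
    return(n)
  }
  ac <- stats::acf(x, lag.max = min(n - 2, 200), plot = FALSE)$acf[-1]
  # Geyer: sum consecutive pairs while positive
  s <- 0
  k <- 1
  while (k + 1 <= length(ac)) {
    pair <- ac[k] + ac[k + 1]
    if (pair < 0) break
    s <- s + pair
    k <- k + 2
  }
  max(1, n / (1 + 2 * s))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_fields <- function(x, fields, what) {
  miss <- setdiff(fields, names(x))
  if (length(miss)) {
    stop(sprintf("%s is missing field(s): %s", what,
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
}
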