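# Cubic B-spline age basis shared by the synthetic world and the trend
# model.  Columns are centred over the canonical estimation grid so the age
# pattern is approximately orthogonal to the intercept.

bmi_age_knots <- function() c(30, 45, 60)
bmi_age_boundary <- function() c(18, 85)

bmi_age_basis <- function(age_mid) {
  ref <- estimation_age_groups()$age_mid
  B_ref <- splines::bs(ref, knots = bmi_age_knots(), degree = 3,
                       Boundary.knots = bmi_age_boundary(), intercept = FALSE)
  ctr <- colMeans(B_ref)
  B <- splines::bs(age_mid, knots = bmi_age_knots(), degree = 3,
                   Boundary.knots = bmi_age_boundary(), intercept = FALSE)
  sweep(unclass(B), 2, ctr)
}

# Coefficients reproducing a plausible adult BMI-age curve on the shared
# basis: BMI rises from age 18, peaks around the late fifties and declines
# afterwards.  Solved once by least squares against a smooth target.
bmi_age_curve_coefs <- function() {
  est <- estimation_age_groups()
  target <- 4.0 * exp(-((est$age_mid - 57)^2) / (2 * 22^2))
  target <- target - mean(target)
  B <- bmi_age_basis(est$age_mid)
  qr.coef(qr(B), target)
}
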