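# Independent oracles, kept deliberately separate from the package's
# closed forms: adaptive quadrature of the cohort integrand, trapezoid
# integration of the foregone-sequestration flux, closed-form two-variable
# OLS via summary sums, and the hand-derived analytic derivative of the
# cumulative-emission closed form with respect to the deforestation rate.

quad_emissions <- function(A1, d, c, r, T, rel.tol = 1e-10) {
  if (d == 0 || T == 0 || A1 == 0 || c == 0) return(0)
  stats::integrate(function(y) A1 * d * exp(-d * y) * c * (1 - exp(-r * (T - y))),
                   lower = 0, upper = T, rel.tol = rel.tol)$value
}

trapezoid_foregone <- function(A1, d, s, T, h = 1e-3) {
  t <- seq(0, T, by = h)
  f <- s * A1 * (1 - exp(-d * t))
  sum((f[-1] + f[-length(f)]) / 2) * h
}

ols_sums <- function(x, y) {
  n <- length(x)
  sxx <- sum(x^2) - sum(x)^2 / n
  sxy <- sum(x * y) - sum(x) * sum(y) / n
  syy <- sum(y^2) - sum(y)^2 / n
  slope <- sxy / sxx
  list(slope = slope,
       intercept = mean(y) - slope * mean(x),
       r_squared = sxy^2 / (sxx * syy))
}

# dE/dd for E = A1 c K(d, r, T), K = 1 - e^{-dT} - d (e^{-dT} - e^{-rT})/(r-d)
demissions_dd <- function(A1, d, c, r, T) {
  edT <- exp(-d * T)
  erT <- exp(-r * T)
  dK <- T * edT -
    ((edT - erT) / (r - d) - d * T * edT / (r - d) +
       d * (edT - erT) / (r - d)^2)
  A1 * c * dK
}

# dS/dd for S = s A1 (T + expm1(-dT)/d)
dforegone_dd <- function(A1, d, s, T) {
  s * A1 * (-T * exp(-d * T) / d - expm1(-d * T) / d^2)
}

# random admissible cohort-model parameter draws (heavy-tailed scales)
random_cohort_params <- function(n, seed) {
  set.seed(seed)
  tibble::tibble(
    A1 = 10^stats::runif(n, 2, 6.3),
    d = 10^stats::runif(n, -4, -1.5),
    c = stats::runif(n, 50, 1400),
    r = 10^stats::runif(n, -2.5, -0.5),
    T = stats::runif(n, 5, 200)
  )
}
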