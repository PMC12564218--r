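## Independent oracles and fixture builders. The oracles deliberately take
## a different computational route from the package (lm on a raw basis,
## adaptive quadrature, dense trapezoid sums, explicit leave-one-out loops).

nine_distances <- c(25, 28, 33, 40, 50, 66, 100, 200, 300)

## random VA profile on the standard grid: smooth monotone-ish trend + noise
random_profile <- function(seed, noise_sd = 2) {
  set.seed(seed)
  base <- 70 + 16 * (log10(nine_distances) - log10(25)) /
    (log10(300) - log10(25))
  va <- clamp_01(base + rnorm(9, sd = noise_sd))
  data.frame(distance_cm = nine_distances, va_letters = va)
}

clamp_01 <- function(v) pmin(pmax(v, 0), 100)

## least-squares polynomial fit through stats::lm on the raw power basis
lm_poly_predict <- function(x, y, degree, newx) {
  xs <- x / max(x)
  fit <- lm(y ~ poly(xs, degree, raw = TRUE))
  unname(predict(fit, newdata = data.frame(xs = newx / max(x))))
}

## explicit leave-one-out RMSE by refitting (brute force)
loocv_rmse_brute <- function(x, y, degree) {
  errs <- vapply(seq_along(x), function(i) {
    xs <- x[-i] / max(x)
    fit <- lm(y[-i] ~ poly(xs, degree, raw = TRUE))
    pred <- unname(predict(fit, newdata = data.frame(xs = x[i] / max(x))))
    y[i] - pred
  }, numeric(1))
  sqrt(mean(errs^2))
}

## adaptive-quadrature area of a fitted visual curve over [lo, hi] (in the
## curve's working axis units)
quadrature_area <- function(curve, lo, hi) {
  f <- function(t) {
    ## evaluate the polynomial directly from its scaled coefficients
    out <- rep(0, length(t))
    for (a in rev(curve$coef_scaled)) out <- out * (t / curve$scale) + a
    out
  }
  stats::integrate(f, lo, hi, rel.tol = 1e-10, abs.tol = 0)$value
}

## dense composite-trapezoid area of the piecewise-linear interpolant
dense_trapz_area <- function(x, y, lo, hi, n_grid = 200001) {
  g <- seq(lo, hi, length.out = n_grid)
  v <- approx(x, y, xout = g)$y
  sum((v[-1] + v[-n_grid]) / 2 * diff(g))
}

## cohort built directly from given tables (bypasses the generator)
manual_cohort <- function(va, qol) {
  vicurve:::new_cohort(tibble::as_tibble(va), tibble::as_tibble(qol),
                       "manual fixture")
}

## complete qol table for the given ids
flat_qol <- function(ids, total = 80, near = 80, dist = 80) {
  tibble::tibble(patient_id = ids, total_score = total,
                 near_activities = near, distance_activities = dist,
                 complete = TRUE)
}

## full best-response NEI-VFQ-25 answer set (all items at maximum function)
vfq_best_responses <- function() {
  ids <- vicurve:::vfq_item_ids()
  r <- setNames(rep(1, length(ids)), ids)
  reversed <- as.character(17:25)  # coded 5 = best on these items
  r[reversed] <- 5
  r
}
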