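## Polynomial visual-curve machinery.
##
## Fitting is done in the scaled variable t = x / s (s = largest fitted
## distance) so the Vandermonde system is well conditioned; stored raw
## coefficients are recovered exactly as a_j / s^j. Integration is analytic
## (antiderivative of the polynomial), never quadrature.

poly_design <- function(x, degree, scale) {
  outer(x / scale, 0:degree, `^`)
}

## Least-squares polynomial fit with hat diagonal (for exact LOOCV).
fit_poly <- function(x, y, degree, scale = max(x)) {
  X <- poly_design(x, degree, scale)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    stopf("polynomial design of degree %d is rank deficient", degree)
  }
  coef_scaled <- qr.coef(qx, y)
  fitted <- drop(X %*% coef_scaled)
  Q <- qr.Q(qx)[, seq_len(qx$rank), drop = FALSE]
  list(coef_scaled = unname(coef_scaled), scale = scale,
       fitted = fitted, residuals = y - fitted, hat = rowSums(Q^2))
}

## Exact leave-one-out RMSE of a linear least-squares fit via the hat
## diagonal: e_i^{(-i)} = r_i / (1 - h_ii).
loocv_rmse <- function(fit) {
  denom <- 1 - fit$hat
  if (any(denom < 1e-10)) return(Inf)
  sqrt(mean((fit$residuals / denom)^2))
}

poly_eval_scaled <- function(coef_scaled, scale, x) {
  t <- x / scale
  out <- rep(0, length(t))
  for (a in rev(coef_scaled)) out <- out * t + a
  out
}

## integral of the polynomial over [lo, hi] in the original x units
poly_area <- function(coef_scaled, scale, lo, hi) {
  j <- seq_along(coef_scaled)
  a <- coef_scaled / j
  tl <- lo / scale
  th <- hi / scale
  scale * (sum(a * th^j) - sum(a * tl^j))
}

#' Select the polynomial degree for a visual-curve fit
#'
#' With five or fewer measurement points the curve interpolates exactly
#' (degree k-1). With more points the degree is chosen deterministically
#' from 3 upwards by exact leave-one-out cross-validation of the
#' least-squares fit; candidates are capped at k-2 so every leave-one-out
#' subproblem remains determined, and at 6. Ties (LOOCV RMSE within 1e-6
#' Letters) break toward the lower degree.
#'
#' @param distance_cm Strictly increasing test distances (cm), length >= 3.
#' @param va_letters Visual acuities (Letters) at those distances.
#' @return Integer polynomial degree.
#' @export
#' @examples
#' select_degree(c(25, 33, 66, 300), c(70, 74, 80, 86)) # 3: exact interpolation
select_degree <- function(distance_cm, va_letters) {
  k <- length(distance_cm)
  if (k < 3) stopf("degree selection needs at least 3 points, got %d", k)
  if (length(va_letters) != k) stopf("distance and VA lengths differ")
  if (k <= 5) return(k - 1L)
  candidates <- 3:min(6L, k - 2L)
  rmse <- vapply(candidates,
                 function(d) loocv_rmse(fit_poly(distance_cm, va_letters, d)),
                 numeric(1))
  best <- min(rmse)
  candidates[which(rmse <= best + 1e-6)[1L]]
}

new_visual_curve <- function(coef_scaled, scale, domain, degree, subset_id,
                             residuals, cv_rmse, x_axis = "cm",
                             distances = NULL) {
  structure(
    list(coef_scaled = coef_scaled, scale = scale, domain = domain,
         degree = degree, subset_id = subset_id,
         fit_diagnostics = list(residuals = residuals, cv_rmse = cv_rmse,
                                distances = distances),
         x_axis = x_axis),
    class = "visual_curve")
}

#' @export
coef.visual_curve <- function(object, ...) {
  ## raw ascending-degree coefficients over the working axis variable
  object$coef_scaled / object$scale^(seq_along(object$coef_scaled) - 1)
}

#' @export
print.visual_curve <- function(x, ...) {
  cat(sprintf("Visual curve [%s]: degree %d polynomial on [%g, %g] %s\n",
              x$subset_id %||% "custom", x$degree,
              x$domain[1], x$domain[2],
              if (x$x_axis == "cm") "cm" else "D"))
  cat("  max |residual|:",
      format(max(abs(x$fit_diagnostics$residuals)), digits = 3), "Letters\n")
  if (is.finite(x$fit_diagnostics$cv_rmse %||% NA_real_)) {
    cat("  LOOCV RMSE:", format(x$fit_diagnostics$cv_rmse, digits = 4),
        "Letters\n")
  }
  invisible(x)
}

## map a distance in cm onto the curve's working axis
axis_x <- function(distance_cm, x_axis) {
  if (x_axis == "cm") distance_cm else 100 / distance_cm
}

check_profile <- function(profile) {
  if (!all(c("distance_cm", "va_letters") %in% names(profile))) {
    stopf("profile must have columns distance_cm and va_letters")
  }
  d <- profile$distance_cm
  v <- profile$va_letters
  if (anyNA(d) || anyNA(v)) stopf("profile contains missing values")
  if (any(d <= 0)) stopf("distances must be positive")
  if (anyDuplicated(d)) stopf("duplicated distances in profile")
  if (length(d) < 2) stopf("profile needs at least 2 points")
  if (any(v < 0 | v > 100)) stopf("VA values must lie in [0, 100] Letters")
  ord <- order(d)
  list(distance_cm = d[ord], va_letters = v[ord])
}

#' Fit a visual curve (ViC) to a patient's measurements
#'
#' Restricts the profile to the distances of one measurement subset and fits
#' a polynomial in distance by least squares, with the degree chosen by
#' [select_degree()] (exact interpolation for four- and five-point subsets).
#'
#' @param profile Data frame with columns `distance_cm` and `va_letters`.
#' @param subset Subset id (`"S4"`, `"S5"`, `"S6"`, `"S9"`) or a numeric
#'   vector of member distances in cm. The piecewise-linear comparator is
#'   not fitted here; see [dct_aoc()].
#' @param x_axis `"diopters"` (default) fits over vergence x = 100/d, the
#'   conventional defocus-curve scale on which the measurement grid is
#'   nearly uniform; `"cm"` fits over linear distance.
#' @param warn_range Warn if the fitted curve leaves [0, 100] Letters inside
#'   its domain (checked on a dense grid).
#' @return A `visual_curve` object.
#' @export
#' @examples
#' prof <- data.frame(distance_cm = c(25, 33, 66, 300),
#'                    va_letters  = c(70, 74, 80, 86))
#' fit_vic(prof, "S4")
fit_vic <- function(profile, subset = "S9", x_axis = c("diopters", "cm"),
                    warn_range = TRUE) {
  x_axis <- match.arg(x_axis)
  if (is.character(subset)) {
    if (identical(subset, "DCT")) {
      stopf("the DCT comparator is piecewise linear; use dct_aoc()")
    }
    subset_id <- match.arg(subset, c("S4", "S5", "S6", "S9"))
    subset_d <- .SUBSETS[[subset_id]]
  } else {
    subset_id <- "custom"
    subset_d <- sort(as.numeric(subset))
  }
  p <- check_profile(profile)
  missing_d <- setdiff(subset_d, p$distance_cm)
  if (length(missing_d)) {
    stopf("profile is missing subset distance(s): %s cm",
          paste(missing_d, collapse = ", "))
  }
  keep <- p$distance_cm %in% subset_d
  d <- p$distance_cm[keep]
  v <- p$va_letters[keep]
  x <- axis_x(d, x_axis)
  ord <- order(x)
  x <- x[ord]; v <- v[ord]

  degree <- select_degree(x, v)
  fit <- fit_poly(x, v, degree)
  cv <- if (length(x) > 5) loocv_rmse(fit) else NA_real_
  curve <- new_visual_curve(fit$coef_scaled, fit$scale, range(x), degree,
                            subset_id, fit$residuals, cv, x_axis,
                            distances = d)
  if (warn_range) {
    grid <- seq(curve$domain[1], curve$domain[2], length.out = 201)
    gv <- poly_eval_scaled(curve$coef_scaled, curve$scale, grid)
    if (any(gv < 0 | gv > 100)) {
      warning(sprintf("fitted curve [%s] exits [0, 100] Letters within its domain",
                      subset_id), call. = FALSE)
    }
  }
  curve
}

#' Evaluate a fitted visual curve at a distance
#'
#' Returns the raw polynomial value (Letters) — no clamping — at a viewing
#' distance in cm. Extrapolation beyond the fitted domain is refused unless
#' explicitly allowed.
#'
#' @param curve A `visual_curve`.
#' @param distance_cm Distances (cm) at which to evaluate.
#' @param allow_extrapolation Permit evaluation outside the fitted domain.
#' @return Numeric VA values in Letters.
#' @export
evaluate_vic <- function(curve, distance_cm, allow_extrapolation = FALSE) {
  stopifnot(inherits(curve, "visual_curve"))
  x <- axis_x(distance_cm, curve$x_axis)
  tol <- 1e-9 * max(1, abs(curve$domain))
  outside <- x < curve$domain[1] - tol | x > curve$domain[2] + tol
  if (any(outside) && !allow_extrapolation) {
    stopf("distance %g cm lies outside the fitted domain [%g, %g]; set allow_extrapolation = TRUE to override",
          distance_cm[which(outside)[1]], curve$domain[1], curve$domain[2])
  }
  poly_eval_scaled(curve$coef_scaled, curve$scale, x)
}

#' @export
predict.visual_curve <- function(object, distance_cm, ...) {
  evaluate_vic(object, distance_cm, ...)
}

new_aoc_result <- function(total, near, distance, subset_id, method,
                           units = "Letters*D") {
  if (!all(is.finite(c(total, near, distance)))) {
    stopf("non-finite AoC component for subset %s", subset_id)
  }
  if (abs(near + distance - total) > 1e-9 * max(1, abs(total))) {
    stopf("AoC conservation violated for subset %s", subset_id)
  }
  structure(list(total = total, near = near, distance = distance,
                 subset_id = subset_id, method = method, units = units),
            class = "aoc_result")
}

#' @export
print.aoc_result <- function(x, ...) {
  cat(sprintf("AoC [%s, %s]: total %.2f | near %.2f | distance %.2f %s\n",
              x$subset_id, x$method, x$total, x$near, x$distance, x$units))
  invisible(x)
}

#' Area-of-the-Curve indices of a fitted visual curve
#'
#' Integrates the fitted polynomial analytically (exact antiderivative, no
#' quadrature) between the smallest and largest fitted distances, and splits
#' the area at 50 cm into the near-vision component AoCN (distances up to
#' the split) and the distance-vision component AoCD (beyond it), so that
#' AoCN + AoCD = total AoC.
#'
#' @param curve A `visual_curve`.
#' @param split_cm Near/distance boundary in cm (default 50), strictly
#'   inside the fitted domain.
#' @return An `aoc_result` with components `total`, `near`, `distance`
#'   (Letters·cm), `subset_id` and `method = "polynomial"`.
#' @export
aoc_indices <- function(curve, split_cm = 50) {
  stopifnot(inherits(curve, "visual_curve"))
  xs <- axis_x(split_cm, curve$x_axis)
  if (xs <= curve$domain[1] || xs >= curve$domain[2]) {
    stopf("split at %g cm falls outside the open fitted domain", split_cm)
  }
  lo <- curve$domain[1]; hi <- curve$domain[2]
  total <- poly_area(curve$coef_scaled, curve$scale, lo, hi)
  ## near vision = short distances: the lower x-range on a cm axis, the
  ## upper x-range on a diopter axis (x = 100/d reverses the order)
  if (curve$x_axis == "cm") {
    near <- poly_area(curve$coef_scaled, curve$scale, lo, xs)
    distance <- poly_area(curve$coef_scaled, curve$scale, xs, hi)
  } else {
    near <- poly_area(curve$coef_scaled, curve$scale, xs, hi)
    distance <- poly_area(curve$coef_scaled, curve$scale, lo, xs)
  }
  new_aoc_result(total, near, distance, curve$subset_id, "polynomial",
                 if (curve$x_axis == "cm") "Letters*cm" else "Letters*D")
}

## trapezoid area of the piecewise-linear interpolant of (x, y) over
## [lo, hi]; lo/hi need not be nodes (linear interpolation at the cuts)
trapz_between <- function(x, y, lo, hi) {
  if (hi <= lo) return(0)
  yl <- approx(x, y, xout = lo)$y
  yh <- approx(x, y, xout = hi)$y
  inner <- x > lo & x < hi
  xx <- c(lo, x[inner], hi)
  yy <- c(yl, y[inner], yh)
  sum(diff(xx) * (head(yy, -1) + tail(yy, -1)) / 2)
}

#' AoC of the conventional defocus-curve comparator
#'
#' Builds the conventional curve by connecting successive measurement points
#' with straight lines and computes total, near and distance areas by exact
#' trapezoid sums. When the split distance is not a measurement node the
#' containing segment is divided at the linearly interpolated value, so that
#' near + distance = total exactly.
#'
#' @param profile Data frame with columns `distance_cm`, `va_letters`
#'   (at least 2 points).
#' @param split_cm Near/distance boundary in cm (default 50), strictly
#'   inside the measured range.
#' @param x_axis `"cm"` or `"diopters"` (x = 100/d).
#' @return An `aoc_result` with `method = "piecewise_linear"`.
#' @export
dct_aoc <- function(profile, split_cm = 50, x_axis = c("diopters", "cm")) {
  x_axis <- match.arg(x_axis)
  p <- check_profile(profile)
  x <- axis_x(p$distance_cm, x_axis)
  ord <- order(x)
  x <- x[ord]; y <- p$va_letters[ord]
  xs <- axis_x(split_cm, x_axis)
  if (xs <= x[1] || xs >= x[length(x)]) {
    stopf("split at %g cm falls outside the open measured range", split_cm)
  }
  lower <- trapz_between(x, y, x[1], xs)
  upper <- trapz_between(x, y, xs, x[length(x)])
  if (x_axis == "cm") {
    near <- lower; distance <- upper
  } else {
    near <- upper; distance <- lower
  }
  new_aoc_result(near + distance, near, distance, "DCT", "piecewise_linear",
                 if (x_axis == "cm") "Letters*cm" else "Letters*D")
}
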