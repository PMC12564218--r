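## Synthetic cohort generator.
##
## Generative model: each patient carries latent near and distance
## abilities (u_N, u_D), bivariate standard normal with correlation
## rho_near_far. The population mean curve is affine in log10 distance,
## mu(d) = a + b log10(d), with (a, b) solved from the two reported
## anchors (VA at 40 cm and at 300 cm). A logistic weight in log10(d)
## with midpoint 50 cm blends the two abilities, and the ability scales
## (sigma_N, sigma_D) are solved so the marginal VA standard deviations
## at the two anchor distances match their reported values after adding
## i.i.d. measurement noise:
##   VA(d) = mu(d) + w(d) sigma_N u_N + (1 - w(d)) sigma_D u_D + eps,
## clamped to [0, 100] Letters. Quality-of-life subscales are affine in
## the corresponding latent ability plus noise, with the slope calibrated
## so corr(all-point AoC, total score) hits a stated target.

QOL_CENTER <- 82          # subscale location (points); see methods vignette
WEIGHT_STEEPNESS <- 6     # logistic slope per log10(distance) unit

#' Simulation parameters for a synthetic visual-function cohort
#'
#' @param n_patients Cohort size (>= 2); the study design uses 100.
#' @param distances_cm Strictly increasing test distances in cm.
#' @param mu_anchor_40,sd_anchor_40 Mean and SD of VA (Letters) at 40 cm.
#' @param mu_anchor_300,sd_anchor_300 Mean and SD of VA (Letters) at 300 cm.
#' @param rho_near_far Correlation of the latent near and distance
#'   abilities, in [-1, 1].
#' @param target_rho_qol Intended Pearson correlation between the all-point
#'   AoC and the total quality-of-life score, in [-1, 1].
#' @param measurement_sd Residual VA measurement noise SD (Letters).
#' @param qol_noise_sd Residual subscale noise SD (points).
#' @param round_letters Round simulated VA to whole letters.
#' @param seed Integer random seed.
#' @return A validated `sim_params` list.
#' @export
#' @examples
#' sim_params(n_patients = 10, seed = 1)
sim_params <- function(n_patients = 100L,
                       distances_cm = c(25, 28, 33, 40, 50, 66, 100, 200, 300),
                       mu_anchor_40 = 74.4, sd_anchor_40 = 7.74,
                       mu_anchor_300 = 85.6, sd_anchor_300 = 4.01,
                       rho_near_far = 0.5, target_rho_qol = 0.70,
                       measurement_sd = 2.0, qol_noise_sd = 6.0,
                       round_letters = FALSE, seed = 1L) {
  p <- list(n_patients = as.integer(n_patients), distances_cm = distances_cm,
            mu_anchor_40 = mu_anchor_40, sd_anchor_40 = sd_anchor_40,
            mu_anchor_300 = mu_anchor_300, sd_anchor_300 = sd_anchor_300,
            rho_near_far = rho_near_far, target_rho_qol = target_rho_qol,
            measurement_sd = measurement_sd, qol_noise_sd = qol_noise_sd,
            round_letters = isTRUE(round_letters), seed = as.integer(seed))
  validate_sim_params(p)
  structure(p, class = "sim_params")
}

validate_sim_params <- function(p) {
  fail <- function(field, msg) stopf("invalid sim_params$%s: %s", field, msg)
  if (is.na(p$n_patients) || p$n_patients < 2) {
    fail("n_patients", "must be an integer >= 2")
  }
  d <- p$distances_cm
  if (length(d) < 2 || any(d <= 0) || any(diff(d) <= 0)) {
    fail("distances_cm", "must be strictly increasing and positive")
  }
  for (f in c("sd_anchor_40", "sd_anchor_300", "measurement_sd",
              "qol_noise_sd")) {
    if (!is.finite(p[[f]]) || p[[f]] < 0) fail(f, "must be a finite SD >= 0")
  }
  for (f in c("rho_near_far", "target_rho_qol")) {
    if (!is.finite(p[[f]]) || abs(p[[f]]) > 1) fail(f, "must lie in [-1, 1]")
  }
  for (f in c("mu_anchor_40", "mu_anchor_300")) {
    if (!is.finite(p[[f]]) || p[[f]] < 0 || p[[f]] > 100) {
      fail(f, "must lie in [0, 100] Letters")
    }
  }
  if (is.na(p$seed)) fail("seed", "must be an integer")
  invisible(p)
}

#' @export
print.sim_params <- function(x, ...) {
  cat(sprintf("Simulation parameters: %d patients x %d distances (%g-%g cm)\n",
              x$n_patients, length(x$distances_cm), min(x$distances_cm),
              max(x$distances_cm)))
  cat(sprintf("  anchors: %0.1f +/- %0.2f Letters @40cm, %0.1f +/- %0.2f @300cm\n",
              x$mu_anchor_40, x$sd_anchor_40, x$mu_anchor_300,
              x$sd_anchor_300))
  cat(sprintf("  rho(near, far) = %g; target corr(AoC, QoL) = %g; seed %d\n",
              x$rho_near_far, x$target_rho_qol, x$seed))
  invisible(x)
}

## population mean curve: affine in log10(distance), through the anchors
mean_curve <- function(distance_cm, params) {
  b <- (params$mu_anchor_300 - params$mu_anchor_40) /
    (log10(300) - log10(40))
  a <- params$mu_anchor_40 - b * log10(40)
  a + b * log10(distance_cm)
}

## logistic near-weight in log10 distance, midpoint 50 cm: w -> 1 near
near_weight <- function(distance_cm) {
  plogis(-WEIGHT_STEEPNESS * (log10(distance_cm) - log10(50)))
}

## Solve (sigma_N, sigma_D) so that the marginal VA variances at the two
## anchor distances match sd_anchor_40^2 and sd_anchor_300^2. Fixed-point
## iteration on the two one-dimensional quadratics; the weights are close
## to 1 and 0 at the anchors so the system is nearly decoupled.
solve_ability_scales <- function(params) {
  m2 <- params$measurement_sd^2
  rhs40 <- params$sd_anchor_40^2 - m2
  rhs300 <- params$sd_anchor_300^2 - m2
  if (rhs40 <= 0 || rhs300 <= 0) {
    stopf("invalid sim_params$measurement_sd: exceeds an anchor SD (no latent variance left)")
  }
  w40 <- near_weight(40)
  w300 <- near_weight(300)
  rho <- params$rho_near_far
  ## positive root of A s^2 + B s + C = 0 given the other scale
  root <- function(A, B, C) {
    disc <- B^2 - 4 * A * C
    if (disc < 0) stopf("ability-scale solve failed (anchor SDs inconsistent)")
    (-B + sqrt(disc)) / (2 * A)
  }
  sN <- sqrt(rhs40)
  sD <- sqrt(rhs300)
  for (i in 1:200) {
    sD_new <- root((1 - w300)^2, 2 * rho * w300 * (1 - w300) * sN,
                   w300^2 * sN^2 - rhs300)
    sN_new <- root(w40^2, 2 * rho * w40 * (1 - w40) * sD_new,
                   (1 - w40)^2 * sD_new^2 - rhs40)
    if (abs(sN_new - sN) < 1e-12 && abs(sD_new - sD) < 1e-12) {
      sN <- sN_new; sD <- sD_new
      break
    }
    sN <- sN_new; sD <- sD_new
  }
  check <- function(w, sN, sD) {
    w^2 * sN^2 + (1 - w)^2 * sD^2 + 2 * rho * w * (1 - w) * sN * sD
  }
  if (abs(check(w40, sN, sD) - rhs40) > 1e-6 * max(1, rhs40) ||
      abs(check(w300, sN, sD) - rhs300) > 1e-6 * max(1, rhs300)) {
    stopf("ability-scale solve did not converge")
  }
  c(sigma_n = sN, sigma_d = sD)
}

## draw latent abilities and the VA matrix (distances x patients)
draw_va <- function(n, params, scales) {
  d <- params$distances_cm
  z1 <- rnorm(n)
  z2 <- rnorm(n)
  u_n <- z1
  u_d <- params$rho_near_far * z1 + sqrt(1 - params$rho_near_far^2) * z2
  mu <- mean_curve(d, params)
  w <- near_weight(d)
  eps <- matrix(rnorm(length(d) * n, sd = params$measurement_sd),
                nrow = length(d))
  Y <- mu + outer(w * scales["sigma_n"], u_n) +
    outer((1 - w) * scales["sigma_d"], u_d) + eps
  Y <- clamp(Y, 0, 100)
  if (params$round_letters) Y <- round(Y)
  list(Y = Y, u_n = u_n, u_d = u_d)
}

## total AoC over all configured distances for each column of Y, on the
## default vergence axis (x = 100/d) used by the analysis pipeline
aoc_all_points <- function(Y, distances, split_cm = 50) {
  x <- 100 / distances
  o <- order(x)
  aoc_poly_batch(x[o], Y[o, , drop = FALSE], 100 / split_cm,
                 near_is_lower = FALSE)$total
}

qol_from_latent <- function(u_n, u_d, beta, e_near, e_dist) {
  near <- clamp(QOL_CENTER + beta * u_n + e_near, 0, 100)
  dist <- clamp(QOL_CENTER + beta * u_d + e_dist, 0, 100)
  list(near = near, dist = dist, total = (near + dist) / 2)
}

#' Calibrate the quality-of-life slope of the generator
#'
#' Finds the affine slope linking the latent abilities to the
#' quality-of-life subscales so that, in a calibration cohort, the Pearson
#' correlation between the all-point AoC and the total score matches
#' `target_rho_qol`. The search is a deterministic monotone
#' bracket-and-bisect on the realised calibration sample (the correlation
#' is increasing in the slope magnitude).
#'
#' @param params A [sim_params()] object.
#' @param n_cal Calibration cohort size (>= 1000).
#' @return The slope (points per latent SD), with the sign of the target.
#' @export
calibrate_qol_slope <- function(params, n_cal = 2000L) {
  validate_sim_params(params)
  if (n_cal < 1000) stopf("n_cal must be >= 1000 for a stable calibration")
  target <- params$target_rho_qol
  if (target == 0) return(0)

  set.seed(derive_seed(params$seed))
  scales <- solve_ability_scales(params)
  sim <- draw_va(n_cal, params, scales)
  aoc <- aoc_all_points(sim$Y, params$distances_cm)
  e_near <- rnorm(n_cal, sd = params$qol_noise_sd)
  e_dist <- rnorm(n_cal, sd = params$qol_noise_sd)

  sgn <- sign(target)
  g <- function(beta) {
    q <- qol_from_latent(sim$u_n, sim$u_d, sgn * beta, e_near, e_dist)
    sgn * cor(aoc, q$total)
  }
  tgt <- abs(target)
  lo <- 0; hi <- 1
  while (g(hi) < tgt) {
    lo <- hi
    hi <- hi * 2
    if (hi > 1e6) {
      stopf("calibration failure: target correlation %g is unattainable with qol_noise_sd = %g",
            target, params$qol_noise_sd)
    }
  }
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (g(mid) < tgt) lo <- mid else hi <- mid
    if (hi - lo < 1e-10 * max(1, hi)) break
  }
  beta <- (lo + hi) / 2
  if (abs(g(beta) - tgt) > 0.02) {
    stopf("calibration failure: best achievable correlation %0.3f misses target %0.3f",
          sgn * g(beta), target)
  }
  sgn * beta
}

new_cohort <- function(va, qol, provenance) {
  structure(list(va = va, qol = qol, provenance = provenance),
            class = "vf_cohort")
}

#' @export
print.vf_cohort <- function(x, ...) {
  cat(sprintf("Visual-function cohort: %d patients, %d VA rows, %d QoL records\n",
              length(unique(x$va$patient_id)), nrow(x$va), nrow(x$qol)))
  if (inherits(x$provenance, "sim_params")) {
    cat(sprintf("  simulated (seed %d, target corr %g)\n",
                x$provenance$seed, x$provenance$target_rho_qol))
  } else {
    cat("  source:", format(x$provenance), "\n")
  }
  invisible(x)
}

#' Simulate a visual-function cohort
#'
#' Generates per-patient VA profiles over the configured distance grid and
#' quality-of-life scores (total, near-activities, distance-activities)
#' whose latent association with the all-point AoC is calibrated to
#' `params$target_rho_qol`. Deterministic for a fixed seed.
#'
#' @param params A [sim_params()] object.
#' @param n_cal Calibration cohort size passed to [calibrate_qol_slope()].
#' @return A `vf_cohort`: list with `va` (long tibble `patient_id`,
#'   `distance_cm`, `va_letters`), `qol` (tibble `patient_id`,
#'   `total_score`, `near_activities`, `distance_activities`, `complete`)
#'   and `provenance` (the parameters).
#' @export
#' @examples
#' coh <- simulate_cohort(sim_params(n_patients = 20, seed = 7))
#' coh
simulate_cohort <- function(params, n_cal = 2000L) {
  validate_sim_params(params)
  beta <- calibrate_qol_slope(params, n_cal)
  scales <- solve_ability_scales(params)

  set.seed(params$seed)
  n <- params$n_patients
  sim <- draw_va(n, params, scales)
  e_near <- rnorm(n, sd = params$qol_noise_sd)
  e_dist <- rnorm(n, sd = params$qol_noise_sd)
  q <- qol_from_latent(sim$u_n, sim$u_d, beta, e_near, e_dist)

  ids <- sprintf("P%05d", seq_len(n))
  d <- params$distances_cm
  va <- tibble::tibble(
    patient_id = rep(ids, each = length(d)),
    distance_cm = rep(d, times = n),
    va_letters = as.vector(sim$Y))
  qol <- tibble::tibble(
    patient_id = ids,
    total_score = q$total,
    near_activities = q$near,
    distance_activities = q$dist,
    complete = TRUE)
  new_cohort(va, qol, params)
}
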