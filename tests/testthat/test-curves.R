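test_that("small subsets interpolate exactly and reproduce every input VA", {
  for (seed in 1:25) {
    prof <- random_profile(seed)
    for (s in c("S4", "S5")) {
      for (ax in c("diopters", "cm")) {
        cv <- fit_vic(prof, s, x_axis = ax, warn_range = FALSE)
        expect_equal(cv$degree, length(va_subsets(s)) - 1L)
        expect_lt(max(abs(cv$fit_diagnostics$residuals)), 1e-6)
        d <- va_subsets(s)
        pred <- evaluate_vic(cv, d)
        expect_equal(pred,
                     prof$va_letters[match(d, prof$distance_cm)],
                     tolerance = 1e-6)
      }
    }
  }
})

test_that("degree selection follows the forced small-k rule", {
  expect_identical(select_degree(c(25, 33, 66, 300), c(70, 74, 80, 86)), 3L)
  expect_identical(select_degree(c(25, 33, 50, 100, 300),
                                 c(70, 74, 77, 82, 86)), 4L)
  expect_error(select_degree(c(25, 300), c(70, 86)), "at least 3")
})

test_that("LOOCV degree selection matches a brute-force refit oracle", {
  ## nine points sampled exactly from a cubic: every candidate fits
  ## perfectly, tie-break picks degree 3
  x <- 100 / nine_distances
  y <- 60 + 5 * x - 0.8 * x^2 + 0.1 * x^3
  expect_identical(select_degree(sort(x), y[order(x)]), 3L)

  for (seed in 1:10) {
    set.seed(seed + 400)
    xs <- sort(x)
    ys <- clamp_01(60 + 5 * xs + rnorm(9, sd = 3))
    picked <- select_degree(xs, ys)
    brute <- vapply(3:6, function(d) loocv_rmse_brute(xs, ys, d), numeric(1))
    expect_identical(picked, (3:6)[which.min(brute)])
    ## and the shortcut LOOCV agrees numerically with explicit refits
    hat_route <- vapply(3:6, function(d) {
      vicurve:::loocv_rmse(vicurve:::fit_poly(xs, ys, d))
    }, numeric(1))
    expect_equal(hat_route, brute, tolerance = 1e-8)
  }
})

test_that("fitted values match an independent lm oracle and Horner evaluation", {
  prof <- random_profile(11)
  cv <- fit_vic(prof, "S9", warn_range = FALSE)
  x <- sort(100 / prof$distance_cm)
  y <- prof$va_letters[order(100 / prof$distance_cm)]
  at <- c(0.5, 1.2, 2.4, 3.7)
  expect_equal(evaluate_vic(cv, 100 / at),
               lm_poly_predict(x, y, cv$degree, at), tolerance = 1e-8)
  ## naive power-sum evaluation agrees with the packaged Horner scheme
  co <- coef(cv)
  naive <- vapply(at, function(t) sum(co * t^(seq_along(co) - 1)),
                  numeric(1))
  expect_equal(evaluate_vic(cv, 100 / at), naive, tolerance = 1e-10)
})

test_that("evaluation refuses extrapolation unless allowed", {
  prof <- random_profile(2)
  cv <- fit_vic(prof, "S4", x_axis = "cm", warn_range = FALSE)
  expect_error(evaluate_vic(cv, 400), "outside the fitted domain")
  expect_silent(evaluate_vic(cv, 400, allow_extrapolation = TRUE))
  expect_equal(evaluate_vic(cv, 120),
               predict(cv, 120))
})

test_that("constant and linear profiles give closed-form AoC", {
  flat <- data.frame(distance_cm = va_subsets("S4"), va_letters = 80)
  cv_cm <- fit_vic(flat, "S4", x_axis = "cm")
  r <- aoc_indices(cv_cm)
  expect_equal(r$total, 80 * 275, tolerance = 1e-9)
  expect_equal(r$near, 80 * 25, tolerance = 1e-9)
  expect_equal(r$distance, 80 * 250, tolerance = 1e-9)
  expect_equal(evaluate_vic(cv_cm, 120), 80, tolerance = 1e-9)

  cv_dpt <- fit_vic(flat, "S4", x_axis = "diopters")
  r2 <- aoc_indices(cv_dpt)
  expect_equal(r2$total, 80 * (4 - 1 / 3), tolerance = 1e-9)
  expect_equal(r2$near, 80 * 2, tolerance = 1e-9)  # vergence 2-4 D (<= 50 cm)

  ## VA = d/5 Letters: integral of x/5 over [25, 300], split at 50
  lin <- data.frame(distance_cm = c(25, 33, 66, 300),
                    va_letters = c(25, 33, 66, 300) / 5)
  rl <- aoc_indices(fit_vic(lin, "S4", x_axis = "cm", warn_range = FALSE))
  expect_equal(rl$total, (300^2 - 25^2) / 10, tolerance = 1e-9)
  expect_equal(rl$near, (50^2 - 25^2) / 10, tolerance = 1e-9)
})

test_that("polynomial AoC matches adaptive quadrature and conserves area", {
  for (seed in 1:30) {
    prof <- random_profile(seed + 100)
    for (s in c("S4", "S6", "S9")) {
      for (ax in c("diopters", "cm")) {
        cv <- fit_vic(prof, s, x_axis = ax, warn_range = FALSE)
        r <- aoc_indices(cv)
        expect_equal(r$near + r$distance, r$total,
                     tolerance = 1e-9)
        expect_equal(r$total,
                     quadrature_area(cv, cv$domain[1], cv$domain[2]),
                     tolerance = 1e-8)
      }
    }
  }
})

test_that("adding c Letters shifts total AoC by exactly c times the domain width", {
  prof <- random_profile(5, noise_sd = 1)
  for (ax in c("diopters", "cm")) {
    cv0 <- fit_vic(prof, "S9", x_axis = ax, warn_range = FALSE)
    prof2 <- prof
    prof2$va_letters <- prof2$va_letters + 7
    cv7 <- fit_vic(prof2, "S9", x_axis = ax, warn_range = FALSE)
    width <- diff(cv0$domain)
    expect_equal(aoc_indices(cv7)$total - aoc_indices(cv0)$total,
                 7 * width, tolerance = 1e-9 * 7 * width)
  }
})

test_that("DCT areas follow hand trapezoid formulas", {
  rect <- data.frame(distance_cm = c(25, 300), va_letters = c(80, 80))
  expect_equal(dct_aoc(rect, x_axis = "cm")$total, 22000, tolerance = 1e-12)

  ramp <- data.frame(distance_cm = c(25, 300), va_letters = c(60, 100))
  r <- dct_aoc(ramp, split_cm = 50, x_axis = "cm")
  va_at_50 <- 60 + 40 * 25 / 275
  expect_equal(r$total, (60 + 100) / 2 * 275, tolerance = 1e-12)
  expect_equal(r$near, (60 + va_at_50) / 2 * 25, tolerance = 1e-12)
  expect_equal(r$distance, r$total - r$near, tolerance = 1e-12)
})

test_that("DCT matches a dense composite-trapezoid oracle on both axes", {
  for (seed in 1:10) {
    prof <- random_profile(seed + 200)
    for (ax in c("diopters", "cm")) {
      r <- dct_aoc(prof, x_axis = ax)
      x <- sort(if (ax == "cm") prof$distance_cm else 100 / prof$distance_cm)
      y <- prof$va_letters[order(if (ax == "cm") prof$distance_cm
                                 else 100 / prof$distance_cm)]
      expect_equal(r$total, dense_trapz_area(x, y, min(x), max(x)),
                   tolerance = 1e-6)
      expect_equal(r$near + r$distance, r$total, tolerance = 1e-12)
    }
  }
})

test_that("a linear profile gives identical polynomial and DCT areas", {
  lin <- data.frame(distance_cm = nine_distances,
                    va_letters = 50 + nine_distances / 10)
  cv <- fit_vic(lin, "S9", x_axis = "cm", warn_range = FALSE)
  expect_equal(aoc_indices(cv)$total, dct_aoc(lin, x_axis = "cm")$total,
               tolerance = 1e-9)
})

test_that("constant profiles yield identical AoC across subsets and methods", {
  flat <- data.frame(distance_cm = nine_distances, va_letters = 73)
  totals <- c(
    vapply(c("S4", "S5", "S6", "S9"), function(s) {
      aoc_indices(fit_vic(flat, s))$total
    }, numeric(1)),
    DCT = dct_aoc(flat)$total)
  expect_equal(unname(totals), rep(73 * (4 - 1 / 3), 5), tolerance = 1e-9)
})

test_that("fit and split preconditions produce named errors", {
  prof <- random_profile(3)
  short <- prof[prof$distance_cm != 66, ]
  expect_error(fit_vic(short, "S4"), "66")
  expect_error(fit_vic(prof, "DCT"), "piecewise")
  cv <- fit_vic(prof, "S4", warn_range = FALSE)
  expect_error(aoc_indices(cv, split_cm = 20), "outside the open")
  expect_error(dct_aoc(prof, split_cm = 301), "outside the open")
  bad <- prof
  bad$va_letters[1] <- 105
  expect_error(fit_vic(bad, "S4"), "\\[0, 100\\]")
})

test_that("a wildly oscillating fit triggers the range diagnostic", {
  wiggle <- data.frame(distance_cm = c(25, 33, 66, 300),
                       va_letters = c(1, 99, 1, 99))
  expect_warning(fit_vic(wiggle, "S4", x_axis = "cm"), "exits \\[0, 100\\]")
})

test_that("cohort-level AoC table agrees with per-patient fits", {
  set.seed(42)
  ids <- sprintf("Q%02d", 1:6)
  va <- do.call(rbind, lapply(seq_along(ids), function(i) {
    p <- random_profile(i + 300)
    data.frame(patient_id = ids[i], p)
  }))
  coh <- manual_cohort(va, flat_qol(ids))
  for (ax in c("diopters", "cm")) {
    tab <- aoc_table(coh, x_axis = ax)
    for (i in seq_along(ids)) {
      prof <- va[va$patient_id == ids[i], c("distance_cm", "va_letters")]
      for (s in c("S4", "S5", "S6", "S9")) {
        r <- aoc_indices(fit_vic(prof, s, x_axis = ax, warn_range = FALSE))
        expect_equal(tab[[paste0(tolower(s), "_total")]][i], r$total,
                     tolerance = 1e-9)
        expect_equal(tab[[paste0(tolower(s), "_near")]][i], r$near,
                     tolerance = 1e-9)
      }
      rd <- dct_aoc(prof, x_axis = ax)
      expect_equal(tab$dct_total[i], rd$total, tolerance = 1e-9)
      expect_equal(tab$dct_near[i], rd$near, tolerance = 1e-9)
    }
  }
  ## tidy layout: 5 subsets per patient
  long <- aoc_table(coh, tidy = TRUE)
  expect_identical(nrow(long), 30L)
  expect_setequal(unique(long$subset), c("S4", "S5", "S6", "S9", "DCT"))
})
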