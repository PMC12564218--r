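## Statistical battery: Shapiro-Wilk-driven method selection, correlations
## with Fisher-z confidence intervals, lowest-quartile group comparisons,
## and the a priori sample-size calculation.

#' Shapiro-Wilk normality p-value
#'
#' Thin wrapper around `stats::shapiro.test()` with the preconditions used
#' throughout the battery; p <= 0.05 flags a non-normal distribution.
#'
#' @param values Numeric vector, 3 <= n <= 5000, non-constant.
#' @return The Shapiro-Wilk p-value.
#' @export
normality_p <- function(values) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 3 || n > 5000) {
    stopf("Shapiro-Wilk requires 3 <= n <= 5000, got n = %d", n)
  }
  if (diff(range(values)) == 0) {
    stopf("normality test undefined for constant input")
  }
  shapiro.test(values)$p.value
}

has_outlier <- function(v) {
  s <- mad(v)  # scaled MAD (consistent with a normal SD)
  if (s == 0) return(any(v != median(v)))
  any(abs(v - median(v)) > 3 * s)
}

#' Choose the correlation method for a variable pair
#'
#' Pearson when both variables pass the Shapiro-Wilk normality test at
#' `alpha` and neither contains an outlier (absolute deviation from the
#' median beyond 3 scaled MADs); Spearman otherwise. Deterministic.
#'
#' @param x,y Numeric vectors of equal length >= 4.
#' @param alpha Normality significance level (default 0.05).
#' @return `"pearson"` or `"spearman"`.
#' @export
choose_method <- function(x, y, alpha = 0.05) {
  if (length(x) != length(y)) stopf("x and y lengths differ")
  if (length(x) < 4) stopf("need at least 4 paired observations")
  normal <- normality_p(x) > alpha && normality_p(y) > alpha
  if (normal && !has_outlier(x) && !has_outlier(y)) "pearson" else "spearman"
}

#' Correlation with Fisher-z confidence interval
#'
#' Computes the coefficient and two-sided p-value by the requested method
#' and a 95% confidence interval via the Fisher z-transform; the Spearman
#' interval uses the standard variance inflation 1.06/(n-3).
#'
#' @param x,y Numeric vectors of equal length >= 4.
#' @param method `"pearson"` or `"spearman"`.
#' @param conf_level Confidence level (default 0.95).
#' @return One-row tibble: `method`, `r`, `ci_low`, `ci_high`, `p_value`,
#'   `n`.
#' @export
#' @examples
#' correlate(1:10, (1:10)^2, "spearman") # rho = 1
correlate <- function(x, y, method = c("pearson", "spearman"),
                      conf_level = 0.95) {
  method <- match.arg(method)
  if (length(x) != length(y)) stopf("x and y lengths differ")
  ok <- !(is.na(x) | is.na(y))
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4) stopf("need at least 4 paired observations")
  if (sd(x) == 0 || sd(y) == 0) {
    stopf("correlation undefined: zero variance in one variable")
  }
  ct <- suppressWarnings(
    cor.test(x, y, method = method, exact = FALSE))
  r <- unname(ct$estimate)
  z_se <- if (method == "pearson") 1 / sqrt(n - 3) else
    sqrt(1.06 / (n - 3))
  zc <- qnorm(1 - (1 - conf_level) / 2)
  ci <- tanh(atanh(clamp(r, -1, 1)) + c(-1, 1) * zc * z_se)
  tibble::tibble(method = method, r = r, ci_low = ci[1], ci_high = ci[2],
                 p_value = ct$p.value, n = n)
}

p_stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))
}

#' Required sample size for a correlation test
#'
#' Smallest n achieving the requested power for detecting a correlation r,
#' under the Fisher z approximation:
#' n = ceil(((z_(1-alpha/tails) + z_power) / atanh(r))^2 + 3).
#'
#' @param r Expected correlation, 0 < |r| < 1.
#' @param alpha Significance level.
#' @param power Target power.
#' @param tails 1 or 2.
#' @return Integer sample size.
#' @export
#' @examples
#' required_n(0.26)  # the design's expected effect size
required_n <- function(r, alpha = 0.05, power = 0.80, tails = 2) {
  if (!is.finite(r) || r == 0 || abs(r) >= 1) {
    stopf("r must satisfy 0 < |r| < 1")
  }
  if (alpha <= 0 || alpha >= 1 || power <= 0 || power >= 1) {
    stopf("alpha and power must lie in (0, 1)")
  }
  if (!tails %in% c(1, 2)) stopf("tails must be 1 or 2")
  z <- qnorm(1 - alpha / tails) + qnorm(power)
  as.integer(ceiling((z / atanh(abs(r)))^2 + 3))
}

#' Correlation battery between AoC indices and quality-of-life scores
#'
#' Reproduces the full index/score pairing grid: total AoC (S4, S5, S6, S9,
#' DCT) against the total score; near AoC (same five, plus the single VA at
#' 40 cm) against the near-activities score; distance AoC (same five, plus
#' the single VA at 300 cm) against the distance-activities score — 17
#' rows. Each pair's method is selected by [choose_method()] and reported
#' with its Fisher-z confidence interval and significance stars.
#'
#' @param cohort A complete-case `vf_cohort`.
#' @param aoc Optional precomputed wide [aoc_table()]; computed if `NULL`.
#' @param alpha Normality level for method selection.
#' @param p_adjust `"none"` (default, matching the study's reporting) or
#'   `"holm"`, which adds a `p_adjusted` column.
#' @return Tibble with columns `index_group`, `index`, `score_name`,
#'   `method`, `r`, `ci_low`, `ci_high`, `p_value`, `stars`, `n`.
#' @export
correlation_battery <- function(cohort, aoc = NULL, alpha = 0.05,
                                p_adjust = c("none", "holm")) {
  p_adjust <- match.arg(p_adjust)
  stopifnot(inherits(cohort, "vf_cohort"))
  if (is.null(aoc)) aoc <- aoc_table(cohort)
  qol <- cohort$qol[match(aoc$patient_id, cohort$qol$patient_id), ]
  if (anyNA(qol$patient_id)) stopf("QoL records missing for some patients")

  single_va <- function(d) {
    v <- cohort$va[cohort$va$distance_cm == d, ]
    out <- v$va_letters[match(aoc$patient_id, v$patient_id)]
    if (anyNA(out)) stopf("single-VA row needs measurements at %g cm", d)
    out
  }
  subsets <- c("s4", "s5", "s6", "s9", "dct")
  labels <- c(s4 = "4", s5 = "5", s6 = "6", s9 = "9", dct = "DCT")

  one <- function(group, index, x, score_name, y) {
    m <- choose_method(x, y, alpha)
    res <- correlate(x, y, m)
    tibble::tibble(index_group = group, index = index,
                   score_name = score_name, res)
  }
  rows <- list()
  for (s in subsets) {
    rows[[length(rows) + 1]] <- one("Total AoC", labels[[s]],
                                    aoc[[paste0(s, "_total")]],
                                    "total_score", qol$total_score)
  }
  for (s in subsets) {
    rows[[length(rows) + 1]] <- one("AoCN", labels[[s]],
                                    aoc[[paste0(s, "_near")]],
                                    "near_activities", qol$near_activities)
  }
  rows[[length(rows) + 1]] <- one("AoCN", "1 (40 cm)", single_va(40),
                                  "near_activities", qol$near_activities)
  for (s in subsets) {
    rows[[length(rows) + 1]] <- one("AoCD", labels[[s]],
                                    aoc[[paste0(s, "_distance")]],
                                    "distance_activities",
                                    qol$distance_activities)
  }
  rows[[length(rows) + 1]] <- one("AoCD", "1 (300 cm)", single_va(300),
                                  "distance_activities",
                                  qol$distance_activities)
  out <- do.call(rbind, rows)
  out$stars <- p_stars(out$p_value)
  if (p_adjust == "holm") {
    out$p_adjusted <- stats::p.adjust(out$p_value, method = "holm")
  }
  out
}

group_test_continuous <- function(low, rest, alpha = 0.05) {
  if (diff(range(c(low, rest))) == 0) {
    return(list(test = "none", p = NA_real_, note = "constant variable"))
  }
  normal <- function(v) {
    if (length(v) < 3 || diff(range(v)) == 0) return(FALSE)
    normality_p(v) > alpha
  }
  if (normal(low) && normal(rest)) {
    list(test = "t_test",
         p = t.test(low, rest, var.equal = TRUE)$p.value, note = "")
  } else {
    list(test = "mann_whitney",
         p = suppressWarnings(wilcox.test(low, rest)$p.value), note = "")
  }
}

group_test_categorical <- function(low, rest) {
  tab <- table(group = rep(c("lowest", "rest"), c(length(low), length(rest))),
               value = c(as.character(low), as.character(rest)))
  if (ncol(tab) < 2) {
    return(list(test = "none", p = NA_real_, note = "constant variable"))
  }
  expected <- suppressWarnings(chisq.test(tab)$expected)
  if (any(expected < 5)) {
    list(test = "fisher_exact", p = fisher.test(tab)$p.value, note = "")
  } else {
    list(test = "chi_square",
         p = suppressWarnings(chisq.test(tab)$p.value), note = "")
  }
}

#' Compare the lowest quality-of-life quartile with the remaining cohort
#'
#' Splits patients at the 25th percentile of the chosen score (ties at the
#' quantile fall into the lowest group) and compares each AoC index — and
#' any extra covariates supplied — between groups: Student's t-test when
#' both groups pass the normality check, Mann-Whitney otherwise; chi-square
#' for categorical covariates, or Fisher's exact test when any expected
#' cell count is below 5.
#'
#' @param cohort A complete-case `vf_cohort` with at least 8 patients.
#' @param aoc Optional precomputed wide [aoc_table()].
#' @param score Which score defines the quartile: `"total"`, `"near"` or
#'   `"distance"`.
#' @param covariates Optional data frame keyed by `patient_id` with extra
#'   numeric (continuous) or character/factor (categorical) columns.
#' @param alpha Normality level.
#' @return Tibble with one row per variable: group sizes, mean +/- SD per
#'   group (continuous), `test_used`, `p_value`, `stars`, `note`.
#' @export
quartile_compare <- function(cohort, aoc = NULL,
                             score = c("total", "near", "distance"),
                             covariates = NULL, alpha = 0.05) {
  score <- match.arg(score)
  stopifnot(inherits(cohort, "vf_cohort"))
  if (is.null(aoc)) aoc <- aoc_table(cohort)
  qol <- cohort$qol[match(aoc$patient_id, cohort$qol$patient_id), ]
  n <- nrow(aoc)
  if (n < 8) stopf("quartile comparison needs at least 8 complete cases")
  sc <- switch(score, total = qol$total_score,
               near = qol$near_activities,
               distance = qol$distance_activities)
  q1 <- quantile(sc, 0.25, names = FALSE)
  lowest <- sc <= q1
  if (sum(lowest) < 3 || sum(!lowest) < 3) {
    stopf("a quartile group has fewer than 3 members")
  }

  vars <- aoc[, setdiff(names(aoc), "patient_id"), drop = FALSE]
  if (!is.null(covariates)) {
    m <- match(aoc$patient_id, covariates$patient_id)
    if (anyNA(m)) stopf("covariates missing for some patients")
    extra <- covariates[m, setdiff(names(covariates), "patient_id"),
                        drop = FALSE]
    vars <- cbind(vars, extra)
  }

  rows <- lapply(names(vars), function(nm) {
    v <- vars[[nm]]
    lo <- v[lowest]; hi <- v[!lowest]
    if (is.numeric(v)) {
      res <- group_test_continuous(lo, hi, alpha)
      tibble::tibble(variable = nm, type = "continuous",
                     n_lowest = sum(lowest), n_rest = sum(!lowest),
                     lowest_mean = mean(lo), lowest_sd = sd(lo),
                     rest_mean = mean(hi), rest_sd = sd(hi),
                     test_used = res$test, p_value = res$p, note = res$note)
    } else {
      res <- group_test_categorical(lo, hi)
      tibble::tibble(variable = nm, type = "categorical",
                     n_lowest = sum(lowest), n_rest = sum(!lowest),
                     lowest_mean = NA_real_, lowest_sd = NA_real_,
                     rest_mean = NA_real_, rest_sd = NA_real_,
                     test_used = res$test, p_value = res$p, note = res$note)
    }
  })
  out <- do.call(rbind, rows)
  out$stars <- ifelse(is.na(out$p_value), "", p_stars(out$p_value))
  out
}
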