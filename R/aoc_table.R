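## Cohort-level AoC computation. All patients share one distance grid, so
## each subset's design matrix, QR factorisation and hat diagonal are
## computed once and reused across the whole cohort; degree selection is the
## same rule as select_degree(), applied per patient.

## Y: matrix of VA values, rows = distances of x, cols = patients.
## Returns list(total, near, distance) numeric vectors over patients.
aoc_poly_batch <- function(x, Y, split_x, near_is_lower) {
  k <- length(x)
  scale <- max(x)
  X_of <- function(d) poly_design(x, d, scale)
  solve_deg <- function(d) {
    qx <- qr(X_of(d))
    coefs <- qr.coef(qx, Y)                      # (d+1) x n
    Q <- qr.Q(qx)[, seq_len(qx$rank), drop = FALSE]
    list(coefs = coefs, hat = rowSums(Q^2))
  }
  if (k <= 5) {
    degrees <- rep.int(k - 1L, ncol(Y))
    fits <- list(solve_deg(k - 1L))
    names(fits) <- as.character(k - 1L)
  } else {
    cands <- 3:min(6L, k - 2L)
    fits <- lapply(cands, solve_deg)
    names(fits) <- as.character(cands)
    rmse <- vapply(seq_along(cands), function(i) {
      f <- fits[[i]]
      R <- (Y - X_of(cands[i]) %*% f$coefs) / (1 - f$hat)
      sqrt(colMeans(R^2))
    }, numeric(ncol(Y)))
    rmse <- if (is.null(dim(rmse))) matrix(rmse, ncol = 1) else t(rmse)
    ## rmse is now cands x n
    best <- apply(rmse, 2, min)
    pick <- apply(rmse <= rep(best, each = nrow(rmse)) + 1e-6, 2, which.max)
    degrees <- cands[pick]
  }
  area_w <- function(d, lo, hi) {
    j <- seq_len(d + 1)
    scale * ((hi / scale)^j - (lo / scale)^j) / j
  }
  total <- near <- numeric(ncol(Y))
  lo <- min(x); hi <- max(x)
  for (d in unique(degrees)) {
    cols <- degrees == d
    cf <- fits[[as.character(d)]]$coefs[, cols, drop = FALSE]
    total[cols] <- drop(area_w(d, lo, hi) %*% cf)
    near[cols] <- if (near_is_lower) drop(area_w(d, lo, split_x) %*% cf)
                  else drop(area_w(d, split_x, hi) %*% cf)
  }
  list(total = total, near = near, distance = total - near,
       degrees = degrees)
}

## Exact trapezoid weights w such that w %*% y gives the area of the
## piecewise-linear interpolant over [lo, hi] (lo/hi inside [min x, max x]).
trapz_weights <- function(x, lo, hi) {
  n <- length(x)
  w <- numeric(n)
  if (hi <= lo) return(w)
  for (i in seq_len(n - 1)) {
    a <- x[i]; b <- x[i + 1]
    l <- max(a, lo); u <- min(b, hi)
    if (u <= l) next
    h <- b - a
    ## integral over [l,u] of linear interp = int of y_i*(b-t)/h + y_{i+1}*(t-a)/h
    w[i]     <- w[i]     + ((b - l)^2 - (b - u)^2) / (2 * h)
    w[i + 1] <- w[i + 1] + ((u - a)^2 - (l - a)^2) / (2 * h)
  }
  w
}

aoc_dct_batch <- function(x, Y, split_x, near_is_lower) {
  lo <- min(x); hi <- max(x)
  w_low <- trapz_weights(x, lo, split_x)
  w_up <- trapz_weights(x, split_x, hi)
  lower <- unname(drop(w_low %*% Y))
  upper <- unname(drop(w_up %*% Y))
  near <- if (near_is_lower) lower else upper
  distance <- if (near_is_lower) upper else lower
  list(total = near + distance, near = near, distance = distance)
}

## long VA tibble -> distances x patients matrix (errors if grid incomplete)
va_matrix <- function(va, distances) {
  ids <- unique(va$patient_id)
  key <- split(seq_len(nrow(va)), va$patient_id)
  Y <- matrix(NA_real_, nrow = length(distances), ncol = length(ids),
              dimnames = list(NULL, ids))
  for (id in ids) {
    rows <- key[[id]]
    m <- match(distances, va$distance_cm[rows])
    if (anyNA(m)) {
      stopf("patient %s: missing distance %g cm", id,
            distances[which(is.na(m))[1]])
    }
    Y[, id] <- va$va_letters[rows][m]
  }
  Y[, ids, drop = FALSE]
}

#' Per-patient AoC index table
#'
#' Computes, for every patient of a cohort, total/near/distance AoC for the
#' polynomial visual curve on the S4, S5, S6 and S9 distance subsets and for
#' the piecewise-linear DCT comparator — 15 indices per patient.
#'
#' @param cohort A `vf_cohort` (see [simulate_cohort()]) or a long VA data
#'   frame with columns `patient_id`, `distance_cm`, `va_letters`. Every
#'   patient must have all nine standard distances.
#' @param split_cm Near/distance boundary (cm), default 50.
#' @param x_axis `"diopters"` (default, x = 100/d) or `"cm"`; areas are in
#'   Letters·D or Letters·cm respectively.
#' @param tidy If `TRUE`, return the long form
#'   (`patient_id, subset, method, aoc_total, aoc_near, aoc_distance`)
#'   instead of the wide 15-column form.
#' @return A tibble, one row per patient (wide) with columns
#'   `s4_total, s4_near, s4_distance, ..., dct_distance`, or the long form.
#' @export
aoc_table <- function(cohort, split_cm = 50, x_axis = c("diopters", "cm"),
                      tidy = FALSE) {
  x_axis <- match.arg(x_axis)
  va <- if (inherits(cohort, "vf_cohort")) cohort$va else cohort
  if (!all(c("patient_id", "distance_cm", "va_letters") %in% names(va))) {
    stopf("need columns patient_id, distance_cm, va_letters")
  }
  Y9 <- va_matrix(va, .DISTANCES_9)
  ids <- colnames(Y9)
  x9 <- axis_x(.DISTANCES_9, x_axis)
  split_x <- axis_x(split_cm, x_axis)
  near_is_lower <- x_axis == "cm"
  ord9 <- order(x9)

  out <- list(patient_id = ids)
  for (s in c("S4", "S5", "S6", "S9")) {
    rows <- match(.SUBSETS[[s]], .DISTANCES_9)
    xs <- axis_x(.DISTANCES_9[rows], x_axis)
    o <- order(xs)
    r <- aoc_poly_batch(xs[o], Y9[rows, , drop = FALSE][o, , drop = FALSE],
                        split_x, near_is_lower)
    nm <- tolower(s)
    out[[paste0(nm, "_total")]] <- r$total
    out[[paste0(nm, "_near")]] <- r$near
    out[[paste0(nm, "_distance")]] <- r$distance
  }
  rd <- aoc_dct_batch(x9[ord9], Y9[ord9, , drop = FALSE], split_x,
                      near_is_lower)
  out$dct_total <- rd$total
  out$dct_near <- rd$near
  out$dct_distance <- rd$distance
  wide <- tibble::as_tibble(out)
  if (tidy) aoc_long(wide) else wide
}
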