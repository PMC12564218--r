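## NEI-VFQ-25 scoring. The standard interval recode (each item mapped
## linearly to 0-100, 100 = best visual function) and the 12-subscale item
## membership are shipped as plain-text tables under extdata; responses
## coded "stopped doing this for other (non-vision) reasons" recode to
## missing. The composite (total) score is the unweighted mean of the 11
## vision-targeted subscales — the general-health item is excluded.

vfq_tables <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      recode <- read.csv(system.file("extdata", "nei_vfq25_recode.csv",
                                     package = "vicurve"),
                         colClasses = c("character", "integer", "numeric"))
      subscales <- read.csv(system.file("extdata", "nei_vfq25_subscales.csv",
                                        package = "vicurve"),
                            colClasses = c("character", "character"))
      cache <<- list(recode = recode, subscales = subscales)
    }
    cache
  }
})

vfq_item_ids <- function() unique(vfq_tables()$recode$item_id)

#' Score one NEI-VFQ-25 questionnaire
#'
#' Recode each item to 0--100 (100 = best visual function) using the
#' standard interval scoring shipped with the package, average non-missing
#' items within each subscale, and form the composite total as the
#' unweighted mean of the vision-targeted subscales (the general-health
#' item is excluded). A record is `complete` only when no near-activities
#' or distance-activities item is missing.
#'
#' @param responses Named numeric vector or two-column data frame
#'   (`item_id`, `response`) of ordinal responses for one patient; `NA`
#'   marks a skipped item.
#' @param patient_id Optional identifier carried into the result.
#' @return One-row tibble: `patient_id`, `total_score`, `near_activities`,
#'   `distance_activities`, `complete`.
#' @export
#' @examples
#' best <- setNames(rep(1, 26), vicurve:::vfq_item_ids())
#' best[c("17", "18", "19", "20", "21", "22", "23", "24", "25")] <- 5
#' score_nei_vfq(best)  # total 100
score_nei_vfq <- function(responses, patient_id = NA_character_) {
  tabs <- vfq_tables()
  if (is.data.frame(responses)) {
    resp <- setNames(responses$response, as.character(responses$item_id))
  } else {
    resp <- responses
  }
  if (is.null(names(resp)) || any(names(resp) == "")) {
    stopf("responses must be named by item id")
  }
  ids <- names(resp)
  unknown <- setdiff(ids, vfq_item_ids())
  if (length(unknown)) {
    stopf("unknown NEI-VFQ-25 item id(s): %s", paste(unknown, collapse = ", "))
  }
  if (anyDuplicated(ids)) stopf("duplicated item responses")

  recoded <- rep(NA_real_, length(ids))
  names(recoded) <- ids
  for (i in seq_along(ids)) {
    r <- resp[[i]]
    if (is.na(r)) next
    hit <- tabs$recode$item_id == ids[i] & tabs$recode$response == r
    if (!any(hit)) {
      stopf("item %s: response %s outside the item's scale", ids[i],
            format(r))
    }
    recoded[i] <- tabs$recode$score[hit]
  }

  sub_score <- function(subscale) {
    items <- tabs$subscales$item_id[tabs$subscales$subscale == subscale]
    vals <- recoded[intersect(items, ids)]
    if (!length(vals) || all(is.na(vals))) return(NA_real_)
    mean(vals, na.rm = TRUE)
  }
  subs <- unique(tabs$subscales$subscale)
  scores <- vapply(subs, sub_score, numeric(1))
  vision <- scores[setdiff(subs, "general_health")]
  total <- if (all(is.na(vision))) NA_real_ else mean(vision, na.rm = TRUE)

  act_items <- tabs$subscales$item_id[
    tabs$subscales$subscale %in% c("near_activities", "distance_activities")]
  complete <- all(act_items %in% ids) && !anyNA(recoded[act_items])

  tibble::tibble(patient_id = patient_id,
                 total_score = total,
                 near_activities = scores[["near_activities"]],
                 distance_activities = scores[["distance_activities"]],
                 complete = complete)
}

#' Score a long table of NEI-VFQ-25 item responses
#'
#' @param items Data frame with columns `patient_id`, `item_id`, `response`.
#' @return Tibble of [score_nei_vfq()] rows, one per patient.
#' @export
score_nei_vfq_table <- function(items) {
  if (!all(c("patient_id", "item_id", "response") %in% names(items))) {
    stopf("need columns patient_id, item_id, response")
  }
  by_pat <- split(items, items$patient_id)
  out <- lapply(names(by_pat), function(id) {
    score_nei_vfq(by_pat[[id]][, c("item_id", "response")], patient_id = id)
  })
  do.call(rbind, out)
}

#' Restrict a cohort to complete cases
#'
#' Keeps patients with a fully completed questionnaire (`complete = TRUE`)
#' and a VA profile covering every configured test distance, mirroring the
#' complete-case inclusion rule of the study design. Counts and reasons for
#' removal are reported via `message()`.
#'
#' @param cohort A `vf_cohort`.
#' @param distances Required distance grid; defaults to the cohort's
#'   provenance grid or the standard nine distances.
#' @return The filtered `vf_cohort`.
#' @export
filter_complete <- function(cohort, distances = NULL) {
  stopifnot(inherits(cohort, "vf_cohort"))
  if (is.null(distances)) {
    distances <- if (inherits(cohort$provenance, "sim_params")) {
      cohort$provenance$distances_cm
    } else {
      .DISTANCES_9
    }
  }
  qol_ok <- cohort$qol$patient_id[!is.na(cohort$qol$complete) &
                                    cohort$qol$complete]
  va_ids <- unique(cohort$va$patient_id)
  has_grid <- vapply(va_ids, function(id) {
    all(distances %in% cohort$va$distance_cm[cohort$va$patient_id == id])
  }, logical(1))
  va_ok <- va_ids[has_grid]

  keep <- intersect(qol_ok, va_ok)
  n_incomplete_q <- sum(!cohort$qol$patient_id %in% qol_ok)
  n_missing_d <- sum(!va_ids %in% va_ok)
  if (n_incomplete_q) {
    message(n_incomplete_q,
            " patient(s) removed: incomplete questionnaire")
  }
  if (n_missing_d) {
    message(n_missing_d, " patient(s) removed: missing distance")
  }
  if (!length(keep)) stopf("no complete cases remain after filtering")

  new_cohort(
    va = cohort$va[cohort$va$patient_id %in% keep, , drop = FALSE],
    qol = cohort$qol[cohort$qol$patient_id %in% keep, , drop = FALSE],
    provenance = cohort$provenance)
}
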