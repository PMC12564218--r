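## CSV readers/writers, run configuration and end-to-end orchestration.
## The tidy CSV dialect is fixed: comma separated, header row, UTF-8,
## period decimal separator.

#' Read a long visual-acuity CSV
#'
#' Expects exactly the columns `patient_id,distance_cm,va_letters`.
#' Malformed or out-of-range rows and duplicated (patient, distance) pairs
#' are rejected with their file line numbers (header = line 1).
#'
#' @param path CSV path.
#' @param distances Optional allowed distance grid; rows at other distances
#'   are rejected.
#' @return Tibble `patient_id`, `distance_cm`, `va_letters`.
#' @export
read_va_csv <- function(path, distances = NULL) {
  df <- read.csv(path, colClasses = "character", fileEncoding = "UTF-8")
  need <- c("patient_id", "distance_cm", "va_letters")
  if (!identical(names(df), need)) {
    stopf("%s: expected header %s", path, paste(need, collapse = ","))
  }
  line <- seq_len(nrow(df)) + 1L
  d <- suppressWarnings(as.numeric(df$distance_cm))
  v <- suppressWarnings(as.numeric(df$va_letters))
  bad <- is.na(d) | is.na(v) | df$patient_id == ""
  if (any(bad)) {
    stopf("%s: malformed row(s) at line(s) %s", path,
          paste(line[bad], collapse = ", "))
  }
  if (any(d <= 0)) {
    stopf("%s: non-positive distance at line(s) %s", path,
          paste(line[d <= 0], collapse = ", "))
  }
  out_of_range <- v < 0 | v > 100
  if (any(out_of_range)) {
    stopf("%s: VA outside [0, 100] Letters at line(s) %s", path,
          paste(line[out_of_range], collapse = ", "))
  }
  dup <- duplicated(paste(df$patient_id, d))
  if (any(dup)) {
    stopf("%s: duplicated (patient, distance) pair at line(s) %s", path,
          paste(line[dup], collapse = ", "))
  }
  if (!is.null(distances)) {
    off_grid <- !d %in% distances
    if (any(off_grid)) {
      stopf("%s: distance not on the configured grid at line(s) %s", path,
            paste(line[off_grid], collapse = ", "))
    }
  }
  tibble::tibble(patient_id = df$patient_id, distance_cm = d, va_letters = v)
}

#' Read a precomputed quality-of-life score CSV
#'
#' Columns: `patient_id,total_score,near_activities,distance_activities`
#' with an optional logical `complete` column (assumed TRUE when absent).
#'
#' @param path CSV path.
#' @return Tibble in the cohort QoL layout.
#' @export
read_qol_csv <- function(path) {
  df <- read.csv(path, fileEncoding = "UTF-8")
  need <- c("patient_id", "total_score", "near_activities",
            "distance_activities")
  if (!all(need %in% names(df))) {
    stopf("%s: expected columns %s", path, paste(need, collapse = ","))
  }
  for (col in need[-1]) {
    v <- df[[col]]
    if (!is.numeric(v) || anyNA(v) || any(v < 0 | v > 100)) {
      stopf("%s: column %s must be numeric in [0, 100]", path, col)
    }
  }
  if (anyDuplicated(df$patient_id)) {
    stopf("%s: duplicated patient_id", path)
  }
  tibble::tibble(patient_id = as.character(df$patient_id),
                 total_score = df$total_score,
                 near_activities = df$near_activities,
                 distance_activities = df$distance_activities,
                 complete = if ("complete" %in% names(df))
                   as.logical(df$complete) else TRUE)
}

#' Read a long NEI-VFQ-25 item-response CSV
#'
#' Columns: `patient_id,item_id,response` (NA responses allowed).
#'
#' @param path CSV path.
#' @return Tibble suitable for [score_nei_vfq_table()].
#' @export
read_items_csv <- function(path) {
  df <- read.csv(path, colClasses = c("character", "character", "numeric"),
                 fileEncoding = "UTF-8")
  need <- c("patient_id", "item_id", "response")
  if (!identical(names(df), need)) {
    stopf("%s: expected header %s", path, paste(need, collapse = ","))
  }
  tibble::as_tibble(df)
}

write_csv_strict <- function(df, path) {
  write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8",
            quote = FALSE)
  path
}

#' Pipeline run configuration
#'
#' Exactly one input source must be given: simulation parameters, or file
#' paths (VA plus either precomputed scores or item responses).
#'
#' @param sim A [sim_params()] object, or `NULL`.
#' @param va_path,qol_path,items_path Input CSV paths (see the readers).
#' @param split_cm Near/distance boundary, strictly inside (25, 300).
#' @param x_axis `"diopters"` (default) or `"cm"`.
#' @param alpha Significance/normality level.
#' @param out_dir Output directory for [run_pipeline()].
#' @param seed Seed recorded in the manifest (and applied to `sim`).
#' @param plots Also write scatterplot PNGs (off by default; the numeric
#'   CSVs are the contract surface).
#' @return A validated `run_config` list.
#' @export
run_config <- function(sim = NULL, va_path = NULL, qol_path = NULL,
                       items_path = NULL, split_cm = 50,
                       x_axis = c("diopters", "cm"), alpha = 0.05,
                       out_dir = NULL, seed = 1L, plots = FALSE) {
  x_axis <- match.arg(x_axis)
  has_sim <- !is.null(sim)
  has_files <- !is.null(va_path)
  if (has_sim == has_files) {
    stopf("exactly one of `sim` and `va_path` must be supplied")
  }
  if (has_files && is.null(qol_path) && is.null(items_path)) {
    stopf("file input needs `qol_path` (scores) or `items_path` (responses)")
  }
  if (!is.null(qol_path) && !is.null(items_path)) {
    stopf("supply only one of `qol_path` and `items_path`")
  }
  if (!(split_cm > 25 && split_cm < 300)) {
    stopf("split_cm must lie strictly inside (25, 300)")
  }
  if (has_sim) {
    stopifnot(inherits(sim, "sim_params"))
    sim$seed <- as.integer(seed)
  }
  structure(list(sim = sim, va_path = va_path, qol_path = qol_path,
                 items_path = items_path, split_cm = split_cm,
                 x_axis = x_axis, alpha = alpha, out_dir = out_dir,
                 seed = as.integer(seed), plots = isTRUE(plots)),
            class = "run_config")
}

#' Read a YAML run configuration
#'
#' The file mirrors [run_config()] field-for-field; a `sim:` block mirrors
#' [sim_params()].
#'
#' @param path YAML path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim <- if (!is.null(y$sim)) do.call(sim_params, y$sim) else NULL
  args <- y[setdiff(names(y), "sim")]
  do.call(run_config, c(list(sim = sim), args))
}

#' Scatterplots of quality-of-life score against AoC
#'
#' One panel per component: total score vs total AoC, near-activities vs
#' AoCN, distance-activities vs AoCD, for one subset's indices.
#'
#' @param cohort A complete-case `vf_cohort`.
#' @param aoc Optional precomputed wide [aoc_table()].
#' @param subset Which subset's indices to plot (default `"S9"`).
#' @return Named list of three ggplot objects (`total`, `near`,
#'   `distance`).
#' @export
plot_score_vs_aoc <- function(cohort, aoc = NULL, subset = "S9") {
  if (is.null(aoc)) aoc <- aoc_table(cohort)
  s <- tolower(subset)
  qol <- cohort$qol[match(aoc$patient_id, cohort$qol$patient_id), ]
  panel <- function(x, y, xlab, ylab) {
    ggplot2::ggplot(data.frame(x = x, y = y),
                    ggplot2::aes(x = x, y = y)) +
      ggplot2::geom_point(alpha = 0.7) +
      ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                           linewidth = 0.4, colour = "grey40") +
      ggplot2::labs(x = xlab, y = ylab) +
      ggplot2::theme_minimal()
  }
  list(
    total = panel(aoc[[paste0(s, "_total")]], qol$total_score,
                  sprintf("Total AoC %s", subset),
                  "NEI-VFQ-25 total score"),
    near = panel(aoc[[paste0(s, "_near")]], qol$near_activities,
                 sprintf("AoCN %s", subset),
                 "Near-activities score"),
    distance = panel(aoc[[paste0(s, "_distance")]], qol$distance_activities,
                     sprintf("AoCD %s", subset),
                     "Distance-activities score"))
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stopf("stage '%s': %s", name, conditionMessage(e))
  })
}

#' Run the full analysis pipeline
#'
#' simulate-or-load -> score -> complete-case filter -> AoC index table ->
#' correlation battery + lowest-quartile comparison -> CSV outputs and a
#' JSON manifest recording the configuration, seed and row counts at every
#' stage.
#'
#' @param config A [run_config()].
#' @return Invisibly, the report bundle: `cohort`, `aoc`, `correlations`,
#'   `quartiles`, `manifest`, and `files` (written paths, when `out_dir`
#'   is set).
#' @export
#' @examples
#' cfg <- run_config(sim = sim_params(n_patients = 30), seed = 7)
#' bundle <- run_pipeline(cfg)
#' bundle$correlations
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  counts <- list()

  cohort <- stage("input", {
    if (!is.null(config$sim)) {
      simulate_cohort(config$sim)
    } else {
      va <- read_va_csv(config$va_path)
      qol <- if (!is.null(config$qol_path)) {
        read_qol_csv(config$qol_path)
      } else {
        score_nei_vfq_table(read_items_csv(config$items_path))
      }
      new_cohort(va, qol,
                 paste("files:", config$va_path,
                       config$qol_path %||% config$items_path))
    }
  })
  counts$patients_in <- length(unique(cohort$va$patient_id))

  cohort <- stage("filter_complete", suppressMessages(filter_complete(cohort)))
  counts$patients_analyzed <- nrow(cohort$qol)

  aoc <- stage("aoc_table",
               aoc_table(cohort, split_cm = config$split_cm,
                         x_axis = config$x_axis))
  counts$aoc_rows <- nrow(aoc)

  correlations <- stage("correlation_battery",
                        correlation_battery(cohort, aoc,
                                            alpha = config$alpha))
  quartiles <- stage("quartile_compare",
                     quartile_compare(cohort, aoc, alpha = config$alpha))
  counts$correlation_rows <- nrow(correlations)
  counts$quartile_rows <- nrow(quartiles)

  manifest <- list(
    package = "vicurve",
    version = as.character(utils::packageVersion("vicurve")),
    seed = config$seed,
    split_cm = config$split_cm,
    x_axis = config$x_axis,
    alpha = config$alpha,
    input = if (!is.null(config$sim)) {
      c(unclass(config$sim)[setdiff(names(config$sim), "distances_cm")],
        list(distances_cm = config$sim$distances_cm))
    } else {
      list(va_path = config$va_path,
           qol_path = config$qol_path, items_path = config$items_path)
    },
    counts = counts)

  files <- NULL
  if (!is.null(config$out_dir)) {
    files <- stage("write_report", {
      dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
      p <- function(f) file.path(config$out_dir, f)
      out <- c(
        va = write_csv_strict(cohort$va, p("va.csv")),
        qol = write_csv_strict(cohort$qol, p("qol.csv")),
        aoc = write_csv_strict(aoc_long(aoc), p("aoc.csv")),
        correlations = write_csv_strict(correlations,
                                        p("correlations.csv")),
        quartiles = write_csv_strict(quartiles, p("quartiles.csv")))
      jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                           digits = NA, pretty = TRUE)
      out <- c(out, manifest = p("manifest.json"))
      if (config$plots) {
        pl <- plot_score_vs_aoc(cohort, aoc)
        for (nm in names(pl)) {
          f <- p(sprintf("scatter_%s.png", nm))
          ggplot2::ggsave(f, pl[[nm]], width = 4.5, height = 3.5, dpi = 150)
          out <- c(out, setNames(f, paste0("plot_", nm)))
        }
      }
      out
    })
  }

  invisible(list(cohort = cohort, aoc = aoc, correlations = correlations,
                 quartiles = quartiles, manifest = manifest, files = files))
}

## wide aoc table -> tidy long CSV layout
aoc_long <- function(aoc_wide) {
  long <- lapply(c("s4", "s5", "s6", "s9", "dct"), function(nm) {
    tibble::tibble(
      patient_id = aoc_wide$patient_id,
      subset = toupper(nm),
      method = if (nm == "dct") "piecewise_linear" else "polynomial",
      aoc_total = aoc_wide[[paste0(nm, "_total")]],
      aoc_near = aoc_wide[[paste0(nm, "_near")]],
      aoc_distance = aoc_wide[[paste0(nm, "_distance")]])
  })
  do.call(rbind, long)
}
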