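# On-disk cohort format: one CSV per trial (time_ms, x_deg, y_deg,
# pupil_mm, valid), a JSON manifest describing subjects/runs/stimuli, and a
# JSON ground-truth registry. All angles in degrees (world coordinates,
# CCW-positive, 0 = rightward); times in ms with motion onset at 0.

MANIFEST_SCHEMA_VERSION <- 1L

#' Write a cohort dataset to a directory
#'
#' @param cohort CohortDataset from \code{simulate_cohort}
#' @param dir output directory (created if needed)
#' @return invisibly, the manifest path
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(file.path(dir, "traces"), recursive = TRUE,
             showWarnings = FALSE)
  runs_meta <- list()
  truth <- list()
  for (rn in names(cohort$runs)) {
    run <- cohort$runs[[rn]]
    trial_files <- character(nrow(run$schedule))
    for (k in seq_along(run$trials)) {
      f <- file.path("traces", sprintf("%s_t%03d.csv", rn, k))
      utils::write.csv(run$trials[[k]]$trace, file.path(dir, f),
                       row.names = FALSE)
      trial_files[k] <- f
    }
    pupil_file <- file.path("traces", sprintf("%s_pupil.csv", rn))
    utils::write.csv(run$pupil$trace, file.path(dir, pupil_file),
                     row.names = FALSE)
    runs_meta[[rn]] <- list(
      subject_id = run$subject_id, condition = run$condition,
      eye = run$eye, dominant_eye = run$dominant_eye,
      schedule = run$schedule, trial_files = trial_files,
      pupil_file = pupil_file,
      pupil_transitions = run$pupil$transitions,
      calibration = run$calibration)
    truth[[rn]] <- lapply(run$trials, function(tr) {
      tt <- tr$truth
      tt$stim <- NULL
      tt
    })
  }
  manifest <- list(schema_version = MANIFEST_SCHEMA_VERSION,
                   seed = cohort$seed, runs = runs_meta)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(file.path(dir, "manifest.json"))
}

#' Read a cohort dataset from a manifest
#'
#' Malformed or missing trial traces are skipped with a warning and
#' counted; a schema mismatch or an empty manifest is a hard error.
#'
#' @param manifest_path path to manifest.json
#' @return CohortDataset (without latent subject parameters);
#'   \code{attr(,"n_excluded")} counts skipped trials
#' @export
read_cohort <- function(manifest_path) {
  man <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  if (is.null(man$schema_version) ||
      man$schema_version != MANIFEST_SCHEMA_VERSION) {
    stop("manifest schema version mismatch")
  }
  if (length(man$runs) == 0) stop("no trials: manifest lists no runs")
  base_dir <- dirname(manifest_path)
  runs <- list()
  excluded <- 0L
  for (rn in names(man$runs)) {
    rm_ <- man$runs[[rn]]
    sched <- as.data.frame(rm_$schedule)
    trials <- vector("list", length(rm_$trial_files))
    keep <- logical(length(trials))
    for (k in seq_along(rm_$trial_files)) {
      f <- file.path(base_dir, rm_$trial_files[k])
      if (!file.exists(f)) {
        warning("missing trace file: ", f, " (excluded)")
        excluded <- excluded + 1L
        next
      }
      tr <- tryCatch(utils::read.csv(f), error = function(e) NULL)
      if (is.null(tr) || !all(c("time_ms", "x_deg", "y_deg") %in%
                                names(tr))) {
        warning("malformed trace file: ", f, " (excluded)")
        excluded <- excluded + 1L
        next
      }
      trials[[k]] <- list(trace = tr, truth = NULL)
      keep[k] <- TRUE
    }
    pupil <- NULL
    pf <- file.path(base_dir, rm_$pupil_file)
    if (file.exists(pf)) {
      pupil <- list(trace = utils::read.csv(pf),
                    transitions = as.data.frame(rm_$pupil_transitions))
    }
    runs[[rn]] <- list(subject_id = rm_$subject_id,
                       condition = rm_$condition, eye = rm_$eye,
                       dominant_eye = rm_$dominant_eye,
                       schedule = sched[keep, , drop = FALSE],
                       trials = trials[keep], pupil = pupil,
                       calibration = as.data.frame(rm_$calibration))
  }
  out <- list(subjects = NULL, runs = runs, seed = man$seed)
  attr(out, "n_excluded") <- excluded
  out
}

#' Run the simulate -> extract -> compare pipeline
#'
#' @param config list with optional elements \code{n_subjects},
#'   \code{n_trials}, \code{conditions}, \code{seed}, \code{out_dir}
#'   (tables are written there as TSV when given)
#' @return list(tables = per-condition metric tables, comparisons =
#'   named list of comparison tables, seed)
#' @export
run_pipeline <- function(config = list()) {
  n_subjects <- config$n_subjects %||% 17
  n_trials <- config$n_trials %||% 90
  conditions <- config$conditions %||% c("left", "right", "binocular")
  seed <- config$seed %||% 1
  cohort <- simulate_cohort(n_subjects, conditions, n_trials, seed)
  tabs <- extract_cohort(cohort)
  comparisons <- list()
  if (all(c("left", "right") %in% conditions)) {
    mono <- cyclopean_average(tabs$left, tabs$right)
    if ("binocular" %in% conditions) {
      comparisons$monocular_vs_binocular <-
        compare_conditions(mono, tabs$binocular)
    }
    dom <- ifelse(tabs$left$dominant_eye == "L", 1, 2)
    dtab <- tabs$left; ndtab <- tabs$right
    swap <- dom == 2
    dtab[swap, ] <- tabs$right[swap, ]
    ndtab[swap, ] <- tabs$left[swap, ]
    comparisons$dominant_vs_nondominant <- compare_conditions(dtab, ndtab)
    if ("binocular" %in% conditions) {
      comparisons$dominant_vs_binocular <-
        compare_conditions(dtab, tabs$binocular)
    }
  }
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    for (cn in names(tabs)) {
      utils::write.table(tabs[[cn]],
                         file.path(config$out_dir,
                                   paste0("metrics_", cn, ".tsv")),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    }
    for (cn in names(comparisons)) {
      utils::write.table(comparisons[[cn]],
                         file.path(config$out_dir,
                                   paste0("compare_", cn, ".tsv")),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    }
    writeLines(jsonlite::toJSON(list(seed = seed, n_subjects = n_subjects,
                                     n_trials = n_trials,
                                     conditions = conditions),
                                auto_unbox = TRUE),
               file.path(config$out_dir, "run_log.json"))
  }
  list(tables = tabs, comparisons = comparisons, seed = seed)
}
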