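# Cohort tables: one row per subject x bottom-layer ROI, with subject-level
# globals (label, total intracranial volume, global mean thickness, total
# surface area) repeated on each row.

roi_measures <- c("gm_volume", "wm_volume", "csf_volume",
                  "thickness_mean", "thickness_sd", "surface_area")

cohort_cols <- c("subject_id", "label", "tiv", "mean_thickness", "total_area",
                 "roi_index", roi_measures)

#' Validate a cohort morphometry table
#'
#' Checks the long cohort table: one row per subject and bottom-layer ROI,
#' exactly the atlas's layer-4 ROI set per subject, strictly positive measures
#' and globals (thickness SD may be zero), and a two-level group label.
#'
#' @param cohort A cohort tibble (see [read_cohort()] for the schema).
#' @param atlas A `roi_atlas`; defaults to the built-in 78-region hierarchy.
#' @return The cohort, invisibly, if valid; otherwise an error naming the
#'   offending subject/column.
#' @export
validate_cohort <- function(cohort, atlas = load_atlas()) {
  missing <- setdiff(cohort_cols, names(cohort))
  if (length(missing) > 0) {
    abort(paste0("cohort is missing column(s): ", paste(missing, collapse = ", ")),
          class = "hiernet_cohort_error")
  }
  n4 <- nrow(atlas$layers[["4"]])
  by_subj <- split(cohort$roi_index, cohort$subject_id)
  for (s in names(by_subj)) {
    idx <- sort(as.integer(by_subj[[s]]))
    if (!identical(idx, seq_len(n4))) {
      miss <- setdiff(seq_len(n4), idx)
      extra <- setdiff(idx, seq_len(n4))
      what <- if (length(miss) > 0) paste0("missing ROI ", miss[1])
              else paste0("unexpected/duplicated ROI ", extra[1])
      abort(paste0("subject ", s, ": ", what), class = "hiernet_cohort_error")
    }
  }
  strict_pos <- setdiff(roi_measures, "thickness_sd")
  for (m in c(strict_pos, "tiv", "mean_thickness", "total_area")) {
    v <- cohort[[m]]
    if (anyNA(v) || any(v <= 0)) {
      bad <- cohort$subject_id[which(is.na(v) | v <= 0)[1]]
      abort(paste0("subject ", bad, ": non-positive or missing ", m),
            class = "hiernet_cohort_error")
    }
  }
  if (any(cohort$thickness_sd < 0)) {
    bad <- cohort$subject_id[which(cohort$thickness_sd < 0)[1]]
    abort(paste0("subject ", bad, ": negative thickness_sd"),
          class = "hiernet_cohort_error")
  }
  if (length(unique(cohort$label)) != 2) {
    abort("cohort must contain exactly two label groups",
          class = "hiernet_cohort_error")
  }
  invisible(cohort)
}

#' Normalize ROI morphometry by subject-level globals
#'
#' Reduces inter-individual scale differences: tissue volumes are divided by
#' the subject's total intracranial volume, mean cortical thickness (and its
#' within-ROI standard deviation, so the similarity kernel's dimensionless
#' ratio is preserved) by the subject's global mean thickness, and surface
#' area by the subject's total cortical surface area. Doubling all raw
#' measures together with the globals leaves the output unchanged.
#'
#' @inheritParams validate_cohort
#' @return The cohort tibble with normalized measures and attribute
#'   `normalized = TRUE`. Normalizing an already-normalized cohort is a no-op.
#' @export
normalize_cohort <- function(cohort, atlas = load_atlas()) {
  if (isTRUE(attr(cohort, "normalized"))) return(cohort)
  validate_cohort(cohort, atlas)
  out <- dplyr::mutate(
    cohort,
    gm_volume = .data$gm_volume / .data$tiv,
    wm_volume = .data$wm_volume / .data$tiv,
    csf_volume = .data$csf_volume / .data$tiv,
    thickness_mean = .data$thickness_mean / .data$mean_thickness,
    thickness_sd = .data$thickness_sd / .data$mean_thickness,
    surface_area = .data$surface_area / .data$total_area
  )
  attr(out, "normalized") <- TRUE
  attr(out, "ground_truth") <- attr(cohort, "ground_truth")
  out
}

#' Write a cohort to its two-file CSV interface
#'
#' Writes `rois.csv` (subject x ROI measures) and `subjects.csv` (labels and
#' globals) under `dir`; a planted-effect ground truth attached by
#' [simulate_cohort()] is stored as a `ground_truth.json` sidecar.
#'
#' @param cohort A cohort tibble.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rois <- cohort[c("subject_id", "roi_index", roi_measures)]
  subjects <- dplyr::distinct(
    cohort[c("subject_id", "label", "tiv", "mean_thickness", "total_area")])
  readr::write_csv(rois, file.path(dir, "rois.csv"), progress = FALSE)
  readr::write_csv(subjects, file.path(dir, "subjects.csv"), progress = FALSE)
  gt <- attr(cohort, "ground_truth")
  if (!is.null(gt)) {
    jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                         dataframe = "columns", digits = NA)
  }
  invisible(dir)
}

#' Read a cohort from its two-file CSV interface
#'
#' @param dir Directory containing `rois.csv` and `subjects.csv` (and
#'   optionally `ground_truth.json`).
#' @param atlas A `roi_atlas` used for validation.
#' @return A validated cohort tibble; any ground-truth sidecar is attached as
#'   attribute `ground_truth` (a warning is raised if the sidecar is absent).
#' @export
read_cohort <- function(dir, atlas = load_atlas()) {
  for (f in c("rois.csv", "subjects.csv")) {
    if (!file.exists(file.path(dir, f))) {
      abort(paste0("cohort file missing: ", file.path(dir, f)),
            class = "hiernet_cohort_error")
    }
  }
  rois <- readr::read_csv(file.path(dir, "rois.csv"), show_col_types = FALSE,
                          progress = FALSE)
  subjects <- readr::read_csv(file.path(dir, "subjects.csv"),
                              show_col_types = FALSE, progress = FALSE)
  for (nm in setdiff(c("subject_id", "roi_index", roi_measures), names(rois))) {
    abort(paste0("rois.csv is missing column ", nm), class = "hiernet_cohort_error")
  }
  for (nm in setdiff(c("subject_id", "label", "tiv", "mean_thickness",
                       "total_area"), names(subjects))) {
    abort(paste0("subjects.csv is missing column ", nm),
          class = "hiernet_cohort_error")
  }
  cohort <- dplyr::inner_join(subjects, rois, by = "subject_id")
  cohort <- tibble::as_tibble(cohort[cohort_cols])
  validate_cohort(cohort, atlas)
  gt_path <- file.path(dir, "ground_truth.json")
  if (file.exists(gt_path)) {
    gt <- jsonlite::read_json(gt_path, simplifyVector = TRUE)
    coerce <- function(df, spec) {
      df <- tibble::as_tibble(df)
      out <- lapply(names(spec), function(nm) {
        v <- if (nm %in% names(df)) unlist(df[[nm]]) else NULL
        do.call(spec[[nm]], list(if (is.null(v)) logical(0) else v))
      })
      tibble::as_tibble(setNames(out, names(spec)))
    }
    gt$roi_effects <- coerce(gt$roi_effects,
                             list(roi = as.integer, measure = as.character,
                                  d = as.numeric))
    gt$edge_effects <- coerce(gt$edge_effects,
                              list(roi_i = as.integer, roi_j = as.integer,
                                   coupling = as.numeric))
    attr(cohort, "ground_truth") <- gt
  } else {
    warn("no ground_truth.json sidecar found; cohort loaded with empty ground truth")
    attr(cohort, "ground_truth") <- NULL
  }
  cohort
}

#' Subject labels in cohort order
#'
#' @inheritParams validate_cohort
#' @param positive Label treated as the positive class (first factor level is
#'   the negative class).
#' @return Named factor of per-subject labels, ordered by first appearance.
#' @export
cohort_labels <- function(cohort, positive = "high") {
  subj <- dplyr::distinct(cohort[c("subject_id", "label")])
  lev <- unique(c(setdiff(sort(unique(subj$label)), positive), positive))
  setNames(factor(subj$label, levels = lev), subj$subject_id)
}
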