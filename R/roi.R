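# ROI aggregation: voxel-wise metric maps -> long-format per-subject table
# (subject, group, timepoint, ROI, metric, mean value) for the statistics
# stage.

#' Mean metric values over labeled ROIs
#'
#' Arithmetic mean of each metric map over the voxels of every ROI in the
#' vocabulary. `NA`/`NaN` voxels (non-fitted) are excluded from the mean and
#' counted separately.
#'
#' @param metric_maps Named list of 3-D arrays (typically `MD`, `FA`, `L`,
#'   `q` from [compute_metric_maps()]).
#' @param label_map Integer 3-D array, codes 1..6 in the order of
#'   [roi_vocabulary()], 0 = background.
#' @param rois Character vector of ROI names to extract (default the full
#'   vocabulary). Every requested ROI must be present in the label map.
#' @return Data frame (roi, metric, value, n_voxels, n_excluded), one row
#'   per ROI x metric.
#' @export
extract_roi_means <- function(metric_maps, label_map,
                              rois = roi_vocabulary()) {
  metric_maps <- metric_maps[intersect(names(metric_maps), .qdti_metrics)]
  if (length(metric_maps) == 0)
    qdti_stop("no metric maps supplied", "qdti_invalid_input")
  for (m in names(metric_maps))
    if (!all(dim(metric_maps[[m]]) == dim(label_map)))
      qdti_stop(sprintf("grid mismatch between label map and %s map", m),
                "qdti_dim_error")
  codes <- match(rois, .qdti_rois)
  if (anyNA(codes))
    qdti_stop("unknown ROI name(s)", "qdti_missing_roi")
  rows <- list()
  for (k in seq_along(rois)) {
    idx <- which(label_map == codes[k])
    if (length(idx) == 0)
      qdti_stop(sprintf("ROI '%s' is empty in the label map", rois[k]),
                "qdti_missing_roi")
    for (m in names(metric_maps)) {
      v <- metric_maps[[m]][idx]
      ok <- is.finite(v)
      if (!any(ok))
        qdti_stop(sprintf("ROI '%s' has no fitted voxels for %s", rois[k], m),
                  "qdti_missing_roi")
      rows[[length(rows) + 1L]] <- data.frame(
        roi = rois[k], metric = m, value = mean(v[ok]),
        n_voxels = sum(ok), n_excluded = sum(!ok), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Assemble the cohort-level metric table
#'
#' Combines per-subject-timepoint ROI means into the complete long-format
#' table, enforcing exactly one row per (subject, timepoint, ROI, metric)
#' and a canonical row order.
#'
#' @param cohort A `dwi_cohort` (supplies subjects, groups, timepoints).
#' @param roi_means Nested list `roi_means[[subject_id]][[timepoint]]` of
#'   data frames from [extract_roi_means()].
#' @return Data frame (subject_id, group, timepoint, roi, metric, value,
#'   n_voxels) sorted by subject, timepoint, ROI, metric.
#' @export
assemble_cohort_table <- function(cohort, roi_means) {
  rows <- list(); gaps <- character()
  for (i in seq_len(nrow(cohort$subjects))) {
    sid <- cohort$subjects$subject_id[i]
    for (tp in cohort$cohort$timepoints) {
      rm <- roi_means[[sid]][[tp]]
      if (is.null(rm)) { gaps <- c(gaps, paste(sid, tp)); next }
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = sid, group = cohort$subjects$group[i], timepoint = tp,
        roi = rm$roi, metric = rm$metric, value = rm$value,
        n_voxels = rm$n_voxels, stringsAsFactors = FALSE)
    }
  }
  if (length(gaps))
    qdti_stop(sprintf("missing subject-timepoint cell(s): %s",
                      paste(gaps, collapse = ", ")), "qdti_incomplete_table")
  out <- do.call(rbind, rows)
  key <- paste(out$subject_id, out$timepoint, out$roi, out$metric)
  if (anyDuplicated(key))
    qdti_stop("duplicate (subject, timepoint, roi, metric) rows", "qdti_incomplete_table")
  out <- out[order(out$subject_id, out$timepoint,
                   match(out$roi, .qdti_rois), match(out$metric, .qdti_metrics)), ]
  rownames(out) <- NULL
  out
}

#' Fit, decompose and tabulate a whole cohort
#'
#' Convenience wrapper chaining tensor fitting, scalar map computation and
#' ROI aggregation over every subject and timepoint of a simulated (or
#' loaded) cohort.
#'
#' @param cohort A `dwi_cohort` with DWI volumes attached.
#' @param method Tensor fit method, `"loglinear"` or `"wls"`.
#' @param rois ROIs to tabulate (default all six).
#' @param use_truth If `TRUE`, bypass fitting and compute maps from the
#'   ground-truth tensor fields instead (diagnostic path).
#' @return The cohort metric table (see [assemble_cohort_table()]).
#' @export
analyze_cohort <- function(cohort, method = "loglinear",
                           rois = roi_vocabulary(), use_truth = FALSE) {
  stopifnot(inherits(cohort, "dwi_cohort"))
  if (!use_truth && is.null(cohort$dwi))
    qdti_stop("cohort has no DWI volumes; generate with dwi = TRUE",
              "qdti_invalid_input")
  codes <- match(rois, .qdti_rois)
  mask <- array(cohort$label_map %in% codes, dim(cohort$label_map))
  means <- list()
  for (sid in cohort$subjects$subject_id) {
    means[[sid]] <- list()
    for (tp in cohort$cohort$timepoints) {
      tf <- if (use_truth) truth_tensor_field(cohort, sid, tp)
            else fit_tensor_field(cohort$dwi[[sid]][[tp]], cohort$scheme,
                                  mask = mask, method = method)$tensor_field
      maps <- compute_metric_maps(tf, mask = mask)
      means[[sid]][[tp]] <- extract_roi_means(maps, cohort$label_map, rois = rois)
    }
  }
  assemble_cohort_table(cohort, means)
}
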