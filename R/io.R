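# File-format plumbing: NIfTI-1 volumes via RNifti, FSL-dialect bval/bvec
# text files, the label-map JSON sidecar and the cohort manifest.

#' Write / read FSL-dialect gradient tables
#'
#' `write_bvalbvec()` writes one row of b-values to `<stem>.bval` and three
#' rows of direction components to `<stem>.bvec`; `read_bvalbvec()` reads
#' them back into a `gradient_scheme`.
#'
#' @param scheme A `gradient_scheme`.
#' @param stem Path stem (without extension).
#' @return `read_bvalbvec()` returns a `gradient_scheme`;
#'   `write_bvalbvec()` the stem, invisibly.
#' @export
write_bvalbvec <- function(scheme, stem) {
  writeLines(paste(format(scheme$bvals, scientific = FALSE, trim = TRUE),
                   collapse = " "), paste0(stem, ".bval"))
  writeLines(apply(scheme$bvecs, 1L, function(r)
    paste(sprintf("%.10f", r), collapse = " ")), paste0(stem, ".bvec"))
  invisible(stem)
}

#' @rdname write_bvalbvec
#' @export
read_bvalbvec <- function(stem) {
  bvals <- scan(paste0(stem, ".bval"), quiet = TRUE)
  bvecs <- matrix(scan(paste0(stem, ".bvec"), quiet = TRUE),
                  nrow = 3L, byrow = TRUE)
  structure(list(bvals = bvals, bvecs = bvecs), class = "gradient_scheme")
}

#' Write scalar metric maps as NIfTI-1 volumes
#'
#' One 3-D file per metric, named `<prefix>_<metric>.nii`. Grid and affine
#' are copied from `reference` when given (e.g. the input DWI image).
#'
#' @param maps Named list of 3-D arrays (from [compute_metric_maps()]).
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @param reference Optional NIfTI image (or path) whose header is copied.
#' @return Named character vector of file paths, invisibly.
#' @export
write_metric_maps <- function(maps, dir, prefix, reference = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  maps <- maps[intersect(names(maps), .qdti_metrics)]
  paths <- character()
  for (m in names(maps)) {
    p <- file.path(dir, paste0(prefix, "_", m, ".nii"))
    img <- if (is.null(reference)) RNifti::asNifti(maps[[m]])
           else RNifti::asNifti(maps[[m]], reference = reference)
    RNifti::writeNifti(img, p)
    paths[m] <- p
  }
  invisible(paths)
}

write_nifti_vol <- function(arr, path, reference = NULL) {
  img <- if (is.null(reference)) RNifti::asNifti(arr)
         else RNifti::asNifti(arr, reference = reference)
  RNifti::writeNifti(img, path)
  path
}

#' Read a DWI volume with its gradient table
#'
#' @param nii_path Path to a 4-D NIfTI DWI volume.
#' @param stem Path stem of the `.bval`/`.bvec` pair; defaults to the NIfTI
#'   path without extension.
#' @return List with `dwi` (4-D array) and `scheme` (`gradient_scheme`).
#' @export
read_dwi <- function(nii_path, stem = sub("\\.nii(\\.gz)?$", "", nii_path)) {
  if (!file.exists(nii_path))
    qdti_stop(sprintf("missing DWI volume: %s", nii_path), "qdti_io_error")
  img <- RNifti::readNifti(nii_path)
  scheme <- read_bvalbvec(stem)
  arr <- array(as.numeric(img), dim = dim(img))
  if (length(dim(arr)) != 4L || dim(arr)[4] != length(scheme$bvals))
    qdti_stop(sprintf("DWI/scheme mismatch for %s", nii_path), "qdti_io_error")
  list(dwi = arr, scheme = scheme)
}

#' Write a simulated cohort to disk
#'
#' Lays a `dwi_cohort` out as NIfTI + text files: per subject-timepoint DWI
#' (`<subject>_<timepoint>_dwi.nii` with a shared `.bval`/`.bvec` pair), a
#' shared integer label map with JSON sidecar mapping codes to ROI names,
#' and a JSON manifest recording subjects, groups, timepoints, seeds,
#' ground-truth eigenvalues/tensors and file paths (ground truth is kept
#' losslessly in the manifest so recovery error stays computable from disk).
#'
#' @param cohort A `dwi_cohort` with DWI attached.
#' @param dir Output directory.
#' @return Path to the manifest, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (is.null(cohort$dwi))
    qdti_stop("cohort has no DWI volumes to write", "qdti_invalid_input")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir))
    qdti_stop(sprintf("cannot create output directory %s", dir), "qdti_io_error")
  write_bvalbvec(cohort$scheme, file.path(dir, "dwi"))
  write_nifti_vol(cohort$label_map, file.path(dir, "labels.nii"))
  jsonlite::write_json(
    list(codes = stats::setNames(as.list(seq_along(.qdti_rois)), .qdti_rois)),
    file.path(dir, "labels.json"), auto_unbox = TRUE)

  files <- list()
  for (sid in cohort$subjects$subject_id) {
    files[[sid]] <- list()
    for (tp in cohort$cohort$timepoints) {
      p <- file.path(dir, sprintf("%s_%s_dwi.nii", sid, tp))
      write_nifti_vol(cohort$dwi[[sid]][[tp]], p)
      files[[sid]][[tp]] <- basename(p)
    }
  }
  truth <- lapply(cohort$truth, function(per_tp)
    lapply(per_tp, function(tr)
      list(rois = rownames(tr$lambdas),
           lambdas = unname(apply(tr$lambdas, 1L, as.numeric, simplify = FALSE)),
           tensors = unname(apply(tr$tensors, 1L, as.numeric, simplify = FALSE)))))
  manifest <- list(
    package = "qdti",
    subjects = cohort$subjects,
    groups = cohort$cohort$groups,
    timepoints = cohort$cohort$timepoints,
    rois = cohort$rois,
    grid = cohort$phantom$dim,
    s0 = cohort$phantom$s0, sigma = cohort$phantom$sigma,
    b_value = cohort$phantom$b_value,
    n_directions = cohort$phantom$n_directions,
    jitter_sd = cohort$cohort$jitter_sd,
    histology_n = as.list(cohort$cohort$histology_n),
    seeds = cohort$seeds,
    files = files,
    label_map = "labels.nii",
    gradient_stem = "dwi",
    truth = truth)
  mp <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(mp)
}

#' Read a cohort back from a manifest
#'
#' Reconstructs a `dwi_cohort` (DWI volumes, label map, scheme, ground
#' truth, seeds) from a directory written by [write_cohort()].
#'
#' @param dir Directory containing `manifest.json`.
#' @return A `dwi_cohort`.
#' @export
read_cohort <- function(dir) {
  mp <- file.path(dir, "manifest.json")
  if (!file.exists(mp))
    qdti_stop(sprintf("no manifest.json in %s", dir), "qdti_io_error")
  man <- jsonlite::read_json(mp, simplifyVector = TRUE)
  scheme <- read_bvalbvec(file.path(dir, man$gradient_stem))
  lab_img <- RNifti::readNifti(file.path(dir, man$label_map))
  # NIfTI readers drop trailing singleton dimensions; restore the 3-D grid
  lab <- array(as.integer(lab_img), dim = man$grid)
  subjects <- as.data.frame(man$subjects, stringsAsFactors = FALSE)

  truth <- list(); dwis <- list()
  for (sid in subjects$subject_id) {
    truth[[sid]] <- list(); dwis[[sid]] <- list()
    for (tp in man$timepoints) {
      tr <- man$truth[[sid]][[tp]]
      as_mat <- function(x) if (is.matrix(x)) x else do.call(rbind, x)
      lam <- as_mat(tr$lambdas); rownames(lam) <- tr$rois
      ten <- as_mat(tr$tensors); rownames(ten) <- tr$rois
      truth[[sid]][[tp]] <- list(lambdas = lam, tensors = ten)
      p <- file.path(dir, man$files[[sid]][[tp]])
      if (!file.exists(p))
        qdti_stop(sprintf("missing DWI volume: %s", p), "qdti_io_error")
      img <- RNifti::readNifti(p)
      dwis[[sid]][[tp]] <- array(as.numeric(img),
                                 dim = c(man$grid, length(scheme$bvals)))
    }
  }
  phantom <- phantom_spec(dim = man$grid, s0 = man$s0, sigma = man$sigma,
                          profiles = build_profiles(groups = man$groups,
                                                    timepoints = man$timepoints),
                          label_map = lab,
                          b_value = man$b_value, n_directions = man$n_directions)
  spec <- cohort_spec(groups = man$groups,
                      n_per_group = sum(subjects$group == man$groups[1]),
                      timepoints = man$timepoints, seed = man$seeds$master,
                      jitter_sd = man$jitter_sd,
                      histology_n = unlist(man$histology_n))
  structure(list(phantom = phantom, cohort = spec, scheme = scheme,
                 subjects = subjects, label_map = lab, rois = man$rois,
                 truth = truth, jitter = NULL, dwi = dwis, seeds = man$seeds),
            class = "dwi_cohort")
}
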