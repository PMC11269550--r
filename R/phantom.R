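# Synthetic study generator. A digital phantom mimics a three-group
# (sham / short-interval / long-interval injury) longitudinal rodent DTI
# study: six labeled regions with tissue-typical eigenvalue profiles,
# group- and timepoint-specific shifts of those profiles, per-subject
# biological jitter, Rician-noise DWI, and immunohistochemistry-like cell
# counts statistically coupled to region-mean pure anisotropy q.

# Tissue-typical eigenvalue triples (mm^2/s). Gray matter (cortex, HPC)
# around FA ~ 0.2, white matter tracts around FA ~ 0.7.
.base_lambdas <- list(
  cortex = c(1.05, 0.80, 0.70) * 1e-3,
  CC     = c(1.55, 0.45, 0.35) * 1e-3,
  HPC    = c(1.00, 0.82, 0.72) * 1e-3,
  mCC    = c(1.50, 0.45, 0.36) * 1e-3,
  EC     = c(1.45, 0.42, 0.34) * 1e-3,
  IC     = c(1.52, 0.44, 0.36) * 1e-3
)

# Principal diffusion direction per region (unit vectors).
.principal_dirs <- list(
  cortex = c(0, 0, 1), CC = c(1, 0, 0), HPC = c(0, 0, 1),
  mCC = c(1, 0, 0), EC = c(0, 1, 0), IC = c(0, 1, 0)
)

# Rotation with first column along `dir` (completed by Gram-Schmidt).
rotation_from_dir <- function(dir) {
  e1 <- dir / sqrt(sum(dir^2))
  helper <- if (abs(e1[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e2 <- helper - sum(helper * e1) * e1
  e2 <- e2 / sqrt(sum(e2^2))
  e3 <- c(e1[2] * e2[3] - e1[3] * e2[2],
          e1[3] * e2[1] - e1[1] * e2[3],
          e1[1] * e2[2] - e1[2] * e2[1])
  cbind(e1, e2, e3)
}

# lambdas (sorted desc) + principal direction -> 6-component tensor
tensor_from_profile <- function(lambdas, dir) {
  R <- rotation_from_dir(dir)
  as_tensor6(R %*% diag(sort(lambdas, decreasing = TRUE)) %*% t(R))
}

#' Default box-ROI label map
#'
#' Partitions the in-plane grid into a 3 x 2 arrangement of boxes, one per
#' ROI (codes 1..6 in the order of [roi_vocabulary()]), separated by a one-
#' voxel background margin where the grid allows it. ROI geometry is
#' deliberately simple: the scalar metrics depend only on the tensors inside
#' each label, not on region shape.
#'
#' @param dim Integer grid dimensions `c(nx, ny, nz)`.
#' @return Integer 3-D array with values 0 (background) to 6.
#' @export
default_label_map <- function(dim) {
  if (length(dim) != 3L || any(dim < c(6L, 4L, 1L)))
    qdti_stop("grid must be at least 6 x 4 x 1", "qdti_config_error")
  lab <- array(0L, dim)
  xb <- floor(seq(0, dim[1], length.out = 4L))
  yb <- floor(seq(0, dim[2], length.out = 3L))
  code <- 0L
  for (iy in 1:2) for (ix in 1:3) {
    code <- code + 1L
    xs <- (xb[ix] + 1L):xb[ix + 1L]
    ys <- (yb[iy] + 1L):yb[iy + 1L]
    if (length(xs) >= 3L) xs <- xs[-c(1L, length(xs))]
    if (length(ys) >= 3L) ys <- ys[-c(1L, length(ys))]
    lab[xs, ys, ] <- code
  }
  lab
}

#' Default group/timepoint effect template
#'
#' The signed effect structure the generator imposes on the base eigenvalue
#' profiles, mirroring the study design it emulates: the short-interval
#' group loses cortical anisotropy (q and FA down) at both imaging days; the
#' long-interval group gains callosal anisotropy (FA and q up); and at day
#' 90 the short-interval group's external and internal capsules are scaled
#' down uniformly (L and q reduced, FA preserved).
#'
#' Effects are expressed as eigenvalue-profile transforms: `"aniso"`
#' shrinks/stretches eigenvalues about their mean by `factor` (changes q and
#' FA, preserves MD); `"scale"` multiplies all eigenvalues by `factor`
#' (changes MD, L and q proportionally, preserves FA).
#'
#' @return Data frame with columns `group`, `roi`, `timepoint`, `kind`,
#'   `factor`.
#' @export
default_effect_template <- function() {
  rbind(
    data.frame(group = "short", roi = "cortex",
               timepoint = c("day50", "day90"), kind = "aniso", factor = 0.88),
    data.frame(group = "long", roi = "CC",
               timepoint = c("day50", "day90"), kind = "aniso", factor = 1.12),
    data.frame(group = "short", roi = c("EC", "IC"),
               timepoint = "day90", kind = "scale", factor = 0.90)
  )
}

apply_profile_effect <- function(lambdas, kind, factor) {
  switch(kind,
         aniso = mean(lambdas) + factor * (lambdas - mean(lambdas)),
         scale = factor * lambdas,
         qdti_stop(sprintf("unknown effect kind '%s'", kind), "qdti_config_error"))
}

#' Build the full eigenvalue profile table
#'
#' Expands base per-ROI eigenvalue triples into one profile per (group,
#' timepoint, ROI) cell and applies an effect template. `template = NULL`
#' gives a null configuration (all groups identical), used for type-I-error
#' calibration.
#'
#' @param template Effect template data frame as in
#'   [default_effect_template()], or `NULL`.
#' @param groups,timepoints Character vectors of cell labels.
#' @param base Named list of base eigenvalue triples per ROI, mm^2/s.
#' @return Data frame with columns `group`, `timepoint`, `roi`, `l1`, `l2`,
#'   `l3`.
#' @export
build_profiles <- function(template = default_effect_template(),
                           groups = c("sham", "short", "long"),
                           timepoints = c("day50", "day90"),
                           base = .base_lambdas) {
  cells <- expand.grid(group = groups, timepoint = timepoints,
                       roi = names(base), stringsAsFactors = FALSE)
  lam <- t(mapply(function(g, tp, roi) {
    l <- base[[roi]]
    if (!is.null(template)) {
      hit <- template$group == g & template$roi == roi & template$timepoint == tp
      for (j in which(hit)) l <- apply_profile_effect(l, template$kind[j], template$factor[j])
    }
    sort(l, decreasing = TRUE)
  }, cells$group, cells$timepoint, cells$roi))
  out <- cbind(cells, l1 = lam[, 1], l2 = lam[, 2], l3 = lam[, 3])
  rownames(out) <- NULL
  out
}

#' Specify a digital DWI phantom
#'
#' Collects everything the simulator needs about the imaged object and the
#' acquisition: grid, ROI label map, per-(group, timepoint, ROI) eigenvalue
#' profiles, principal diffusion directions, baseline signal, noise level,
#' and gradient-scheme parameters.
#'
#' @param dim Grid dimensions, default `c(96, 96, 5)`.
#' @param s0 Baseline (b = 0) signal, default 1000.
#' @param sigma Rician channel noise SD, default `s0 / 30` (SNR 30 at
#'   b = 0).
#' @param profiles Profile table from [build_profiles()].
#' @param label_map Integer label array on `dim`; default box layout.
#' @param principal_dirs Named list of unit vectors per ROI.
#' @param b_value,n_directions Gradient scheme parameters (s/mm^2;
#'   directions + 1 b = 0 volume).
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(dim = c(96, 96, 5), s0 = 1000, sigma = s0 / 30,
                         profiles = build_profiles(),
                         label_map = default_label_map(dim),
                         principal_dirs = .principal_dirs,
                         b_value = 1000, n_directions = 30) {
  if (!all(dim(label_map) == dim))
    qdti_stop("label map does not match grid dimensions", "qdti_config_error")
  rois <- unique(profiles$roi)
  counts <- table(factor(label_map[label_map > 0],
                         levels = seq_along(.qdti_rois),
                         labels = .qdti_rois))
  if (any(counts[rois] == 0))
    qdti_stop(sprintf("empty ROI(s) in label map: %s",
                      paste(rois[counts[rois] == 0], collapse = ", ")),
              "qdti_config_error")
  if (any(profiles[, c("l1", "l2", "l3")] < 0))
    qdti_stop("profile eigenvalues must be non-negative", "qdti_config_error")
  if (sigma < 0) qdti_stop("`sigma` must be non-negative", "qdti_invalid_parameter")
  structure(list(dim = as.integer(dim), s0 = s0, sigma = sigma,
                 profiles = profiles, label_map = label_map,
                 principal_dirs = principal_dirs,
                 b_value = b_value, n_directions = as.integer(n_directions)),
            class = "phantom_spec")
}

#' Specify a simulated cohort
#'
#' The study skeleton: three groups of six subjects imaged at two
#' timepoints by default, with multiplicative per-subject eigenvalue jitter
#' standing in for biological variability, and the histology subgroup sizes
#' used for synthetic cell counts.
#'
#' @param groups Group names.
#' @param n_per_group Subjects per group (>= 2).
#' @param timepoints Timepoint names (>= 1); order is the within-subject
#'   order.
#' @param seed Master seed; all sub-streams are derived from it.
#' @param jitter_sd SD of the multiplicative per-subject, per-ROI,
#'   per-eigenvalue jitter (default 0.03).
#' @param histology_n Named integer vector: subjects per group entering the
#'   synthetic histology arm (default sham 4, short 3, long 4).
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(groups = c("sham", "short", "long"), n_per_group = 6,
                        timepoints = c("day50", "day90"), seed = 1,
                        jitter_sd = 0.03,
                        histology_n = c(sham = 4, short = 3, long = 4)) {
  histology_given <- !missing(histology_n)
  if (n_per_group < 2L) qdti_stop("need >= 2 subjects per group", "qdti_config_error")
  if (length(timepoints) < 1L) qdti_stop("need >= 1 timepoint", "qdti_config_error")
  histology_n <- histology_n[intersect(names(histology_n), groups)]
  if (length(histology_n) == 0) histology_n <- stats::setNames(rep(min(2L, n_per_group), length(groups)), groups)
  if (!histology_given) histology_n <- pmin(histology_n, n_per_group)
  if (any(histology_n > n_per_group))
    qdti_stop("histology_n cannot exceed n_per_group", "qdti_config_error")
  structure(list(groups = groups, n_per_group = as.integer(n_per_group),
                 timepoints = timepoints, seed = as.integer(seed),
                 jitter_sd = jitter_sd, histology_n = histology_n),
            class = "cohort_spec")
}

#' Generate a synthetic study cohort
#'
#' For every subject x timepoint, builds the ground-truth tensor field from
#' the group/timepoint eigenvalue profiles (with per-subject multiplicative
#' jitter held constant across timepoints), simulates the DWI signal and
#' adds Rician noise using sub-seeds derived deterministically from the
#' master seed. Ground truth is stored losslessly (per-ROI eigenvalues and
#' tensors), so recovery error is always computable.
#'
#' @param phantom A `phantom_spec`.
#' @param cohort A `cohort_spec`.
#' @param dwi If `FALSE`, skip DWI synthesis and keep only ground truth
#'   (fast path for count-level studies).
#' @return An object of class `dwi_cohort` with fields `phantom`, `cohort`,
#'   `scheme`, `subjects` (data frame subject_id/group), `label_map`,
#'   `truth[[subject]][[timepoint]]` (per-ROI `lambdas` and `tensors`),
#'   `dwi[[subject]][[timepoint]]` (4-D arrays, or `NULL`), and `seeds`.
#' @export
generate_cohort <- function(phantom, cohort, dwi = TRUE) {
  stopifnot(inherits(phantom, "phantom_spec"), inherits(cohort, "cohort_spec"))
  need <- expand.grid(group = cohort$groups, timepoint = cohort$timepoints,
                      roi = unique(phantom$profiles$roi), stringsAsFactors = FALSE)
  key <- function(d) paste(d$group, d$timepoint, d$roi)
  missing <- setdiff(key(need), key(phantom$profiles))
  if (length(missing))
    qdti_stop(sprintf("no eigenvalue profile for: %s",
                      paste(missing, collapse = "; ")), "qdti_config_error")

  rois <- unique(phantom$profiles$roi)
  subjects <- data.frame(
    subject_id = unlist(lapply(cohort$groups, function(g)
      sprintf("%s_%02d", g, seq_len(cohort$n_per_group)))),
    group = rep(cohort$groups, each = cohort$n_per_group),
    stringsAsFactors = FALSE)

  scheme_seed <- derive_seed(cohort$seed, "scheme")
  scheme <- make_gradient_scheme(phantom$n_directions, phantom$b_value,
                                 seed = scheme_seed)

  prof <- phantom$profiles
  prof_row <- function(g, tp, roi)
    as.numeric(prof[prof$group == g & prof$timepoint == tp & prof$roi == roi,
                    c("l1", "l2", "l3")][1, ])

  lab <- phantom$label_map
  grid <- phantom$dim
  nvol <- length(scheme$bvals)

  truth <- list(); dwis <- list(); jit <- list(); noise_seeds <- list()
  for (i in seq_len(nrow(subjects))) {
    sid <- subjects$subject_id[i]; g <- subjects$group[i]
    jitter <- with_seed(derive_seed(cohort$seed, sid, "jitter"),
                        matrix(pmax(1 + stats::rnorm(length(rois) * 3,
                                                     sd = cohort$jitter_sd), 0.02),
                               length(rois), 3L, dimnames = list(rois, NULL)))
    jit[[sid]] <- jitter
    truth[[sid]] <- list(); dwis[[sid]] <- list(); noise_seeds[[sid]] <- list()
    for (tp in cohort$timepoints) {
      lambdas <- t(vapply(rois, function(roi)
        sort(prof_row(g, tp, roi) * jitter[roi, ], decreasing = TRUE),
        numeric(3)))
      tensors <- t(vapply(rois, function(roi)
        as.numeric(tensor_from_profile(lambdas[roi, ],
                                       phantom$principal_dirs[[roi]])),
        numeric(6)))
      truth[[sid]][[tp]] <- list(lambdas = lambdas, tensors = tensors)
      if (dwi) {
        roi_sig <- t(vapply(rois, function(roi)
          simulate_signal(tensors[roi, ], scheme, phantom$s0), numeric(nvol)))
        lookup <- rbind(0, roi_sig)              # row 1 = background
        clean <- array(lookup[cbind(rep(as.integer(lab) + 1L, nvol),
                                    rep(seq_len(nvol), each = length(lab)))],
                       c(grid, nvol))
        ns <- derive_seed(cohort$seed, sid, tp, "noise")
        noise_seeds[[sid]][[tp]] <- ns
        dwis[[sid]][[tp]] <- add_rician_noise(clean, phantom$sigma, seed = ns)
      }
    }
  }
  structure(list(phantom = phantom, cohort = cohort, scheme = scheme,
                 subjects = subjects, label_map = lab, rois = rois,
                 truth = truth, jitter = jit,
                 dwi = if (dwi) dwis else NULL,
                 seeds = list(master = cohort$seed, scheme = scheme_seed,
                              noise = noise_seeds)),
            class = "dwi_cohort")
}

#' @export
print.dwi_cohort <- function(x, ...) {
  cat(sprintf("<dwi_cohort> %d subjects (%s) x %d timepoints, grid %s, %s\n",
              nrow(x$subjects),
              paste(x$cohort$groups, collapse = "/"),
              length(x$cohort$timepoints),
              paste(x$phantom$dim, collapse = "x"),
              if (is.null(x$dwi)) "ground truth only" else "with DWI"))
  invisible(x)
}

#' Expand a subject's ground-truth tensor field
#'
#' @param cohort A `dwi_cohort`.
#' @param subject_id,timepoint Which volume to expand.
#' @return 4-D array `[X, Y, Z, 6]` (lower-triangular order), zero tensors
#'   in the background.
#' @export
truth_tensor_field <- function(cohort, subject_id, timepoint) {
  tr <- cohort$truth[[subject_id]][[timepoint]]
  if (is.null(tr)) qdti_stop("unknown subject/timepoint", "qdti_config_error")
  lab <- cohort$label_map
  lookup <- rbind(0, tr$tensors)
  grid <- dim(lab)
  array(lookup[cbind(rep(as.integer(lab) + 1L, 6L),
                     rep(1:6, each = length(lab)))], c(grid, 6L))
}

#' Ground-truth ROI metric table
#'
#' Long-format table of the four scalar metrics computed directly from each
#' subject's ground-truth per-ROI eigenvalues (no simulation or fitting
#' involved).
#'
#' @param cohort A `dwi_cohort`.
#' @return Data frame (subject_id, group, timepoint, roi, metric, value).
#' @export
truth_metric_table <- function(cohort) {
  rows <- list()
  for (i in seq_len(nrow(cohort$subjects))) {
    sid <- cohort$subjects$subject_id[i]
    for (tp in cohort$cohort$timepoints) {
      lam <- cohort$truth[[sid]][[tp]]$lambdas
      sc <- tensor_scalars(lam)
      for (m in .qdti_metrics)
        rows[[length(rows) + 1L]] <- data.frame(
          subject_id = sid, group = cohort$subjects$group[i], timepoint = tp,
          roi = rownames(lam), metric = m, value = sc[[m]],
          stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$subject_id, out$timepoint, out$roi, out$metric), ]
}

#' Default immunohistochemistry coupling
#'
#' Builds the per-(stain, ROI) linear models linking synthetic cell counts
#' to the region-mean pure anisotropy q of the final timepoint. GFAP
#' (astrocytes) and CD-68 (microglia) counts decrease with q; NeuN (neurons)
#' increases with q in gray matter (cortex, hippocampus), so that low
#' cortical q co-occurs with neuronal loss. For coupled rows the count noise
#' SD is calibrated so the population correlation between q and count equals
#' `target_r` for that stain, given the spread of q implied by the phantom
#' profiles, the jitter SD, and the histology subgroup weights; the spread
#' is evaluated by a fixed-seed Monte-Carlo draw (4000 per group) internal
#' to the calibration.
#'
#' @param phantom A `phantom_spec`.
#' @param cohort A `cohort_spec`.
#' @param target_r Named population correlations per stain (default GFAP
#'   -0.65, CD68 -0.30, NeuN +0.65).
#' @return Data frame (stain, roi, slope, intercept, sd): slope/intercept in
#'   counts per (mm^2/s) and counts; sd in counts.
#' @export
default_ihc_coupling <- function(phantom, cohort,
                                 target_r = c(GFAP = -0.65, CD68 = -0.30,
                                              NeuN = 0.65)) {
  rois <- unique(phantom$profiles$roi)
  tp <- utils::tail(cohort$timepoints, 1)
  hn <- cohort$histology_n
  w <- hn / sum(hn)

  # population mean/sd of q per ROI under jitter + group mixture
  qstat <- lapply(rois, function(roi) {
    ms <- vs <- numeric(length(hn))
    for (k in seq_along(hn)) {
      g <- names(hn)[k]
      l0 <- as.numeric(phantom$profiles[phantom$profiles$group == g &
                                        phantom$profiles$timepoint == tp &
                                        phantom$profiles$roi == roi,
                                        c("l1", "l2", "l3")][1, ])
      qs <- with_seed(derive_seed(760, roi, g, "ihc-calib"), {
        jf <- matrix(pmax(1 + stats::rnorm(4000 * 3, sd = cohort$jitter_sd), 0.02),
                     4000, 3)
        lam <- sweep(jf, 2L, l0, `*`)
        tensor_scalars(lam)$q
      })
      ms[k] <- mean(qs); vs[k] <- stats::var(qs)
    }
    mu <- sum(w * ms)
    list(mean = mu, sd = sqrt(sum(w * (vs + (ms - mu)^2))))
  })
  names(qstat) <- rois

  base_count <- function(stain, roi) {
    if (stain == "NeuN") return(if (roi == "cortex") 900 else if (roi == "HPC") 700 else 60)
    if (stain == "GFAP") 260 else 140
  }
  slope_of <- function(stain, roi) {
    if (stain == "GFAP") return(-3e5)
    if (stain == "CD68") return(-1.2e5)
    if (roi %in% c("cortex", "HPC")) 5e5 else 0   # NeuN coupled in gray matter only
  }
  rows <- list()
  for (stain in names(target_r)) for (roi in rois) {
    sl <- slope_of(stain, roi)
    r <- target_r[[stain]]
    sdev <- if (sl != 0) abs(sl) * qstat[[roi]]$sd * sqrt(1 / r^2 - 1) else 8
    rows[[length(rows) + 1L]] <- data.frame(
      stain = stain, roi = roi, slope = sl,
      intercept = base_count(stain, roi) - sl * qstat[[roi]]$mean,
      sd = sdev, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Generate synthetic immunohistochemistry counts
#'
#' Draws per-subject, per-ROI cell counts for the GFAP, CD-68 and NeuN
#' stains from linear models on the subject's ground-truth ROI-mean q at the
#' final timepoint: `count = round(max(0, intercept + slope * q + e))`,
#' `e ~ Normal(0, sd)`. Only the histology subgroup of each group (the first
#' `histology_n` subjects) receives counts, matching the unequal subgroup
#' design the statistics stage must handle.
#'
#' @param cohort A `dwi_cohort`.
#' @param coupling Coupling table as from [default_ihc_coupling()]; `NULL`
#'   uses the default.
#' @param seed Integer seed; default derived from the cohort master seed.
#' @return Data frame (subject_id, group, roi, stain, count, q_truth).
#' @export
generate_ihc_counts <- function(cohort, coupling = NULL, seed = NULL) {
  stopifnot(inherits(cohort, "dwi_cohort"))
  if (is.null(coupling))
    coupling <- default_ihc_coupling(cohort$phantom, cohort$cohort)
  if (any(coupling$sd < 0))
    qdti_stop("coupling SD must be non-negative", "qdti_invalid_parameter")
  if (is.null(seed)) seed <- derive_seed(cohort$seeds$master, "ihc")
  tp <- utils::tail(cohort$cohort$timepoints, 1)
  hn <- cohort$cohort$histology_n

  subs <- do.call(rbind, lapply(names(hn), function(g) {
    s <- cohort$subjects[cohort$subjects$group == g, , drop = FALSE]
    utils::head(s, hn[[g]])
  }))
  rows <- list()
  with_seed(seed, {
    for (i in seq_len(nrow(subs))) {
      sid <- subs$subject_id[i]
      lam <- cohort$truth[[sid]][[tp]]$lambdas
      qv <- stats::setNames(tensor_scalars(lam)$q, rownames(lam))
      for (j in seq_len(nrow(coupling))) {
        roi <- coupling$roi[j]
        mu <- coupling$intercept[j] + coupling$slope[j] * qv[[roi]]
        cnt <- round(max(0, mu + stats::rnorm(1, sd = coupling$sd[j])))
        rows[[length(rows) + 1L]] <- data.frame(
          subject_id = sid, group = subs$group[i], roi = roi,
          stain = coupling$stain[j], count = cnt, q_truth = qv[[roi]],
          stringsAsFactors = FALSE)
      }
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$stain, out$roi, out$subject_id), ]
}
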