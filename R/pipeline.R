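# Pipeline orchestration: one configuration object drives
# simulate -> fit -> decompose -> summarize -> test, reproducibly.

.config_sections <- c("out", "phantom", "cohort", "fit", "stats", "verbose")
.phantom_keys <- c("dim", "s0", "sigma", "b_value", "n_directions", "template")
.cohort_keys  <- c("groups", "n_per_group", "timepoints", "seed", "jitter_sd",
                   "histology_n")
.fit_keys     <- c("method")
.stats_keys   <- c("alpha", "posthoc_mode")

#' Build a pipeline run configuration
#'
#' A fully serializable description of one synthetic-study run: phantom and
#' cohort parameters, fitting method, statistics options and the master
#' seed. A saved configuration re-run with the same seed reproduces every
#' output byte-for-byte.
#'
#' @param out Output root directory.
#' @param phantom Named list overriding phantom defaults (`dim`, `s0`,
#'   `sigma`, `b_value`, `n_directions`, `template` = `"default"` or
#'   `"null"`).
#' @param cohort Named list overriding cohort defaults (`groups`,
#'   `n_per_group`, `timepoints`, `seed`, `jitter_sd`, `histology_n`).
#' @param fit Named list: `method` = `"loglinear"` or `"wls"`.
#' @param stats Named list: `alpha`, `posthoc_mode`.
#' @param verbose Emit progress messages.
#' @return Object of class `run_config`.
#' @export
run_config <- function(out = "qdti_run", phantom = list(), cohort = list(),
                       fit = list(), stats = list(), verbose = TRUE) {
  reject_unknown <- function(x, allowed, where) {
    bad <- setdiff(names(x), allowed)
    if (length(bad))
      qdti_stop(sprintf("unknown %s key(s): %s", where,
                        paste(bad, collapse = ", ")), "qdti_config_error")
    x
  }
  phantom <- utils::modifyList(
    list(dim = c(96, 96, 5), s0 = 1000, sigma = 1000 / 30, b_value = 1000,
         n_directions = 30, template = "default"),
    reject_unknown(phantom, .phantom_keys, "phantom"))
  histology_given <- "histology_n" %in% names(cohort)
  cohort <- utils::modifyList(
    list(groups = c("sham", "short", "long"), n_per_group = 6,
         timepoints = c("day50", "day90"), seed = 1, jitter_sd = 0.03,
         histology_n = c(sham = 4, short = 3, long = 4)),
    reject_unknown(cohort, .cohort_keys, "cohort"))
  if (!histology_given)
    cohort$histology_n <- pmin(cohort$histology_n, cohort$n_per_group)
  fit <- utils::modifyList(list(method = "loglinear"),
                           reject_unknown(fit, .fit_keys, "fit"))
  stats <- utils::modifyList(list(alpha = 0.05, posthoc_mode = "per_day"),
                             reject_unknown(stats, .stats_keys, "stats"))
  if (!phantom$template %in% c("default", "null"))
    qdti_stop("phantom$template must be 'default' or 'null'", "qdti_config_error")
  structure(list(out = out, phantom = phantom, cohort = cohort, fit = fit,
                 stats = stats, verbose = isTRUE(verbose)),
            class = "run_config")
}

#' Save / load a run configuration
#'
#' Configurations serialize to JSON (or YAML, if the `yaml` package is
#' available and the path ends in `.yaml`/`.yml`). Unknown keys in a loaded
#' document are rejected.
#'
#' @param config A `run_config`.
#' @param path File path (`.json`, `.yaml` or `.yml`).
#' @return `load_run_config()` returns a `run_config`; `save_run_config()`
#'   the path, invisibly.
#' @export
save_run_config <- function(config, path) {
  x <- unclass(config)
  x$cohort$histology_n <- as.list(x$cohort$histology_n)   # keep names in JSON
  if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      qdti_stop("the 'yaml' package is required for YAML configs", "qdti_io_error")
    yaml::write_yaml(x, path)
  } else {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' @rdname save_run_config
#' @export
load_run_config <- function(path) {
  if (!file.exists(path)) qdti_stop(sprintf("no such config: %s", path), "qdti_io_error")
  x <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      qdti_stop("the 'yaml' package is required for YAML configs", "qdti_io_error")
    yaml::read_yaml(path)
  } else jsonlite::read_json(path, simplifyVector = TRUE)
  bad <- setdiff(names(x), .config_sections)
  if (length(bad))
    qdti_stop(sprintf("unknown config key(s): %s", paste(bad, collapse = ", ")),
              "qdti_config_error")
  if (!is.null(x$cohort$histology_n)) x$cohort$histology_n <- unlist(x$cohort$histology_n)
  run_config(out = if (is.null(x$out)) "qdti_run" else x$out,
             phantom = as.list(x$phantom), cohort = as.list(x$cohort),
             fit = as.list(x$fit), stats = as.list(x$stats),
             verbose = isTRUE(x$verbose))
}

qdti_log <- function(config, stage, msg) {
  if (isTRUE(config$verbose))
    message(sprintf("%s [%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                    stage, msg))
}

config_specs <- function(config) {
  template <- if (config$phantom$template == "null") NULL else default_effect_template()
  ph <- phantom_spec(dim = config$phantom$dim, s0 = config$phantom$s0,
                     sigma = config$phantom$sigma,
                     profiles = build_profiles(template = template,
                                               groups = config$cohort$groups,
                                               timepoints = config$cohort$timepoints),
                     label_map = default_label_map(config$phantom$dim),
                     b_value = config$phantom$b_value,
                     n_directions = config$phantom$n_directions)
  co <- cohort_spec(groups = config$cohort$groups,
                    n_per_group = config$cohort$n_per_group,
                    timepoints = config$cohort$timepoints,
                    seed = config$cohort$seed,
                    jitter_sd = config$cohort$jitter_sd,
                    histology_n = config$cohort$histology_n)
  list(phantom = ph, cohort = co)
}

#' Simulate a cohort to disk
#'
#' Generates the synthetic cohort described by the configuration and writes
#' it under `<out>/cohort`: DWI NIfTI volumes, bval/bvec, label map with
#' JSON sidecar, synthetic histology counts CSV, manifest, and a snapshot
#' of the configuration itself.
#'
#' @param config A `run_config`.
#' @return The cohort directory, invisibly.
#' @export
run_simulate <- function(config) {
  sp <- config_specs(config)
  qdti_log(config, "simulate",
           sprintf("generating cohort (seed %d, grid %s)",
                   sp$cohort$seed, paste(sp$phantom$dim, collapse = "x")))
  cohort <- generate_cohort(sp$phantom, sp$cohort, dwi = TRUE)
  cdir <- file.path(config$out, "cohort")
  write_cohort(cohort, cdir)
  counts <- generate_ihc_counts(cohort)
  utils::write.csv(counts, file.path(cdir, "ihc_counts.csv"), row.names = FALSE)
  save_run_config(config, file.path(config$out, "config.json"))
  qdti_log(config, "simulate",
           sprintf("wrote %d DWI volumes to %s",
                   nrow(cohort$subjects) * length(sp$cohort$timepoints), cdir))
  invisible(cdir)
}

#' Analyze a cohort on disk
#'
#' Reads a cohort directory, fits the tensor per voxel, writes per-subject
#' MD/FA/L/q NIfTI maps, assembles the cohort metric table, runs the
#' statistical battery (rmANOVA + Bonferroni post hocs per ROI x metric;
#' one-way ANOVA + Tukey on the histology counts; q-vs-count correlations)
#' and writes the results CSV plus a plain-text report.
#'
#' @param config A `run_config`.
#' @param cohort_dir Cohort directory (default `<out>/cohort`).
#' @return Named list of output paths, invisibly.
#' @export
run_analyze <- function(config, cohort_dir = file.path(config$out, "cohort")) {
  cohort <- read_cohort(cohort_dir)
  qdti_log(config, "analyze", sprintf("fitting %d subject-timepoints (%s)",
                                      nrow(cohort$subjects) *
                                        length(cohort$cohort$timepoints),
                                      config$fit$method))
  mask <- array(cohort$label_map > 0L, dim(cohort$label_map))
  maps_dir <- file.path(config$out, "maps")
  means <- list(); n_nonphys <- 0L; n_clip <- 0L
  for (sid in cohort$subjects$subject_id) {
    means[[sid]] <- list()
    for (tp in cohort$cohort$timepoints) {
      fit <- fit_tensor_field(cohort$dwi[[sid]][[tp]], cohort$scheme,
                              mask = mask, method = config$fit$method)
      n_clip <- n_clip + fit$n_clipped
      maps <- compute_metric_maps(fit$tensor_field, mask = mask)
      n_nonphys <- n_nonphys + maps$n_nonphysical
      write_metric_maps(maps, maps_dir, sprintf("%s_%s", sid, tp))
      means[[sid]][[tp]] <- extract_roi_means(maps, cohort$label_map,
                                              rois = cohort$rois)
    }
  }
  table <- assemble_cohort_table(cohort, means)
  tpath <- file.path(config$out, "metric_table.csv")
  utils::write.csv(table, tpath, row.names = FALSE)

  stats <- run_group_stats(table, alpha = config$stats$alpha,
                           posthoc_mode = config$stats$posthoc_mode)
  cpath <- file.path(cohort_dir, "ihc_counts.csv")
  corr <- NULL
  if (file.exists(cpath)) {
    counts <- utils::read.csv(cpath, stringsAsFactors = FALSE)
    stats <- rbind(stats, run_ihc_stats(counts, alpha = config$stats$alpha))
    corr <- run_metric_ihc_correlations(table, counts)
  }
  spath <- file.path(config$out, "stats.csv")
  utils::write.csv(stats, spath, row.names = FALSE)

  rpath <- file.path(config$out, "report.txt")
  sig <- stats[stats$significant, ]
  lines <- c("qdti run report",
             sprintf("cohort: %s", cohort_dir),
             sprintf("subjects: %d  timepoints: %d  seed: %d",
                     nrow(cohort$subjects), length(cohort$cohort$timepoints),
                     cohort$seeds$master),
             sprintf("fit: %s  clipped samples: %d  non-physical voxels: %d",
                     config$fit$method, n_clip, n_nonphys),
             sprintf("tests run: %d  significant at alpha=%g: %d",
                     nrow(stats), config$stats$alpha, nrow(sig)),
             if (nrow(sig)) paste("  *", sig$test, sig$roi, sig$metric,
                                  sig$effect, sprintf("p=%.4g", sig$p)))
  if (!is.null(corr))
    lines <- c(lines, "q-vs-histology correlations:",
               sprintf("  %s %s: r=%.3f (n=%d, p=%.3g)", corr$roi, corr$stain,
                       corr$r, corr$n, corr$p))
  writeLines(lines, rpath)
  qdti_log(config, "analyze", sprintf("wrote %s, %s, %s", tpath, spath, rpath))
  invisible(list(metric_table = tpath, stats = spath, report = rpath,
                 maps = maps_dir))
}

#' Run the whole pipeline
#'
#' [run_simulate()] followed by [run_analyze()]: one command reproduces the
#' entire synthetic study from a configuration and seed.
#'
#' @param config A `run_config`.
#' @return Output paths from [run_analyze()], invisibly.
#' @export
run_all <- function(config) {
  cdir <- run_simulate(config)
  run_analyze(config, cdir)
}
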