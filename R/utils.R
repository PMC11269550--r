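# Shared internal helpers: ROI/metric vocabularies, seed streams, RNG scoping.

.qdti_rois    <- c("cortex", "CC", "HPC", "mCC", "EC", "IC")
.qdti_metrics <- c("MD", "FA", "L", "q")

#' ROI and metric vocabularies
#'
#' The six labeled regions analyzed by the pipeline (sensorimotor cortex,
#' corpus callosum under the impact site, hippocampus, medial corpus
#' callosum, external capsule, internal capsule) and the four tensor scalar
#' metrics.
#'
#' @return Character vector of ROI names or metric names.
#' @export
roi_vocabulary <- function() .qdti_rois

#' @rdname roi_vocabulary
#' @export
metric_vocabulary <- function() .qdti_metrics

#' Derive a reproducible sub-seed from a master seed and labels
#'
#' Hashes the master seed together with an arbitrary sequence of labels
#' (subject id, timepoint, purpose, ...) into an integer below 2^31 so that
#' every stochastic stage of a simulation draws from its own independent,
#' reproducible stream.
#'
#' @param master Integer master seed.
#' @param ... Labels (coerced to character) identifying the sub-stream.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(master, ...) {
  if (!is.numeric(master) || length(master) != 1L || !is.finite(master))
    stop("`master` must be a single finite number", call. = FALSE)
  labels <- paste(vapply(list(...), function(x) paste(as.character(x), collapse = ","),
                         character(1)), collapse = "/")
  h <- abs(as.double(master)) %% 2147483647
  for (code in utf8ToInt(labels)) h <- (h * 31 + code) %% 2147483647
  as.integer(h)
}

# Evaluate `expr` under `seed` without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) stats::runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

# stop() with a class so callers/tests can condition on the failure mode
qdti_stop <- function(msg, class) {
  stop(structure(class = c(class, "qdti_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}
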