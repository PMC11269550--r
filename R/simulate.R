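# DWI signal simulation: gradient schemes, the monoexponential tensor signal
# model S = S0 * exp(-b g' D g), and Rician (magnitude-MRI) noise.

#' Generate a diffusion gradient scheme
#'
#' Builds one b = 0 volume plus `n_directions` approximately uniform unit
#' direction vectors on the sphere (spherical Fibonacci spiral, rotated by a
#' seed-derived random rotation so different seeds give different but equally
#' uniform layouts).
#'
#' @param n_directions Number of diffusion-weighted directions, at least 6
#'   (tensor identifiability).
#' @param b_value b-factor for the weighted volumes, s/mm^2.
#' @param seed Integer seed for the orienting rotation; `NULL` keeps the
#'   canonical spiral.
#' @return An object of class `gradient_scheme`: list with `bvals` (length
#'   n_directions + 1, the b = 0 entry first) and `bvecs` (3 x (n_directions
#'   + 1) matrix of unit columns, zero column for b = 0).
#' @examples
#' sch <- make_gradient_scheme(30, b_value = 1000, seed = 1)
#' @export
make_gradient_scheme <- function(n_directions, b_value = 1000, seed = NULL) {
  if (n_directions < 6L)
    qdti_stop("at least 6 directions are required for tensor identifiability",
              "qdti_identifiability_error")
  if (b_value <= 0)
    qdti_stop("`b_value` must be positive", "qdti_invalid_parameter")
  if (n_directions == 6L) {
    # icosahedral vertex set: the classic minimal identifiable DTI scheme
    # (the 6-point golden-angle spiral is degenerate in quadratic-form space)
    gr <- (1 + sqrt(5)) / 2
    g <- cbind(c(1, gr, 0), c(-1, gr, 0), c(0, 1, gr),
               c(0, -1, gr), c(gr, 0, 1), c(gr, 0, -1))
  } else {
    # Fibonacci spiral on the sphere: near-uniform for any n
    i <- seq_len(n_directions) - 0.5
    phi <- pi * (1 + sqrt(5)) * i
    z <- 1 - 2 * i / n_directions
    r <- sqrt(pmax(1 - z^2, 0))
    g <- rbind(r * cos(phi), r * sin(phi), z)
  }
  if (!is.null(seed)) {
    rot <- with_seed(seed, qr.Q(qr(matrix(stats::rnorm(9), 3L, 3L))))
    if (det(rot) < 0) rot[, 1] <- -rot[, 1]
    g <- rot %*% g
  }
  g <- g / rep(sqrt(colSums(g^2)), each = 3L)
  scheme <- structure(list(bvals = c(0, rep(b_value, n_directions)),
                           bvecs = cbind(c(0, 0, 0), g)),
                      class = "gradient_scheme")
  if (qr(build_design_matrix(scheme))$rank < 7L)
    qdti_stop("generated directions are collinear; tensor not identifiable",
              "qdti_identifiability_error")
  scheme
}

#' @export
print.gradient_scheme <- function(x, ...) {
  cat(sprintf("<gradient_scheme> %d volumes (%d b=0, %d b=%g s/mm^2)\n",
              length(x$bvals), sum(x$bvals == 0), sum(x$bvals > 0),
              max(x$bvals)))
  invisible(x)
}

#' Simulate the noise-free DWI signal of a tensor
#'
#' Monoexponential tensor signal model: `S = s0 * exp(-b * g' D g)` per
#' scheme entry; b = 0 entries return `s0` exactly.
#'
#' @param tensor A `dti_tensor` (or 6-vector / 3x3 matrix), mm^2/s.
#' @param scheme A `gradient_scheme`.
#' @param s0 Baseline (b = 0) signal, arbitrary units, positive.
#' @return Numeric vector of signals, one per scheme volume.
#' @export
simulate_signal <- function(tensor, scheme, s0 = 1000) {
  if (s0 <= 0) qdti_stop("`s0` must be positive", "qdti_invalid_parameter")
  m <- tensor_matrix(tensor)
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 0)
    warning("non-physical tensor (negative eigenvalue); signal computed anyway",
            call. = FALSE)
  adc <- colSums(scheme$bvecs * (m %*% scheme$bvecs))   # g' D g per volume
  as.numeric(s0 * exp(-scheme$bvals * adc))
}

#' Add Rician noise to magnitude signals
#'
#' Corrupts signals with the magnitude-MRI noise model
#' `sqrt((S + e1)^2 + e2^2)` with `e1, e2 ~ Normal(0, sigma^2)`. `sigma = 0`
#' returns the input unchanged; a fixed seed makes the draw reproducible.
#'
#' @param signal Numeric vector (or array) of noise-free magnitudes.
#' @param sigma Noise standard deviation of each Gaussian channel, same
#'   units as `signal`; must be non-negative.
#' @param seed Optional integer seed.
#' @return Noisy magnitudes with the shape of `signal`.
#' @export
add_rician_noise <- function(signal, sigma, seed = NULL) {
  if (!is.numeric(sigma) || length(sigma) != 1L || is.na(sigma) || sigma < 0)
    qdti_stop("`sigma` must be a single non-negative number", "qdti_invalid_parameter")
  if (sigma == 0) return(signal)
  n <- length(signal)
  noisy <- with_seed(seed, {
    e1 <- stats::rnorm(n, sd = sigma)
    e2 <- stats::rnorm(n, sd = sigma)
    sqrt((as.numeric(signal) + e1)^2 + e2^2)
  })
  if (!is.null(dim(signal))) dim(noisy) <- dim(signal)
  noisy
}
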