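# Tensor estimation: ordinary log-linear least squares per voxel, with an
# optional one-pass weighted refinement (weights = squared predicted
# signals, the usual variance stabilization for log-transformed Rician
# magnitudes at moderate SNR).

#' Design matrix of the log-linear tensor model
#'
#' One row per scheme volume mapping the parameter vector
#' (Dxx, Dxy, Dyy, Dxz, Dyz, Dzz, ln S0) to the log-signal:
#' `(-b gx^2, -2b gx gy, -b gy^2, -2b gx gz, -2b gy gz, -b gz^2, 1)`.
#' Column order matches the package's lower-triangular tensor storage.
#'
#' @param scheme A `gradient_scheme`.
#' @return Numeric matrix, `n_volumes x 7`, rank 7 for identifiable schemes.
#' @export
build_design_matrix <- function(scheme) {
  b <- scheme$bvals
  g <- scheme$bvecs
  X <- cbind(-b * g[1, ]^2,
             -2 * b * g[1, ] * g[2, ],
             -b * g[2, ]^2,
             -2 * b * g[1, ] * g[3, ],
             -2 * b * g[2, ] * g[3, ],
             -b * g[3, ]^2,
             1)
  colnames(X) <- c("dxx", "dxy", "dyy", "dxz", "dyz", "dzz", "log_s0")
  X
}

# signals -> clipped log-signals; returns list(log_signal, n_clipped)
clip_log <- function(signals, min_signal) {
  n_clipped <- sum(signals < min_signal)
  list(y = log(pmax(signals, min_signal)), n_clipped = n_clipped)
}

default_min_signal <- function(signals, scheme) {
  s0_hat <- mean(signals[scheme$bvals == 0])
  max(1e-6 * s0_hat, .Machine$double.xmin)
}

fit_result <- function(beta, X, y, n_clipped) {
  tensor <- dti_tensor(dxx = beta[1], dyy = beta[3], dzz = beta[6],
                       dxy = beta[2], dxz = beta[4], dyz = beta[5])
  ev <- eigen(tensor_matrix(tensor), symmetric = TRUE, only.values = TRUE)$values
  structure(list(tensor = tensor,
                 log_s0 = unname(beta[7]),
                 s0 = exp(unname(beta[7])),
                 residual_norm = sqrt(sum((y - X %*% beta)^2)),
                 nonphysical = min(ev) < 0,
                 n_clipped = n_clipped),
            class = "tensor_fit")
}

#' @export
print.tensor_fit <- function(x, ...) {
  cat(sprintf("<tensor_fit> s0 = %.4g, residual = %.3g%s\n", x$s0,
              x$residual_norm, if (x$nonphysical) " [non-physical]" else ""))
  print(x$tensor)
  invisible(x)
}

#' Fit a diffusion tensor to one voxel's signals
#'
#' `fit_tensor_loglinear()` performs ordinary least squares on log-signals;
#' `fit_tensor_wls()` adds one weighted refit with weights equal to the
#' squared signals predicted by the log-linear pass. Both recover the
#' generating tensor exactly on noiseless data. Signals below `min_signal`
#' are clipped before the log; the number of clipped entries is reported in
#' the result.
#'
#' @param signals Numeric vector of DWI magnitudes, one per scheme volume.
#' @param scheme A `gradient_scheme`.
#' @param min_signal Positive clipping floor; default `1e-6` times the mean
#'   b = 0 signal.
#' @return An object of class `tensor_fit`: `tensor` (a `dti_tensor`),
#'   `log_s0`, `s0`, `residual_norm`, `nonphysical` flag (any eigenvalue
#'   < 0) and `n_clipped`.
#' @export
fit_tensor_loglinear <- function(signals, scheme, min_signal = NULL) {
  X <- build_design_matrix(scheme)
  if (length(signals) != nrow(X))
    qdti_stop("signal length does not match scheme", "qdti_dim_error")
  if (length(signals) < 7L)
    qdti_stop("at least 7 volumes are required", "qdti_identifiability_error")
  if (qr(X)$rank < 7L)
    qdti_stop("rank-deficient design: directions do not identify the tensor",
              "qdti_identifiability_error")
  if (is.null(min_signal)) min_signal <- default_min_signal(signals, scheme)
  cl <- clip_log(signals, min_signal)
  beta <- qr.coef(qr(X), cl$y)
  fit_result(beta, X, cl$y, cl$n_clipped)
}

#' @rdname fit_tensor_loglinear
#' @export
fit_tensor_wls <- function(signals, scheme, min_signal = NULL) {
  first <- fit_tensor_loglinear(signals, scheme, min_signal)
  X <- build_design_matrix(scheme)
  if (is.null(min_signal)) min_signal <- default_min_signal(signals, scheme)
  cl <- clip_log(signals, min_signal)
  beta0 <- c(unclass(first$tensor), first$log_s0)
  w <- as.numeric(exp(X %*% beta0))^2          # predicted-signal^2 weights
  sw <- sqrt(w)
  beta <- qr.coef(qr(X * sw), cl$y * sw)
  out <- fit_result(beta, X, cl$y, cl$n_clipped)
  out$residual_norm <- sqrt(sum(w * (cl$y - X %*% beta)^2))
  out
}

#' Fit a tensor field to a 4-D DWI volume
#'
#' Applies the per-voxel fit to every voxel inside a mask. The log-linear
#' method is solved for all voxels in one matrix operation; the WLS
#' refinement loops over voxels.
#'
#' @param dwi 4-D array `[X, Y, Z, n_volumes]`.
#' @param scheme A `gradient_scheme` matching the 4th dimension.
#' @param mask Logical 3-D array; voxels outside are not fitted (left `NA`).
#' @param method `"loglinear"` (default) or `"wls"`.
#' @param min_signal Clipping floor; default per voxel as in the scalar fit.
#' @return A list: `tensor_field` (4-D `[X, Y, Z, 6]`, lower-triangular
#'   order, `NA` outside the mask), `log_s0` and `residual_norm` 3-D maps,
#'   and `n_clipped` (total clipped samples).
#' @export
fit_tensor_field <- function(dwi, scheme, mask = NULL,
                             method = c("loglinear", "wls"),
                             min_signal = NULL) {
  method <- match.arg(method)
  d <- dim(dwi)
  if (length(d) != 4L || d[4] != length(scheme$bvals))
    qdti_stop("DWI 4th dimension does not match the gradient scheme",
              "qdti_dim_error")
  grid <- d[1:3]
  if (is.null(mask)) mask <- array(TRUE, grid)
  if (!all(dim(mask) == grid))
    qdti_stop("mask grid does not match DWI grid", "qdti_dim_error")
  idx <- which(array(as.logical(mask), grid))
  S <- matrix(dwi, nrow = prod(grid))[idx, , drop = FALSE]   # voxels x volumes

  X <- build_design_matrix(scheme)
  if (qr(X)$rank < 7L)
    qdti_stop("rank-deficient design", "qdti_identifiability_error")
  if (is.null(min_signal)) {
    s0_hat <- rowMeans(S[, scheme$bvals == 0, drop = FALSE])
    floor_vox <- pmax(1e-6 * s0_hat, .Machine$double.xmin)
  } else floor_vox <- rep(min_signal, length(idx))
  n_clipped <- sum(S < floor_vox)
  Y <- log(pmax(S, floor_vox))                               # voxels x volumes

  if (method == "loglinear") {
    beta <- t(qr.coef(qr(X), t(Y)))                          # voxels x 7
  } else {
    beta <- matrix(NA_real_, length(idx), 7L)
    for (i in seq_len(length(idx))) {
      f <- fit_tensor_wls(S[i, ], scheme, min_signal = floor_vox[i])
      beta[i, ] <- c(unclass(f$tensor), f$log_s0)
    }
  }
  resid <- sqrt(rowSums((Y - beta %*% t(X))^2))

  tensor_field <- array(NA_real_, c(grid, 6L))
  nvox <- prod(grid)
  for (k in 1:6) tensor_field[idx + (k - 1L) * nvox] <- beta[, k]
  log_s0 <- array(NA_real_, grid); log_s0[idx] <- beta[, 7L]
  rn <- array(NA_real_, grid); rn[idx] <- resid
  list(tensor_field = tensor_field, log_s0 = log_s0,
       residual_norm = rn, n_clipped = n_clipped)
}
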