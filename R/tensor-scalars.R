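# Tensor scalar core: the diffusion tensor data model and the four scalar
# metrics MD, FA, L, q computed from its eigenvalues.
#
# The apparent diffusion tensor D is a symmetric 3x3 matrix of diffusivities
# (mm^2/s). Its eigenvalues lambda1 >= lambda2 >= lambda3 carry all the
# information the scalar metrics use:
#
#   MD = lambda_bar = (l1 + l2 + l3) / 3          mean diffusivity
#   L  = sqrt(l1^2 + l2^2 + l3^2)                 total diffusion magnitude
#                                                 (= Frobenius norm of D)
#   q  = sqrt(sum_i (l_i - lambda_bar)^2)         pure anisotropy
#   FA = sqrt(3/2) * q / L                        fractional anisotropy
#
# Algebraically q^2 + 3 MD^2 = L^2, so FA folds the anisotropic component q
# and the magnitude L into a single normalized index; q and L keep the two
# components separate, which is the point of carrying all four.

#' Construct a diffusion tensor
#'
#' Builds the six-component representation of a symmetric 3x3 apparent
#' diffusion tensor. Components are stored in lower-triangular order
#' (Dxx, Dxy, Dyy, Dxz, Dyz, Dzz), the order used for 4-D tensor NIfTI
#' volumes throughout the package.
#'
#' @param dxx,dyy,dzz Diagonal diffusivities, mm^2/s.
#' @param dxy,dxz,dyz Off-diagonal diffusivities, mm^2/s.
#' @return A named numeric vector of class `dti_tensor`.
#' @examples
#' dti_tensor(1.7e-3, 0.3e-3, 0.2e-3)
#' @export
dti_tensor <- function(dxx, dyy, dzz, dxy = 0, dxz = 0, dyz = 0) {
  x <- c(dxx = dxx, dxy = dxy, dyy = dyy, dxz = dxz, dyz = dyz, dzz = dzz)
  if (!is.numeric(x) || length(x) != 6L)
    qdti_stop("tensor components must be six numbers", "qdti_invalid_input")
  structure(as.double(x), names = names(x), class = "dti_tensor")
}

#' @export
print.dti_tensor <- function(x, ...) {
  cat("<dti_tensor> (mm^2/s)\n")
  print(tensor_matrix(x))
  invisible(x)
}

#' Convert between 6-component tensors and 3x3 symmetric matrices
#'
#' @param tensor A `dti_tensor`, a 6-vector in lower-triangular order
#'   (Dxx, Dxy, Dyy, Dxz, Dyz, Dzz), or a 3x3 symmetric matrix.
#' @return `tensor_matrix()` returns the 3x3 symmetric matrix;
#'   `as_tensor6()` the 6-component `dti_tensor`.
#' @export
tensor_matrix <- function(tensor) {
  if (is.matrix(tensor)) {
    if (!all(dim(tensor) == c(3L, 3L)))
      qdti_stop("tensor matrix must be 3x3", "qdti_invalid_input")
    return(tensor)
  }
  t6 <- unclass(tensor)
  if (!is.numeric(t6) || length(t6) != 6L)
    qdti_stop("tensor must have six components", "qdti_invalid_input")
  matrix(c(t6[1], t6[2], t6[4],
           t6[2], t6[3], t6[5],
           t6[4], t6[5], t6[6]), 3L, 3L)
}

#' @rdname tensor_matrix
#' @export
as_tensor6 <- function(tensor) {
  m <- tensor_matrix(tensor)
  dti_tensor(dxx = m[1, 1], dyy = m[2, 2], dzz = m[3, 3],
             dxy = m[1, 2], dxz = m[1, 3], dyz = m[2, 3])
}

#' Eigendecompose a diffusion tensor
#'
#' Returns the eigenvalues of the symmetric tensor sorted descending
#' (lambda1 >= lambda2 >= lambda3), their mean lambda_bar (which equals MD),
#' and the matching eigenvectors.
#'
#' @inheritParams tensor_matrix
#' @return An object of class `eigen_spectrum` with fields `lambda1`,
#'   `lambda2`, `lambda3`, `lambda_bar` and `vectors` (3x3, columns matched
#'   to the sorted eigenvalues).
#' @examples
#' eigen_decompose(dti_tensor(1.7e-3, 0.3e-3, 0.2e-3))
#' @export
eigen_decompose <- function(tensor) {
  m <- tensor_matrix(tensor)
  if (!all(is.finite(m)))
    qdti_stop("tensor components must be finite", "qdti_invalid_input")
  e <- eigen(m, symmetric = TRUE)
  structure(list(lambda1 = e$values[1], lambda2 = e$values[2],
                 lambda3 = e$values[3], lambda_bar = mean(e$values),
                 vectors = e$vectors),
            class = "eigen_spectrum")
}

#' @export
print.eigen_spectrum <- function(x, ...) {
  cat(sprintf("<eigen_spectrum> lambda = (%.4g, %.4g, %.4g), lambda_bar = %.4g mm^2/s\n",
              x$lambda1, x$lambda2, x$lambda3, x$lambda_bar))
  invisible(x)
}

# Accept an eigen_spectrum, a length-3 numeric vector of eigenvalues, or a
# tensor; always return eigenvalues sorted descending.
as_lambdas <- function(spec) {
  if (inherits(spec, "eigen_spectrum"))
    return(c(spec$lambda1, spec$lambda2, spec$lambda3))
  if (is.numeric(spec) && length(spec) == 3L) {
    if (!all(is.finite(spec)))
      qdti_stop("eigenvalues must be finite", "qdti_invalid_input")
    return(sort(spec, decreasing = TRUE))
  }
  e <- eigen_decompose(spec)
  c(e$lambda1, e$lambda2, e$lambda3)
}

#' Scalar metrics from an eigenvalue spectrum
#'
#' `compute_md()`, `compute_L()`, `compute_q()` and `compute_fa()` evaluate
#' the four tensor scalar metrics from an eigenvalue spectrum (or directly
#' from a tensor). FA is defined as 0 at the zero tensor (continuity
#' convention) and clamped to `[0, 1]`; negative eigenvalues from noisy fits
#' are retained for MD, L and q so that diffusivity summaries stay unbiased.
#'
#' @param spec An `eigen_spectrum`, a numeric vector of three eigenvalues
#'   (mm^2/s), or anything `eigen_decompose()` accepts.
#' @return A single diffusivity (mm^2/s), or a dimensionless value in
#'   `[0, 1]` for `compute_fa()`.
#' @examples
#' lam <- c(1.7, 0.3, 0.2) * 1e-3
#' compute_md(lam); compute_L(lam); compute_q(lam); compute_fa(lam)
#' @export
compute_md <- function(spec) mean(as_lambdas(spec))

#' @rdname compute_md
#' @export
compute_L <- function(spec) sqrt(sum(as_lambdas(spec)^2))

#' @rdname compute_md
#' @export
compute_q <- function(spec) {
  lam <- as_lambdas(spec)
  sqrt(sum((lam - mean(lam))^2))
}

#' @rdname compute_md
#' @export
compute_fa <- function(spec) {
  lam <- as_lambdas(spec)
  L <- sqrt(sum(lam^2))
  if (L == 0) return(0)
  q <- sqrt(sum((lam - mean(lam))^2))
  min(max(sqrt(1.5) * q / L, 0), 1)
}

#' Vectorized scalar metrics for many spectra
#'
#' Evaluates MD, FA, L and q for a matrix of eigenvalue triples, one row per
#' voxel. Rows need not be sorted; all four metrics are symmetric functions
#' of the spectrum. A `nonphysical` flag marks rows with any negative
#' eigenvalue (FA for those rows is still reported, clamped to `[0, 1]`).
#'
#' @param lambdas Numeric matrix with 3 columns (eigenvalues, mm^2/s), or a
#'   single length-3 vector.
#' @return A data frame with columns `MD`, `FA`, `L`, `q`, `nonphysical`.
#' @export
tensor_scalars <- function(lambdas) {
  if (is.null(dim(lambdas))) lambdas <- matrix(lambdas, ncol = 3L)
  if (ncol(lambdas) != 3L)
    qdti_stop("`lambdas` must have three columns", "qdti_invalid_input")
  md <- rowMeans(lambdas)
  L  <- sqrt(rowSums(lambdas^2))
  q  <- sqrt(rowSums((lambdas - md)^2))
  fa <- ifelse(L > 0, pmin(pmax(sqrt(1.5) * q / L, 0), 1), 0)
  data.frame(MD = md, FA = fa, L = L, q = q,
             nonphysical = apply(lambdas < 0, 1L, any))
}

# Eigenvalues (sorted descending) for a matrix of 6-component tensors,
# one row per voxel, lower-triangular order.
eigvals_many <- function(t6) {
  if (is.null(dim(t6))) t6 <- matrix(t6, ncol = 6L)
  n <- nrow(t6)
  out <- matrix(NA_real_, n, 3L)
  for (i in seq_len(n)) {
    m <- matrix(c(t6[i, 1], t6[i, 2], t6[i, 4],
                  t6[i, 2], t6[i, 3], t6[i, 5],
                  t6[i, 4], t6[i, 5], t6[i, 6]), 3L, 3L)
    out[i, ] <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  }
  out
}

#' Voxel-wise scalar metric maps from a tensor field
#'
#' Applies the four scalar metrics to every voxel of a tensor field inside a
#' mask. Outside-mask voxels are set to `fill`.
#'
#' @param tensor_field 4-D array `[X, Y, Z, 6]` of tensor components in
#'   lower-triangular order (Dxx, Dxy, Dyy, Dxz, Dyz, Dzz), mm^2/s.
#' @param mask Logical (or 0/1) 3-D array on the same grid; `NULL` means all
#'   voxels.
#' @param fill Value written outside the mask (default `NA`).
#' @return A list with 3-D arrays `MD`, `FA`, `L`, `q`, a logical array
#'   `nonphysical` flagging voxels whose fitted tensor has a negative
#'   eigenvalue, and the count `n_nonphysical`.
#' @export
compute_metric_maps <- function(tensor_field, mask = NULL, fill = NA_real_) {
  d <- dim(tensor_field)
  if (length(d) != 4L || d[4] != 6L)
    qdti_stop("`tensor_field` must be a 4-D array with 6 components", "qdti_dim_error")
  grid <- d[1:3]
  if (is.null(mask)) mask <- array(TRUE, grid)
  if (!all(dim(mask) == grid))
    qdti_stop("mask grid does not match tensor field grid", "qdti_dim_error")
  mask <- array(as.logical(mask), grid)
  idx <- which(mask)
  nvox <- prod(grid)
  t6 <- matrix(tensor_field, nrow = nvox, ncol = 6L)[idx, , drop = FALSE]
  if (!all(is.finite(t6)))
    qdti_stop("tensor field has non-finite components inside the mask",
              "qdti_invalid_input")
  lam <- eigvals_many(t6)
  sc <- tensor_scalars(lam)
  blank <- array(fill, grid)
  maps <- list(MD = blank, FA = blank, L = blank, q = blank)
  for (m in names(maps)) maps[[m]][idx] <- sc[[m]]
  nonphys <- array(FALSE, grid)
  nonphys[idx] <- sc$nonphysical
  c(maps, list(nonphysical = nonphys, n_nonphysical = sum(sc$nonphysical)))
}
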