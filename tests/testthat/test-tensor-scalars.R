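# Scalar metric core: eigendecomposition, MD/FA/L/q, and their algebraic
# identities.

test_that("isotropic and diagonal tensors decompose to their diagonals", {
  iso <- eigen_decompose(dti_tensor(7e-4, 7e-4, 7e-4))
  expect_equal(c(iso$lambda1, iso$lambda2, iso$lambda3), rep(7e-4, 3))
  expect_equal(iso$lambda_bar, 7e-4)

  dg <- eigen_decompose(dti_tensor(1.7e-3, 0.3e-3, 0.2e-3))
  expect_equal(c(dg$lambda1, dg$lambda2, dg$lambda3), c(1.7, 0.3, 0.2) * 1e-3)
  expect_equal(dg$lambda_bar, 2.2e-3 / 3)
})

test_that("non-finite tensor components are rejected", {
  expect_error(eigen_decompose(dti_tensor(NaN, 1e-3, 1e-3)),
               class = "qdti_invalid_input")
  expect_error(eigen_decompose(dti_tensor(Inf, 1e-3, 1e-3)),
               class = "qdti_invalid_input")
})

test_that("eigenvalues match the characteristic-polynomial oracle", {
  set.seed(11)
  for (i in 1:50) {
    m <- tensor_matrix(rand_tensors(1)$t6[1, ])
    e <- eigen_decompose(m)
    expect_equal(c(e$lambda1, e$lambda2, e$lambda3), oracle_cubic_eigvals(m),
                 tolerance = 1e-12)
  }
})

test_that("the four scalars reproduce their closed forms", {
  lam <- c(1.7, 0.3, 0.2) * 1e-3
  expect_equal(compute_md(lam), 2.2e-3 / 3)
  # frozen high-precision evaluations of the defining formulas
  expect_equal(compute_L(lam), 1.737814719698277e-03, tolerance = 1e-10)
  expect_equal(compute_q(lam), 1.186029791643813e-03, tolerance = 1e-10)
  expect_equal(compute_fa(lam), 8.358681096254011e-01, tolerance = 1e-10)

  d <- 1.4e-3
  expect_equal(compute_md(c(d, d, d)), d)
  expect_equal(compute_q(c(d, d, d)), 0)
  expect_equal(compute_fa(c(d, d, d)), 0)
  expect_equal(compute_L(c(d, d, d)), d * sqrt(3))
  expect_equal(compute_L(c(d, 0, 0)), d)
  expect_equal(compute_q(c(d, 0, 0)), d * sqrt(2 / 3))
  expect_equal(compute_fa(c(d, 0, 0)), 1)
})

test_that("MD equals trace/3 of the originating tensor", {
  set.seed(4)
  tens <- rand_tensors(20)
  for (i in 1:20) {
    m <- tensor_matrix(tens$t6[i, ])
    expect_equal(compute_md(eigen_decompose(m)), sum(diag(m)) / 3,
                 tolerance = 1e-12)
  }
})

test_that("FA at the zero tensor is 0 by convention and FA stays in [0,1]", {
  expect_identical(compute_fa(c(0, 0, 0)), 0)
  set.seed(9)
  sc <- tensor_scalars(rand_tensors(500)$lambdas)
  expect_true(all(sc$FA >= 0 & sc$FA <= 1))
  expect_false(any(sc$nonphysical))
})

test_that("scalar identities hold across random physical tensors", {
  set.seed(21)
  sc <- tensor_scalars(rand_tensors(10000)$lambdas)
  expect_lt(max(abs(sc$FA - sqrt(1.5) * sc$q / sc$L)), 1e-12)
  expect_lt(max(abs(sc$q^2 + 3 * sc$MD^2 - sc$L^2)), 1e-18)
})

test_that("metrics are rotation invariant and L equals the Frobenius norm", {
  set.seed(31)
  for (i in 1:25) {
    tn <- rand_tensors(1)
    m <- tensor_matrix(tn$t6[1, ])
    R <- rand_rotation()
    a <- tensor_scalars(as.numeric(
      unlist(eigen_decompose(m)[c("lambda1", "lambda2", "lambda3")])))
    b <- tensor_scalars(as.numeric(
      unlist(eigen_decompose(R %*% m %*% t(R))[c("lambda1", "lambda2", "lambda3")])))
    for (col in c("MD", "FA", "L", "q"))
      expect_equal(a[[col]], b[[col]], tolerance = 1e-10)
    expect_equal(a$L, sqrt(sum(m^2)), tolerance = 1e-12)
  }
})

test_that("q is invariant to adding a constant to all eigenvalues", {
  set.seed(41)
  lam <- rand_tensors(50)$lambdas
  expect_equal(tensor_scalars(lam)$q, tensor_scalars(lam + 3e-4)$q,
               tolerance = 1e-12)
})

test_that("metric maps equal per-voxel scalar evaluation", {
  set.seed(51)
  grid <- c(4, 3, 2)
  nvox <- prod(grid)
  tens <- rand_tensors(nvox)
  field <- array(tens$t6, c(grid, 6))
  maps <- compute_metric_maps(field)
  for (v in seq_len(nvox)) {
    e <- eigen_decompose(tens$t6[v, ])
    expect_equal(maps$MD[v], e$lambda_bar, tolerance = 1e-12)
    expect_equal(maps$q[v], compute_q(e), tolerance = 1e-12)
    expect_equal(maps$FA[v], compute_fa(e), tolerance = 1e-12)
    expect_equal(maps$L[v], compute_L(e), tolerance = 1e-12)
  }
  expect_lt(max(abs(maps$FA - sqrt(1.5) * maps$q / maps$L)), 1e-12)
})

test_that("uniform isotropic fields give zero FA and q maps", {
  field <- array(rep(as.numeric(dti_tensor(7e-4, 7e-4, 7e-4)), each = 8),
                 c(2, 2, 2, 6))
  maps <- compute_metric_maps(field)
  expect_true(all(maps$FA == 0))
  expect_true(all(maps$q == 0))
})

test_that("rotated tensor fields give identical scalar maps", {
  set.seed(61)
  nvox <- 12
  tens <- rand_tensors(nvox)
  R <- rand_rotation()
  rot <- t(apply(tens$t6, 1, function(t6)
    as.numeric(as_tensor6(R %*% tensor_matrix(t6) %*% t(R)))))
  m1 <- compute_metric_maps(array(tens$t6, c(3, 2, 2, 6)))
  m2 <- compute_metric_maps(array(rot, c(3, 2, 2, 6)))
  for (col in c("MD", "FA", "L", "q"))
    expect_equal(m1[[col]], m2[[col]], tolerance = 1e-10)
})

test_that("masking and grid mismatches are handled", {
  field <- array(rep(as.numeric(dti_tensor(1e-3, 1e-3, 1e-3)), each = 8),
                 c(2, 2, 2, 6))
  mask <- array(c(TRUE, FALSE), c(2, 2, 2))
  maps <- compute_metric_maps(field, mask = mask, fill = -1)
  expect_true(all(maps$MD[!mask] == -1))
  expect_true(all(maps$MD[mask] == 1e-3))
  expect_error(compute_metric_maps(field, mask = array(TRUE, c(3, 2, 2))),
               class = "qdti_dim_error")
  expect_error(compute_metric_maps(array(0, c(2, 2, 2, 5))),
               class = "qdti_dim_error")
})
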