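# DWI simulation: gradient schemes, the tensor signal model, Rician noise,
# and the cohort generator.

test_that("gradient schemes are identifiable with unit directions", {
  sch6 <- make_gradient_scheme(6, b_value = 1000)
  expect_length(sch6$bvals, 7)
  expect_equal(sum(sch6$bvals == 0), 1)
  expect_true(is.finite(kappa(build_design_matrix(sch6))))

  sch30 <- make_gradient_scheme(30, b_value = 1000, seed = 3)
  norms <- sqrt(colSums(sch30$bvecs[, sch30$bvals > 0]^2))
  expect_true(all(abs(norms - 1) < 1e-6))
  expect_equal(qr(build_design_matrix(sch30))$rank, 7)

  expect_error(make_gradient_scheme(5), class = "qdti_identifiability_error")
})

test_that("different seeds rotate the scheme but preserve uniformity", {
  a <- make_gradient_scheme(30, seed = 1)
  b <- make_gradient_scheme(30, seed = 2)
  expect_false(isTRUE(all.equal(a$bvecs, b$bvecs)))
  # pairwise angular structure is rotation invariant
  gram <- function(s) sort(round(abs(crossprod(s$bvecs[, s$bvals > 0])), 8))
  expect_equal(gram(a), gram(b))
})

test_that("the signal model matches its closed form", {
  sch <- make_gradient_scheme(12, b_value = 1000, seed = 5)
  d <- 0.8e-3
  s <- simulate_signal(dti_tensor(d, d, d), sch, s0 = 500)
  expect_equal(s, 500 * exp(-sch$bvals * d))
  expect_equal(s[sch$bvals == 0], 500)

  # b = 1000 along x for diag(1.7, 0.3, 0.2)e-3: attenuation exp(-1.7)
  sch_x <- structure(list(bvals = c(0, 1000), bvecs = cbind(c(0, 0, 0), c(1, 0, 0))),
                     class = "gradient_scheme")
  s <- simulate_signal(dti_tensor(1.7e-3, 0.3e-3, 0.2e-3), sch_x, s0 = 1)
  expect_equal(s[2], exp(-1.7e-3 * 1000), tolerance = 1e-12)

  expect_warning(simulate_signal(dti_tensor(-1e-3, 1e-3, 1e-3), sch, s0 = 1),
                 "non-physical")
  expect_error(simulate_signal(dti_tensor(1e-3, 1e-3, 1e-3), sch, s0 = 0),
               class = "qdti_invalid_parameter")
})

test_that("rician noise is exact at sigma 0, Rayleigh at signal 0, reproducible", {
  s <- c(100, 50, 0.5)
  expect_identical(add_rician_noise(s, 0), s)
  expect_error(add_rician_noise(s, -1), class = "qdti_invalid_parameter")

  # zero signal: magnitude is Rayleigh with mean sigma * sqrt(pi/2)
  z <- add_rician_noise(rep(0, 1e5), sigma = 10, seed = 99)
  expect_equal(mean(z), 10 * sqrt(pi / 2), tolerance = 0.01)

  expect_identical(add_rician_noise(s, 5, seed = 1), add_rician_noise(s, 5, seed = 1))
  arr <- array(100, c(3, 3, 2))
  expect_equal(dim(add_rician_noise(arr, 5, seed = 2)), dim(arr))
})

test_that("baseline SNR of simulated volumes approximates s0/sigma", {
  ph <- tiny_phantom(dim = c(48, 48, 6), template = NULL)   # >1e4 in-ROI voxels
  ch <- generate_cohort(ph, cohort_spec(n_per_group = 2, seed = 8, jitter_sd = 0))
  b0 <- ch$dwi[[1]][[1]][, , , which(ch$scheme$bvals == 0)]
  vox <- b0[ch$label_map > 0]
  expect_gt(length(vox), 1e4)
  expect_equal(mean(vox) / sd(vox), ph$s0 / ph$sigma, tolerance = 0.05)
})

test_that("null configuration with zero noise and jitter is group-identical", {
  ph <- tiny_phantom(template = NULL, sigma = 0)
  ch <- generate_cohort(ph, cohort_spec(n_per_group = 2, seed = 1, jitter_sd = 0))
  tab <- analyze_cohort(ch)
  agg <- aggregate(value ~ group + roi + metric + timepoint, tab, mean)
  spread <- tapply(agg$value, paste(agg$roi, agg$metric, agg$timepoint),
                   function(v) diff(range(v)))
  expect_lt(max(spread), 1e-12)
})

test_that("the generator is effect-faithful without noise", {
  ph <- tiny_phantom(sigma = 0)   # default effect template
  ch <- generate_cohort(ph, cohort_spec(n_per_group = 2, seed = 1, jitter_sd = 0))
  tab <- analyze_cohort(ch)
  g90 <- function(roi, metric, grp)
    mean(tab$value[tab$roi == roi & tab$metric == metric &
                   tab$timepoint == "day90" & tab$group == grp])
  # short-interval EC/IC q and L reduced at day 90; FA untouched by scaling
  expect_lt(g90("EC", "q", "short"), g90("EC", "q", "sham"))
  expect_lt(g90("IC", "L", "short"), g90("IC", "L", "sham"))
  expect_equal(g90("EC", "FA", "short"), g90("EC", "FA", "sham"), tolerance = 1e-8)
  # cortex anisotropy down for short; CC anisotropy up for long
  expect_lt(g90("cortex", "FA", "short"), g90("cortex", "FA", "sham"))
  expect_gt(g90("CC", "q", "long"), g90("CC", "q", "sham"))
  # anisotropy transform preserves MD
  expect_equal(g90("cortex", "MD", "short"), g90("cortex", "MD", "sham"),
               tolerance = 1e-8)
})

test_that("identical cohort specs generate bit-identical cohorts", {
  ph <- tiny_phantom()
  a <- generate_cohort(ph, cohort_spec(n_per_group = 2, seed = 5))
  b <- generate_cohort(ph, cohort_spec(n_per_group = 2, seed = 5))
  expect_identical(a$dwi, b$dwi)
  expect_identical(a$truth, b$truth)
  c2 <- generate_cohort(ph, cohort_spec(n_per_group = 2, seed = 6))
  expect_false(identical(a$dwi, c2$dwi))
})

test_that("missing profiles raise a configuration error", {
  ph <- tiny_phantom()
  co <- cohort_spec(groups = c("sham", "short", "extra"), n_per_group = 2)
  expect_error(generate_cohort(ph, co), class = "qdti_config_error")
})

test_that("ihc counts follow the configured affine model", {
  ph <- tiny_phantom()
  ch <- generate_cohort(ph, cohort_spec(n_per_group = 4, seed = 2), dwi = FALSE)
  coupling <- data.frame(stain = "GFAP", roi = "EC",
                         slope = -3e5, intercept = 500, sd = 0)
  cnt <- generate_ihc_counts(ch, coupling = coupling, seed = 1)
  expect_equal(cnt$count, round(pmax(0, 500 - 3e5 * cnt$q_truth)))
  expect_true(all(cnt$count >= 0 & cnt$count == round(cnt$count)))
  # histology subgroup sizes: sham 4, short 3, long 4
  expect_equal(as.integer(table(cnt$group)[c("sham", "short", "long")]),
               c(4L, 3L, 4L))

  flat <- data.frame(stain = "GFAP", roi = "EC", slope = 0, intercept = 123, sd = 0)
  cnt2 <- generate_ihc_counts(ch, coupling = flat, seed = 1)
  expect_true(all(cnt2$count == 123))

  bad <- data.frame(stain = "GFAP", roi = "EC", slope = 0, intercept = 1, sd = -1)
  expect_error(generate_ihc_counts(ch, coupling = bad), class = "qdti_invalid_parameter")

  expect_identical(generate_ihc_counts(ch, seed = 3), generate_ihc_counts(ch, seed = 3))
})
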