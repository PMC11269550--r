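# Independent brute-force oracles and small fixtures shared across tests.
# Every oracle below recomputes its quantity from first principles, never
# through the code path it checks.

# --- eigenvalues: roots of the characteristic polynomial ---------------
oracle_cubic_eigvals <- function(m) {
  s <- max(abs(m))           # work near magnitude 1: coefficient rounding
  m <- m / s                 # at the 1e-3 scale otherwise dominates
  c2 <- -(m[1, 1] + m[2, 2] + m[3, 3])
  c1 <- m[1, 1] * m[2, 2] + m[1, 1] * m[3, 3] + m[2, 2] * m[3, 3] -
    m[1, 2]^2 - m[1, 3]^2 - m[2, 3]^2
  c0 <- -det(m)
  r <- Re(polyroot(c(c0, c1, c2, 1)))
  # two Newton polishing steps: polyroot alone is only ~1e-12 accurate
  for (step in 1:2) {
    f  <- r^3 + c2 * r^2 + c1 * r + c0
    fp <- 3 * r^2 + 2 * c2 * r + c1
    r <- ifelse(fp != 0, r - f / fp, r)
  }
  sort(r, decreasing = TRUE) * s
}

# --- split-plot ANOVA: direct sums-of-squares decomposition ------------
# balanced complete designs only (equal n per group, all timepoints)
oracle_rm_anova_F <- function(d) {
  gm <- mean(d$value)
  tps <- unique(d$timepoint)
  t_ <- length(tps)
  subj <- aggregate(value ~ subject_id + group, d, mean)
  N <- nrow(subj)
  k <- length(unique(subj$group))
  n_g <- table(subj$group)
  m_g <- tapply(subj$value, subj$group, mean)
  ss_group <- t_ * sum(n_g * (m_g - gm)^2)
  ss_subj  <- t_ * sum((subj$value - m_g[as.character(subj$group)])^2)
  m_t <- tapply(d$value, d$timepoint, mean)
  ss_time <- N * sum((m_t - gm)^2)
  m_gt <- tapply(d$value, list(d$group, d$timepoint), mean)
  ss_gt <- 0
  for (g in rownames(m_gt)) for (tp in colnames(m_gt))
    ss_gt <- ss_gt + n_g[[g]] * (m_gt[g, tp] - m_g[[g]] - m_t[[tp]] + gm)^2
  subj_mean <- setNames(subj$value, subj$subject_id)
  resid <- d$value - subj_mean[d$subject_id] -
    m_gt[cbind(as.character(d$group), as.character(d$timepoint))] +
    m_g[as.character(d$group)]
  ss_we <- sum(resid^2)
  c(group = (ss_group / (k - 1)) / (ss_subj / (N - k)),
    timepoint = (ss_time / (t_ - 1)) / (ss_we / ((N - k) * (t_ - 1))),
    interaction = (ss_gt / ((k - 1) * (t_ - 1))) / (ss_we / ((N - k) * (t_ - 1))))
}

# --- studentized range CDF by direct double integration ----------------
oracle_ptukey <- function(q, k, df) {
  inner <- function(s) {
    vapply(s, function(si) {
      integrate(function(z)
        dnorm(z) * (pnorm(z) - pnorm(z - q * si))^(k - 1),
        -Inf, Inf, rel.tol = 1e-11)$value
    }, numeric(1))
  }
  # density of s = sqrt(chi2_df / df)
  f_s <- function(s) 2 * exp((df / 2) * log(df / 2) - lgamma(df / 2) +
                               (df - 1) * log(s) - df * s^2 / 2)
  k * integrate(function(s) f_s(s) * inner(s), 0, Inf, rel.tol = 1e-10)$value
}

# Tukey-Kramer adjusted p for one contrast, from scratch
oracle_tukey_p <- function(values, groups, a, b) {
  groups <- as.character(groups)
  gs <- unique(groups)
  n <- table(groups)
  mse <- sum(unlist(tapply(values, groups, function(v) (v - mean(v))^2))) /
    (length(values) - length(gs))
  m <- tapply(values, groups, mean)
  qs <- abs(m[[a]] - m[[b]]) / sqrt(mse / 2 * (1 / n[[a]] + 1 / n[[b]]))
  1 - oracle_ptukey(qs, length(gs), length(values) - length(gs))
}

# --- Pearson r and slope from the raw product-moment sums --------------
oracle_pearson <- function(x, y) {
  n <- length(x)
  sxy <- sum(x * y) - sum(x) * sum(y) / n
  sxx <- sum(x^2) - sum(x)^2 / n
  syy <- sum(y^2) - sum(y)^2 / n
  list(r = sxy / sqrt(sxx * syy), slope = sxy / sxx,
       intercept = mean(y) - (sxy / sxx) * mean(x))
}

# --- random physical tensors -------------------------------------------
rand_rotation <- function() {
  R <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

# n random physical tensors: eigenvalues uniform on realistic brain range,
# random orientation; returns lambdas (n x 3, sorted desc) and t6 (n x 6)
rand_tensors <- function(n) {
  lam <- matrix(runif(3 * n, 0.1e-3, 2.2e-3), n, 3)
  lam <- t(apply(lam, 1, sort, decreasing = TRUE))
  t6 <- matrix(NA_real_, n, 6)
  for (i in seq_len(n)) {
    R <- rand_rotation()
    t6[i, ] <- as.numeric(as_tensor6(R %*% diag(lam[i, ]) %*% t(R)))
  }
  list(lambdas = lam, t6 = t6)
}

# --- small study fixtures ----------------------------------------------
tiny_phantom <- function(dim = c(6, 4, 1), template = default_effect_template(),
                         sigma = 1000 / 30, n_directions = 6, ...) {
  phantom_spec(dim = dim, s0 = 1000, sigma = sigma,
               profiles = build_profiles(template = template),
               n_directions = n_directions, ...)
}

# balanced mixed-design dataset for the statistics oracles
fixed_rm_dataset <- function(seed = 7, k = 3, n = 4, t_ = 2) {
  set.seed(seed)
  groups <- LETTERS[seq_len(k)]
  d <- expand.grid(subject_id = character(0))
  rows <- list()
  for (g in groups) for (s in seq_len(n)) for (tp in seq_len(t_))
    rows[[length(rows) + 1]] <- data.frame(
      subject_id = paste0(g, s), group = g, timepoint = paste0("t", tp),
      value = rnorm(1, mean = match(g, groups) * 0.3 + tp * 0.1),
      stringsAsFactors = FALSE)
  do.call(rbind, rows)
}
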