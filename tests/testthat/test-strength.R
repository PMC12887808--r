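test_that("joint reconstruction reduces to the marginal case for J = 1 and orthogonal variants", {
  reg <- toy_region(c(10, -4), diag(2), n = 10000)
  ja1 <- joint_from_marginal(reg, "v1")
  expect_equal(unname(ja1$gamma), reg$sumstats$beta[1])
  expect_equal(unname(ja1$sigma[1, 1]), reg$sumstats$se[1]^2)
  ja2 <- joint_from_marginal(reg)
  expect_equal(unname(ja2$gamma), reg$sumstats$beta)
  expect_equal(unname(ja2$sigma), diag(reg$sumstats$se^2), tolerance = 1e-12)
})

test_that("joint reconstruction matches multivariable OLS on individual-level data", {
  set.seed(9)
  n <- 20000
  panel <- simulate_panel(n, 30, block_sizes = c(15L, 15L),
                          within_block_rho = 0.7, seed = 5)
  idx <- c(2, 6, 20)
  y <- drop(panel$G[, idx] %*% c(0.05, 0.03, -0.04)) + rnorm(n)
  reg <- sumstats_from_panel(panel, list(values = y))
  ja <- joint_from_marginal(reg, panel$ids[idx])
  fit <- lm(y ~ panel$G[, idx])
  expect_equal(unname(ja$gamma), unname(coef(fit)[-1]), tolerance = 0.02)
  expect_equal(unname(diag(ja$sigma)), unname(diag(vcov(fit))[-1]),
               tolerance = 0.02)
  # R^2 chain vs coefficient of determination: exact in-sample identity
  st <- instrument_strength(reg, panel$ids[idx])
  expect_equal(st$r2, summary(fit)$r.squared, tolerance = 1e-10)
})

test_that("F-statistic follows the hand-computed formula values", {
  # single variant: F is exactly the squared z-statistic
  reg <- toy_region(10, matrix(1), n = 10000, se = 0.02)
  ja <- joint_from_marginal(reg)
  expect_equal(f_statistic(ja), 100)
  # zero effects give F = 0
  reg0 <- toy_region(c(0, 0), diag(2))
  expect_equal(f_statistic(joint_from_marginal(reg0)), 0)
  # two orthogonal modest signals: mean of single-variant F values scaled
  # by (N-2)/(N-1), to leading order in z^2/N
  N <- 20000
  regA <- toy_region(c(5, 4), diag(2), n = N)
  FA <- f_statistic(joint_from_marginal(regA))
  expect_equal(FA, (5^2 + 4^2) / 2 * (N - 2) / (N - 1), tolerance = 2e-3)
})

test_that("r2_from_f and adjusted_r2 evaluate their formulas", {
  expect_equal(r2_from_f(0, 1000, 2), 0)
  expect_equal(r2_from_f(1000, 1002, 1), 0.5)
  expect_lt(r2_from_f(1e9, 1000, 3), 1)
  expect_error(r2_from_f(10, 4, 3), class = "cisiv_domain_error")

  expect_equal(adjusted_r2(0.5, 101, 1), 1 - 0.5 * 100 / 99)
  expect_lt(adjusted_r2(0, 100, 1), 0)
  expect_equal(adjusted_r2(0.37, 500, 0), 0.37)  # J = 0 is the identity
  expect_error(adjusted_r2(0.5, 3, 2), class = "cisiv_domain_error")

  # monotonicity of the chain
  f_grid <- seq(0, 50, by = 5)
  r2s <- vapply(f_grid, r2_from_f, numeric(1), N = 5000, J = 3)
  expect_true(all(diff(r2s) > 0))
  adj <- vapply(1:10, function(J) adjusted_r2(0.3, 5000, J), numeric(1))
  expect_true(all(diff(adj) < 0))
})

test_that("the J = 1 chain equals the closed-form z^2 / (N - 2 + z^2)", {
  for (z in c(3.5, 8, 40, 120)) {
    N <- 10708
    reg <- toy_region(z, matrix(1), n = N)
    st <- instrument_strength(reg, "v1")
    expect_equal(st$r2, z^2 / (N - 2 + z^2), tolerance = 1e-12)
  }
})

test_that("stabilize_ld floors eigenvalues without touching off-diagonals", {
  expect_identical(stabilize_ld(diag(3)), diag(3))
  m <- matrix(1, 2, 2)
  s <- stabilize_ld(m)
  expect_equal(diag(s), rep(1 + 1e-8, 2))
  expect_equal(s[1, 2], 1)
  ev <- eigen(s, symmetric = TRUE, only.values = TRUE)$values
  expect_lt(max(abs(sort(ev) - c(1e-8, 2 + 1e-8))), 1e-12)
  # idempotent, and any output has min eigenvalue >= 1e-8
  set.seed(2)
  for (i in 1:5) {
    A <- tcrossprod(matrix(rnorm(12), 4, 3)) / 3   # rank-deficient PSD
    A <- stats::cov2cor(A + diag(1e-12, 4))
    s1 <- stabilize_ld(A)
    expect_gte(min(eigen(s1, symmetric = TRUE, only.values = TRUE)$values),
               1e-8 - 1e-15)
    expect_equal(stabilize_ld(s1), s1)
    expect_equal(s1[upper.tri(s1)], A[upper.tri(A)])
  }
})

test_that("is_singular detects rank deficiency, including haplotype-style collinearity", {
  expect_false(is_singular(diag(2)))
  expect_true(is_singular(matrix(1, 2, 2)))
  # third variant equals a blend of the first two in correlation space:
  # Schur complement 1 - 2 * 0.9^2 (1 - 0.62) / (1 - 0.62^2) = 0 exactly
  R <- corr_mat(3, list(c(1, 2, 0.62), c(1, 3, 0.9), c(2, 3, 0.9)))
  expect_true(is_singular(R))
  # no pair is extreme, so a pairwise check would miss it
  expect_lt(max(abs(R[upper.tri(R)])), 0.95)
})
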