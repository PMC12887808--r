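test_that("panels are standardized, block-structured and seed-reproducible", {
  p <- simulate_panel(1500, 40, block_sizes = c(20L, 20L), seed = 3)
  expect_lt(max(abs(colMeans(p$G))), 1e-10)
  expect_lt(max(abs(apply(p$G, 2, var) - 1)), 1e-10)
  p2 <- simulate_panel(1500, 40, block_sizes = c(20L, 20L), seed = 3)
  expect_identical(p$G, p2$G)
  expect_error(simulate_panel(1500, 40, block_sizes = c(20L, 10L)),
               class = "cisiv_usage_error")
})

test_that("gaussian mode reproduces the target AR(1) correlations", {
  n <- 4000
  p <- simulate_panel(n, 2, block_sizes = 2L, within_block_rho = 0.5,
                      mode = "gaussian", seed = 5)
  expect_lt(abs(cor(p$G[, 1], p$G[, 2]) - 0.5), 4 / sqrt(n))
  p0 <- simulate_panel(n, 10, block_sizes = 10L, within_block_rho = 0,
                       mode = "gaussian", seed = 6)
  C <- cor(p0$G)
  expect_lt(max(abs(C[upper.tri(C)])), 4 / sqrt(n))
})

test_that("trait generation hits its variance-explained targets", {
  p <- simulate_panel(20000, 60, block_sizes = c(30L, 30L), seed = 11)
  t1 <- simulate_trait(p, "one_causal", h2 = 0.40, seed = 12)
  expect_lt(abs(t1$true_r2 - 0.40), 0.02)
  t2 <- simulate_trait(p, "two_causal", h2 = 0.40, rho_causal = 0.5, seed = 13)
  expect_lt(abs(t2$true_r2 - 0.40), 0.03)
  expect_length(t2$causal_ids, 2L)
  r12 <- cor(p$G[, t2$causal_idx[1]], p$G[, t2$causal_idx[2]])
  expect_lt(abs(r12 - 0.5), 0.05 + 1e-9)
  # each causal variant marginally explains about h2 (1 + rho)^2 / (2 + 2 rho)
  expect_lt(max(abs(t2$marginal_true_r2 - 0.30)), 0.03)
  # a null trait leaves almost nothing below the selection filter
  t0 <- simulate_trait(p, "one_causal", h2 = 0, seed = 14)
  reg0 <- sumstats_from_panel(p, t0, ld = FALSE)
  expect_lte(n_variants(filter_by_p(reg0)), 3L)
})

test_that("summary statistics agree with per-variant regression", {
  p <- simulate_panel(1000, 12, block_sizes = c(6L, 6L), seed = 21)
  tr <- simulate_trait(p, "one_causal", seed = 22)
  reg <- sumstats_from_panel(p, tr)
  expect_identical(unique(reg$sumstats$n), 1000L)
  j <- 5
  fit <- summary(lm(tr$values ~ p$G[, j]))$coefficients
  expect_equal(reg$sumstats$beta[j], fit[2, 1], tolerance = 1e-10)
  expect_equal(reg$sumstats$se[j], fit[2, 2], tolerance = 1e-10)
  expect_equal(reg$sumstats$pval[j], fit[2, 4], tolerance = 1e-8)
  expect_equal(unname(reg$ld[1, 2]), cor(p$G[, 1], p$G[, 2]), tolerance = 1e-12)
})

test_that("summary-statistics strength matches individual-level R^2 per replicate", {
  for (i in 1:6) {
    sim <- sim_region(n = 3000, J = 40, scenario = if (i %% 2) "one_causal"
                      else "two_causal", seed = 400 + i)
    st <- instrument_strength(sim$region, sim$trait$causal_ids)
    expect_lt(abs(st$r2 - sim$trait$true_r2), 0.01)
  }
})

test_that("scenario reports are deterministic and normalize lead-only to 1", {
  args <- list(scenario = "one_causal", reps = 3, n = 600, J = 24,
               block_sizes = c(12L, 12L),
               methods = c("lead_only", "prune_modified", "susie"),
               seed = 31)
  r1 <- do.call(run_main_scenarios, args)
  r2 <- do.call(run_main_scenarios, args)
  expect_identical(r1$replicates, r2$replicates)
  lead <- r1$summary[r1$summary$method == "lead_only", ]
  expect_equal(lead$median_normalized_r2, 1)
  expect_true(all(c("median_J", "median_r2") %in% names(r1$summary)))
})

test_that("removing the causal variant and its proxies favours multi-variant methods", {
  pr <- run_proxy_removal_study(reps = 4, n = 4000, J = 80,
                                block_sizes = rep(20L, 4),
                                proxy_thresholds = c(0.95, 0.4),
                                methods = c("lead_only", "prune_modified"),
                                seed = 41)
  s <- pr$summary
  lead <- s[s$method == "lead_only", ]
  mod <- s[s$method == "prune_modified", ]
  for (thr in c(0.95, 0.4)) {
    expect_gt(mod$median_r2[mod$proxy_threshold == thr],
              lead$median_r2[lead$proxy_threshold == thr])
  }
  # the gap grows as more proxies are removed
  gap <- mod$median_normalized_r2
  expect_gt(gap[mod$proxy_threshold == 0.4], gap[mod$proxy_threshold == 0.95])
})

test_that("pleiotropy biases every strategy; the no-pleiotropy control is clean", {
  base <- list(reps = 12, n = 2500, J = 80, block_sizes = rep(20L, 4),
               methods = c("lead_only", "cojo", "prune_modified"), seed = 51)
  biased <- do.call(run_pleiotropy_study, c(base, theta = 0.3, delta = 0.15))
  expect_true(all(biased$summary$bias_detected))
  expect_true(all(sign(biased$summary$bias) == sign(0.15)))
  clean <- do.call(run_pleiotropy_study, c(base, theta = 0.3, delta = 0))
  expect_true(all(abs(clean$summary$bias) < 6 * clean$summary$mc_se))
})
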