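test_that("null z-scores produce uniform effects and no credible sets", {
  reg <- toy_region(rep(0, 20), diag(20))
  fit <- susie_rss_fit(reg, K = 5)
  expect_true(all(abs(fit$alpha - 1 / 20) < 1e-12))
  expect_true(all(fit$V == 0))
  expect_length(credible_sets(fit, reg$ld), 0)
})

test_that("a single strong orthogonal signal gets PIP near 1 and one set", {
  set.seed(51)
  z <- rnorm(30, 0, 0.5)
  z[7] <- 30
  reg <- toy_region(z, diag(30), n = 20000)
  fit <- susie_rss_fit(reg)
  expect_gt(fit$pip[["v7"]], 0.99)
  sets <- credible_sets(fit, reg$ld)
  expect_length(sets, 1)
  expect_identical(sets[[1]]$member_ids, "v7")
  expect_equal(sets[[1]]$purity, 1)
})

test_that("alpha rows stay normalized and the objective never decreases", {
  for (i in 1:4) {
    reg <- filter_by_p(sim_region(n = 3000, J = 60, scenario = "two_causal",
                                  seed = 60 + i)$region)
    fit <- susie_rss_fit(reg)
    expect_equal(unname(rowSums(fit$alpha)), rep(1, nrow(fit$alpha)),
                 tolerance = 1e-6)
    expect_true(all(fit$pip >= 0 & fit$pip <= 1))
    expect_true(all(diff(fit$elbo_trace) > -1e-6))
  }
})

test_that("credible-set construction follows the prefix-sum and purity rules", {
  mk_fit <- function(alpha_row, ids) {
    structure(list(alpha = matrix(alpha_row, 1), mu = matrix(1, 1, length(ids)),
                   pip = stats::setNames(alpha_row, ids), V = 1,
                   elbo_trace = 0, converged = TRUE, ids = ids),
              class = "susie_fit")
  }
  ids <- c("a", "b", "c")
  ld <- corr_mat(3, list(c(1, 2, 0.9)))
  dimnames(ld) <- list(ids, ids)
  # 0.97 alone reaches 0.95: singleton
  s1 <- credible_sets(mk_fit(c(0.97, 0.02, 0.01), ids), ld)
  expect_identical(s1[[1]]$member_ids, "a")
  expect_equal(s1[[1]]$purity, 1)
  # needs two members; their |r| = 0.9 passes the purity floor
  s2 <- credible_sets(mk_fit(c(0.5, 0.46, 0.04), ids), ld)
  expect_setequal(s2[[1]]$member_ids, c("a", "b"))
  expect_equal(s2[[1]]$purity, 0.9)
  expect_gte(s2[[1]]$cumulative_alpha, 0.95)
  # diffuse effect over weakly correlated variants fails purity
  J <- 40
  ldJ <- diag(J); dimnames(ldJ) <- list(sprintf("v%d", 1:J), sprintf("v%d", 1:J))
  s3 <- credible_sets(mk_fit(rep(1 / J, J), sprintf("v%d", 1:J)), ldJ)
  expect_length(s3, 0)
})

test_that("representative selection collapses duplicates and falls back when empty", {
  reg <- toy_region(c(9, 8, 7), diag(3), n = 20000)
  fit <- susie_rss_fit(reg)
  sel0 <- select_from_credible_sets(list(), fit, reg)
  expect_identical(sel0$J, 0L)
  sets <- list(list(effect_index = 1, member_ids = c("v1", "v2"),
                    cumulative_alpha = 0.96, purity = 0.9, representative = "v1"),
               list(effect_index = 2, member_ids = c("v1", "v3"),
                    cumulative_alpha = 0.97, purity = 0.9, representative = "v1"))
  # both sets share their max-PIP variant: collapsed to one instrument
  fit$pip[] <- c(0.99, 0.1, 0.1)
  sel <- select_from_credible_sets(sets, fit, reg)
  expect_identical(sel$selected_ids, "v1")
})

test_that("permuting variants (with matching LD) permutes the fit identically", {
  sim <- sim_region(n = 2500, J = 30, block_sizes = c(15L, 15L), seed = 77)
  reg <- filter_by_p(sim$region, 0.01)
  perm <- rev(seq_len(n_variants(reg)))
  fitA <- susie_rss_fit(reg, K = 4)
  fitB <- susie_rss_fit(subset_region(reg, perm), K = 4)
  expect_equal(fitB$pip[names(fitA$pip)], fitA$pip, tolerance = 1e-8)
  expect_equal(fitB$alpha[, colnames(fitA$alpha)], fitA$alpha, tolerance = 1e-8)
})

test_that("the causal variant lies in a 95% credible set in >= 90% of replicates", {
  reps <- 100L
  hits <- 0L
  for (i in seq_len(reps)) {
    sim <- sim_region(n = 2000, J = 60, scenario = "one_causal", seed = 1000 + i)
    reg <- filter_by_p(sim$region)
    fit <- suppressWarnings(susie_rss_fit(reg))
    sets <- credible_sets(fit, reg$ld)
    if (any(vapply(sets, function(s) sim$trait$causal_ids %in% s$member_ids,
                   logical(1)))) {
      hits <- hits + 1L
    }
  }
  expect_gte(hits / reps, 0.90)
})

test_that("two independent signals yield two credible sets in most replicates", {
  reps <- 20L
  good <- 0L
  for (i in seq_len(reps)) {
    panel <- simulate_panel(4000, 60, block_sizes = c(30L, 30L),
                            within_block_rho = 0.8, seed = 2000 + i)
    set.seed(3000 + i)
    y <- drop(panel$G[, c(10, 40)] %*% rep(sqrt(0.2), 2)) +
      rnorm(4000, 0, sqrt(0.6))
    reg <- filter_by_p(sumstats_from_panel(panel, list(values = y)))
    fit <- suppressWarnings(susie_rss_fit(reg))
    if (length(credible_sets(fit, reg$ld)) == 2L) good <- good + 1L
  }
  expect_gte(good / reps, 0.90)
})
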