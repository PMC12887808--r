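# Self-contained simulator: block-correlated genotype panels, traits with
# one or two causal variants at a known variance explained, the derived
# marginal summary statistics, and scenario runners for method evaluation.

default_block_sizes <- function(J) {
  sizes <- integer()
  while (sum(sizes) < J) sizes <- c(sizes, sample(20:80, 1L))
  sizes[length(sizes)] <- sizes[length(sizes)] - (sum(sizes) - J)
  sizes[sizes > 0]
}

#' Simulate a block-correlated genotype panel
#'
#' Draws a latent multivariate-normal panel with block-diagonal AR(1)
#' correlation (within a block, `cor(i, j) = within_block_rho^|i-j|`;
#' blocks independent), thresholds it into 0/1/2 genotype calls under
#' Hardy-Weinberg cut-points at per-variant minor-allele frequencies drawn
#' uniformly from `maf_range`, and column-standardizes the result (mean 0,
#' sample variance 1). `mode = "gaussian"` skips the thresholding, giving
#' exact latent correlations for numerical tests.
#'
#' @param n Individuals (>= 100).
#' @param J Variants (>= 2).
#' @param block_sizes Integer vector summing to `J`; default random sizes
#'   of 20-80 drawn under `seed`.
#' @param within_block_rho AR(1) parameter within blocks (default 0.9).
#' @param maf_range Range for the uniform MAF draw (default 0.05-0.5).
#' @param mode `"genotype"` (default) or `"gaussian"`.
#' @param maf Optional length-`J` MAF vector overriding the uniform draw
#'   (used to share allele frequencies between two-sample panels).
#' @param seed Integer seed; the panel is a deterministic function of the
#'   arguments.
#' @return An object of class `genotype_panel`: `G` (n x J standardized
#'   matrix), `ids`, `maf`, `block` (per-variant block index), `block_sizes`,
#'   `within_block_rho`, `mode`, `seed`.
#' @export
simulate_panel <- function(n, J, block_sizes = NULL, within_block_rho = 0.9,
                           maf_range = c(0.05, 0.5),
                           mode = c("genotype", "gaussian"), maf = NULL,
                           seed = 1L) {
  mode <- match.arg(mode)
  if (n < 100) stop_cisiv("need n >= 100", "cisiv_usage_error")
  if (J < 2) stop_cisiv("need J >= 2", "cisiv_usage_error")
  with_seed(seed, {
    if (is.null(block_sizes)) block_sizes <- default_block_sizes(J)
    if (sum(block_sizes) != J) {
      stop_cisiv("block_sizes must sum to J", "cisiv_usage_error")
    }
    if (is.null(maf)) {
      maf <- stats::runif(J, maf_range[1], maf_range[2])
    } else if (length(maf) != J) {
      stop_cisiv("maf must have length J", "cisiv_usage_error")
    }
    rho <- within_block_rho
    G <- matrix(0, n, J)
    col0 <- 0L
    for (B in block_sizes) {
      E <- matrix(stats::rnorm(n * B), n, B)
      if (B > 1 && rho != 0) {
        w <- sqrt(1 - rho^2)
        for (j in 2:B) E[, j] <- rho * E[, j - 1] + w * E[, j]
      }
      if (mode == "genotype") {
        p <- maf[col0 + seq_len(B)]
        q1 <- rep(stats::qnorm((1 - p)^2), each = n)
        q2 <- rep(stats::qnorm(1 - p^2), each = n)
        E <- (E > q1) + (E > q2)
      }
      sds <- apply(E, 2, stats::sd)
      if (any(sds == 0)) {
        stop_cisiv("degenerate (constant) genotype column; increase n",
                   "cisiv_degenerate_error")
      }
      G[, col0 + seq_len(B)] <- scale(E)
      col0 <- col0 + B
    }
    structure(list(G = G, n = n, J = J,
                   ids = sprintf("v%04d", seq_len(J)),
                   maf = if (mode == "genotype") maf else rep(NA_real_, J),
                   block = rep(seq_along(block_sizes), block_sizes),
                   block_sizes = block_sizes, within_block_rho = rho,
                   mode = mode, seed = as.integer(seed)),
              class = "genotype_panel")
  })
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat(sprintf("genotype_panel: %d individuals x %d variants (%s mode), %d block(s), AR(1) rho = %.2f\n",
              x$n, x$J, x$mode, length(x$block_sizes), x$within_block_rho))
  invisible(x)
}

#' Simulate a trait with one or two causal variants
#'
#' One causal variant: effect `sqrt(h2)` on a randomly chosen standardized
#' variant with residual variance `1 - h2`, so the causal variant explains
#' `h2` of the trait variance in expectation. Two causal variants: a first
#' variant is drawn at random and a partner is searched whose empirical
#' correlation is within `rho_tol` of `rho_causal`; both receive effect
#' `sqrt(h2 / (2 + 2 rho_causal))`, so jointly they explain `h2` and each
#' marginally `h2 (1 + rho_causal)^2 / (2 + 2 rho_causal)` (30% at
#' `h2 = 0.4`, `rho_causal = 0.5`). The realized variance explained is
#' recorded from in-replicate regression on the causal variant(s).
#'
#' @param panel A `genotype_panel`.
#' @param scenario `"one_causal"` or `"two_causal"`.
#' @param h2 Target variance explained by the causal variants (default 0.4).
#' @param rho_causal Target correlation of the causal pair (default 0.5).
#' @param rho_tol Search tolerance around `rho_causal` (default 0.05).
#' @param seed Integer seed.
#' @return An object of class `simulated_trait`: `values`, `causal_ids`,
#'   `causal_idx`, `effect_sizes`, `residual_variance`, `true_r2` (joint),
#'   `marginal_true_r2` (per causal variant), `scenario`, `seed`.
#' @export
simulate_trait <- function(panel, scenario = c("one_causal", "two_causal"),
                           h2 = 0.40, rho_causal = 0.5, rho_tol = 0.05,
                           seed = 1L) {
  scenario <- match.arg(scenario)
  if (h2 < 0 || h2 >= 1) stop_cisiv("h2 must lie in [0, 1)", "cisiv_usage_error")
  with_seed(seed, {
    G <- panel$G
    n <- panel$n
    if (scenario == "one_causal") {
      idx <- sample.int(panel$J, 1L)
      betas <- sqrt(h2)
      genetic <- betas * G[, idx]
    } else {
      idx <- NULL
      for (try in seq_len(25L)) {
        c1 <- sample.int(panel$J, 1L)
        cors <- drop(crossprod(G, G[, c1])) / (n - 1)
        cand <- which(abs(cors - rho_causal) <= rho_tol)
        cand <- setdiff(cand, c1)
        if (length(cand)) {
          c2 <- cand[sample.int(length(cand), 1L)]
          idx <- c(c1, c2)
          break
        }
      }
      if (is.null(idx)) {
        stop_cisiv("no variant pair near the target correlation; increase J or adjust blocks",
                   "cisiv_search_error")
      }
      betas <- rep(sqrt(h2 / (2 + 2 * rho_causal)), 2L)
      genetic <- G[, idx, drop = FALSE] %*% betas
    }
    y <- drop(genetic) + stats::rnorm(n, 0, sqrt(1 - h2))
    fit <- stats::lm.fit(cbind(1, G[, idx, drop = FALSE]), y)
    true_r2 <- 1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
    marg <- vapply(idx, function(i) {
      stats::cor(G[, i], y)^2
    }, numeric(1))
    structure(list(values = y, causal_ids = panel$ids[idx], causal_idx = idx,
                   effect_sizes = betas, residual_variance = 1 - h2,
                   true_r2 = true_r2, marginal_true_r2 = marg,
                   scenario = scenario, seed = as.integer(seed)),
              class = "simulated_trait")
  })
}

#' Marginal summary statistics and empirical LD from a panel
#'
#' Regresses the trait on each variant in turn (univariable OLS with
#' intercept) to produce per-variant `beta`, `se`, two-sided p (Student-t)
#' and `n`, and packages them with the panel's empirical correlation matrix
#' as an [aligned_region]. P-values are floored at `1e-320` to respect the
#' open-interval contract. With `ld = FALSE` the LD matrix is omitted
#' (single-variant operations only), which avoids the J x J crossproduct
#' when only marginal quantities are needed.
#'
#' @param panel A `genotype_panel`.
#' @param trait A `simulated_trait` (or any length-n numeric in `$values`).
#' @param ld Compute the empirical LD matrix (default `TRUE`).
#' @return An [aligned_region].
#' @export
sumstats_from_panel <- function(panel, trait, ld = TRUE) {
  G <- panel$G
  n <- panel$n
  y <- trait$values
  yc <- y - mean(y)
  ssx <- n - 1                       # columns standardized: sum G_j^2 = n - 1
  b <- drop(crossprod(G, yc)) / ssx
  rss <- sum(yc^2) - b^2 * ssx
  se <- sqrt(pmax(rss, 0) / (n - 2) / ssx)
  pval <- pmax(2 * stats::pt(-abs(b / se), df = n - 2), 1e-320)
  eaf <- ifelse(is.na(panel$maf), 0.5, panel$maf)
  ss <- data.frame(variant_id = panel$ids, chrom = "1",
                   pos = seq_len(panel$J) * 1000L,
                   effect_allele = "A", other_allele = "G",
                   eaf = eaf, beta = b, se = se, pval = pval, n = n,
                   stringsAsFactors = FALSE)
  R <- NULL
  if (ld) {
    R <- crossprod(G) / ssx
    R <- (R + t(R)) / 2
    diag(R) <- 1
    dimnames(R) <- list(panel$ids, panel$ids)
  }
  aligned_region(region_sumstats(ss), R)
}

# Run one configured method on a region; returns a cis_selection or NULL on
# error (scenario runners record NA for failed replicates).
run_method <- function(region, method, tuning, seed) {
  tryCatch(
    switch(method,
      lead_only = select_instruments(region, "lead_only", seed = seed),
      prune_standard = select_instruments(region, "prune_standard",
                                          r2_threshold = tuning, seed = seed),
      prune_modified = select_instruments(region, "prune_modified",
                                          r2_threshold = tuning, seed = seed),
      cojo = select_instruments(region, "cojo",
                                collinearity_threshold = tuning, seed = seed),
      susie = select_instruments(region, "susie", seed = seed),
      pca = select_instruments(region, "pca",
                               variance_threshold = tuning, seed = seed),
      stop_cisiv(sprintf("unknown method '%s'", method), "cisiv_usage_error")),
    error = function(e) NULL)
}

default_tunings <- list(lead_only = NA_real_, prune_standard = 0.4,
                        prune_modified = 0.4, cojo = 0.5, susie = NA_real_,
                        pca = 0.999)

method_grid <- function(methods, tunings) {
  rows <- lapply(methods, function(m) {
    tv <- tunings[[m]] %||% default_tunings[[m]]
    data.frame(method = m, tuning = tv, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

method_key <- function(method, tuning) {
  paste(method, ifelse(is.na(tuning), "none", tuning))
}

summarize_replicates <- function(repl) {
  key <- method_key(repl$method, repl$tuning)
  out <- do.call(rbind, lapply(split(repl, key), function(d) {
    data.frame(method = d$method[1], tuning = d$tuning[1],
               reps = nrow(d), n_failed = sum(is.na(d$r2)),
               median_J = stats::median(d$J, na.rm = TRUE),
               median_r2 = stats::median(d$r2, na.rm = TRUE),
               median_normalized_r2 =
                 stats::median(d$r2 / d$lead_r2, na.rm = TRUE),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Run the main simulation scenarios
#'
#' Per replicate: a fresh genotype panel, a trait with one or two causal
#' variants (jointly explaining `h2` of trait variance), the derived
#' marginal summary statistics plus empirical LD, and every requested
#' method at its tuning value. Reports per-replicate realized variance
#' explained and per-method medians of `J` and R^2 (plus R^2 normalized by
#' the lead-variant-only R^2 of the same replicate).
#'
#' @param scenario `"one_causal"` or `"two_causal"`.
#' @param reps Number of replicates (default 100).
#' @param n,J Panel dimensions (defaults 20000 and 1620).
#' @param methods Methods to run (subset of `lead_only`, `prune_standard`,
#'   `prune_modified`, `cojo`, `susie`, `pca`).
#' @param tunings Named list of one tuning value per method (vector-valued
#'   entries are expanded into separate rows).
#' @param h2,rho_causal Trait-model parameters (defaults 0.4 and 0.5).
#' @param block_sizes,within_block_rho Panel structure (see
#'   [simulate_panel()]).
#' @param seed Master seed; the full report is a deterministic function of
#'   the arguments.
#' @return An object of class `scenario_report` with `$replicates` (one row
#'   per replicate x method x tuning) and `$summary` (medians). A replicate
#'   where a method errors records `NA` and is counted in `n_failed`.
#' @export
run_main_scenarios <- function(scenario = c("one_causal", "two_causal"),
                               reps = 100L, n = 20000L, J = 1620L,
                               methods = c("lead_only", "prune_modified",
                                           "cojo", "susie", "pca"),
                               tunings = list(), h2 = 0.40, rho_causal = 0.5,
                               block_sizes = NULL, within_block_rho = 0.9,
                               seed = 1L) {
  scenario <- match.arg(scenario)
  grid <- method_grid(methods, tunings)
  grid <- grid[rep(seq_len(nrow(grid)), 1), , drop = FALSE]
  # expand vector tunings
  grid <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    data.frame(method = grid$method[i], tuning = grid$tuning[[i]],
               stringsAsFactors = FALSE)
  }))
  seeds <- matrix(spawn_seeds(seed, 3L * reps), ncol = 3L)
  need_ld <- any(grid$method != "lead_only")
  repl <- vector("list", reps)
  for (i in seq_len(reps)) {
    panel <- simulate_panel(n, J, block_sizes = block_sizes,
                            within_block_rho = within_block_rho,
                            seed = seeds[i, 1])
    trait <- simulate_trait(panel, scenario, h2 = h2,
                            rho_causal = rho_causal, seed = seeds[i, 2])
    region <- sumstats_from_panel(panel, trait, ld = need_ld)
    lead <- run_method(region, "lead_only", NA, seeds[i, 3])
    lead_r2 <- if (is.null(lead)) NA_real_ else lead$r2
    rows <- lapply(seq_len(nrow(grid)), function(g) {
      if (grid$method[g] == "lead_only") {
        sel <- lead
      } else {
        sel <- run_method(region, grid$method[g], grid$tuning[g], seeds[i, 3])
      }
      data.frame(rep = i, method = grid$method[g], tuning = grid$tuning[g],
                 J = if (is.null(sel)) NA_integer_ else sel$J,
                 r2 = if (is.null(sel)) NA_real_ else sel$r2,
                 adj_r2 = if (is.null(sel)) NA_real_ else sel$adj_r2,
                 lead_r2 = lead_r2, true_r2 = trait$true_r2,
                 mean_marginal_true_r2 = mean(trait$marginal_true_r2),
                 stringsAsFactors = FALSE)
    })
    repl[[i]] <- do.call(rbind, rows)
  }
  repl <- do.call(rbind, repl)
  structure(list(scenario = scenario, reps = reps, n = n, J = J,
                 replicates = repl, summary = summarize_replicates(repl),
                 params = list(h2 = h2, rho_causal = rho_causal, seed = seed)),
            class = "scenario_report")
}

#' @export
print.scenario_report <- function(x, ...) {
  cat(sprintf("scenario_report: %s, %d replicate(s), n = %d, J = %d\n",
              x$scenario, x$reps, x$n, x$J))
  print(x$summary, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Proxy-removal study: selection without the causal variant
#'
#' One-causal-variant scenario in which, after trait generation, the causal
#' variant and every variant whose squared correlation with it exceeds a
#' threshold are removed from the summary statistics and LD before
#' selection — emulating an untyped causal variant. Reported per threshold
#' and method.
#'
#' @inheritParams run_main_scenarios
#' @param proxy_thresholds Squared-correlation thresholds above which
#'   proxies are removed (default `c(0.95, 0.8, 0.4)`; lower removes more).
#' @return A `scenario_report`-like object with `$replicates` carrying a
#'   `proxy_threshold` column and `$summary` split by threshold.
#' @export
run_proxy_removal_study <- function(reps = 100L, n = 20000L, J = 1620L,
                                    proxy_thresholds = c(0.95, 0.8, 0.4),
                                    methods = c("lead_only", "prune_modified",
                                                "cojo", "susie", "pca"),
                                    tunings = list(), h2 = 0.40,
                                    block_sizes = NULL, within_block_rho = 0.9,
                                    seed = 1L) {
  grid <- method_grid(methods, tunings)
  seeds <- matrix(spawn_seeds(seed, 3L * reps), ncol = 3L)
  repl <- list()
  for (i in seq_len(reps)) {
    panel <- simulate_panel(n, J, block_sizes = block_sizes,
                            within_block_rho = within_block_rho,
                            seed = seeds[i, 1])
    trait <- simulate_trait(panel, "one_causal", h2 = h2, seed = seeds[i, 2])
    region <- sumstats_from_panel(panel, trait, ld = TRUE)
    cidx <- trait$causal_idx
    r2_to_causal <- region$ld[, cidx]^2
    for (thr in proxy_thresholds) {
      keep <- which(r2_to_causal <= thr)
      keep <- setdiff(keep, cidx)
      sub <- subset_region(region, keep)
      lead <- run_method(sub, "lead_only", NA, seeds[i, 3])
      lead_r2 <- if (is.null(lead)) NA_real_ else lead$r2
      for (g in seq_len(nrow(grid))) {
        sel <- if (grid$method[g] == "lead_only") lead else
          run_method(sub, grid$method[g], grid$tuning[g], seeds[i, 3])
        repl[[length(repl) + 1L]] <- data.frame(
          rep = i, proxy_threshold = thr, method = grid$method[g],
          tuning = grid$tuning[g],
          J = if (is.null(sel)) NA_integer_ else sel$J,
          r2 = if (is.null(sel)) NA_real_ else sel$r2,
          adj_r2 = if (is.null(sel)) NA_real_ else sel$adj_r2,
          lead_r2 = lead_r2, true_r2 = trait$true_r2,
          mean_marginal_true_r2 = mean(trait$marginal_true_r2),
          stringsAsFactors = FALSE)
      }
    }
  }
  repl <- do.call(rbind, repl)
  summ <- do.call(rbind, lapply(split(repl, repl$proxy_threshold), function(d) {
    s <- summarize_replicates(d)
    s$proxy_threshold <- d$proxy_threshold[1]
    s
  }))
  rownames(summ) <- NULL
  structure(list(scenario = "proxy_removal", reps = reps, n = n, J = J,
                 replicates = repl, summary = summ,
                 params = list(h2 = h2, proxy_thresholds = proxy_thresholds,
                               seed = seed)),
            class = "scenario_report")
}

#' Pleiotropy study: MR bias when a causal variant also hits the outcome
#'
#' Two independent causal variants (drawn from different LD blocks) drive
#' the exposure; one of them additionally exerts a direct effect `delta` on
#' the outcome. Exposure and outcome samples are independent draws sharing
#' allele frequencies and block structure (two-sample design). Per method,
#' the mean IVW estimate, its Monte-Carlo standard error and the bias
#' relative to the true causal effect `theta` are reported. With
#' `delta = 0` all methods are unbiased; with `delta != 0` every strategy
#' that selects the pleiotropic variant (or its LD partners) is biased in
#' the direction of `delta`.
#'
#' @inheritParams run_main_scenarios
#' @param theta True causal effect of the exposure on the outcome.
#' @param delta Direct (pleiotropic) effect of the first causal variant on
#'   the outcome.
#' @return An object of class `pleiotropy_report` with `$replicates`
#'   (per-replicate estimates) and `$summary` (mean estimate, Monte-Carlo
#'   SE, bias, and whether |bias| exceeds two Monte-Carlo SEs).
#' @export
run_pleiotropy_study <- function(reps = 100L, n = 20000L, J = 1620L,
                                 theta = 0.3, delta = 0.1,
                                 methods = c("lead_only", "prune_modified",
                                             "cojo", "susie", "pca"),
                                 tunings = list(), h2 = 0.40,
                                 block_sizes = NULL, within_block_rho = 0.9,
                                 seed = 1L) {
  grid <- method_grid(methods, tunings)
  seeds <- matrix(spawn_seeds(seed, 6L * reps), ncol = 6L)
  repl <- list()
  for (i in seq_len(reps)) {
    px <- simulate_panel(n, J, block_sizes = block_sizes,
                         within_block_rho = within_block_rho,
                         seed = seeds[i, 1])
    if (length(px$block_sizes) < 2L) {
      stop_cisiv("pleiotropy study needs at least two LD blocks",
                 "cisiv_usage_error")
    }
    py <- simulate_panel(n, J, block_sizes = px$block_sizes,
                         within_block_rho = within_block_rho,
                         maf = px$maf, seed = seeds[i, 2])
    # two independent causal variants: one from each of two random blocks
    picks <- with_seed(seeds[i, 3], {
      bl <- sample(unique(px$block), 2L)
      c(sample(which(px$block == bl[1]), 1L),
        sample(which(px$block == bl[2]), 1L))
    })
    b <- sqrt(h2 / 2)
    mk_exposure <- function(panel, eseed) {
      g <- drop(panel$G[, picks, drop = FALSE] %*% rep(b, 2L))
      with_seed(eseed, g + stats::rnorm(panel$n, 0, sqrt(1 - h2)))
    }
    x_exp <- mk_exposure(px, seeds[i, 4])
    x_out <- mk_exposure(py, seeds[i, 5])
    y_out <- with_seed(seeds[i, 6],
                       theta * x_out + delta * py$G[, picks[1]] +
                         stats::rnorm(py$n, 0, 1))
    region_x <- sumstats_from_panel(px, list(values = x_exp), ld = TRUE)
    outcome <- sumstats_from_panel(py, list(values = y_out), ld = FALSE)$sumstats
    for (g in seq_len(nrow(grid))) {
      sel <- run_method(region_x, grid$method[g], grid$tuning[g], seeds[i, 3])
      mr <- if (is.null(sel) || (sel$J == 0L)) NULL else
        tryCatch(mr_with_selection(region_x, outcome, sel),
                 error = function(e) NULL)
      repl[[length(repl) + 1L]] <- data.frame(
        rep = i, method = grid$method[g], tuning = grid$tuning[g],
        J = if (is.null(sel)) NA_integer_ else sel$J,
        estimate = if (is.null(mr)) NA_real_ else mr$estimate,
        se = if (is.null(mr)) NA_real_ else mr$se,
        stringsAsFactors = FALSE)
    }
  }
  repl <- do.call(rbind, repl)
  key <- method_key(repl$method, repl$tuning)
  summ <- do.call(rbind, lapply(split(repl, key), function(d) {
    est <- d$estimate[!is.na(d$estimate)]
    mc_se <- stats::sd(est) / sqrt(length(est))
    data.frame(method = d$method[1], tuning = d$tuning[1],
               reps = nrow(d), n_failed = sum(is.na(d$estimate)),
               mean_estimate = mean(est), mc_se = mc_se,
               bias = mean(est) - theta,
               bias_detected = abs(mean(est) - theta) > 2 * mc_se,
               stringsAsFactors = FALSE)
  }))
  rownames(summ) <- NULL
  structure(list(reps = reps, n = n, J = J, theta = theta, delta = delta,
                 replicates = repl, summary = summ,
                 params = list(h2 = h2, seed = seed)),
            class = "pleiotropy_report")
}

#' @export
print.pleiotropy_report <- function(x, ...) {
  cat(sprintf("pleiotropy_report: %d replicate(s), theta = %.3g, delta = %.3g\n",
              x$reps, x$theta, x$delta))
  print(x$summary, row.names = FALSE, digits = 4)
  invisible(x)
}
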