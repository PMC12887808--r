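# Sum-of-single-effects regression on z-statistics and LD (the
# summary-statistics variant of the SuSiE model), written directly against
# the sufficient statistics X'X = R, X'y = z with residual variance fixed
# at 1 on the z scale. Produces per-effect inclusion probabilities, overall
# PIPs, coverage-alpha credible sets with a purity filter, and one
# representative instrument per credible set.

# log Bayes factor of a single-effect regression with prior variance V,
# observation bhat with unit sampling variance.
single_effect_lbf <- function(bhat, V) {
  0.5 * (log(1 / (1 + V)) + bhat^2 * V / (1 + V))
}

# Fit one single-effect regression on residual z-scores `bhat`.
# prior_grid is searched (plus the null V = 0) when optimize = TRUE.
fit_ser <- function(bhat, V, prior_grid, optimize) {
  J <- length(bhat)
  log_pi <- -log(J)  # uniform prior over variants
  if (optimize) {
    ll <- vapply(prior_grid, function(v) logsumexp(log_pi + single_effect_lbf(bhat, v)),
                 numeric(1))
    best <- which.max(ll)
    # the null model (V -> 0) has marginal log-likelihood 0
    if (ll[best] <= 0) V <- 0 else V <- prior_grid[best]
  }
  if (V == 0) {
    return(list(V = 0, alpha = rep(1 / J, J), mu = rep(0, J),
                post_var = rep(0, J), loglik = 0))
  }
  lbf <- single_effect_lbf(bhat, V)
  w <- lbf - max(lbf)
  alpha <- exp(w) / sum(exp(w))
  shrink <- V / (1 + V)
  list(V = V, alpha = alpha, mu = shrink * bhat,
       post_var = rep(shrink, J), loglik = logsumexp(log_pi + lbf))
}

# Variational objective (up to an additive constant that absorbs y'y):
# -0.5 * E||y - Xb||^2 - sum_k KL_k, with X'X = R, X'y = z, sigma^2 = 1.
susie_objective <- function(z, R, alpha, mu, post_var, V) {
  K <- nrow(alpha); J <- ncol(alpha)
  b_k <- alpha * mu                      # K x J per-effect posterior means
  b_bar <- colSums(b_k)
  quad <- drop(crossprod(b_bar, R %*% b_bar))
  for (k in seq_len(K)) {
    quad <- quad - drop(crossprod(b_k[k, ], R %*% b_k[k, ]))
    quad <- quad + sum(alpha[k, ] * (mu[k, ]^2 + post_var[k, ]))
  }
  e_rss <- -2 * sum(b_bar * z) + quad
  kl <- 0
  for (k in seq_len(K)) {
    a <- alpha[k, ]
    ent <- sum(ifelse(a > 0, a * log(a * J), 0))  # KL(alpha || uniform)
    if (V[k] > 0) {
      tau <- post_var[k, ]
      ent <- ent + sum(a * 0.5 * (log(V[k] / tau) + (tau + mu[k, ]^2) / V[k] - 1))
    }
    kl <- kl + ent
  }
  -0.5 * e_rss - kl
}

#' Fit a sum-of-single-effects model to summary statistics
#'
#' Models the joint effect vector as a sum of `K` single-effect vectors,
#' each placing its effect on one variant. Fitting cycles over the effects:
#' for effect k the expected contributions of the other K - 1 effects are
#' removed from the z-scores through the LD matrix, a single-effect Bayesian
#' regression is fitted to the residual (per-variant normal-prior Bayes
#' factors, inclusion weights proportional to prior times BF), and its
#' posterior mean is restored. Iteration stops when the variational
#' objective changes by less than `elbo_tol` or after `max_iter` cycles
#' (then a warning is raised and `converged = FALSE`). The prior effect
#' variance is, by default, optimized per effect over a log grid, with the
#' effect declared null when the null model fits at least as well.
#'
#' @param region An [aligned_region] with LD, typically pre-filtered at
#'   p < 0.001.
#' @param K Number of single-effect vectors (default 10).
#' @param prior_variance `"optimize"` (default) or a fixed positive value on
#'   the z^2 scale.
#' @param prior_grid Grid searched when optimizing the prior variance.
#' @param max_iter,elbo_tol Convergence controls (defaults 300 and 1e-3).
#' @return An object of class `susie_fit`: `alpha` (K x J inclusion
#'   probabilities, rows sum to 1), `mu` (K x J posterior means given
#'   inclusion), `pip` (per-variant posterior inclusion probabilities),
#'   `V` (per-effect prior variances; 0 marks a null effect),
#'   `elbo_trace`, `converged`, `ids`.
#' @export
susie_rss_fit <- function(region, K = 10L, prior_variance = "optimize",
                          prior_grid = 2^seq(-10, 6, by = 1),
                          max_iter = 300L, elbo_tol = 1e-3) {
  ss <- region$sumstats
  J <- nrow(ss)
  if (J == 0) stop_cisiv("region is empty", "cisiv_usage_error")
  if (J == 1) {
    R <- matrix(1, 1, 1, dimnames = list(ss$variant_id, ss$variant_id))
  } else {
    if (is.null(region$ld)) stop_cisiv("region has no LD matrix", "cisiv_usage_error")
    R <- stabilize_ld(region$ld)
  }
  # standardized-scale effective z: keeps the single-effect residuals
  # linearly consistent with R when individual variants explain a large
  # share of trait variance (raw beta/se is heteroscedastic across variants
  # in that regime and manufactures spurious secondary effects)
  z <- effective_z(ss$beta / ss$se, region_n(region))
  optimize <- identical(prior_variance, "optimize")
  V_fixed <- if (optimize) NA_real_ else as.numeric(prior_variance)

  alpha <- matrix(1 / J, K, J)
  mu <- matrix(0, K, J)
  post_var <- matrix(0, K, J)
  V <- rep(0, K)
  b_k <- alpha * mu
  b_bar <- colSums(b_k)
  elbo_trace <- numeric()
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    for (k in seq_len(K)) {
      b_bar <- b_bar - b_k[k, ]
      resid <- z - drop(R %*% b_bar)
      ser <- fit_ser(resid, V_fixed, prior_grid, optimize)
      V[k] <- ser$V
      alpha[k, ] <- ser$alpha
      mu[k, ] <- ser$mu
      post_var[k, ] <- ser$post_var
      b_k[k, ] <- ser$alpha * ser$mu
      b_bar <- b_bar + b_k[k, ]
    }
    elbo_trace <- c(elbo_trace,
                    susie_objective(z, R, alpha, mu, post_var, V))
    if (it > 1 && abs(diff(utils::tail(elbo_trace, 2))) < elbo_tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning(sprintf("sum-of-single-effects fit did not converge in %d iterations",
                    max_iter))
  }
  pip <- 1 - apply(1 - alpha, 2, prod)
  colnames(alpha) <- colnames(mu) <- ss$variant_id
  structure(list(alpha = alpha, mu = mu, pip = stats::setNames(pip, ss$variant_id),
                 V = V, elbo_trace = elbo_trace, converged = converged,
                 ids = ss$variant_id),
            class = "susie_fit")
}

#' @export
print.susie_fit <- function(x, ...) {
  cat(sprintf("sum-of-single-effects fit: %d variants, %d effects (%d informative)\n",
              length(x$ids), nrow(x$alpha), sum(x$V > 0)))
  cat(sprintf("  converged: %s after %d iteration(s); objective %.4f\n",
              x$converged, length(x$elbo_trace),
              utils::tail(x$elbo_trace, 1)))
  top <- utils::head(sort(x$pip, decreasing = TRUE), 5)
  cat("  top PIPs:", paste(sprintf("%s=%.3f", names(top), top), collapse = ", "), "\n")
  invisible(x)
}

#' Credible sets from a sum-of-single-effects fit
#'
#' For each informative effect, variants are ranked by their effect-specific
#' inclusion probabilities in descending order and accumulated until the
#' cumulative probability reaches `coverage`. A set's purity is the minimum
#' absolute pairwise correlation among its members (1 for singletons); sets
#' below `purity_min` are discarded, and identical member sets arising from
#' different effects are merged.
#'
#' @param fit A `susie_fit`.
#' @param ld LD matrix over the fit's variants.
#' @param coverage Target cumulative inclusion probability (default 0.95).
#' @param purity_min Minimum purity (default 0.5).
#' @return List of credible sets; each is a list with `effect_index`,
#'   `member_ids`, `cumulative_alpha`, `purity`, `representative` (largest
#'   overall PIP; ties by first occurrence).
#' @export
credible_sets <- function(fit, ld, coverage = 0.95, purity_min = 0.5) {
  sets <- list()
  seen <- character()
  for (k in seq_len(nrow(fit$alpha))) {
    if (fit$V[k] <= 0) next
    a <- fit$alpha[k, ]
    ord <- order(a, decreasing = TRUE)
    m <- which(cumsum(a[ord]) >= coverage)[1]
    if (is.na(m)) next
    members <- fit$ids[ord[seq_len(m)]]
    purity <- if (length(members) == 1L) 1 else {
      sub <- abs(ld[members, members])
      min(sub[upper.tri(sub)])
    }
    if (purity < purity_min) next
    key <- paste(sort(members), collapse = "|")
    if (key %in% seen) next
    seen <- c(seen, key)
    pip_m <- fit$pip[members]
    sets[[length(sets) + 1L]] <- list(
      effect_index = k, member_ids = members,
      cumulative_alpha = sum(a[ord[seq_len(m)]]), purity = purity,
      representative = members[which.max(pip_m)])
  }
  sets
}

#' Select one representative instrument per credible set
#'
#' Within each credible set the variant with the largest overall PIP is
#' selected (ties broken uniformly at random under `seed`); duplicate
#' representatives across sets are collapsed. An empty set list yields an
#' empty selection, for which callers typically fall back to the lead
#' variant.
#'
#' @param sets List of credible sets from [credible_sets()].
#' @param fit The `susie_fit` the sets came from.
#' @param region The [aligned_region] used for the fit (for strength).
#' @param seed Integer seed for tie-breaks.
#' @return A `cis_selection`.
#' @export
select_from_credible_sets <- function(sets, fit, region, seed = 1L) {
  tuning <- list(K = nrow(fit$alpha))
  if (!length(sets)) {
    return(empty_selection("susie", tuning, seed,
                           extra = list(n_credible_sets = 0L)))
  }
  reps <- with_seed(seed, vapply(sets, function(cs) {
    pip_m <- fit$pip[cs$member_ids]
    best <- cs$member_ids[pip_m == max(pip_m)]
    if (length(best) == 1L) best else best[sample.int(length(best), 1L)]
  }, character(1)))
  ids <- unique(reps)
  new_selection("susie", tuning, ids, region, seed = seed,
                extra = list(n_credible_sets = length(sets),
                             credible_sets = sets))
}
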