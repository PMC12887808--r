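# Stepwise conditional-and-joint instrument selection: forward additions on
# conditional p-values with a collinearity gate, backward elimination of
# selected variants whose conditional p rises above the cutoff.

#' Collinearity of a candidate with the selected set
#'
#' The proportion of variance of the candidate variant explained by
#' regressing it on the selected variants in correlation space:
#' `r_cs' R_ss^-1 r_cs`, where `r_cs` holds the candidate-selected
#' correlations and `R_ss` is the selected-set LD submatrix (stabilized when
#' numerically singular).
#'
#' @param candidate Variant ID under consideration.
#' @param selected Non-empty character vector of selected variant IDs.
#' @param ld LD matrix covering candidate and selected variants.
#' @return Squared multiple correlation in `[0, 1]` (up to numerical
#'   tolerance).
#' @export
collinearity_r2 <- function(candidate, selected, ld) {
  if (!length(selected)) stop_cisiv("selected set must be non-empty", "cisiv_usage_error")
  if (candidate %in% selected) {
    stop_cisiv("candidate already selected", "cisiv_usage_error")
  }
  Rss <- ld[selected, selected, drop = FALSE]
  if (is_singular(Rss)) Rss <- stabilize_ld(Rss)
  rcs <- ld[candidate, selected]
  drop(crossprod(rcs, solve(Rss, rcs)))
}

#' Conditional association of a candidate given selected variants
#'
#' Fits the joint model on `selected + candidate` via
#' [joint_from_marginal()] and returns the candidate's joint-model
#' coefficient, its standard error from the reconstructed covariance, and
#' the two-sided p-value from the standard-normal reference. Conditioning on
#' an empty set returns the marginal statistics.
#'
#' @param region An [aligned_region].
#' @param selected Character vector of already-selected variant IDs (may be
#'   empty).
#' @param candidate Variant ID to test.
#' @return Named numeric vector `c(beta, se, pval)`.
#' @export
conditional_assoc <- function(region, selected, candidate) {
  ids <- c(selected, candidate)
  ja <- joint_from_marginal(region, ids)
  b <- ja$gamma[[candidate]]
  s <- sqrt(ja$sigma[candidate, candidate])
  p <- exp(joint_logp(region, ids)[[candidate]])
  c(beta = b, se = s, pval = p)
}

# Joint-model two-sided log p-values of a variant set, from the
# standardized-scale conditional statistic (effective_z): for small
# per-variant R^2 this equals gamma/se of the raw reconstruction, and it
# remains calibrated when individual variants explain a large share of
# trait variance (where the equal-marginal-residual-variance approximation
# behind S R^-1 S breaks down and would over-reject). The log scale keeps
# comparisons meaningful where the p-values themselves underflow.
joint_logp <- function(region, ids) {
  reg <- subset_region(region, ids)
  ss <- reg$sumstats
  n <- region_n(reg)
  if (length(ids) == 1L) {
    R <- matrix(1, 1, 1)
  } else {
    R <- reg$ld
    if (is_singular(R)) R <- stabilize_ld(R)
  }
  zt <- effective_z(ss$beta / ss$se, n)
  Rinv <- solve(R)
  zc <- drop(Rinv %*% zt) / sqrt(diag(Rinv))
  stats::setNames(log(2) + stats::pnorm(-abs(zc), log.p = TRUE), ids)
}

joint_pvalues <- function(region, ids) exp(joint_logp(region, ids))

#' Stepwise conditional-and-joint instrument selection
#'
#' Starts from the variant with the smallest marginal p-value (if below
#' `p_cutoff`, else the selection is empty). Forward step: for every
#' remaining variant, its collinearity with the selected set
#' ([collinearity_r2()]) is checked — above `collinearity_threshold` the
#' conditional p is set to 1; otherwise the conditional p is computed via
#' [conditional_assoc()]. The variant with the smallest conditional p below
#' `p_cutoff` is added. Backward step: joint-model p-values of all selected
#' variants are recomputed and, if any is at or above the cutoff, the one
#' with the largest conditional p is removed (at most one per iteration).
#' Iterates until no addition and no removal. A variant removed twice is
#' barred from re-entry to prevent oscillation. No prior p-value filter is
#' required; the cutoff acts internally.
#'
#' @param region An [aligned_region] with LD.
#' @param collinearity_threshold Tuning parameter in (0, 1); reference grid
#'   0.1 to 0.9 in steps of 0.1.
#' @param p_cutoff Conditional p-value cutoff (default 0.001).
#' @param max_iter Maximum outer iterations before a convergence error.
#' @return A `cis_selection`.
#' @export
cojo_select <- function(region, collinearity_threshold, p_cutoff = 0.001,
                        max_iter = 1000L) {
  tuning <- list(collinearity_threshold = collinearity_threshold,
                 p_cutoff = p_cutoff)
  ss <- region$sumstats
  if (!nrow(ss) || min(ss$pval) >= p_cutoff) {
    return(empty_selection("cojo", tuning))
  }
  ids <- ss$variant_id
  log_cutoff <- log(p_cutoff)
  selected <- ids[pick_lead(ss, seq_len(nrow(ss)), "position")]
  removals <- stats::setNames(integer(length(ids)), ids)
  barred <- character()
  for (iter in seq_len(max_iter)) {
    changed <- FALSE
    # forward (conditional p compared on the log scale: printed p-values
    # underflow in strong regions)
    remaining <- setdiff(ids, c(selected, barred))
    if (length(remaining)) {
      pc <- vapply(remaining, function(v) {
        if (collinearity_r2(v, selected, region$ld) > collinearity_threshold) {
          0   # log(1): gated out
        } else {
          joint_logp(region, c(selected, v))[[v]]
        }
      }, numeric(1))
      if (min(pc) < log_cutoff) {
        selected <- c(selected, remaining[which.min(pc)])
        changed <- TRUE
      }
    }
    # backward
    if (length(selected) > 1L) {
      pj <- joint_logp(region, selected)
      if (max(pj) >= log_cutoff) {
        worst <- names(pj)[which.max(pj)]
        selected <- setdiff(selected, worst)
        removals[worst] <- removals[worst] + 1L
        if (removals[worst] >= 2L) barred <- c(barred, worst)
        changed <- TRUE
      }
    }
    if (!changed) {
      return(new_selection("cojo", tuning, selected, region))
    }
  }
  stop_cisiv(sprintf("stepwise selection did not converge in %d iterations; current set: %s",
                     max_iter, paste(selected, collapse = ", ")),
             "cisiv_convergence_error")
}
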