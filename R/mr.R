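# Fixed-effects inverse-variance-weighted MR with correlated instruments.

ivw_core <- function(gx, gy, Omega, stabilized) {
  prec <- solve(Omega, cbind(gx, gy))
  denom <- drop(crossprod(gx, prec[, 1]))
  est <- drop(crossprod(gx, prec[, 2])) / denom
  se <- sqrt(1 / denom)
  z975 <- stats::qnorm(0.975)
  structure(list(estimate = est, se = se,
                 ci_low = est - z975 * se, ci_high = est + z975 * se,
                 pval = 2 * stats::pnorm(-abs(est / se)),
                 J = length(gx), stabilized = stabilized),
            class = "cis_mr")
}

#' Inverse-variance-weighted MR with correlated instruments
#'
#' Fixed-effects IVW for instruments that may be mutually correlated. The
#' weighting matrix is `Omega_ij = se_y_i * se_y_j * rho_ij`; when `Omega`
#' is numerically singular ([is_singular()]) its diagonal is inflated by
#' `epsilon = -lambda_min + 1e-8` and the result is flagged `stabilized`.
#' The estimate is `(gx' Omega^-1 gx)^-1 gx' Omega^-1 gy` with standard
#' error `sqrt((gx' Omega^-1 gx)^-1)`; no residual inflation is applied and
#' the p-value uses the standard-normal reference. With one instrument this
#' reduces to the Wald ratio; with uncorrelated instruments it equals the
#' textbook fixed-effects IVW combination.
#'
#' @param gamma_x Exposure associations per instrument.
#' @param se_x Their standard errors (kept for the input contract; the
#'   fixed-effects weights use outcome uncertainty only).
#' @param gamma_y Outcome associations per instrument.
#' @param se_y Their standard errors.
#' @param rho Instrument correlation matrix (LD submatrix, or identity for
#'   a principal-component basis). Default identity.
#' @return An object of class `cis_mr`: `estimate`, `se`, `ci_low`,
#'   `ci_high`, `pval`, `J`, `stabilized`.
#' @export
mr_ivw <- function(gamma_x, se_x, gamma_y, se_y, rho = diag(length(gamma_x))) {
  J <- length(gamma_x)
  if (J < 1) stop_cisiv("need at least one instrument", "cisiv_usage_error")
  stopifnot(length(se_x) == J, length(gamma_y) == J, length(se_y) == J,
            all(dim(rho) == J))
  if (any(se_x <= 0) || any(se_y <= 0)) {
    stop_cisiv("standard errors must be positive", "cisiv_validation_error")
  }
  Omega <- tcrossprod(se_y) * rho
  stabilized <- FALSE
  if (is_singular(Omega)) {
    Omega <- stabilize_ld(Omega)
    stabilized <- TRUE
  }
  ivw_core(gamma_x, gamma_y, Omega, stabilized)
}

#' @export
print.cis_mr <- function(x, ...) {
  cat(sprintf("IVW MR estimate (fixed effects, %d correlated instrument%s%s)\n",
              x$J, if (x$J == 1) "" else "s",
              if (x$stabilized) ", LD stabilized" else ""))
  cat(sprintf("  estimate = %.4f (se %.4f), 95%% CI [%.4f, %.4f], p = %.3g\n",
              x$estimate, x$se, x$ci_low, x$ci_high, x$pval))
  invisible(x)
}

#' @export
coef.cis_mr <- function(object, ...) c(estimate = object$estimate)

#' @export
confint.cis_mr <- function(object, parm, level = 0.95, ...) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  m <- matrix(c(object$estimate - z * object$se,
                object$estimate + z * object$se), 1, 2,
              dimnames = list("estimate",
                              sprintf("%.1f %%", c((1 - level) / 2,
                                                   1 - (1 - level) / 2) * 100)))
  m
}

# Match outcome rows to region variants, flipping alleles where needed.
align_outcome <- function(region, outcome, ids) {
  ss <- region$sumstats
  ridx <- match(ids, ss$variant_id)
  oidx <- match(ids, outcome$variant_id)
  if (anyNA(oidx)) {
    stop_cisiv(sprintf("selected variant(s) missing from outcome: %s",
                       paste(ids[is.na(oidx)], collapse = ", ")),
               "cisiv_key_error")
  }
  beta_y <- outcome$beta[oidx]
  same <- outcome$effect_allele[oidx] == ss$effect_allele[ridx]
  flip <- outcome$effect_allele[oidx] == ss$other_allele[ridx]
  if (any(!(same | flip))) {
    stop_cisiv(sprintf("outcome alleles irreconcilable for: %s",
                       paste(ids[!(same | flip)], collapse = ", ")),
               "cisiv_harmonization_error")
  }
  beta_y[flip] <- -beta_y[flip]
  list(beta = beta_y, se = outcome$se[oidx])
}

#' MR from a selection result
#'
#' Wires a `cis_selection` into [mr_ivw()]: variant-based selections use the
#' selected variants' marginal exposure and outcome associations with the
#' LD submatrix as the instrument correlation; a principal-component
#' selection transforms both sets of associations to the component basis
#' ([transform_to_pcs()]) first.
#'
#' @param region_x The exposure [aligned_region] the selection was fitted
#'   on.
#' @param outcome A [region_sumstats] for the outcome, harmonized to the
#'   same coded alleles (mismatched-but-flippable alleles are flipped).
#' @param sel A `cis_selection`.
#' @return A `cis_mr`.
#' @export
mr_with_selection <- function(region_x, outcome, sel) {
  if (sel$method == "pca") {
    basis <- sel$pc_basis
    sub <- subset_region(region_x, basis$source_ids)
    tr <- transform_to_pcs(sub, basis, outcome = outcome)
    Om <- tr$outcome_omega
    stabilized <- FALSE
    if (is_singular(Om)) {
      Om <- stabilize_ld(Om)
      stabilized <- TRUE
    }
    return(ivw_core(tr$beta, tr$outcome_beta, Om, stabilized))
  }
  ids <- sel$selected_ids
  if (!length(ids)) stop_cisiv("selection is empty", "cisiv_usage_error")
  ss <- region_x$sumstats
  ridx <- match(ids, ss$variant_id)
  if (anyNA(ridx)) {
    stop_cisiv(sprintf("selected variant(s) missing from region: %s",
                       paste(ids[is.na(ridx)], collapse = ", ")),
               "cisiv_key_error")
  }
  out <- align_outcome(region_x, outcome, ids)
  rho <- if (length(ids) == 1L) matrix(1, 1, 1) else
    region_x$ld[ids, ids, drop = FALSE]
  mr_ivw(ss$beta[ridx], ss$se[ridx], out$beta, out$se, rho)
}
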