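# Instrument strength from marginal summary statistics plus LD:
# reconstruction of the joint (multivariable) model, the F-statistic,
# variance explained and adjusted R^2, and the eigenvalue machinery used to
# keep ill-conditioned LD matrices invertible.

SING_EPS <- 1e-8

#' Test an LD (or covariance) matrix for numerical singularity
#'
#' A symmetric matrix is treated as singular when its smallest eigenvalue
#' falls below `1e-8 * max(1, largest eigenvalue)` — a relative tolerance so
#' that well-conditioned matrices on any scale pass.
#'
#' @param r A symmetric numeric matrix.
#' @return `TRUE` if numerically singular.
#' @export
is_singular <- function(r) {
  ev <- eigen(r, symmetric = TRUE, only.values = TRUE)$values
  min(ev) < SING_EPS * max(1, max(ev))
}

#' Stabilize an LD matrix by inflating its diagonal
#'
#' If the smallest eigenvalue `lambda_min` of `r` is at most `1e-8`, adds
#' `epsilon = -lambda_min + 1e-8` to every diagonal entry so that all
#' eigenvalues become at least `1e-8`; otherwise returns the input
#' unchanged. Off-diagonal entries are never modified, and the operation is
#' idempotent.
#'
#' @param r A symmetric numeric matrix.
#' @return The (possibly) stabilized matrix.
#' @export
stabilize_ld <- function(r) {
  lmin <- min(eigen(r, symmetric = TRUE, only.values = TRUE)$values)
  if (lmin > SING_EPS) return(r)
  diag(r) <- diag(r) + (-lmin + SING_EPS)
  r
}

#' Reconstruct joint effects from marginal statistics and LD
#'
#' Given marginal effects `beta`, standard errors `se` (so z = beta/se) and
#' the LD submatrix `R` over a variant subset, returns the multivariable
#' effect vector `gamma = S R^-1 z` and its covariance `sigma = S R^-1 S`
#' with `S = diag(se)` — the standard summary-statistics joint-regression
#' reconstruction, valid when per-variant phenotypic variance is
#' approximately constant across the region (small per-variant R^2). `R` is
#' stabilized via [stabilize_ld()] before inversion when numerically
#' singular.
#'
#' @param region An [aligned_region].
#' @param subset Variant IDs to include; default all.
#' @return An object of class `joint_assoc`: list with `ids`, `gamma`,
#'   `sigma`, `n`.
#' @export
joint_from_marginal <- function(region, subset = NULL) {
  ids <- subset %||% region$sumstats$variant_id
  if (!length(ids)) stop_cisiv("subset must be non-empty", "cisiv_usage_error")
  reg <- subset_region(region, ids)
  ss <- reg$sumstats
  J <- nrow(ss)
  if (J == 1) {
    R <- matrix(1, 1, 1, dimnames = list(ss$variant_id, ss$variant_id))
  } else {
    if (is.null(reg$ld)) stop_cisiv("region has no LD matrix", "cisiv_usage_error")
    R <- reg$ld
    if (is_singular(R)) R <- stabilize_ld(R)
  }
  z <- ss$beta / ss$se
  Rinv_z <- solve(R, z)
  S <- ss$se
  gamma <- S * Rinv_z
  sigma <- (S * solve(R)) * rep(S, each = J)  # S R^-1 S
  sigma <- (sigma + t(sigma)) / 2
  dimnames(sigma) <- list(ss$variant_id, ss$variant_id)
  structure(list(ids = ss$variant_id,
                 gamma = stats::setNames(gamma, ss$variant_id),
                 sigma = sigma, n = region_n(reg),
                 marginal_z = stats::setNames(z, ss$variant_id), R = R),
            class = "joint_assoc")
}

#' F-statistic for a set of correlated instruments
#'
#' Computes the joint-model F-statistic from a reconstructed multivariable
#' association. The marginal z-statistics are first mapped to the
#' standardized (variant-trait correlation) scale,
#' `rho_j = z_j / sqrt(N - 2 + z_j^2)`, giving the joint variance explained
#' `u = rho' R^-1 rho`; the statistic is the usual joint-regression
#' `F = ((N - J - 1) / J) * u / (1 - u)`. For a single instrument this
#' reduces exactly to the squared z-statistic, and for small per-variant
#' effects it agrees with `(N - J) / (J (N - 1)) * gamma' sigma^-1 gamma`;
#' unlike that raw quadratic form it remains exact when individual variants
#' explain a large share of trait variance. For `joint_assoc` objects built
#' by hand without marginal z-scores the raw quadratic form is used.
#'
#' @param ja A `joint_assoc` from [joint_from_marginal()].
#' @return The F value (non-negative).
#' @export
f_statistic <- function(ja) {
  J <- length(ja$gamma)
  N <- ja$n
  if (N <= J + 1) stop_cisiv("need N > J + 1 for the F-statistic", "cisiv_domain_error")
  if (!is.null(ja$marginal_z) && !is.null(ja$R)) {
    rho <- ja$marginal_z / sqrt(N - 2 + ja$marginal_z^2)
    u <- drop(crossprod(rho, solve(ja$R, rho)))
    u <- min(max(u, 0), 1 - 1e-12)
    return((N - J - 1) / J * u / (1 - u))
  }
  sig <- ja$sigma
  if (is_singular(sig)) sig <- stabilize_ld(sig)
  Q <- drop(crossprod(ja$gamma, solve(sig, ja$gamma)))
  max(0, (N - J) / (J * (N - 1)) * Q)
}

#' Variance explained from the F-statistic
#'
#' `R^2 = J F / (N - J - 1 + J F)`; lies in `[0, 1)` and is strictly
#' increasing in `F` for fixed `N`, `J`.
#'
#' @param F F-statistic (non-negative).
#' @param N GWAS sample size.
#' @param J Number of instruments.
#' @return R-squared.
#' @export
r2_from_f <- function(F, N, J) {
  if (N <= J + 1) stop_cisiv("need N > J + 1 for R^2", "cisiv_domain_error")
  if (F < 0) stop_cisiv("F must be non-negative", "cisiv_domain_error")
  J * F / (N - J - 1 + J * F)
}

#' Adjusted variance explained
#'
#' `R^2_adj = 1 - (1 - R^2)(N - 1)/(N - J - 1)`: penalizes instrument count;
#' never exceeds `R^2` and can be negative. With `J = 0` it reduces to the
#' identity (bookkeeping for the empty selection).
#'
#' @param r2 R-squared in `[0, 1)`.
#' @param N GWAS sample size.
#' @param J Number of instruments.
#' @return Adjusted R-squared.
#' @export
adjusted_r2 <- function(r2, N, J) {
  if (N <= J + 1) stop_cisiv("need N > J + 1 for adjusted R^2", "cisiv_domain_error")
  if (r2 < 0 || r2 >= 1) stop_cisiv("r2 must lie in [0, 1)", "cisiv_domain_error")
  1 - (1 - r2) * (N - 1) / (N - J - 1)
}

# Standardized-scale effective z-statistic: sqrt(n-1) times the marginal
# variant-trait correlation implied by a t-statistic z with n-2 residual df.
# Equals z when the per-variant explained variance is negligible; unlike raw
# z it stays linearly consistent with the LD matrix for strong signals,
# where per-variant marginal residual variances differ. Used for conditional
# p-values and for the sum-of-single-effects inputs.
effective_z <- function(z, n) {
  sqrt(n - 1) * z / sqrt(n - 2 + z^2)
}

# F / R^2 / adjusted R^2 from a joint variance explained u in [0, 1).
strength_from_u <- function(u, N, J) {
  u <- min(max(u, 0), 1 - 1e-12)
  F <- (N - J - 1) / J * u / (1 - u)
  r2 <- r2_from_f(F, N, J)
  list(J = J, F = F, r2 = r2, adj_r2 = adjusted_r2(r2, N, J))
}

#' Instrument strength of a variant subset
#'
#' Convenience chain: [joint_from_marginal()] then [f_statistic()],
#' [r2_from_f()] and [adjusted_r2()]. An empty subset returns `J = 0`,
#' `r2 = 0`.
#'
#' @param region An [aligned_region].
#' @param ids Variant IDs; default all variants in the region.
#' @return List with `J`, `F`, `r2`, `adj_r2`.
#' @export
instrument_strength <- function(region, ids = NULL) {
  ids <- ids %||% region$sumstats$variant_id
  if (!length(ids)) return(list(J = 0L, F = NA_real_, r2 = 0, adj_r2 = 0))
  ja <- joint_from_marginal(region, ids)
  F <- f_statistic(ja)
  N <- ja$n
  J <- length(ids)
  r2 <- r2_from_f(F, N, J)
  list(J = J, F = F, r2 = r2, adj_r2 = adjusted_r2(r2, N, J))
}
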