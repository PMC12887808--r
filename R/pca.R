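# Principal-component instruments: eigendecomposition of the z-weighted LD
# matrix, retention of the leading components up to a variance threshold,
# and re-expression of the summary statistics in the component basis.

#' z-weighted LD matrix
#'
#' Entry ij of the LD matrix is weighted by `z_i * z_j` with
#' `z = beta / se`, prioritizing variants with stronger marginal
#' associations: `W = (z z') * R` (elementwise). `W` is symmetric and
#' positive semi-definite (Schur product of PSD matrices). The region is
#' expected to be pre-filtered at p < 0.001 and pre-pruned at r^2 <= 0.95
#' (see [preprune_r2()]).
#'
#' @param region An [aligned_region] with LD.
#' @return The weighted matrix with variant IDs as dimnames.
#' @export
weighted_ld <- function(region) {
  if (is.null(region$ld)) stop_cisiv("region has no LD matrix", "cisiv_usage_error")
  z <- region$sumstats$beta / region$sumstats$se
  W <- tcrossprod(z) * region$ld
  dimnames(W) <- dimnames(region$ld)
  W
}

#' Principal-component basis of a weighted LD matrix
#'
#' Eigendecomposes `W`, clips negative numerical eigenvalues to zero, and
#' retains the smallest number of leading components whose cumulative
#' eigenvalue fraction (relative to the clipped trace) reaches
#' `variance_threshold`. Eigenvector signs are fixed by making each
#' component's largest-magnitude loading positive.
#'
#' @param W Weighted LD matrix from [weighted_ld()].
#' @param variance_threshold Fraction of variance to preserve, in (0, 1];
#'   reference grids are 0.90 to 0.99 by 0.01 and 0.990 to 0.999 by 0.001.
#' @param ids Variant IDs in loading row order; default `rownames(W)`.
#' @return An object of class `pc_basis`: `loadings` (J x k, orthonormal
#'   columns), `eigenvalues` (length k, non-increasing), `variance_fraction`,
#'   `source_ids`.
#' @export
pc_basis <- function(W, variance_threshold, ids = rownames(W)) {
  if (variance_threshold <= 0 || variance_threshold > 1) {
    stop_cisiv("variance_threshold must lie in (0, 1]", "cisiv_usage_error")
  }
  ee <- eigen(W, symmetric = TRUE)
  vals <- pmax(ee$values, 0)
  total <- sum(vals)
  if (total <= 0) {
    stop_cisiv("weighted LD matrix has no signal to decompose",
               "cisiv_degenerate_error")
  }
  frac <- cumsum(vals) / total
  k <- which(frac >= variance_threshold - 1e-12)[1]
  L <- ee$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i <- which.max(abs(L[, j]))
    if (L[i, j] < 0) L[, j] <- -L[, j]
  }
  rownames(L) <- ids
  structure(list(loadings = L, eigenvalues = vals[seq_len(k)],
                 variance_fraction = frac[k], source_ids = ids),
            class = "pc_basis")
}

#' Re-express associations in the principal-component basis
#'
#' Transforms marginal exposure associations to the retained components:
#' `beta_pc = L' beta` with covariance `L' S R S L` (`L` the loadings, `S =
#' diag(se)`). The same transformation is applied to outcome associations
#' when supplied. The transformed system provides `k` instruments used
#' directly for strength (F, R^2 with J = k) and for IVW MR.
#'
#' @param region The [aligned_region] the basis was built from (same
#'   variants, same order).
#' @param basis A `pc_basis`.
#' @param outcome Optional [region_sumstats] for the outcome, harmonized to
#'   the same coded alleles and covering the basis variants.
#' @return List of class `pc_assoc` with `beta`, `omega` and, when an
#'   outcome is given, `outcome_beta`, `outcome_omega`.
#' @export
transform_to_pcs <- function(region, basis, outcome = NULL) {
  ss <- region$sumstats
  if (!identical(ss$variant_id, basis$source_ids)) {
    stop_cisiv("region variants do not match the PC basis", "cisiv_usage_error")
  }
  L <- basis$loadings
  R <- region$ld
  if (is.null(R) && nrow(ss) == 1L) R <- matrix(1, 1, 1)
  SRS <- (ss$se * R) * rep(ss$se, each = nrow(ss))
  out <- list(beta = drop(crossprod(L, ss$beta)),
              omega = crossprod(L, SRS %*% L),
              basis = basis)
  if (!is.null(outcome)) {
    idx <- match(basis$source_ids, outcome$variant_id)
    if (anyNA(idx)) {
      stop_cisiv(sprintf("outcome is missing variant(s): %s",
                         paste(basis$source_ids[is.na(idx)], collapse = ", ")),
                 "cisiv_key_error")
    }
    se_y <- outcome$se[idx]
    SRSy <- (se_y * R) * rep(se_y, each = nrow(ss))
    out$outcome_beta <- drop(crossprod(L, outcome$beta[idx]))
    out$outcome_omega <- crossprod(L, SRSy %*% L)
  }
  structure(out, class = "pc_assoc")
}

# PCA selection wrapper used by select_instruments(): expects the region
# already p-filtered and r^2-pre-pruned.
pca_select <- function(region, variance_threshold) {
  tuning <- list(variance_threshold = variance_threshold)
  if (n_variants(region) == 0) return(empty_selection("pca", tuning))
  basis <- pc_basis(weighted_ld(region), variance_threshold)
  new_selection("pca", tuning, character(), region, pc_basis = basis)
}
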