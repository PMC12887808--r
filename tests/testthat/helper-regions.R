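# Builders for small fixed regions used across the tests.

# Region from chosen z-scores and an LD matrix: beta = z * se.
toy_region <- function(z, R, n = 10000L, se = rep(0.01, length(z)),
                       ids = sprintf("v%d", seq_along(z)),
                       alleles = c("A", "G")) {
  beta <- z * se
  pval <- pmax(2 * stats::pnorm(-abs(z)), 1e-320)
  ss <- data.frame(variant_id = ids, chrom = "1",
                   pos = seq_along(z) * 100L,
                   effect_allele = alleles[1], other_allele = alleles[2],
                   eaf = 0.3, beta = beta, se = se, pval = pval, n = n,
                   stringsAsFactors = FALSE)
  R <- as.matrix(R)
  dimnames(R) <- list(ids, ids)
  aligned_region(region_sumstats(ss), R)
}

# Small standardized panel + trait + region in one call.
sim_region <- function(n = 2000L, J = 60L,
                       block_sizes = c(J %/% 2L, J - J %/% 2L),
                       scenario = "one_causal", h2 = 0.4, rho = 0.8,
                       seed = 1L, ld = TRUE) {
  panel <- simulate_panel(n, J, block_sizes = block_sizes,
                          within_block_rho = rho, seed = seed)
  trait <- simulate_trait(panel, scenario, h2 = h2, seed = seed + 1L)
  list(panel = panel, trait = trait,
       region = sumstats_from_panel(panel, trait, ld = ld))
}

# Valid correlation matrix from a few off-diagonal entries, checked PSD.
corr_mat <- function(J, entries = list()) {
  R <- diag(J)
  for (e in entries) R[e[1], e[2]] <- R[e[2], e[1]] <- e[3]
  stopifnot(min(eigen(R, symmetric = TRUE, only.values = TRUE)$values) > -1e-10)
  R
}

expect_selection_valid <- function(sel) {
  expect_s3_class(sel, "cis_selection")
  expect_true(sel$r2 >= 0 && sel$r2 < 1)
  expect_lte(sel$adj_r2, sel$r2 + 1e-12)
  if (sel$method != "pca") expect_identical(sel$J, length(sel$selected_ids))
}
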