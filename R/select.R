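# Unified front-end: one fitting function covering all selection
# strategies, applying the shared pre-selection filters.

#' Select cis-MR instruments from a harmonized region
#'
#' The central fitting function. Applies the shared pre-selection pipeline
#' (marginal p < `p_filter` for every method except the stepwise
#' conditional selection, which filters internally; additionally
#' r^2 <= `preprune_cap` before PCA) and dispatches to the requested
#' strategy:
#'
#' * `lead_only` — the single variant with the smallest marginal p-value.
#' * `prune_standard` / `prune_modified` — LD-pruning ([prune_standard()],
#'   [prune_modified()]); requires `r2_threshold`.
#' * `cojo` — stepwise conditional-and-joint selection ([cojo_select()]);
#'   uses `collinearity_threshold` and `p_filter` as the conditional-p
#'   cutoff.
#' * `susie` — sum-of-single-effects fine-mapping ([susie_rss_fit()]) with
#'   one representative per credible set; if no credible set survives
#'   coverage and purity, falls back to the lead variant with
#'   `extra$fallback = "lead"`.
#' * `pca` — principal-component instruments ([pc_basis()]); requires
#'   `variance_threshold`.
#'
#' @param region An [aligned_region] (unfiltered; filters are applied here).
#' @param method Selection strategy.
#' @param r2_threshold Pruning threshold (pruning methods).
#' @param collinearity_threshold Collinearity gate (stepwise selection).
#' @param variance_threshold Variance-preserved threshold (PCA).
#' @param K,coverage,purity_min Sum-of-single-effects controls.
#' @param p_filter Marginal p-value pre-filter / conditional-p cutoff.
#' @param preprune_cap Squared-correlation cap applied before PCA.
#' @param seed Integer seed for random tie-breaks.
#' @param ... Passed to the underlying method function.
#' @return A `cis_selection`.
#' @export
select_instruments <- function(region,
                               method = c("lead_only", "prune_standard",
                                          "prune_modified", "cojo", "susie",
                                          "pca"),
                               r2_threshold = NULL,
                               collinearity_threshold = NULL,
                               variance_threshold = NULL,
                               K = 10L, coverage = 0.95, purity_min = 0.5,
                               p_filter = 0.001, preprune_cap = 0.95,
                               seed = 1L, ...) {
  method <- match.arg(method)
  if (method == "cojo") {
    if (is.null(collinearity_threshold)) {
      stop_cisiv("cojo requires collinearity_threshold", "cisiv_usage_error")
    }
    return(cojo_select(region, collinearity_threshold, p_cutoff = p_filter, ...))
  }
  filt <- filter_by_p(region, p_filter)
  if (n_variants(filt) == 0) {
    return(empty_selection(method, list(p_filter = p_filter), seed))
  }
  switch(method,
    lead_only = {
      lead <- with_seed(seed, pick_lead(filt$sumstats,
                                        seq_len(n_variants(filt)), "random"))
      new_selection("lead_only", list(), filt$sumstats$variant_id[lead],
                    filt, seed = seed)
    },
    prune_standard = {
      if (is.null(r2_threshold)) {
        stop_cisiv("pruning requires r2_threshold", "cisiv_usage_error")
      }
      prune_standard(filt, r2_threshold, seed = seed, ...)
    },
    prune_modified = {
      if (is.null(r2_threshold)) {
        stop_cisiv("pruning requires r2_threshold", "cisiv_usage_error")
      }
      prune_modified(filt, r2_threshold, seed = seed, ...)
    },
    susie = {
      fit <- susie_rss_fit(filt, K = K, ...)
      sets <- credible_sets(fit, filt$ld %||% matrix(1, 1, 1),
                            coverage = coverage, purity_min = purity_min)
      sel <- select_from_credible_sets(sets, fit, filt, seed = seed)
      if (sel$J == 0L) {
        lead <- with_seed(seed, pick_lead(filt$sumstats,
                                          seq_len(n_variants(filt)), "random"))
        sel <- new_selection("susie", list(K = K),
                             filt$sumstats$variant_id[lead], filt, seed = seed,
                             extra = list(fallback = "lead",
                                          n_credible_sets = 0L))
      }
      sel
    },
    pca = {
      if (is.null(variance_threshold)) {
        stop_cisiv("pca requires variance_threshold", "cisiv_usage_error")
      }
      pruned <- preprune_r2(filt, preprune_cap)
      pca_select(pruned, variance_threshold)
    })
}
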