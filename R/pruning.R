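# LD-pruning instrument selection: the standard marginal-p / pairwise-r^2
# iteration, and the gated variant that admits a candidate only when it
# raises adjusted R^2 and keeps the selected LD submatrix non-singular.

# Index of the minimum-p variant among `pool`. Printed p-values underflow
# to a common floor in strong regions, so ties are resolved by the larger
# |z| first; only exact |z| ties fall through to the random (RNG already
# seeded by the caller) or positional tie-break.
pick_lead <- function(ss, pool, tie_break) {
  p <- ss$pval[pool]
  cand <- pool[p == min(p)]
  if (length(cand) > 1L) {
    az <- abs(ss$beta[cand] / ss$se[cand])
    cand <- cand[az == max(az)]
  }
  if (length(cand) == 1L) return(cand)
  if (tie_break == "position") cand[order(ss$pos[cand])][1L] else
    cand[sample.int(length(cand), 1L)]
}

#' Standard LD-pruning
#'
#' Iteratively selects the remaining variant with the smallest marginal
#' p-value (ties broken at random under `seed`), then excludes all remaining
#' variants whose squared correlation with the new selection exceeds
#' `r2_threshold`, until no variants remain. Every pair of selected variants
#' therefore has `r^2 <= r2_threshold`. The region should already be
#' filtered at p < 0.001 (see [filter_by_p()]).
#'
#' @param region An [aligned_region] with LD.
#' @param r2_threshold Pairwise squared-correlation threshold (the tuning
#'   parameter; the reference grid is 0 to 0.8 in steps of 0.02).
#' @param seed Integer seed for random tie-breaks.
#' @param tie_break `"random"` (default) or `"position"` for deterministic
#'   pipelines.
#' @return A `cis_selection`.
#' @export
prune_standard <- function(region, r2_threshold, seed = 1L,
                           tie_break = c("random", "position")) {
  tie_break <- match.arg(tie_break)
  tuning <- list(r2_threshold = r2_threshold)
  if (n_variants(region) == 0) {
    return(empty_selection("prune_standard", tuning, seed))
  }
  ss <- region$sumstats
  r2 <- if (is.null(region$ld)) NULL else region$ld^2
  selected <- with_seed(seed, {
    pool <- seq_len(nrow(ss))
    sel <- integer()
    while (length(pool)) {
      i <- pick_lead(ss, pool, tie_break)
      sel <- c(sel, i)
      pool <- setdiff(pool, i)
      if (length(pool) && !is.null(r2)) pool <- pool[r2[i, pool] <= r2_threshold]
    }
    sel
  })
  new_selection("prune_standard", tuning, ss$variant_id[selected], region,
                seed = seed)
}

#' Adjusted-R^2-gated (modified) LD-pruning
#'
#' Same selection-exclusion loop as [prune_standard()], but a candidate is
#' permanently retained only if (a) adding it strictly increases the
#' adjusted R^2 of the selected set and (b) the LD submatrix of the
#' tentative set is not numerically singular ([is_singular()]). A rejected
#' candidate is removed from further consideration but does not trigger
#' r^2-based exclusion of its neighbours, so other variants in its LD block
#' stay eligible. Adjusted R^2 is strictly increasing along the recorded
#' selection sequence.
#'
#' @inheritParams prune_standard
#' @return A `cis_selection`; `$extra$sequence` records the accepted
#'   variants and the adjusted R^2 after each acceptance.
#' @export
prune_modified <- function(region, r2_threshold, seed = 1L,
                           tie_break = c("random", "position")) {
  tie_break <- match.arg(tie_break)
  tuning <- list(r2_threshold = r2_threshold)
  if (n_variants(region) == 0) {
    return(empty_selection("prune_modified", tuning, seed))
  }
  ss <- region$sumstats
  N <- region_n(region)
  r2 <- if (is.null(region$ld)) NULL else region$ld^2
  res <- with_seed(seed, {
    pool <- seq_len(nrow(ss))
    sel <- integer()
    adj_cur <- 0   # adjusted R^2 of the empty set
    seq_ids <- character(); seq_adj <- numeric()
    while (length(pool)) {
      i <- pick_lead(ss, pool, tie_break)
      pool <- setdiff(pool, i)
      tent <- c(sel, i)
      ok <- TRUE
      if (length(tent) > 1L) {
        sub <- region$ld[tent, tent, drop = FALSE]
        if (is_singular(sub)) ok <- FALSE
      }
      if (ok && N <= length(tent) + 1L) ok <- FALSE
      if (ok) {
        st <- instrument_strength(region, ss$variant_id[tent])
        if (st$adj_r2 > adj_cur + 1e-12) {
          sel <- tent
          adj_cur <- st$adj_r2
          seq_ids <- c(seq_ids, ss$variant_id[i])
          seq_adj <- c(seq_adj, st$adj_r2)
          if (length(pool) && !is.null(r2)) {
            pool <- pool[r2[i, pool] <= r2_threshold]
          }
        }
      }
      # rejected candidates are simply dropped; neighbours stay eligible
    }
    list(sel = sel, seq = data.frame(variant_id = seq_ids, adj_r2 = seq_adj))
  })
  new_selection("prune_modified", tuning, ss$variant_id[res$sel], region,
                seed = seed, extra = list(sequence = res$seq))
}
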