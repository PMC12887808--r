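# Region-level method comparison: all selectors across tuning grids,
# normalized R^2 (relative to the lead variant alone), dense method ranks,
# and the recommended lead-only side-by-side MR check.

default_grids <- list(prune_modified = c(0.1, 0.2, 0.4),
                      cojo = c(0.1, 0.5, 0.9),
                      susie = NA_real_,
                      pca = c(0.90, 0.95, 0.99))

#' Compare selection methods on one region
#'
#' Runs the lead-variant-only baseline plus every method/tuning combination
#' in `grids`, reporting J, F, R^2, adjusted R^2, R^2 normalized by the
#' lead-only R^2, and a dense rank by normalized R^2 (rank 1 = largest;
#' ties share the better rank). When outcome summary statistics are
#' supplied, each row additionally carries the IVW MR estimate and an
#' instability flag: a row is flagged when its MR standard error is smaller
#' than `instability_se_frac` (default 0.5) of the lead-only standard
#' error, or its point estimate differs from the lead-only estimate by more
#' than `instability_z` (default 2) combined standard errors — the
#' recommended safeguard against numerically unstable multi-variant
#' estimates.
#'
#' @param region An [aligned_region].
#' @param outcome Optional [region_sumstats] for the outcome.
#' @param grids Named list mapping method name to a vector of tuning values
#'   (`NA` for methods without a tuning parameter). Default: pruning at
#'   r^2 = 0.1/0.2/0.4, stepwise selection at collinearity 0.1/0.5/0.9,
#'   PCA at 90/95/99% variance, and the fine-mapping selector.
#' @param seed Integer seed for tie-breaks.
#' @param p_filter Marginal p pre-filter passed to [select_instruments()].
#' @param instability_se_frac,instability_z Instability-flag thresholds.
#' @return A data frame of class `comparison_report`, one row per
#'   method/tuning (lead_only first, normalized R^2 = 1).
#' @export
compare_methods <- function(region, outcome = NULL, grids = default_grids,
                            seed = 1L, p_filter = 0.001,
                            instability_se_frac = 0.5, instability_z = 2) {
  lead <- run_method(region, "lead_only", NA, seed)
  if (is.null(lead) || lead$J == 0L || lead$r2 <= 0) {
    stop_cisiv("no variant passes the selection filters; lead-only R^2 is zero",
               "cisiv_usage_error")
  }
  rows <- list(data.frame(method = "lead_only", tuning = NA_real_,
                          stringsAsFactors = FALSE))
  for (m in names(grids)) {
    rows[[length(rows) + 1L]] <- data.frame(method = m, tuning = grids[[m]],
                                            stringsAsFactors = FALSE)
  }
  grid <- do.call(rbind, rows)
  sels <- vector("list", nrow(grid))
  out <- lapply(seq_len(nrow(grid)), function(i) {
    sel <- if (grid$method[i] == "lead_only") lead else
      run_method(region, grid$method[i], grid$tuning[i], seed)
    sels[[i]] <<- sel
    data.frame(method = grid$method[i], tuning = grid$tuning[i],
               J = if (is.null(sel)) NA_integer_ else sel$J,
               F = if (is.null(sel)) NA_real_ else sel$F,
               r2 = if (is.null(sel)) NA_real_ else sel$r2,
               adj_r2 = if (is.null(sel)) NA_real_ else sel$adj_r2,
               normalized_r2 = if (is.null(sel)) NA_real_ else sel$r2 / lead$r2,
               stringsAsFactors = FALSE)
  })
  rep <- do.call(rbind, out)
  # dense rank, 1 = largest normalized R^2, ties share the better rank
  vals <- sort(unique(round(rep$normalized_r2, 12)), decreasing = TRUE)
  rep$rank <- match(round(rep$normalized_r2, 12), vals)
  if (!is.null(outcome)) {
    mr_lead <- mr_with_selection(region, outcome, lead)
    mr_rows <- lapply(seq_len(nrow(rep)), function(i) {
      sel <- sels[[i]]
      mr <- if (is.null(sel) || sel$J == 0L) NULL else
        tryCatch(mr_with_selection(region, outcome, sel),
                 error = function(e) NULL)
      if (is.null(mr)) {
        data.frame(mr_estimate = NA_real_, mr_se = NA_real_,
                   stabilized = NA, instability_suspect = NA)
      } else {
        shift <- abs(mr$estimate - mr_lead$estimate) /
          sqrt(mr$se^2 + mr_lead$se^2)
        data.frame(mr_estimate = mr$estimate, mr_se = mr$se,
                   stabilized = mr$stabilized,
                   instability_suspect =
                     mr$se < instability_se_frac * mr_lead$se ||
                     shift > instability_z)
      }
    })
    rep <- cbind(rep, do.call(rbind, mr_rows))
  }
  rownames(rep) <- NULL
  class(rep) <- c("comparison_report", "data.frame")
  attr(rep, "lead_r2") <- lead$r2
  rep
}

#' Summarize method ranks across regions
#'
#' Aggregates the per-region ranks of [compare_methods()] reports into a
#' per-method/tuning distribution (minimum, quartiles, maximum).
#'
#' @param reports A list of `comparison_report` objects (>= 1).
#' @return A data frame with one row per method/tuning and columns
#'   `min_rank`, `q1_rank`, `median_rank`, `q3_rank`, `max_rank`.
#' @export
rank_methods <- function(reports) {
  if (!length(reports)) stop_cisiv("need at least one report", "cisiv_usage_error")
  all <- do.call(rbind, lapply(reports, function(r) {
    as.data.frame(r)[, c("method", "tuning", "rank")]
  }))
  key <- method_key(all$method, all$tuning)
  out <- do.call(rbind, lapply(split(all, key), function(d) {
    q <- stats::quantile(d$rank, c(0, 0.25, 0.5, 0.75, 1), na.rm = TRUE)
    data.frame(method = d$method[1], tuning = d$tuning[1],
               min_rank = q[1], q1_rank = q[2], median_rank = q[3],
               q3_rank = q[4], max_rank = q[5], stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
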