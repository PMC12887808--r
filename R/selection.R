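# The classed result returned by every selection strategy, plus its methods.

# Build a cis_selection from a region and a chosen variant set (or PC basis).
new_selection <- function(method, tuning, selected_ids, region,
                          pc_basis = NULL, seed = NA_integer_,
                          extra = list()) {
  if (method == "pca") {
    stopifnot(!is.null(pc_basis))
    # strength of the component basis: project the standardized-scale
    # (correlation) system onto the retained components
    sub <- subset_region(region, pc_basis$source_ids)
    N <- region_n(region)
    k <- ncol(pc_basis$loadings)
    L <- pc_basis$loadings
    z <- sub$sumstats$beta / sub$sumstats$se
    rho <- z / sqrt(N - 2 + z^2)
    RL <- crossprod(L, sub$ld %*% L)
    if (is_singular(RL)) RL <- stabilize_ld(RL)
    proj <- drop(crossprod(L, rho))
    u <- drop(crossprod(proj, solve(RL, proj)))
    st <- strength_from_u(u, N, k)
    selected_ids <- character()
  } else {
    st <- instrument_strength(region, selected_ids)
  }
  structure(list(method = method, tuning = tuning,
                 selected_ids = selected_ids, pc_basis = pc_basis,
                 J = st$J, F = st$F, r2 = st$r2, adj_r2 = st$adj_r2,
                 seed = seed, extra = extra, joint = NULL,
                 region_n = region_n(region)),
            class = "cis_selection")
}

empty_selection <- function(method, tuning, seed = NA_integer_, extra = list()) {
  structure(list(method = method, tuning = tuning,
                 selected_ids = character(), pc_basis = NULL,
                 J = 0L, F = NA_real_, r2 = 0, adj_r2 = 0,
                 seed = seed, extra = extra, joint = NULL,
                 region_n = NA_integer_),
            class = "cis_selection")
}

#' @export
print.cis_selection <- function(x, ...) {
  tun <- if (length(x$tuning)) {
    paste(names(x$tuning), unlist(x$tuning), sep = " = ", collapse = ", ")
  } else "none"
  cat(sprintf("cis-MR instrument selection (%s)\n", x$method))
  cat(sprintf("  tuning: %s\n", tun))
  cat(sprintf("  J = %d, F = %s, R2 = %s, adj. R2 = %s\n", x$J,
              format(x$F, digits = 4), format(x$r2, digits = 4),
              format(x$adj_r2, digits = 4)))
  if (length(x$selected_ids)) {
    shown <- utils::head(x$selected_ids, 8)
    cat(sprintf("  instruments: %s%s\n", paste(shown, collapse = ", "),
                if (x$J > 8) ", ..." else ""))
  } else if (!is.null(x$pc_basis)) {
    cat(sprintf("  instruments: %d principal component(s) of the weighted LD matrix\n",
                x$J))
  }
  if (!is.null(x$extra$fallback)) {
    cat(sprintf("  note: fell back to %s\n", x$extra$fallback))
  }
  invisible(x)
}

#' @export
summary.cis_selection <- function(object, ...) {
  print(object)
  seqn <- object$extra$sequence
  if (!is.null(seqn)) {
    cat("selection sequence:\n")
    print(seqn, row.names = FALSE)
  }
  invisible(object)
}

#' Joint effect estimates of the selected instruments
#'
#' For variant-based selections, returns the multivariable effect vector of
#' the selected set from [joint_from_marginal()] on the fitting region.
#'
#' @param object A `cis_selection`.
#' @param region The [aligned_region] the selection was fitted on.
#' @param ... Unused.
#' @return Named numeric vector of joint effects.
#' @export
coef.cis_selection <- function(object, region, ...) {
  if (!length(object$selected_ids)) return(stats::setNames(numeric(), character()))
  joint_from_marginal(region, object$selected_ids)$gamma
}
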