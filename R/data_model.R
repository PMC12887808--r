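#' @keywords internal
"_PACKAGE"

# Canonical summary-statistics columns for a single cis region.
SUMSTATS_COLS <- c("variant_id", "chrom", "pos", "effect_allele",
                   "other_allele", "eaf", "beta", "se", "pval", "n")

#' Validate a region summary-statistics table
#'
#' Checks a data frame of per-variant marginal association statistics for a
#' single cis gene region: one row per variant with the effect estimate
#' (`beta`), its standard error (`se`), two-sided p-value, effect-allele
#' frequency and GWAS sample size. Rows with missing `beta` or `se` are
#' dropped with a message.
#'
#' @param df A data frame containing the columns `variant_id`, `chrom`,
#'   `pos`, `effect_allele`, `other_allele`, `eaf`, `beta`, `se`, `pval`, `n`.
#' @return The validated data frame with class `region_sumstats`.
#' @export
region_sumstats <- function(df) {
  missing_cols <- setdiff(SUMSTATS_COLS, names(df))
  if (length(missing_cols)) {
    stop_cisiv(sprintf("missing required column(s): %s",
                       paste(missing_cols, collapse = ", ")),
               "cisiv_format_error")
  }
  df <- as.data.frame(df)[, SUMSTATS_COLS]
  drop <- is.na(df$beta) | is.na(df$se)
  if (any(drop)) {
    message(sprintf("dropping %d row(s) with missing beta/se", sum(drop)))
    df <- df[!drop, , drop = FALSE]
  }
  df$variant_id <- as.character(df$variant_id)
  df$chrom <- as.character(df$chrom)
  df$pos <- as.integer(df$pos)
  for (col in c("eaf", "beta", "se", "pval")) df[[col]] <- as.numeric(df[[col]])
  df$n <- as.integer(df$n)
  if (anyDuplicated(df$variant_id)) {
    stop_cisiv("variant_id values must be unique", "cisiv_validation_error")
  }
  bad_se <- which(!(df$se > 0))
  if (length(bad_se)) {
    stop_cisiv(sprintf("non-positive se at row %d (variant %s)",
                       bad_se[1], df$variant_id[bad_se[1]]),
               "cisiv_validation_error")
  }
  if (any(df$eaf <= 0 | df$eaf >= 1)) {
    stop_cisiv("eaf must lie strictly between 0 and 1", "cisiv_validation_error")
  }
  if (any(df$pval <= 0 | df$pval > 1)) {
    stop_cisiv("pval must lie in (0, 1]", "cisiv_validation_error")
  }
  rownames(df) <- NULL
  class(df) <- c("region_sumstats", "data.frame")
  df
}

#' Read region summary statistics from a delimited file
#'
#' Reads a tab-delimited GWAS summary-statistics file with a header row. File
#' columns with non-canonical names can be mapped via `column_map`, a named
#' character vector `c(canonical = "file_name")` (for example
#' `c(variant_id = "SNP", beta = "BETA")`).
#'
#' @param path Path to a tab-delimited file with a header.
#' @param column_map Optional named character vector mapping canonical column
#'   names to the names used in the file.
#' @return A validated [region_sumstats] data frame.
#' @export
read_sumstats <- function(path, column_map = NULL) {
  if (!file.exists(path)) {
    stop_cisiv(sprintf("file not found: %s", path), "cisiv_format_error")
  }
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(column_map)) {
    for (canon in names(column_map)) {
      src <- column_map[[canon]]
      if (!src %in% names(df)) {
        stop_cisiv(sprintf("mapped column '%s' (for '%s') not found in file",
                           src, canon), "cisiv_format_error")
      }
      names(df)[names(df) == src] <- canon
    }
  }
  region_sumstats(df)
}

#' Write region summary statistics to a tab-delimited file
#'
#' @param ss A [region_sumstats] data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(ss, path) {
  utils::write.table(as.data.frame(ss), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Construct and validate an LD matrix
#'
#' An LD matrix is a square matrix of signed correlations between variants,
#' carried as a base matrix whose row and column names are the variant IDs.
#' Validity requires symmetry, a unit diagonal and entries bounded by 1 in
#' absolute value (all up to a 1e-8 tolerance).
#'
#' @param r A square numeric matrix of signed correlations.
#' @param ids Optional variant IDs; defaults to the existing dimnames.
#' @return The validated matrix with `ids` as dimnames.
#' @export
ld_matrix <- function(r, ids = rownames(r)) {
  r <- as.matrix(r)
  if (nrow(r) != ncol(r)) {
    stop_cisiv("LD matrix must be square", "cisiv_format_error")
  }
  if (is.null(ids) || length(ids) != nrow(r)) {
    stop_cisiv("LD matrix needs one variant ID per row", "cisiv_format_error")
  }
  dimnames(r) <- list(ids, ids)
  if (max(abs(r - t(r))) > 1e-8) {
    stop_cisiv("LD matrix is not symmetric (tolerance 1e-8)",
               "cisiv_validation_error")
  }
  if (max(abs(diag(r) - 1)) > 1e-8) {
    stop_cisiv("LD matrix diagonal must equal 1 (tolerance 1e-8)",
               "cisiv_validation_error")
  }
  if (max(abs(r)) > 1 + 1e-8) {
    stop_cisiv("LD entries must satisfy |r| <= 1 (tolerance 1e-8)",
               "cisiv_validation_error")
  }
  r
}

#' Read an LD matrix from a file
#'
#' Two layouts are supported. `square`: the first row is a whitespace-
#' delimited header of variant IDs and the body is the square matrix of
#' correlations. `long`: a whitespace-delimited table with columns `SNP_A`,
#' `SNP_B` and `R` (PLINK `.ld` style); the matrix is symmetrized by
#' mirroring, and pairs absent from the file are set to 0 with a warning.
#'
#' @param path Path to the LD file.
#' @param format `"square"` or `"long"`.
#' @return A validated LD matrix (see [ld_matrix()]).
#' @export
read_ld <- function(path, format = c("square", "long")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    stop_cisiv(sprintf("file not found: %s", path), "cisiv_format_error")
  }
  if (format == "square") {
    header <- scan(path, what = character(), nlines = 1, quiet = TRUE)
    body <- utils::read.table(path, skip = 1, header = FALSE)
    if (nrow(body) != length(header) || ncol(body) != length(header)) {
      stop_cisiv(sprintf(
        "square LD file must have a %d x %d body to match its header; got %d x %d",
        length(header), length(header), nrow(body), ncol(body)),
        "cisiv_format_error")
    }
    r <- as.matrix(body)
    ld_matrix(r, ids = header)
  } else {
    tab <- utils::read.table(path, header = TRUE)
    need <- c("SNP_A", "SNP_B", "R")
    if (!all(need %in% names(tab))) {
      stop_cisiv("long LD file requires columns SNP_A, SNP_B, R",
                 "cisiv_format_error")
    }
    ids <- unique(c(tab$SNP_A, tab$SNP_B))
    J <- length(ids)
    r <- matrix(0, J, J, dimnames = list(ids, ids))
    diag(r) <- 1
    r[cbind(match(tab$SNP_A, ids), match(tab$SNP_B, ids))] <- tab$R
    r[cbind(match(tab$SNP_B, ids), match(tab$SNP_A, ids))] <- tab$R
    n_missing <- (J * (J - 1)) %/% 2 - nrow(unique(tab[c("SNP_A", "SNP_B")]))
    if (n_missing > 0) {
      warning(sprintf("%d unobserved variant pair(s) set to r = 0", n_missing))
    }
    ld_matrix(r, ids = ids)
  }
}

#' Construct an aligned region
#'
#' Bundles summary statistics and an LD matrix over the same variants in the
#' same order: the joint input contract for every selection method. Use
#' [harmonize()] to build one from unaligned inputs.
#'
#' @param sumstats A [region_sumstats] data frame.
#' @param ld An LD matrix over the same variants in the same order, or `NULL`
#'   when only single-variant operations are needed.
#' @param palindromic_flagged Character vector of variant IDs flagged as
#'   palindromic with ambiguous frequency (kept, not dropped).
#' @return An object of class `aligned_region`.
#' @export
aligned_region <- function(sumstats, ld = NULL, palindromic_flagged = character()) {
  if (!inherits(sumstats, "region_sumstats")) sumstats <- region_sumstats(sumstats)
  if (!is.null(ld)) {
    ld <- ld_matrix(ld)
    if (!identical(rownames(ld), sumstats$variant_id)) {
      stop_cisiv("sumstats and LD must cover identical variants in identical order",
                 "cisiv_validation_error")
    }
  }
  structure(list(sumstats = sumstats, ld = ld,
                 palindromic_flagged = palindromic_flagged),
            class = "aligned_region")
}

#' @export
print.aligned_region <- function(x, ...) {
  cat(sprintf("aligned_region: %d variant(s), N = %s, LD %s\n",
              nrow(x$sumstats),
              if (nrow(x$sumstats)) format(region_n(x)) else "NA",
              if (is.null(x$ld)) "absent" else "present"))
  if (length(x$palindromic_flagged)) {
    cat(sprintf("  %d palindromic variant(s) flagged\n",
                length(x$palindromic_flagged)))
  }
  invisible(x)
}

#' Number of variants in an aligned region
#' @param region An `aligned_region`.
#' @return Integer count.
#' @export
n_variants <- function(region) nrow(region$sumstats)

# Region-level GWAS sample size: min(n) when heterogeneous (conservative).
region_n <- function(region) {
  if (!nrow(region$sumstats)) return(NA_integer_)
  min(region$sumstats$n)
}

# Subset an aligned region to variant indices or IDs, preserving order given.
subset_region <- function(region, which_) {
  ss <- region$sumstats
  if (is.character(which_)) {
    idx <- match(which_, ss$variant_id)
    if (anyNA(idx)) {
      stop_cisiv(sprintf("variant(s) not in region: %s",
                         paste(which_[is.na(idx)], collapse = ", ")),
                 "cisiv_key_error")
    }
  } else {
    idx <- which_
  }
  ss2 <- ss[idx, , drop = FALSE]
  rownames(ss2) <- NULL
  class(ss2) <- c("region_sumstats", "data.frame")
  ld2 <- if (is.null(region$ld)) NULL else region$ld[idx, idx, drop = FALSE]
  structure(list(sumstats = ss2, ld = ld2,
                 palindromic_flagged =
                   intersect(region$palindromic_flagged, ss2$variant_id)),
            class = "aligned_region")
}

is_palindromic <- function(a1, a2) {
  p <- paste(pmin(a1, a2), pmax(a1, a2))
  p %in% c("A T", "C G")
}

#' Harmonize summary statistics to an LD reference
#'
#' Restricts both inputs to their common variants (ordered by genomic
#' position, ties by variant ID), and re-expresses every effect with respect
#' to the LD reference's coded allele: when the summary-statistics effect
#' allele is the reference's other allele, `beta` is negated and `eaf`
#' replaced by `1 - eaf`. Strand flips are not attempted. Palindromic
#' variants (A/T or C/G) with 0.42 < eaf < 0.58 are flagged in the result
#' but kept.
#'
#' @param ss A [region_sumstats] data frame.
#' @param ld An LD matrix (see [ld_matrix()]).
#' @param ld_coded_alleles Named character vector mapping variant ID to the
#'   allele whose dosage the LD reference counts.
#' @return An [aligned_region].
#' @export
harmonize <- function(ss, ld, ld_coded_alleles) {
  common <- intersect(ss$variant_id, rownames(ld))
  if (!length(common)) {
    stop_cisiv("no variants shared between sumstats and LD",
               "cisiv_harmonization_error")
  }
  ss2 <- ss[match(common, ss$variant_id), , drop = FALSE]
  ord <- order(ss2$pos, ss2$variant_id)
  ss2 <- ss2[ord, , drop = FALSE]
  coded <- ld_coded_alleles[ss2$variant_id]
  if (anyNA(coded)) {
    stop_cisiv(sprintf("no coded allele provided for: %s",
                       paste(ss2$variant_id[is.na(coded)], collapse = ", ")),
               "cisiv_harmonization_error")
  }
  match_ok <- ss2$effect_allele == coded
  flip_ok <- ss2$other_allele == coded
  bad <- !(match_ok | flip_ok)
  if (any(bad)) {
    stop_cisiv(sprintf("irreconcilable alleles for: %s",
                       paste(ss2$variant_id[bad], collapse = ", ")),
               "cisiv_harmonization_error")
  }
  if (any(flip_ok)) {
    tmp <- ss2$effect_allele[flip_ok]
    ss2$effect_allele[flip_ok] <- ss2$other_allele[flip_ok]
    ss2$other_allele[flip_ok] <- tmp
    ss2$beta[flip_ok] <- -ss2$beta[flip_ok]
    ss2$eaf[flip_ok] <- 1 - ss2$eaf[flip_ok]
  }
  flagged <- ss2$variant_id[is_palindromic(ss2$effect_allele, ss2$other_allele) &
                              ss2$eaf > 0.42 & ss2$eaf < 0.58]
  rownames(ss2) <- NULL
  class(ss2) <- c("region_sumstats", "data.frame")
  aligned_region(ss2, ld[ss2$variant_id, ss2$variant_id],
                 palindromic_flagged = flagged)
}

#' Filter a region by marginal p-value
#'
#' Keeps variants with marginal p strictly below `p_threshold` (default
#' 0.001, the pre-selection filter applied before pruning, fine-mapping and
#' PCA). An empty result is valid; the caller decides how to proceed.
#'
#' @param region An [aligned_region].
#' @param p_threshold Strict upper bound on the marginal p-value.
#' @return The filtered [aligned_region].
#' @export
filter_by_p <- function(region, p_threshold = 0.001) {
  keep <- which(region$sumstats$pval < p_threshold)
  subset_region(region, keep)
}

#' Remove near-duplicate variants by a squared-correlation cap
#'
#' Greedy pass in ascending marginal p-value order: a variant is dropped when
#' its squared correlation with any already-kept variant exceeds `r2_cap`
#' (default 0.95, used before PCA to remove extremely highly correlated
#' variants). The region's lead variant always survives.
#'
#' @param region A non-empty [aligned_region] with LD.
#' @param r2_cap Strict upper bound on pairwise squared correlation.
#' @return The pruned [aligned_region], original variant order preserved.
#' @export
preprune_r2 <- function(region, r2_cap = 0.95) {
  J <- n_variants(region)
  if (J == 0) stop_cisiv("region is empty", "cisiv_usage_error")
  if (J == 1) return(region)
  if (is.null(region$ld)) stop_cisiv("region has no LD matrix", "cisiv_usage_error")
  ss <- region$sumstats
  # |z| breaks p-value ties (printed p underflows in strong regions)
  ord <- order(ss$pval, -abs(ss$beta / ss$se), ss$pos, ss$variant_id)
  kept <- integer()
  r2 <- region$ld^2
  for (i in ord) {
    if (!length(kept) || all(r2[i, kept] <= r2_cap)) kept <- c(kept, i)
  }
  subset_region(region, sort(kept))
}
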