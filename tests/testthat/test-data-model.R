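test_that("sumstats round-trip through write and read preserves all fields", {
  reg <- toy_region(c(5, -3, 2), corr_mat(3, list(c(1, 2, 0.5))))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_sumstats(reg$sumstats, f)
  back <- read_sumstats(f)
  for (col in c("eaf", "beta", "se", "pval")) {
    expect_equal(back[[col]], reg$sumstats[[col]], tolerance = 1e-12)
  }
  expect_identical(back$variant_id, reg$sumstats$variant_id)
  expect_identical(back$n, reg$sumstats$n)
})

test_that("read_sumstats maps non-canonical column names and validates", {
  ss <- toy_region(c(4, 3, 2), diag(3))$sumstats
  df <- as.data.frame(ss)
  names(df)[names(df) == "variant_id"] <- "SNP"
  names(df)[names(df) == "beta"] <- "BETA"
  names(df)[names(df) == "se"] <- "SE"
  f <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
  back <- read_sumstats(f, column_map = c(variant_id = "SNP", beta = "BETA",
                                          se = "SE"))
  expect_equal(back$beta, ss$beta, tolerance = 1e-12)
  expect_error(read_sumstats(f), class = "cisiv_format_error")

  # non-positive se names the offending row
  df2 <- as.data.frame(ss)
  df2$se[2] <- 0
  f2 <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(df2, f2, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_sumstats(f2), "row 2", class = "cisiv_validation_error")
})

test_that("read_ld handles square and long formats, rejects asymmetry", {
  f <- withr::local_tempfile(fileext = ".ld")
  writeLines(c("A B", "1 0.5", "0.5 1"), f)
  m <- read_ld(f, "square")
  expect_equal(m["A", "B"], 0.5)

  flong <- withr::local_tempfile(fileext = ".ld")
  writeLines(c("SNP_A SNP_B R", "A B 0.3"), flong)
  m2 <- read_ld(flong, "long")
  expect_equal(unname(m2), matrix(c(1, 0.3, 0.3, 1), 2))

  # unobserved pairs are zero-filled with a warning
  flong2 <- withr::local_tempfile(fileext = ".ld")
  writeLines(c("SNP_A SNP_B R", "A B 0.3", "A C 0.2"), flong2)
  expect_warning(m3 <- read_ld(flong2, "long"), "unobserved")
  expect_equal(m3["B", "C"], 0)

  fbad <- withr::local_tempfile(fileext = ".ld")
  writeLines(c("A B", "1 0.5", "0.4 1"), fbad)
  expect_error(read_ld(fbad, "square"), class = "cisiv_validation_error")
})

test_that("harmonize flips effects to the LD coded allele and intersects", {
  ss <- toy_region(c(5, 4, 3), diag(3))$sumstats
  ss$variant_id <- c("A", "B", "C")
  R <- diag(3); dimnames(R) <- list(c("B", "C", "D"), c("B", "C", "D"))
  coded <- c(B = "G", C = "A", D = "A")  # B needs a flip
  reg <- harmonize(ss, R, coded)
  expect_identical(reg$sumstats$variant_id, c("B", "C"))
  b_orig <- ss$beta[ss$variant_id == "B"]
  expect_equal(reg$sumstats$beta[reg$sumstats$variant_id == "B"], -b_orig)
  expect_equal(reg$sumstats$eaf[reg$sumstats$variant_id == "B"], 1 - 0.3)
  # matching allele untouched
  expect_equal(reg$sumstats$beta[reg$sumstats$variant_id == "C"],
               ss$beta[ss$variant_id == "C"])
  # idempotent: second application changes nothing
  reg2 <- harmonize(reg$sumstats, reg$ld, c(B = "G", C = "A"))
  expect_equal(reg2$sumstats$beta, reg$sumstats$beta)
  expect_equal(reg2$sumstats$eaf, reg$sumstats$eaf)
  # irreconcilable alleles error with the variant named
  expect_error(harmonize(ss, R, c(B = "T", C = "A", D = "A")), "B",
               class = "cisiv_harmonization_error")
})

test_that("palindromic variants with ambiguous frequency are flagged, kept", {
  ss <- toy_region(c(5, 4), diag(2), alleles = c("A", "T"))$sumstats
  ss$eaf <- c(0.5, 0.2)
  R <- diag(2); dimnames(R) <- list(ss$variant_id, ss$variant_id)
  reg <- harmonize(ss, R, stats::setNames(c("A", "A"), ss$variant_id))
  expect_identical(reg$palindromic_flagged, "v1")
  expect_identical(nrow(reg$sumstats), 2L)
})

test_that("filter_by_p keeps strictly sub-threshold variants", {
  z <- stats::qnorm(c(1e-8, 0.01, 5e-4) / 2)  # two-sided p of 1e-8, .01, 5e-4
  reg <- toy_region(z, diag(3))
  expect_identical(n_variants(filter_by_p(reg)), 2L)
  expect_identical(n_variants(filter_by_p(reg, 1.0)), 3L)
  expect_identical(n_variants(filter_by_p(reg, 1e-12)), 0L)
})

test_that("preprune_r2 greedily drops near-duplicates, keeps the lead", {
  z <- stats::qnorm(c(1e-9, 1e-5) / 2)
  reg <- toy_region(z, corr_mat(2, list(c(1, 2, sqrt(0.99)))))
  out <- preprune_r2(reg, 0.95)
  expect_identical(out$sumstats$variant_id, "v1")
  # all pairs below the cap: unchanged
  reg2 <- toy_region(c(6, 5, 4), corr_mat(3, list(c(1, 2, 0.5))))
  expect_identical(n_variants(preprune_r2(reg2, 0.95)), 3L)
  expect_identical(n_variants(preprune_r2(subset_region(reg2, 1L), 0.95)), 1L)
})

test_that("filter and preprune retain the same set under row permutation", {
  set.seed(4)
  for (i in 1:5) {
    J <- 12
    base <- sim_region(n = 600, J = J, block_sizes = c(6L, 6L), seed = i)$region
    perm <- sample(J)
    permuted <- subset_region(base, perm)
    a <- sort(filter_by_p(base, 0.05)$sumstats$variant_id)
    b <- sort(filter_by_p(permuted, 0.05)$sumstats$variant_id)
    expect_identical(a, b)
    pa <- preprune_r2(base, 0.6)$sumstats$variant_id
    pb <- preprune_r2(permuted, 0.6)$sumstats$variant_id
    expect_identical(sort(pa), sort(pb))
    r2 <- base$ld[pa, pa]^2
    expect_lte(max(r2[upper.tri(r2)]), 0.6)
  }
})

test_that("the shipped synthetic example region loads and harmonizes cleanly", {
  ssf <- system.file("extdata", "example_synthetic_exposure.tsv", package = "cisiv")
  ldf <- system.file("extdata", "example_synthetic_ld.tsv", package = "cisiv")
  ss <- read_sumstats(ssf)
  ld <- read_ld(ldf, "square")
  reg <- harmonize(ss, ld, stats::setNames(ss$effect_allele, ss$variant_id))
  expect_identical(n_variants(reg), 40L)
  sel <- select_instruments(reg, "cojo", collinearity_threshold = 0.5)
  expect_gte(sel$J, 1L)
  expect_gt(sel$r2, 0)
})

test_that("rows with missing beta or se are dropped with a message", {
  ss <- as.data.frame(toy_region(c(4, 3, 2), diag(3))$sumstats)
  ss$beta[2] <- NA
  expect_message(out <- region_sumstats(ss), "1 row")
  expect_identical(nrow(out), 2L)
})
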