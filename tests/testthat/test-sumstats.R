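test_that("reading a well-formed TSV returns all rows and logs nothing", {
  df <- data.frame(rsid = c("rs1", "rs2", "rs3"),
                   effect_allele = c("A", "C", "T"),
                   other_allele = c("G", "T", "C"),
                   eaf = c(0.2, 0.4, 0.3), beta = c(0.1, -0.05, 0.02),
                   se = c(0.01, 0.02, 0.01), pvalue = c(1e-20, 1e-3, 0.04),
                   n = 50000)
  path <- write_sumstats_tsv(df, tempfile(fileext = ".tsv"))
  ds <- read_summary_dataset(path, trait_name = "bmi")
  expect_s3_class(ds, "summary_dataset")
  expect_equal(nrow(ds$snps), 3)
  expect_equal(nrow(ds$rejected), 0)
  expect_equal(ds$snps$beta, df$beta)
})

test_that("invalid rows are rejected with reasons, not fatal", {
  df <- data.frame(rsid = paste0("rs", 1:6),
                   effect_allele = c("A", "C", "", "A", "A", "A"),
                   other_allele = c("G", "C", "G", "G", "G", "G"),
                   eaf = c(0.2, 0.3, 0.3, 1.7, 0.3, 0.3),
                   beta = 0.1, se = c(0.01, 0.01, 0.01, 0.01, 0, 0.01),
                   pvalue = c(0.01, 0.01, 0.01, 0.01, 0.01, 1.4), n = 1000)
  path <- write_sumstats_tsv(df, tempfile(fileext = ".tsv"))
  ds <- read_summary_dataset(path, trait_name = "x")
  expect_equal(ds$snps$rsid, "rs1")
  expect_setequal(ds$rejected$reason,
                  c("identical alleles", "empty allele", "eaf outside [0,1]",
                    "nonpositive se", "pvalue outside (0,1]"))
  expect_equal(ds$rejected$reason[ds$rejected$rsid == "rs5"],
               "nonpositive se")
})

test_that("duplicated rsids and configuration errors are named", {
  df <- data.frame(rsid = c("rs1", "rs1"), effect_allele = "A",
                   other_allele = "G", eaf = 0.3, beta = 0.1, se = 0.01,
                   pvalue = 0.01, n = 1000)
  path <- write_sumstats_tsv(df, tempfile(fileext = ".tsv"))
  expect_error(read_summary_dataset(path, trait_name = "x"), "rs1")

  df2 <- df[1, ]
  names(df2)[names(df2) == "se"] <- "stderr"
  path2 <- write_sumstats_tsv(df2, tempfile(fileext = ".tsv"))
  expect_error(read_summary_dataset(path2, trait_name = "x"), "se")
  # zero valid rows
  df3 <- data.frame(rsid = "rs9", effect_allele = "A", other_allele = "G",
                    eaf = 0.3, beta = 0.1, se = 0, pvalue = 0.01, n = 1000)
  path3 <- write_sumstats_tsv(df3, tempfile(fileext = ".tsv"))
  expect_error(read_summary_dataset(path3, trait_name = "x"), "no valid rows")
})

test_that("binary traits require case information", {
  snps <- data.frame(rsid = "rs1", effect_allele = "A", other_allele = "G",
                     eaf = 0.3, beta = 0.1, se = 0.01, pvalue = 0.01,
                     n = 1000)
  expect_error(summary_dataset(snps, "cancer", "binary"), "case")
  expect_silent(summary_dataset(snps, "cancer", "binary",
                                case_fraction = 0.1))
})

test_that("harmonization aligns, flips and drops as documented", {
  exposure <- make_ds(c("rs1", "rs2", "rs3"), beta = c(0.1, 0.1, 0.1),
                      se = 0.01, ea = c("A", "A", "A"),
                      oa = c("G", "G", "T"), eaf = c(0.3, 0.3, 0.3),
                      name = "exp")
  outcome <- make_ds(c("rs1", "rs2", "rs3"), beta = c(0.2, 0.2, 0.2),
                     se = 0.02, ea = c("A", "G", "A"),
                     oa = c("G", "A", "T"), eaf = c(0.3, 0.7, 0.5),
                     name = "out", type = "binary", case_fraction = 0.1)
  h <- harmonize(exposure, outcome)
  # rs1 aligned: unchanged; rs2 swapped: flipped; rs3 palindromic eaf 0.5: dropped
  expect_equal(h$rsids, c("rs1", "rs2"))
  expect_equal(h$by, c(0.2, -0.2))
  expect_equal(h$eaf_y, c(0.3, 0.3))
  expect_equal(h$dropped$rsid, "rs3")
  expect_equal(h$dropped$reason, "palindromic-ambiguous")
  # bookkeeping: kept + dropped = intersection
  expect_equal(length(h$rsids) + nrow(h$dropped), 3)
})

test_that("strand flips resolve through complements for non-palindromes", {
  exposure <- make_ds("rs1", beta = 0.1, se = 0.01, ea = "A", oa = "G")
  flipped <- make_ds("rs1", beta = 0.2, se = 0.02, ea = "T", oa = "C",
                     eaf = 0.3, name = "out")
  h <- harmonize(exposure, flipped)
  expect_equal(h$by, 0.2)          # same orientation on the other strand
  strand_swapped <- make_ds("rs1", beta = 0.2, se = 0.02, ea = "C",
                            oa = "T", eaf = 0.7, name = "out")
  h2 <- harmonize(exposure, strand_swapped)
  expect_equal(h2$by, -0.2)
  expect_equal(h2$eaf_y, 0.3)
})

test_that("flipping both outcome alleles and beta leaves the result invariant", {
  set.seed(5)
  k <- 12
  exposure <- make_ds(sprintf("rs%02d", 1:k), beta = rnorm(k, 0, 0.05),
                      se = 0.01, ea = "A", oa = "G", eaf = 0.25,
                      name = "exp")
  outcome <- make_ds(sprintf("rs%02d", 1:k), beta = rnorm(k, 0, 0.05),
                     se = 0.02, ea = "A", oa = "G", eaf = 0.25,
                     name = "out")
  flipped <- outcome
  flipped$snps$effect_allele <- "G"
  flipped$snps$other_allele <- "A"
  flipped$snps$beta <- -flipped$snps$beta
  flipped$snps$eaf <- 1 - flipped$snps$eaf
  h1 <- harmonize(exposure, outcome)
  h2 <- harmonize(exposure, flipped)
  expect_equal(h1$by, h2$by)
  expect_equal(h1$eaf_y, h2$eaf_y)
  expect_equal(h1$rsids, h2$rsids)
})

test_that("harmonization is idempotent", {
  exposure <- make_ds(c("rs1", "rs2"), beta = c(0.1, -0.2), se = 0.01,
                      ea = c("A", "C"), oa = c("G", "T"), name = "exp")
  outcome <- make_ds(c("rs1", "rs2"), beta = c(0.2, 0.1), se = 0.02,
                     ea = c("G", "C"), oa = c("A", "T"), name = "out")
  h1 <- harmonize(exposure, outcome)
  # rebuild datasets from the harmonized set and harmonize again
  rebuild <- function(h, beta, se, name) {
    make_ds(h$rsids, beta = beta, se = se, ea = h$effect_allele,
            oa = h$other_allele, eaf = h$eaf_y, name = name)
  }
  exp2 <- rebuild(h1, h1$bx[, 1], h1$sx[, 1], "exp")
  out2 <- rebuild(h1, h1$by, h1$sy, "out")
  h2 <- harmonize(exp2, out2)
  expect_equal(h2$by, h1$by)
  expect_equal(h2$bx[, 1], h1$bx[, 1])
  expect_equal(nrow(h2$dropped), 0)
})

test_that("palindromes with missing eaf are dropped under both policies", {
  exposure <- make_ds("rs1", beta = 0.1, se = 0.01, ea = "A", oa = "T",
                      eaf = NA, name = "exp")
  outcome <- make_ds("rs1", beta = 0.2, se = 0.02, ea = "A", oa = "T",
                     eaf = 0.2, name = "out")
  for (pol in c("drop_ambiguous", "infer_by_eaf")) {
    h <- harmonize(exposure, outcome, palindrome_policy = pol)
    expect_equal(h$dropped$reason, "palindromic-ambiguous")
  }
})

test_that("infer_by_eaf orients informative palindromes by frequency", {
  exposure <- make_ds("rs1", beta = 0.1, se = 0.01, ea = "A", oa = "T",
                      eaf = 0.2, name = "exp")
  outcome <- make_ds("rs1", beta = 0.2, se = 0.02, ea = "A", oa = "T",
                     eaf = 0.8, name = "out")
  h <- harmonize(exposure, outcome, palindrome_policy = "infer_by_eaf")
  expect_equal(h$by, -0.2)
  expect_equal(h$eaf_y, 0.2)
})

test_that("empty intersection is an input error", {
  a <- make_ds("rs1", 0.1, 0.01, name = "a")
  b <- make_ds("rs2", 0.1, 0.01, name = "b")
  expect_error(harmonize(a, b), "shared")
})

test_that("harmonized sets round-trip through the TSV writer", {
  h <- toy_h(bx = c(0.1, 0.2), by = c(0.05, 0.1))
  path <- tempfile(fileext = ".tsv")
  df <- write_harmonized(h, path)
  back <- read.delim(path)
  expect_equal(back$beta_outcome, h$by)
  expect_equal(back$beta_X1, h$bx[, 1])
  expect_true(file.exists(paste0(path, ".dropped.tsv")))
})
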