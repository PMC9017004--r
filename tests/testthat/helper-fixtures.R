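# Small deterministic fixtures built in code.

# A summary_dataset from parallel vectors, filling sensible defaults.
make_ds <- function(rsid, beta, se, eaf = 0.3, pvalue = NULL,
                    n = 10000, ea = "A", oa = "G", name = "trait",
                    type = "continuous", n_cases = NULL,
                    case_fraction = NULL, chrom = NULL, pos = NULL) {
  k <- length(rsid)
  if (is.null(pvalue)) pvalue <- pmax(2 * pnorm(-abs(beta / se)), 1e-300)
  snps <- data.frame(rsid = rsid, effect_allele = rep(ea, length.out = k),
                     other_allele = rep(oa, length.out = k),
                     eaf = rep(eaf, length.out = k), beta = beta, se = se,
                     pvalue = pvalue, n = rep(n, length.out = k),
                     stringsAsFactors = FALSE)
  if (!is.null(n_cases)) snps$n_cases <- rep(n_cases, length.out = k)
  if (!is.null(chrom)) snps$chrom <- rep(chrom, length.out = k)
  if (!is.null(pos)) snps$pos <- pos
  summary_dataset(snps, trait_name = name, trait_type = type,
                  case_fraction = case_fraction)
}

# A toy single-exposure harmonized set with controllable ratios.
toy_h <- function(bx, by, sx = 0.01, sy = 0.01, ld = NULL, n = 50000) {
  harmonized_set(bx = bx, sx = rep(sx, length.out = length(bx)),
                 by = by, sy = rep(sy, length.out = length(bx)),
                 nx = n, ny = n, ncase_y = round(0.1 * n), eaf = 0.3,
                 ld = ld)
}

# Write a summary-stats TSV in the package's default column dialect.
write_sumstats_tsv <- function(df, path) {
  names(df)[names(df) == "pvalue"] <- "pval"
  names(df)[names(df) == "n_cases"] <- "ncase"
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
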