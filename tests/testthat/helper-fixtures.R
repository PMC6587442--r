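# shared fixture builders; everything is generated in code at test time

# minimal VCF text with two samples; returns the file path
write_test_vcf <- function(records,
                           samples = c("S1", "S2"),
                           path = withr::local_tempfile(fileext = ".vcf",
                                                        .local_envir = parent.frame())) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1>",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  writeLines(c(header, records), path)
  path
}

# a block of identical-looking genotype calls for one position
make_calls <- function(n, p_best, dev = 0, genotype = "het",
                       chrom = "chr1", pos = 100L) {
  tibble::tibble(
    chrom = chrom, pos = pos,
    dev_ab = rep_len(dev, n),
    p_best = rep_len(p_best, n),
    genotype = rep_len(genotype, n)
  )
}

# independent enumeration oracle for the exact two-sided binomial p-value:
# probabilities computed from log-binomial coefficients (not dbinom), summed
# over outcomes no more likely than the observed one
binom_two_sided_oracle <- function(alt, depth, p) {
  k <- 0:depth
  logp <- lchoose(depth, k) + k * log(p) + (depth - k) * log1p(-p)
  d <- exp(logp)
  sum(d[d <= d[alt + 1] * (1 + 1e-7)])
}

# independent hypergeometric enumeration oracle for the two-sided Fisher
# exact p-value of a 2x2 table (minimum-likelihood ordering)
fisher_oracle <- function(a, b, c, d) {
  m <- a + b          # row 1 total
  n_ <- c + d         # row 2 total
  k <- a + c          # column 1 total
  lo <- max(0L, k - n_)
  hi <- min(k, m)
  x <- lo:hi
  probs <- exp(lchoose(m, x) + lchoose(n_, k - x) - lchoose(m + n_, k))
  sum(probs[probs <= probs[x == a] * (1 + 1e-7)])
}

rank_auc_ref <- function(score, label) {
  n1 <- sum(label == 1)
  n0 <- sum(label == 0)
  r <- rank(score)
  (sum(r[label == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
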