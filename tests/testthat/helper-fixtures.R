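# shared fixture builders (all fixtures are generated in code)

# a phased 2-sample / 2-variant VCF, optionally corrupted
write_fixture_vcf <- function(path, gt = c("0|1", "1|1", "0|0", "1|0"),
                              alt2 = "G") {
  lines <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##contig=<ID=chr11>",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "SA", "SB", sep = "\t"),
    paste("chr11", "100", "rsA", "A", "G", ".", ".", ".", "GT",
          gt[1], gt[2], sep = "\t"),
    paste("chr11", "200", "rsB", "C", alt2, ".", ".", ".", "GT",
          gt[3], gt[4], sep = "\t"))
  writeLines(lines, path)
  path
}

# build a 2-variant panel realizing exact 2x2 haplotype counts
# (focal = alt allele at both sites)
panel_from_counts <- function(n11, n10, n01, n00,
                              ids = c("s1", "s2"), pos = c(100L, 200L)) {
  a1 <- c(rep(1L, n11 + n10), rep(0L, n01 + n00))
  a2 <- c(rep(1L, n11), rep(0L, n10), rep(1L, n01), rep(0L, n00))
  v <- data.frame(id = ids, chrom = "chr11", pos = pos, ref = "A", alt = "G")
  HaplotypePanel(cbind(a1, a2), v)
}

# an information-rich length-8 PWM (consensus ACGTACGT)
toy_pwm <- function(main = 0.97, name = "toy8") {
  cons <- c(1, 2, 3, 4, 1, 2, 3, 4)  # A C G T A C G T
  m <- matrix((1 - main) / 3, 4, 8)
  m[cbind(cons, 1:8)] <- main
  rownames(m) <- c("A", "C", "G", "T")
  PWMotif(name, m, pseudocount = 0)
}

# brute-force LD oracle using pure integer count arithmetic
ld_oracle <- function(n11, n10, n01, n00) {
  # doubles are exact for these integer products (well below 2^53)
  n11 <- as.numeric(n11); n10 <- as.numeric(n10)
  n01 <- as.numeric(n01); n00 <- as.numeric(n00)
  N <- n11 + n10 + n01 + n00
  nA <- n11 + n10; nB <- n11 + n01
  D_num <- N * n11 - nA * nB                 # D = D_num / N^2
  r2 <- D_num^2 / (nA * (N - nA) * nB * (N - nB))
  Dmax_num <- if (D_num >= 0) min(nA * (N - nB), (N - nA) * nB)
              else min(nA * nB, (N - nA) * (N - nB))
  list(D = D_num / N^2, r2 = r2,
       Dprime = if (D_num == 0) 0 else abs(D_num) / Dmax_num)
}
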