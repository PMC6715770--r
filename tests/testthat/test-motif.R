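test_that("log-odds scoring is exact, maximal at consensus, and validated", {
  pwm <- toy_pwm()
  # background-equal PWM scores 0 everywhere
  flat <- PWMotif("flat", matrix(0.25, 4, 5), pseudocount = 0)
  for (k in c("AAAAA", "ACGTA", "TTTTT"))
    expect_equal(logoddsScore(flat, k), 0)

  # hand-summed log ratios on a 4-long PWM
  m <- matrix(c(0.7, 0.1, 0.1, 0.1,
                0.1, 0.6, 0.2, 0.1,
                0.25, 0.25, 0.25, 0.25,
                0.05, 0.05, 0.1, 0.8), 4, 4)
  rownames(m) <- c("A", "C", "G", "T")
  p4 <- PWMotif("p4", m, pseudocount = 0)
  expect_equal(logoddsScore(p4, "ACGT"),
               log(0.7 / 0.25) + log(0.6 / 0.25) + log(0.25 / 0.25) +
               log(0.8 / 0.25), tolerance = 1e-12)

  # consensus dominates every other k-mer (spot-check all 4-mers)
  kmers <- do.call(paste0, expand.grid(rep(list(c("A", "C", "G", "T")), 4)))
  scores <- vapply(kmers, function(k) logoddsScore(p4, k), 0)
  expect_equal(names(which.max(scores)), consensusString4(p4))

  expect_error(logoddsScore(p4, "ACG"), "length")
  expect_error(logoddsScore(p4, "ACNT"), "non-ACGT")
})

test_that("DP score p-value equals exhaustive enumeration for L <= 6", {
  bases <- c("A", "C", "G", "T")
  for (cfg in list(list(L = 4, bg = rep(0.25, 4), seed = 1),
                   list(L = 5, bg = c(0.3, 0.2, 0.2, 0.3), seed = 2),
                   list(L = 6, bg = rep(0.25, 4), seed = 3))) {
    set.seed(cfg$seed)
    m <- matrix(rexp(4 * cfg$L), 4, cfg$L)
    pwm <- PWMotif(paste0("r", cfg$L), m, background = cfg$bg)
    # enumeration oracle over all 4^L k-mers on the same discretized scores
    lo_int <- round(log(pwmProbs(pwm) / pwmBackground(pwm)) / 1e-3)
    grid <- as.matrix(expand.grid(rep(list(1:4), cfg$L)))
    kscore <- rowSums(matrix(lo_int[cbind(as.vector(grid),
                                          rep(1:cfg$L, each = nrow(grid)))],
                             nrow(grid)))
    kprob <- apply(grid, 1, function(g) prod(pwmBackground(pwm)[g]))
    qs <- sort(unique(kscore))
    probe <- qs[unique(round(seq(1, length(qs), length.out = 7)))]
    for (q in probe) {
      s <- q * 1e-3  # back to nats
      expect_equal(scorePvalue(pwm, s), sum(kprob[kscore >= q]),
                   tolerance = 1e-9)
    }
    # monotone non-increasing in score
    ps <- vapply(qs * 1e-3, function(s) scorePvalue(pwm, s), 0)
    expect_true(all(diff(ps) <= 1e-15))
    # boundary behavior: below the minimum -> 1; beyond the maximum -> the
    # smallest representable positive mass, never more than the max-score tail
    expect_equal(scorePvalue(pwm, min(kscore) * 1e-3 - 10), 1)
    above <- scorePvalue(pwm, max(kscore) * 1e-3 + 10)
    expect_gt(above, 0)
    expect_lte(above, scorePvalue(pwm, max(kscore) * 1e-3) + 1e-12)
  }
})

test_that("scanAlleles is degenerate-safe and strand-symmetric", {
  pwm <- toy_pwm()
  pl <- plantMotifSnp(pwm, seed = 41)
  # identical alleles give identical hit lists
  same <- scanAlleles(pwm, pl$seq_ref, pl$seq_ref)
  expect_equal(same$hits_ref, same$hits_alt)

  hits <- scanAlleles(pwm, pl$seq_ref, pl$seq_alt)
  ref_cc <- hits$hits_ref[hits$hits_ref$covers_center, ]
  expect_true(pl$offset %in% ref_cc$offset)
  best_ref <- max(hits$hits_ref$score)
  best_alt <- if (nrow(hits$hits_alt)) max(hits$hits_alt$score) else -Inf
  expect_lt(best_alt, best_ref)  # alt carries the worst center base

  # reverse-complementing both sequences mirrors offsets, keeps scores
  rc <- function(s) as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(s)))
  fl <- scanAlleles(pwm, rc(pl$seq_ref), rc(pl$seq_alt))
  mirror <- function(h) {
    h$offset <- 51 - length(pwm) - h$offset
    h$strand <- ifelse(h$strand == "+", "-", "+")
    h[order(h$offset, h$strand), c("offset", "strand", "score")]
  }
  got <- fl$hits_ref[order(fl$hits_ref$offset, fl$hits_ref$strand),
                     c("offset", "strand", "score")]
  want <- mirror(hits$hits_ref)
  rownames(got) <- rownames(want) <- NULL
  expect_equal(got, want, tolerance = 1e-12)

  expect_error(scanAlleles(pwm, pl$seq_ref, substr(pl$seq_ref, 1, 50)),
               "51")
  bad <- pl$seq_alt
  substr(bad, 3, 3) <- ifelse(substr(bad, 3, 3) == "A", "C", "A")
  expect_error(scanAlleles(pwm, pl$seq_ref, bad), "central base")
})

test_that("disruption significance: determinism, degeneracy, monotonicity", {
  # A-preferring 15-mer whose column 11 (the one aligned with the window
  # center when planted at offset 15) holds a uniquely extreme worst base:
  # mutating consensus -> that base is rarer under the null than any other
  # single mutation, so the observed disruption must come out significant.
  m <- matrix(c(0.97, 0.01, 0.01, 0.01), 4, 15)
  m[, 11] <- c(0.99, 0.005, 0.004, 0.001)
  rownames(m) <- c("A", "C", "G", "T")
  pwm <- PWMotif("sharp15", m, pseudocount = 0)
  bg <- rep(c("C", "G"), length.out = 51)
  ref <- bg; ref[16:30] <- "A"                 # 0-based offset 15
  alt <- ref; alt[26] <- "T"                   # center column's 0.001 base
  seq_ref <- paste(ref, collapse = ""); seq_alt <- paste(alt, collapse = "")

  d1 <- disruptionSignificance(pwm, seq_ref, seq_alt, n_sim = 2000, seed = 99)
  d2 <- disruptionSignificance(pwm, seq_ref, seq_alt, n_sim = 2000, seed = 99)
  expect_equal(d1$p_empirical, d2$p_empirical)
  expect_equal(d1$delta, log(0.001 / 0.99), tolerance = 1e-12)
  expect_lt(d1$p_empirical, 0.05)
  # the null can reach this |delta| only via column 11, so p is about
  # (1/15) * 0.99 * (1/3)
  expect_equal(d1$p_empirical, 0.022, tolerance = 0.5)

  # degenerate: identical alleles, |delta| = 0, add-one convention gives p = 1
  d0 <- disruptionSignificance(pwm, seq_ref, seq_ref, n_sim = 500, seed = 99)
  expect_equal(d0$delta, 0)
  expect_equal(d0$p_empirical, 1)

  # p is monotone non-increasing in |delta| for a fixed seed and n_sim:
  # same PWM and null sample, milder alternate base -> smaller |delta|
  skew <- PWMotif("skew", {
    m <- matrix(c(0.70, 0.20, 0.06, 0.04), 4, 8)
    rownames(m) <- c("A", "C", "G", "T"); m
  }, pseudocount = 0)
  pls <- plantMotifSnp(skew, seed = 7)        # alt = worst base (T, 0.04)
  mild_alt <- pls$seq_ref
  substr(mild_alt, 26, 26) <- "C"             # second-best base (0.20)
  d_worst <- disruptionSignificance(skew, pls$seq_ref, pls$seq_alt,
                                    n_sim = 500, seed = 99, threshold = 1)
  d_mild <- disruptionSignificance(skew, pls$seq_ref, mild_alt,
                                   n_sim = 500, seed = 99, threshold = 1)
  expect_lt(abs(d_mild$delta), abs(d_worst$delta))
  expect_gte(d_mild$p_empirical, d_worst$p_empirical)

  # no motif anywhere near the center -> refuse
  flatbg <- paste(rep("C", 51), collapse = "")
  expect_error(disruptionSignificance(pwm, flatbg, flatbg, n_sim = 10,
                                      seed = 1),
               "no motif to disrupt")
})
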