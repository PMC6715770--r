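test_that("simConfig validates rates, block structure and effect references", {
  expect_error(simConfig(seed = 1, nHaplotypes = 11), "even")
  expect_error(simConfig(seed = 1, nHaplotypes = 100, nSamples = 51), "nSamples")
  expect_error(simConfig(seed = 1, censoringRate = 1.5), "censoringRate")
  expect_error(simConfig(seed = 1,
    blocks = list(list(ids = c("v1", "v2"), kappa = 0.5),
                  list(ids = c("v2", "v3"), kappa = 0.5))), "overlapping")
  expect_error(simConfig(seed = 1, blocks = list(list(ids = "v1", kappa = 2))),
               "kappa")
  expect_error(simConfig(seed = 1,
    eqtlEffects = data.frame(gene = "nope", variant = "v1", beta = 1)),
    "unknown gene")
  expect_error(simConfig(seed = 1,
    eqtlEffects = data.frame(gene = "g1", variant = "nope", beta = 1)),
    "unknown variant")
})

test_that("founder-copying blocks give the designed LD extremes", {
  # kappa = 1: every within-block pair in perfect LD
  cfg1 <- simConfig(seed = 3, nHaplotypes = 200,
                    blocks = list(list(ids = c("v1", "v2", "v3"), kappa = 1,
                                       freq = 0.5)))
  pan1 <- simulateHaplotypes(cfg1)
  for (pair in list(c("v1", "v2"), c("v1", "v3"), c("v2", "v3"))) {
    ld <- ldPair(pan1, pair[1], pair[2])
    expect_equal(ld$r2, 1)
    expect_equal(ld$Dprime, 1)
  }

  # kappa = 0: r2 vanishes up to sampling error at n = 10,000
  cfg0 <- simConfig(seed = 4, nHaplotypes = 10000,
                    variants = data.frame(id = paste0("v", 1:5), chrom = "c",
                                          pos = 1:5 * 100L, ref = "A",
                                          alt = "G", freq = NA_real_),
                    blocks = list(list(ids = paste0("v", 1:5), kappa = 0,
                                       freq = 0.4)))
  pan0 <- simulateHaplotypes(cfg0)
  for (i in 1:4) for (j in (i + 1):5)
    expect_lt(ldPair(pan0, paste0("v", i), paste0("v", j))$r2, 0.01)
})

test_that("generators are pure functions of (config, seed)", {
  cfg <- simConfig(seed = 9, nHaplotypes = 100, nSamples = 40,
                   blocks = list(list(ids = c("v1", "v2"), kappa = 0.9)),
                   eqtlEffects = data.frame(gene = "g1", variant = "v1",
                                            beta = -0.5),
                   survGene = "g1", survLogHR = -0.4)
  expect_identical(simulateHaplotypes(cfg), simulateHaplotypes(cfg))
  pan <- simulateHaplotypes(cfg)
  coh1 <- simulateCohort(pan, cfg)
  coh2 <- simulateCohort(pan, cfg)
  expect_identical(exprMatrix(coh1), exprMatrix(coh2))
  expect_identical(survivalTable(coh1), survivalTable(coh2))
  spec <- list(list(center = 1e6, n_snps = 5, category = "immune",
                    window = 1e5))
  expect_identical(catalogRecords(simulateGwasCatalog(cfg, spec)),
                   catalogRecords(simulateGwasCatalog(cfg, spec)))
  # and the caller's RNG stream is untouched
  set.seed(123); before <- rnorm(1)
  set.seed(123); invisible(simulateHaplotypes(cfg)); after <- rnorm(1)
  expect_identical(before, after)
})

test_that("empirical allele frequencies converge to configured values", {
  freqs <- c(0.15, 0.5, 0.82)
  cfg <- simConfig(seed = 21, nHaplotypes = 10000,
                   variants = data.frame(id = paste0("v", 1:3), chrom = "c",
                                         pos = 1:3 * 10L, ref = "A", alt = "G",
                                         freq = freqs))
  pan <- simulateHaplotypes(cfg)
  for (k in 1:3) {
    se <- sqrt(freqs[k] * (1 - freqs[k]) / 10000)
    expect_lt(abs(alleleFrequency(pan, paste0("v", k), "G") - freqs[k]), 3 * se)
  }
})

test_that("noiseless cohort is exactly additive in the risk-allele dosage", {
  cfg <- simConfig(seed = 2, nHaplotypes = 120, nSamples = 60,
                   noiseSd = 0, cnEffect = 0,
                   eqtlEffects = data.frame(gene = "g1", variant = "v1",
                                            beta = -1))
  pan <- simulateHaplotypes(cfg)
  coh <- simulateCohort(pan, cfg)
  mu <- simConfig(seed = 2)@genes$mu[1]
  expect_equal(unname(exprMatrix(coh)["g1", ]),
               unname(mu - 1 * dosageMatrix(coh)["v1", ]))
  # genes without planted effects sit at baseline
  expect_equal(unname(exprMatrix(coh)["g2", ]), rep(mu, 60))
})

test_that("protective expression effect lengthens survival at large n", {
  cfg <- simConfig(seed = 31, nHaplotypes = 4000, nSamples = 2000,
                   noiseSd = 1, censoringRate = 0.2,
                   eqtlEffects = data.frame(gene = "g1", variant = "v1",
                                            beta = -1),
                   survGene = "g1", survLogHR = -0.7)
  pan <- simulateHaplotypes(cfg)
  coh <- simulateCohort(pan, cfg)
  st <- survivalTable(coh)
  st$group <- medianSplit(exprMatrix(coh)["g1", st$sample])
  med <- vapply(split(st$time, st$group), median, 0)
  expect_gt(med[["high"]], med[["low"]])
  expect_lt(logrankTest(st)$p, 0.01)
})

test_that("simulated GWAS clusters reproduce their construction bookkeeping", {
  cfg <- simConfig(seed = 6)
  spec <- list(
    list(center = 1e6, n_snps = 5, category = "immune", window = 1e5),
    list(center = 5e6, n_snps = 3, category = "immune", window = 5e4),
    list(center = 1e6, n_snps = 1, category = "cancer", window = 10))
  cat <- simulateGwasCatalog(cfg, spec)
  expect_equal(nrow(catalogRecords(cat)), 9L)
  q <- variantRecord("q", "chr11", 1e6)
  expect_equal(countProximal(cat, q, 1e5, "immune"), 5L)
  q2 <- variantRecord("q2", "chr11", 5e6)
  expect_equal(countProximal(cat, q2, 5e4, "immune"), 3L)
  expect_equal(nrow(catalogRecords(simulateGwasCatalog(cfg, list()))), 0L)
})

test_that("plantMotifSnp embeds a center-overlapping consensus match", {
  pwm <- toy_pwm()
  pl <- plantMotifSnp(pwm, seed = 13)
  expect_equal(nchar(pl$seq_ref), 51L)
  ref <- strsplit(pl$seq_ref, "")[[1]]
  alt <- strsplit(pl$seq_alt, "")[[1]]
  expect_equal(which(ref != alt), 26L)             # Hamming distance 1, center
  expect_true(pl$offset <= 25 && 25 <= pl$offset + length(pwm) - 1)
  expect_equal(paste(ref[(pl$offset + 1):(pl$offset + 8)], collapse = ""),
               consensusString4(pwm))
  # the scanner finds the planted ref hit at the planted offset
  hits <- scanAlleles(pwm, pl$seq_ref, pl$seq_alt, threshold = 1e-3)
  hit <- hits$hits_ref[hits$hits_ref$strand == "+", ]
  expect_true(pl$offset %in% hit$offset[hit$covers_center])

  long <- PWMotif("long", matrix(1, 4, 26))
  expect_error(plantMotifSnp(long, seed = 1), "> 25")
})
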