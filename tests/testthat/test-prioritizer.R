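gr <- function(chrom, start1, end1 = NULL, width = NULL, ...)
  GenomicRanges::GRanges(chrom,
                         IRanges::IRanges(start1, end = end1, width = width),
                         ...)

test_that("snpInIntervals honors BED half-open boundaries", {
  # BED interval [100, 200): 0-based p = 100 inside, p = 200 outside
  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr11\t100\t200", bed)
  peaks <- readIntervals(bed)
  at_start <- variantRecord("a", "chr11", 101)   # 0-based 100
  at_end <- variantRecord("b", "chr11", 201)     # 0-based 200
  inside <- variantRecord("c", "chr11", 150)
  other <- variantRecord("d", "chr2", 150)
  expect_true(snpInIntervals(at_start, peaks)$hit)
  expect_false(snpInIntervals(at_end, peaks)$hit)
  expect_true(snpInIntervals(inside, peaks)$hit)
  expect_false(snpInIntervals(other, peaks)$hit)
  expect_false(snpInIntervals(inside, GenomicRanges::GRanges())$hit)
})

test_that("snpInIntervals equals a brute-force double loop on random input", {
  set.seed(61)
  ivs <- gr("chr1", sample.int(10000, 100), width = sample(50:300, 100,
                                                           replace = TRUE))
  starts <- GenomicRanges::start(ivs); ends <- GenomicRanges::end(ivs)
  for (i in 1:1000) {
    pos <- sample.int(11000, 1)
    snp <- variantRecord(paste0("s", i), "chr1", pos)
    got <- snpInIntervals(snp, ivs)
    want <- which(starts <= pos & pos <= ends)
    expect_equal(sort(got$matches), want)
    expect_equal(got$hit, length(want) > 0)
  }
})

test_that("snpInteractsRegion requires SNP anchor + target mate, unordered", {
  snp <- variantRecord("rs", "chr11", 1500)
  target <- gr("chr11", 65000, 66000)
  hit_pair <- InteractionPairs(gr("chr11", 1000, 2000),
                               gr("chr11", 65500, 65800), 5)
  expect_true(snpInteractsRegion(snp, hit_pair, target)$hit)
  # swapped anchors: still true (constructor canonicalizes, logic is symmetric)
  swapped <- InteractionPairs(gr("chr11", 65500, 65800),
                              gr("chr11", 1000, 2000), 5)
  expect_true(snpInteractsRegion(snp, swapped, target)$hit)
  # SNP inside an anchor whose mate misses the target
  miss <- InteractionPairs(gr("chr11", 1000, 2000), gr("chr11", 90000, 91000), 1)
  expect_false(snpInteractsRegion(snp, miss, target)$hit)
  # neither anchor contains the SNP
  faroff <- InteractionPairs(gr("chr11", 5000, 6000), gr("chr11", 65500, 65800), 1)
  expect_false(snpInteractsRegion(snp, faroff, target)$hit)

  # brute force over a random batch
  set.seed(71)
  a1 <- gr("chr11", sample.int(5000, 50), width = 200)
  a2 <- gr("chr11", sample.int(5000, 50) + 60000, width = 200)
  ints <- InteractionPairs(a1, a2, seq_len(50))
  for (pos in sample.int(5500, 40)) {
    s <- variantRecord("x", "chr11", pos)
    got <- snpInteractsRegion(s, ints, target)
    want <- which((GenomicRanges::start(a1) <= pos & pos <= GenomicRanges::end(a1) &
                   GenomicRanges::start(a2) <= 66000 & GenomicRanges::end(a2) >= 65000))
    expect_equal(got$support, want)
  }
})

# a small planted locus shared by the evidence-table tests
planted_locus <- function(seed = 101, kappa = 0.95) {
  variants <- data.frame(
    id = c("tag", "prox_func", "prox_plain", "indep"),
    chrom = "chr11", pos = c(65583185L, 65586200L, 65590000L, 65650000L),
    ref = c("T", "A", "C", "G"), alt = c("G", "C", "T", "A"),
    freq = NA_real_)
  cfg <- simConfig(seed = seed, nHaplotypes = 400, nSamples = 150,
                   variants = variants,
                   blocks = list(list(ids = c("tag", "prox_func", "prox_plain"),
                                      kappa = kappa, freq = 0.5)))
  panel <- simulateHaplotypes(cfg)
  # PRE1-like peak over the functional proxy only
  peaks <- list(NK = gr("chr11", 65586000, 65586500, name = "PRE1"),
                Tcell = gr("chr11", 65586100, 65586400))
  h3k4me1 <- gr("chr11", 65585900, 65586600)
  target <- gr("chr11", 65667000, 65672000)      # gene 3' end window
  ints <- InteractionPairs(gr("chr11", 65586000, 65586500),
                           gr("chr11", 65668000, 65670000), 12)
  pwm <- toy_pwm()
  pl <- plantMotifSnp(pwm, seed = seed + 1)
  list(panel = panel, peaks = peaks, h3k4me1 = h3k4me1, target = target,
       ints = ints, pwm = pwm,
       sequences = list(prox_func = pl[c("seq_ref", "seq_alt")]))
}

test_that("buildEvidenceTable ranks the planted functional proxy first", {
  loc <- planted_locus()
  ev <- buildEvidenceTable(loc$panel, "tag", peak_sets = loc$peaks,
                           h3k4me1 = loc$h3k4me1, interactions = loc$ints,
                           target = loc$target, pwms = list(loc$pwm),
                           sequences = loc$sequences, n_sim = 200, seed = 5)
  expect_equal(ev$variant[1], "prox_func")
  expect_true(ev$in_dhs[1] && ev$in_NK[1] && ev$in_Tcell[1])
  expect_true(ev$in_h3k4me1[1] && ev$interacts_target[1])
  expect_false(any(ev$in_dhs[-1]))
  expect_lt(ev$motif_delta[1], 0)
  # rows are a subset of the LD expansion; candidates satisfy the gates
  ld <- ldExpand(loc$panel, "tag")
  expect_true(all(ev$variant %in% ld$variant))
  expect_true(all(ev$r2_to_tag >= 0.8 | ev$variant == "tag"))
  expect_true(all(ev$maf >= 0.05))
  # motif results only for the DHS-gated candidate
  expect_equal(names(attr(ev, "motif_results")), "prox_func")
  expect_true(is.na(ev$motif_p[ev$variant == "tag"]))
})

test_that("evidence gates: no peaks -> no flags, no motif scans; tag rows stay", {
  loc <- planted_locus()
  ev0 <- buildEvidenceTable(loc$panel, "tag", peak_sets = list(),
                            pwms = list(loc$pwm), sequences = loc$sequences,
                            n_sim = 50, seed = 5)
  expect_false(any(ev0$in_dhs))
  expect_length(attr(ev0, "motif_results"), 0L)
  expect_true(all(is.na(ev0$motif_p)))
  # the tag itself sits outside every peak but still appears, flags false
  ev <- buildEvidenceTable(loc$panel, "tag", peak_sets = loc$peaks,
                           h3k4me1 = loc$h3k4me1, interactions = loc$ints,
                           target = loc$target)
  tagrow <- ev[ev$variant == "tag", ]
  expect_equal(nrow(tagrow), 1L)
  expect_false(tagrow$in_dhs | tagrow$in_h3k4me1 | tagrow$interacts_target)
  # adding an irrelevant peak set never removes rows
  ev2 <- buildEvidenceTable(loc$panel, "tag",
                            peak_sets = c(loc$peaks,
                                          list(noise = gr("chr9", 1, 100))),
                            h3k4me1 = loc$h3k4me1, interactions = loc$ints,
                            target = loc$target)
  expect_setequal(ev2$variant, ev$variant)
  # gated candidate without a sequence window -> warning, empty motif fields
  expect_warning(
    evw <- buildEvidenceTable(loc$panel, "tag", peak_sets = loc$peaks,
                              pwms = list(loc$pwm), sequences = list(),
                              n_sim = 50, seed = 5),
    "no sequence window.*prox_func")
  expect_true(all(is.na(evw$motif_p)))
})

test_that("runPipeline produces all stage outputs deterministically", {
  loc <- planted_locus()
  config <- list(
    tag = "tag", seed = 11,
    simulate = list(
      seed = 101, nHaplotypes = 400, nSamples = 150,
      variants = variantInfo(loc$panel) |>
        transform(freq = NA_real_),
      blocks = list(list(ids = c("tag", "prox_func", "prox_plain"),
                         kappa = 0.95, freq = 0.5)),
      eqtlEffects = data.frame(gene = "g2", variant = "tag", beta = -0.7),
      survGene = "g2", survLogHR = -0.5, censoringRate = 0.25,
      gwas_clusters = list(
        list(center = 65583185, n_snps = 6, category = "immune", window = 9e4),
        list(center = 65583185, n_snps = 1, category = "cancer", window = 10),
        list(center = 85e6, n_snps = 1, category = "cancer", window = 10)),
      planted_motif = list(candidate = "prox_func", pwm_index = 1)),
    query_category = "cancer", neighbor_category = "immune",
    peaks = loc$peaks, h3k4me1 = loc$h3k4me1, interactions = loc$ints,
    target = loc$target, pwms = list(loc$pwm), n_sim = 100)

  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  res <- runPipeline(config, d1)
  runPipeline(config, d2)
  files <- c("01_pleiotropy.tsv", "02_eqtl.tsv", "03_survival.tsv",
             "03_km_high.tsv", "03_km_low.tsv", "04_ld_expand.tsv",
             "05_evidence.tsv", "06_motif.tsv", "run.log")
  for (f in files) {
    expect_true(file.exists(file.path(d1, f)), info = f)
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
  # planted scenario is recovered end to end
  expect_equal(res$pleiotropy$neighbor_count[1], 6L)
  expect_equal(res$eqtl$gene[1], "g2")
  expect_lt(res$eqtl$beta_genotype[1], 0)
  expect_equal(res$evidence$variant[1], "prox_func")
  expect_lt(res$survival$logrank$p, 0.05)

  # a config without expression input fails naming the eQTL stage
  bad <- list(tag = "tag",
              inputs = list(haplotypes = {
                f <- withr::local_tempfile(fileext = ".tsv")
                writeHaplotypes(loc$panel, f); f
              }))
  expect_error(runPipeline(bad, withr::local_tempdir()), "stage 'eqtl'")
})
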