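# seeded generators for every pipeline input.
#
# LD is generated by a founder-copying block model: within a block all
# variants share an allele frequency p; each haplotype draws a founder state
# z ~ Bern(p) and, with probability kappa, carries z at every block variant
# (otherwise independent Bern(p) draws per variant).  Pairwise allelic
# correlation within a block is then exactly kappa (E[r2] ~ kappa^2), allele
# frequencies converge to p, and kappa = 1 gives r2 = 1.

#' Simulation configuration
#'
#' Validated container for every generator parameter.  Defaults describe a
#' small breast-cancer-style locus: one tag SNP with a high-LD proxy block,
#' a cohort with additive genotype and copy-number effects on expression, and
#' exponential survival whose hazard depends on the designated gene.
#'
#' @slot seed integer RNG seed (mandatory).
#' @slot nHaplotypes even number of haplotypes.
#' @slot nSamples number of diploid samples, `<= nHaplotypes / 2`.
#' @slot variants data.frame(id, chrom, pos, ref, alt, freq); `freq` is the
#'   target alternate (risk) allele frequency, NA = drawn from `freqRange`.
#' @slot blocks list of `list(ids, kappa, freq)` LD blocks; `ids` are variant
#'   ids, `kappa` in `[0,1]` the haplotype-sharing rate, `freq` the shared
#'   block allele frequency (drawn from `freqRange` when NULL).
#' @slot genes data.frame(id, chrom, tss, mu) with baseline expression `mu`.
#' @slot eqtlEffects data.frame(gene, variant, beta): expression change per
#'   risk-allele copy.
#' @slot cnEffect expression change per unit log2 copy-ratio.
#' @slot cnLog2Sd SD of the per-gene log2 copy-ratio jitter around 0.
#' @slot noiseSd SD of the additive Gaussian expression noise.
#' @slot exprFloor expression is truncated below at this value (0).
#' @slot survGene gene whose z-scored expression drives the hazard (NA = none).
#' @slot survBaseline baseline hazard (events per day).
#' @slot survLogHR log-hazard change per expression SD.
#' @slot censoringRate probability a subject is censored.
#' @slot freqRange uniform range for undeclared allele frequencies.
#' @slot popLabel population label stamped on simulated haplotypes.
#' @exportClass SimConfig
setClass("SimConfig", representation(
  seed = "integer", nHaplotypes = "integer", nSamples = "integer",
  variants = "data.frame", blocks = "list", genes = "data.frame",
  eqtlEffects = "data.frame", cnEffect = "numeric", cnLog2Sd = "numeric",
  noiseSd = "numeric", exprFloor = "numeric", survGene = "character",
  survBaseline = "numeric", survLogHR = "numeric", censoringRate = "numeric",
  freqRange = "numeric", popLabel = "character"))

setValidity("SimConfig", function(object) {
  msg <- character()
  if (length(object@seed) != 1L || is.na(object@seed))
    msg <- c(msg, "seed is mandatory")
  if (object@nHaplotypes %% 2L != 0L) msg <- c(msg, "nHaplotypes must be even")
  if (object@nSamples > object@nHaplotypes / 2L)
    msg <- c(msg, "nSamples must be <= nHaplotypes / 2")
  if (object@censoringRate < 0 || object@censoringRate > 1)
    msg <- c(msg, "censoringRate must be in [0, 1]")
  for (b in object@blocks) {
    if (b$kappa < 0 || b$kappa > 1) msg <- c(msg, "block kappa must be in [0, 1]")
    if (!all(b$ids %in% object@variants$id))
      msg <- c(msg, "block references unknown variant id(s)")
  }
  ids <- unlist(lapply(object@blocks, `[[`, "ids"))
  if (anyDuplicated(ids)) msg <- c(msg, "overlapping LD blocks")
  fr <- object@variants$freq
  if (any(!is.na(fr) & (fr <= 0 | fr >= 1)))
    msg <- c(msg, "variant freq must be in (0, 1)")
  if (nrow(object@eqtlEffects)) {
    if (!all(object@eqtlEffects$gene %in% object@genes$id))
      msg <- c(msg, paste("eqtlEffects references unknown gene(s):",
        paste(setdiff(object@eqtlEffects$gene, object@genes$id), collapse = ",")))
    if (!all(object@eqtlEffects$variant %in% object@variants$id))
      msg <- c(msg, paste("eqtlEffects references unknown variant(s):",
        paste(setdiff(object@eqtlEffects$variant, object@variants$id), collapse = ",")))
  }
  if (!is.na(object@survGene) && !(object@survGene %in% object@genes$id))
    msg <- c(msg, "survGene not in genes")
  if (length(msg)) msg else TRUE
})

#' Construct a SimConfig
#'
#' @param seed integer RNG seed.
#' @param nHaplotypes,nSamples panel and cohort sizes.
#' @param variants,blocks,genes,eqtlEffects,cnEffect,cnLog2Sd,noiseSd,exprFloor
#'   see [SimConfig-class]; sensible defaults are filled in when omitted.
#' @param survGene,survBaseline,survLogHR,censoringRate survival generator
#'   parameters.
#' @param freqRange,popLabel frequency draw range and population label.
#' @return A validated [SimConfig-class].
#' @examples
#' cfg <- simConfig(seed = 1)
#' cfg
#' @export
simConfig <- function(seed, nHaplotypes = 1000L, nSamples = nHaplotypes %/% 2L,
                      variants = NULL, blocks = list(), genes = NULL,
                      eqtlEffects = NULL, cnEffect = 0.5, cnLog2Sd = 0.25,
                      noiseSd = 1, exprFloor = 0, survGene = NA_character_,
                      survBaseline = 1 / 1000, survLogHR = 0,
                      censoringRate = 0.3, freqRange = c(0.1, 0.9),
                      popLabel = "EUR") {
  if (is.null(variants))
    variants <- data.frame(id = paste0("v", 1:10), chrom = "chr11",
                           pos = 65e6 + (0:9) * 2000L, ref = "A", alt = "G",
                           freq = NA_real_)
  if (is.null(variants$freq)) variants$freq <- NA_real_
  if (is.null(genes))
    genes <- data.frame(id = paste0("g", 1:4), chrom = "chr11",
                        tss = 65e6 + c(-5e5, 5e4, 2e5, 4e5), mu = 10)
  if (is.null(genes$mu)) genes$mu <- 10
  if (is.null(eqtlEffects))
    eqtlEffects <- data.frame(gene = character(), variant = character(),
                              beta = numeric())
  new("SimConfig", seed = as.integer(seed),
      nHaplotypes = as.integer(nHaplotypes), nSamples = as.integer(nSamples),
      variants = variants, blocks = blocks, genes = genes,
      eqtlEffects = eqtlEffects, cnEffect = cnEffect, cnLog2Sd = cnLog2Sd,
      noiseSd = noiseSd, exprFloor = exprFloor,
      survGene = as.character(survGene), survBaseline = survBaseline,
      survLogHR = survLogHR, censoringRate = censoringRate,
      freqRange = freqRange, popLabel = popLabel)
}

setMethod("show", "SimConfig", function(object) {
  cat(sprintf("SimConfig: seed %d, %d haplotypes, %d samples, %d variants, %d blocks, %d genes\n",
              object@seed, object@nHaplotypes, object@nSamples,
              nrow(object@variants), length(object@blocks), nrow(object@genes)))
})

#' Simulate a phased haplotype panel with block LD structure
#'
#' Identical seeds give byte-identical panels; the caller's RNG state is left
#' untouched.
#'
#' @param config a [SimConfig-class].
#' @return A [HaplotypePanel-class], `nHaplotypes` x `nrow(variants)`.
#' @export
simulateHaplotypes <- function(config) {
  local_seed(config@seed, {
    v <- config@variants
    n <- config@nHaplotypes
    freq <- v$freq
    freq[is.na(freq)] <- runif(sum(is.na(freq)), config@freqRange[1],
                               config@freqRange[2])
    a <- matrix(0L, nrow = n, ncol = nrow(v))
    for (k in seq_len(nrow(v))) a[, k] <- rbinom(n, 1L, freq[k])
    for (b in config@blocks) {
      idx <- match(b$ids, v$id)
      pb <- b$freq %||% runif(1, config@freqRange[1], config@freqRange[2])
      freq[idx] <- pb
      z <- rbinom(n, 1L, pb)       # founder state per haplotype
      copies <- rbinom(n, 1L, b$kappa) == 1L
      for (k in idx) {
        col <- rbinom(n, 1L, pb)
        col[copies] <- z[copies]
        a[, k] <- col
      }
    }
    colnames(a) <- v$id
    HaplotypePanel(a, v[, c("id", "chrom", "pos", "ref", "alt")],
                   population = rep(config@popLabel, n))
  })
}

#' Simulate a cohort from a haplotype panel
#'
#' Samples are formed by pairing consecutive haplotypes; dosage is the
#' risk-allele (alt) count.  Per-gene copy number is drawn as a log2 copy
#' ratio N(0, `cnLog2Sd`), and expression follows
#' `mu + sum(beta_g * dosage) + cnEffect * log2ratio + N(0, noiseSd)`,
#' truncated below at `exprFloor`.  Survival times are exponential with hazard
#' `survBaseline * exp(survLogHR * z)` where `z` is the z-scored expression of
#' `survGene`; with probability `censoringRate` a subject is censored at a
#' uniform fraction of its event time.
#'
#' @param panel a [HaplotypePanel-class] (from [simulateHaplotypes()]).
#' @param config the same [SimConfig-class].
#' @return A [CohortData-class].
#' @export
simulateCohort <- function(panel, config) {
  .assert(config@nSamples <= nHaplotypes(panel) %/% 2L,
          "nSamples exceeds available haplotype pairs")
  local_seed(config@seed + 1L, {
    ns <- config@nSamples
    hap <- alleleMatrix(panel)[seq_len(2L * ns), , drop = FALSE]
    dosage <- hap[seq(1, 2 * ns, 2), , drop = FALSE] +
              hap[seq(2, 2 * ns, 2), , drop = FALSE]
    dosage <- t(dosage)  # variants x samples
    smp <- paste0("P", seq_len(ns))
    colnames(dosage) <- smp
    g <- config@genes
    cn <- matrix(rnorm(nrow(g) * ns, 0, config@cnLog2Sd), nrow = nrow(g),
                 dimnames = list(g$id, smp))
    expr <- matrix(rep(g$mu, ns), nrow = nrow(g), dimnames = list(g$id, smp))
    ef <- config@eqtlEffects
    for (i in seq_len(nrow(ef)))
      expr[ef$gene[i], ] <- expr[ef$gene[i], ] + ef$beta[i] * dosage[ef$variant[i], ]
    expr <- expr + config@cnEffect * cn
    expr <- expr + matrix(rnorm(nrow(g) * ns, 0, config@noiseSd), nrow = nrow(g))
    expr <- pmax(expr, config@exprFloor)

    z <- if (!is.na(config@survGene)) {
      e <- expr[config@survGene, ]
      if (sd(e) > 0) (e - mean(e)) / sd(e) else rep(0, ns)
    } else rep(0, ns)
    hazard <- config@survBaseline * exp(config@survLogHR * z)
    t_event <- rexp(ns, hazard)
    censored <- runif(ns) < config@censoringRate
    time <- ifelse(censored, runif(ns) * t_event, t_event)
    surv <- data.frame(sample = smp, time = time,
                       event = as.integer(!censored))
    CohortData(dosage, cn, expr, surv,
               genes = g[, c("id", "chrom", "tss")])
  })
}

#' Simulate a clustered GWAS catalog
#'
#' Places `n_snps` associations of a category uniformly in
#' `[center - window, center + window]` per cluster, with p-values log-uniform
#' between 1e-12 and 1e-5.
#'
#' @param config a [SimConfig-class] (seed and chromosome naming).
#' @param cluster_spec list of `list(center, n_snps, category, window,
#'   chrom, trait)`; `chrom` defaults to the config's first variant chromosome
#'   and `trait` to the category label.
#' @return A [GwasCatalog-class].
#' @export
simulateGwasCatalog <- function(config, cluster_spec) {
  default_chrom <- if (nrow(config@variants)) config@variants$chrom[1] else "chr11"
  local_seed(config@seed + 2L, {
    recs <- list()
    for (ci in seq_along(cluster_spec)) {
      cl <- cluster_spec[[ci]]
      .assert(cl$window > 0, "cluster window must be positive")
      if (cl$n_snps == 0) next
      pos <- round(runif(cl$n_snps, cl$center - cl$window, cl$center + cl$window))
      recs[[length(recs) + 1L]] <- data.frame(
        snp_id = sprintf("cl%d_snp%d", ci, seq_len(cl$n_snps)),
        chrom = cl$chrom %||% default_chrom, pos = as.integer(pos),
        trait = cl$trait %||% cl$category, category = cl$category,
        p_value = 10^runif(cl$n_snps, -12, -5))
    }
    if (!length(recs))
      return(GwasCatalog(data.frame(snp_id = character(), chrom = character(),
                                    pos = integer(), trait = character(),
                                    category = character(), p_value = numeric())))
    GwasCatalog(do.call(rbind, recs))
  })
}

#' Plant a motif-overlapping SNP in a 51-mer
#'
#' Builds a random background 51-mer with the PWM consensus embedded so that
#' it covers the central base (0-based offset 25); the reference sequence
#' carries the consensus base at the center and the alternate sequence the
#' consensus column's lowest-probability base.  The two sequences differ only
#' at the center.
#'
#' @param pwm a [PWMotif-class] of length <= 25.
#' @param seed integer RNG seed.
#' @return list(seq_ref, seq_alt, offset) with `offset` the 0-based start of
#'   the planted match.
#' @export
plantMotifSnp <- function(pwm, seed) {
  L <- length(pwm)
  .assert(L <= 25, "PWM length ", L, " > 25: match cannot both fit the 51-bp ",
          "window and cover its center")
  local_seed(seed, {
    center <- 25L  # 0-based
    lo <- max(0L, center - L + 1L); hi <- min(center, 51L - L)
    offset <- sample(lo:hi, 1L)
    bg <- sample(DNA_BASES4, 51, replace = TRUE, prob = pwmBackground(pwm))
    cons <- strsplit(consensusString4(pwm), "")[[1]]
    seq_ref <- bg
    seq_ref[(offset + 1):(offset + L)] <- cons
    col <- center - offset + 1L
    worst <- DNA_BASES4[which.min(pwmProbs(pwm)[, col])]
    if (worst == seq_ref[center + 1]) {
      ord <- order(pwmProbs(pwm)[, col])
      worst <- DNA_BASES4[ord[2]]  # consensus ties the minimum: pick next
    }
    seq_alt <- seq_ref
    seq_alt[center + 1] <- worst
    list(seq_ref = paste(seq_ref, collapse = ""),
         seq_alt = paste(seq_alt, collapse = ""), offset = offset)
  })
}
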