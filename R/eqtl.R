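# cis-eQTL scan with copy-number adjustment and the conditional
# (genotype-stratified) residual-effect test.

#' Filter genes by mean expression
#'
#' Keeps genes whose mean expression across samples is `>= min_mean`
#' (the conventional mean-FPKM >= 1 expressed-gene filter).
#'
#' @param expr genes x samples non-negative matrix.
#' @param min_mean minimum row mean (default 1).
#' @return The filtered matrix.
#' @export
filterExpressed <- function(expr, min_mean = 1) {
  expr[rowMeans(expr) >= min_mean, , drop = FALSE]
}

#' Genes within a centered cis window of a SNP
#'
#' A 3-Mb centered region corresponds to the default `window = 1.5e6` (half
#' width); boundaries are inclusive.
#'
#' @param genes data.frame(id, chrom, tss).
#' @param snp a [variantRecord()].
#' @param window half-width in bp (default 1.5e6).
#' @return The subset of `genes` with same chromosome and
#'   `|tss - snp$pos| <= window`.
#' @export
cisGeneSet <- function(genes, snp, window = 1.5e6) {
  .assert(window > 0, "window must be positive")
  keep <- genes$chrom == snp$chrom & abs(genes$tss - snp$pos) <= window
  out <- genes[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Copy-number-adjusted eQTL fit for one gene
#'
#' Ordinary least squares of expression on (intercept, risk-allele dosage,
#' copy-number covariate), with two-sided t-tests for each slope.  When the
#' copy-number covariate is constant (or omitted) the model reduces exactly to
#' simple regression on dosage.  `r_genotype` is the standardized genotype
#' effect `beta_genotype * sd(dosage) / sd(expression)`.
#'
#' @param expression numeric response vector.
#' @param dosage risk-allele dosage in 0/1/2; must be polymorphic.
#' @param cn optional copy-number covariate (taken linearly as provided; the
#'   simulator emits log2 copy ratios).
#' @return list(n, beta_genotype, se_genotype, p_genotype, beta_cn, p_cn,
#'   r_genotype); `beta_cn`/`p_cn` are NA when cn is constant or omitted.
#' @examples
#' d <- rep(0:2, each = 4)
#' eqtlFit(5 - d, d)$beta_genotype  # exactly -1
#' @export
eqtlFit <- function(expression, dosage, cn = NULL) {
  n <- length(expression)
  .assert(length(dosage) == n && (is.null(cn) || length(cn) == n),
          "expression, dosage and cn must be aligned")
  .assert(n >= 4, "need at least 4 samples")
  if (sd(dosage) == 0) stop("constant dosage: genotype effect is unidentifiable",
                            call. = FALSE)
  use_cn <- !is.null(cn) && sd(cn) > 0
  if (use_cn) {
    X <- cbind(1, dosage, cn)
    kap <- kappa(X, exact = TRUE)
    if (abs(cor(dosage, cn)) > 1 - 1e-10 || kap > 1e10)
      stop("collinear dosage and cn covariates (condition number ",
           format(kap, digits = 3), ")", call. = FALSE)
    fit <- lm(expression ~ dosage + cn)
  } else {
    fit <- lm(expression ~ dosage)
  }
  cf <- summary(fit)$coefficients
  out <- list(
    n = n,
    beta_genotype = cf["dosage", "Estimate"],
    se_genotype = cf["dosage", "Std. Error"],
    p_genotype = cf["dosage", "Pr(>|t|)"],
    beta_cn = if (use_cn) cf["cn", "Estimate"] else NA_real_,
    p_cn = if (use_cn) cf["cn", "Pr(>|t|)"] else NA_real_,
    r_genotype = if (sd(expression) > 0)
      cf["dosage", "Estimate"] * sd(dosage) / sd(expression) else NA_real_)
  out
}

#' Cis-eQTL scan over a gene set
#'
#' Runs [eqtlFit()] for each gene, regressing its expression on the SNP's
#' dosage and the gene's own copy-number covariate.  Per-gene failures (e.g.
#' constant dosage in a subset) are recorded in the `error` column rather than
#' aborting the scan.  P-values are reported unadjusted, with a
#' Benjamini-Hochberg column alongside.
#'
#' @param cohort a [CohortData-class].
#' @param snp a [variantRecord()] whose id indexes the cohort dosage matrix.
#' @param genes character vector of gene ids (typically the output of
#'   [filterExpressed()] intersected with [cisGeneSet()]).
#' @return data.frame(gene, n, beta_genotype, se_genotype, p_genotype,
#'   beta_cn, p_cn, r_genotype, p_bh, error), sorted by `p_genotype`.
#' @export
eqtlScan <- function(cohort, snp, genes) {
  dm <- dosageMatrix(cohort)
  .assert(snp$id %in% rownames(dm), "SNP '", snp$id, "' not genotyped in cohort")
  dosage <- dm[snp$id, ]
  em <- exprMatrix(cohort); cm <- cnMatrix(cohort)
  .assert(all(genes %in% rownames(em)), "gene(s) missing from expression matrix")
  rows <- lapply(genes, function(g) {
    res <- tryCatch(eqtlFit(em[g, ], dosage,
                            if (g %in% rownames(cm)) cm[g, ] else NULL),
                    error = function(e) e)
    if (inherits(res, "error"))
      data.frame(gene = g, n = NA_integer_, beta_genotype = NA_real_,
                 se_genotype = NA_real_, p_genotype = NA_real_,
                 beta_cn = NA_real_, p_cn = NA_real_, r_genotype = NA_real_,
                 error = conditionMessage(res))
    else
      data.frame(gene = g, n = res$n, beta_genotype = res$beta_genotype,
                 se_genotype = res$se_genotype, p_genotype = res$p_genotype,
                 beta_cn = res$beta_cn, p_cn = res$p_cn,
                 r_genotype = res$r_genotype, error = NA_character_)
  })
  out <- do.call(rbind, rows)
  out$p_bh <- p.adjust(out$p_genotype, method = "BH")
  out <- out[order(out$p_genotype), c("gene", "n", "beta_genotype",
             "se_genotype", "p_genotype", "beta_cn", "p_cn", "r_genotype",
             "p_bh", "error")]
  rownames(out) <- NULL
  out
}

#' Conditional (genotype-stratified) eQTL test
#'
#' Restricts to samples carrying `conditioning_value` at the conditioning
#' variant, then Welch-tests expression between carriers of the primary risk
#' allele (dosage >= 1) and non-carriers (dosage = 0), two-sided with
#' Satterthwaite degrees of freedom.  The statistic is oriented as
#' carriers minus non-carriers.
#'
#' @param expression numeric vector.
#' @param dosage_primary primary-variant dosage in 0/1/2.
#' @param dosage_conditioning conditioning-variant dosage in 0/1/2.
#' @param conditioning_value genotype stratum to keep (0, 1 or 2).
#' @return list(t, df, p, n_carrier, n_noncarrier, mean_carrier,
#'   mean_noncarrier).
#' @export
conditionalEqtl <- function(expression, dosage_primary, dosage_conditioning,
                            conditioning_value) {
  keep <- dosage_conditioning == conditioning_value
  .assert(any(keep), "no samples with conditioning genotype ",
          conditioning_value)
  e <- expression[keep]; d <- dosage_primary[keep]
  carrier <- d >= 1
  if (!any(carrier)) stop("empty stratum: no primary risk-allele carriers ",
                          "within conditioning genotype ", conditioning_value,
                          call. = FALSE)
  if (all(carrier)) stop("empty stratum: no primary non-carriers within ",
                         "conditioning genotype ", conditioning_value,
                         call. = FALSE)
  tt <- t.test(e[carrier], e[!carrier], var.equal = FALSE,
               alternative = "two.sided")
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, n_carrier = sum(carrier),
       n_noncarrier = sum(!carrier), mean_carrier = mean(e[carrier]),
       mean_noncarrier = mean(e[!carrier]))
}
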