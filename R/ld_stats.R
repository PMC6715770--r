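# haplotype-based linkage disequilibrium statistics.
#
# Conventions: the "focal" allele at each site defaults to the alternate
# allele; D carries its sign, D' is reported as |D|/Dmax (the unsigned
# convention GWAS papers print), r2 = D^2 / (pA qA pB qB).

#' Focal-allele frequency in a haplotype panel
#'
#' @param panel a [HaplotypePanel-class].
#' @param variant variant id present in the panel.
#' @param allele allele string; must be the ref or alt allele of the variant.
#' @return count of `allele` haplotypes / total haplotypes.
#' @examples
#' v <- data.frame(id = "v1", chrom = "c", pos = 1L, ref = "A", alt = "G")
#' p <- HaplotypePanel(matrix(c(0L, 1L, 1L, 1L), 4, 1), v)
#' alleleFrequency(p, "v1", "G")  # 0.75
#' @export
alleleFrequency <- function(panel, variant, allele) {
  v <- variantInfo(panel)
  k <- match(variant, v$id)
  .assert(!is.na(k), "unknown variant '", variant, "'")
  a <- alleleMatrix(panel)[, k]
  if (allele == v$alt[k]) mean(a == 1L)
  else if (allele == v$ref[k]) mean(a == 0L)
  else stop("allele '", allele, "' is neither ref (", v$ref[k], ") nor alt (",
            v$alt[k], ") of ", variant, call. = FALSE)
}

#' LD statistics from a 2x2 haplotype count table
#'
#' `n11` counts haplotypes carrying the focal allele at both sites, `n10`
#' focal at site 1 only, and so on.  Returns the coefficient of linkage
#' disequilibrium D = n11/N - pA*pB, its normalization
#' D' = |D| / Dmax (Dmax = min(pA(1-pB), (1-pA)pB) for D > 0 and
#' min(pA pB, (1-pA)(1-pB)) for D < 0), and the squared allelic correlation
#' r2 = D^2 / (pA(1-pA) pB(1-pB)).
#'
#' @param n11,n10,n01,n00 non-negative haplotype counts; total must be positive
#'   and both sites polymorphic.
#' @return list(n11, n10, n01, n00, pA, pB, D, Dprime, r2).
#' @examples
#' # a high-D', low-r2 pair: rare focal allele at site 1 riding almost
#' # exclusively on one allele of a common site 2
#' ldFromCounts(188, 3, 355, 460)
#' @export
ldFromCounts <- function(n11, n10, n01, n00) {
  .assert(all(c(n11, n10, n01, n00) >= 0), "counts must be non-negative")
  N <- n11 + n10 + n01 + n00
  .assert(N > 0, "total haplotype count must be positive")
  pA <- (n11 + n10) / N
  pB <- (n11 + n01) / N
  if (pA <= 0 || pA >= 1 || pB <= 0 || pB >= 1)
    stop("monomorphic site in count table: r2 is undefined", call. = FALSE)
  D <- n11 / N - pA * pB
  Dmax <- if (D >= 0) min(pA * (1 - pB), (1 - pA) * pB)
          else min(pA * pB, (1 - pA) * (1 - pB))
  Dprime <- if (D == 0) 0 else abs(D) / Dmax
  r2 <- D^2 / (pA * (1 - pA) * pB * (1 - pB))
  out <- list(n11 = n11, n10 = n10, n01 = n01, n00 = n00,
              pA = pA, pB = pB, D = D, Dprime = Dprime, r2 = r2)
  stopifnot(out$r2 <= out$Dprime^2 + 1e-12)  # algebraic invariant
  out
}

# joint 2x2 focal-allele counts for two variant columns
.pair_counts <- function(panel, v1, v2) {
  v <- variantInfo(panel)
  k1 <- match(v1, v$id); k2 <- match(v2, v$id)
  .assert(!is.na(k1), "unknown variant '", v1, "'")
  .assert(!is.na(k2), "unknown variant '", v2, "'")
  a1 <- alleleMatrix(panel)[, k1]
  a2 <- alleleMatrix(panel)[, k2]
  c(n11 = sum(a1 == 1L & a2 == 1L), n10 = sum(a1 == 1L & a2 == 0L),
    n01 = sum(a1 == 0L & a2 == 1L), n00 = sum(a1 == 0L & a2 == 0L))
}

#' Pairwise LD between two panel variants
#'
#' Tabulates the 2x2 haplotype table (focal = alternate allele at each site)
#' and delegates to [ldFromCounts()].  D' and r2 are symmetric in the two
#' variants and invariant under swapping which allele is focal.
#'
#' @inheritParams alleleFrequency
#' @param v1,v2 variant ids.
#' @return As [ldFromCounts()], plus `v1`, `v2` and focal allele labels.
#' @export
ldPair <- function(panel, v1, v2) {
  n <- .pair_counts(panel, v1, v2)
  out <- ldFromCounts(n[["n11"]], n[["n10"]], n[["n01"]], n[["n00"]])
  v <- variantInfo(panel)
  out$v1 <- v1; out$v2 <- v2
  out$focal1 <- v$alt[match(v1, v$id)]
  out$focal2 <- v$alt[match(v2, v$id)]
  out
}

#' Expand a tag SNP into its high-LD proxy set
#'
#' All panel variants on the tag's chromosome within `window` bp with minor
#' allele frequency >= `maf_min` and r2 >= `r2_min` with the tag, sorted by
#' descending r2 then position.  The tag itself is always included (r2 = 1).
#' Monomorphic variants are skipped (their r2 is undefined and their MAF is 0).
#'
#' @inheritParams alleleFrequency
#' @param tag tag variant id.
#' @param r2_min minimum squared correlation with the tag (default 0.8).
#' @param maf_min minimum minor allele frequency (default 0.05).
#' @param window half-width in bp around the tag position (default 1e6).
#' @return data.frame(variant, chrom, pos, pA, pB, D, Dprime, r2); `pA` is the
#'   tag's focal (alt) allele frequency, `pB` the proxy's.
#' @export
ldExpand <- function(panel, tag, r2_min = 0.8, maf_min = 0.05, window = 1e6) {
  v <- variantInfo(panel)
  kt <- match(tag, v$id)
  .assert(!is.na(kt), "tag variant '", tag, "' not in panel")
  cand <- which(v$chrom == v$chrom[kt] & abs(v$pos - v$pos[kt]) <= window)
  rows <- lapply(cand, function(k) {
    if (k != kt) {
      f <- mean(alleleMatrix(panel)[, k] == 1L)
      if (min(f, 1 - f) < maf_min || f %in% c(0, 1)) return(NULL)
    }
    ld <- ldPair(panel, tag, v$id[k])
    if (k != kt && ld$r2 < r2_min) return(NULL)
    data.frame(variant = v$id[k], chrom = v$chrom[k], pos = v$pos[k],
               pA = ld$pA, pB = ld$pB, D = ld$D, Dprime = ld$Dprime, r2 = ld$r2)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(variant = character(), chrom = character(), pos = integer(),
                      pA = numeric(), pB = numeric(), D = numeric(),
                      Dprime = numeric(), r2 = numeric())
  out <- out[order(-out$r2, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Labeled 2x2 joint haplotype count table
#'
#' Rows are the alleles of `v1` (alt first), columns those of `v2`.  Row and
#' column sums equal the marginal allele counts.
#'
#' @inheritParams ldPair
#' @return list(table = 2x2 integer matrix with allele dimnames, total = N).
#' @export
haplotypeBiasTable <- function(panel, v1, v2) {
  n <- .pair_counts(panel, v1, v2)
  v <- variantInfo(panel)
  a1 <- c(v$alt[match(v1, v$id)], v$ref[match(v1, v$id)])
  a2 <- c(v$alt[match(v2, v$id)], v$ref[match(v2, v$id)])
  tab <- matrix(as.integer(c(n[["n11"]], n[["n10"]], n[["n01"]], n[["n00"]])),
                nrow = 2, byrow = TRUE,
                dimnames = list(paste0(v1, "-", a1), paste0(v2, "-", a2)))
  list(table = tab, total = sum(tab))
}
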