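#' HaplotypePanel: phased allele matrix
#'
#' Holds a matrix of phased alleles (rows = haplotypes, columns = biallelic
#' variants, entries 0 = reference allele, 1 = alternate allele), per-variant
#' metadata, and per-haplotype sample / population labels.  This is the sole
#' substrate of all linkage-disequilibrium computations.
#'
#' @slot alleles integer matrix of 0/1, haplotypes x variants.
#' @slot variants data.frame with columns id, chrom, pos (1-based), ref, alt.
#' @slot samples character, sample of origin of each haplotype.
#' @slot population character, population label of each haplotype.
#' @exportClass HaplotypePanel
setClass("HaplotypePanel",
  representation(alleles = "matrix", variants = "data.frame",
                 samples = "character", population = "character"))

setValidity("HaplotypePanel", function(object) {
  a <- object@alleles; v <- object@variants
  msg <- character()
  if (!all(c("id", "chrom", "pos", "ref", "alt") %in% names(v)))
    msg <- c(msg, "variants must have columns id, chrom, pos, ref, alt")
  if (ncol(a) != nrow(v)) msg <- c(msg, "ncol(alleles) != nrow(variants)")
  if (!all(a %in% c(0L, 1L))) msg <- c(msg, "alleles must be 0/1")
  if (!identical(colnames(a), as.character(v$id)))
    msg <- c(msg, "colnames(alleles) must equal variants$id")
  if (length(object@samples) != nrow(a) || length(object@population) != nrow(a))
    msg <- c(msg, "samples/population must have one entry per haplotype")
  if (nrow(v) && any(v$pos < 1)) msg <- c(msg, "positions must be >= 1")
  if (nrow(v) && any(v$ref == v$alt)) msg <- c(msg, "ref must differ from alt")
  if (nrow(v) && anyDuplicated(v$id)) msg <- c(msg, "duplicated variant ids")
  if (length(msg)) msg else TRUE
})

#' Construct a HaplotypePanel
#'
#' @param alleles 0/1 matrix, haplotypes x variants.
#' @param variants data.frame(id, chrom, pos, ref, alt).
#' @param samples optional sample label per haplotype; defaults to pairing
#'   consecutive haplotypes into samples S1, S2, ...
#' @param population optional population label per haplotype (default "ALL").
#' @return A [HaplotypePanel-class] object.
#' @examples
#' v <- data.frame(id = c("v1", "v2"), chrom = "chr11", pos = c(100L, 200L),
#'                 ref = "A", alt = "G")
#' HaplotypePanel(matrix(c(0, 1, 1, 0), 2, 2, dimnames = list(NULL, v$id)), v)
#' @export
HaplotypePanel <- function(alleles, variants, samples = NULL, population = NULL) {
  storage.mode(alleles) <- "integer"
  variants$id <- as.character(variants$id)
  variants$chrom <- as.character(variants$chrom)
  variants$pos <- as.integer(variants$pos)
  rownames(variants) <- NULL
  colnames(alleles) <- variants$id
  n <- nrow(alleles)
  if (is.null(samples)) samples <- paste0("S", ceiling(seq_len(n) / 2))
  if (is.null(population)) population <- rep("ALL", n)
  if (is.null(rownames(alleles)) && n > 0)
    rownames(alleles) <- paste0(samples, "_h",
                                stats::ave(seq_len(n), samples, FUN = seq_along))
  new("HaplotypePanel", alleles = alleles, variants = variants,
      samples = as.character(samples), population = as.character(population))
}

#' CohortData: aligned sample-level molecular and clinical data
#'
#' Genotype dosages, per-gene copy-number covariate (stored as log2 copy
#' ratio), expression, survival records, and gene metadata for one cohort.
#' All matrices share an identical sample column order.
#'
#' @slot dosage numeric matrix, variants x samples, risk-allele dosage 0/1/2.
#' @slot cn numeric matrix, genes x samples, log2(copy number / 2).
#' @slot expression numeric matrix, genes x samples, non-negative.
#' @slot survival data.frame(sample, time, event) with event 1 = death, 0 = censored.
#' @slot genes data.frame(id, chrom, tss) gene metadata.
#' @exportClass CohortData
setClass("CohortData",
  representation(dosage = "matrix", cn = "matrix", expression = "matrix",
                 survival = "data.frame", genes = "data.frame"))

setValidity("CohortData", function(object) {
  msg <- character()
  s <- colnames(object@expression)
  if (is.null(s)) msg <- c(msg, "expression must have sample colnames")
  if (!identical(colnames(object@dosage), s) || !identical(colnames(object@cn), s))
    msg <- c(msg, "dosage/cn/expression sample columns must align")
  if (!all(c("sample", "time", "event") %in% names(object@survival)))
    msg <- c(msg, "survival needs columns sample, time, event")
  if (!all(c("id", "chrom", "tss") %in% names(object@genes)))
    msg <- c(msg, "genes needs columns id, chrom, tss")
  if (!identical(rownames(object@expression), as.character(object@genes$id)))
    msg <- c(msg, "expression rownames must equal genes$id")
  if (nrow(object@survival) && any(object@survival$time < 0, na.rm = TRUE))
    msg <- c(msg, "survival times must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Construct a CohortData object
#'
#' @param dosage variants x samples dosage matrix (0/1/2).
#' @param cn genes x samples log2 copy-ratio matrix.
#' @param expression genes x samples non-negative expression matrix.
#' @param survival data.frame(sample, time, event).
#' @param genes data.frame(id, chrom, tss).
#' @return A [CohortData-class] object.
#' @export
CohortData <- function(dosage, cn, expression, survival, genes) {
  genes$id <- as.character(genes$id)
  rownames(genes) <- NULL
  new("CohortData", dosage = as.matrix(dosage), cn = as.matrix(cn),
      expression = as.matrix(expression), survival = survival, genes = genes)
}

#' GwasCatalog: variant/trait association records
#'
#' @slot records data.frame(snp_id, chrom, pos, trait, category, p_value);
#'   duplicate (snp_id, trait) pairs are dropped at construction.
#' @exportClass GwasCatalog
setClass("GwasCatalog", representation(records = "data.frame"))

setValidity("GwasCatalog", function(object) {
  r <- object@records
  need <- c("snp_id", "chrom", "pos", "trait", "category", "p_value")
  if (!all(need %in% names(r)))
    return(paste("records must have columns", paste(need, collapse = ", ")))
  if (nrow(r) && any(r$pos < 1)) return("positions must be >= 1")
  TRUE
})

#' Construct a GwasCatalog
#'
#' Duplicate (snp_id, trait) records are deduplicated, keeping the first.
#'
#' @param records data.frame(snp_id, chrom, pos, trait, category, p_value).
#' @return A [GwasCatalog-class] object.
#' @export
GwasCatalog <- function(records) {
  records$snp_id <- as.character(records$snp_id)
  records$chrom <- as.character(records$chrom)
  records$pos <- as.integer(records$pos)
  records$trait <- as.character(records$trait)
  records$category <- as.character(records$category)
  records <- records[!duplicated(records[c("snp_id", "trait")]), , drop = FALSE]
  rownames(records) <- NULL
  new("GwasCatalog", records = records)
}

#' PWMotif: position weight matrix
#'
#' A transcription-factor binding preference as a 4 x L column-stochastic
#' probability matrix over A, C, G, T with a 0-order background.  Probabilities
#' are pseudocount-smoothed at construction:
#' `p = (m + pseudocount * background) / colSums(...)`.
#'
#' @slot name motif identifier.
#' @slot probs 4 x L matrix, rows A/C/G/T, columns sum to 1.
#' @slot background length-4 base frequency vector summing to 1.
#' @slot pseudocount smoothing mass added (per unit background) at load.
#' @exportClass PWMotif
setClass("PWMotif",
  representation(name = "character", probs = "matrix",
                 background = "numeric", pseudocount = "numeric"))

setValidity("PWMotif", function(object) {
  p <- object@probs
  msg <- character()
  if (!identical(rownames(p), DNA_BASES4)) msg <- c(msg, "probs rows must be A,C,G,T")
  if (ncol(p) < 4) msg <- c(msg, "motif length must be >= 4")
  if (any(abs(colSums(p) - 1) > 1e-9)) msg <- c(msg, "columns must sum to 1")
  if (abs(sum(object@background) - 1) > 1e-9) msg <- c(msg, "background must sum to 1")
  if (any(p <= 0)) msg <- c(msg, "probabilities must be positive after smoothing")
  if (length(msg)) msg else TRUE
})

#' Construct a PWMotif from counts or probabilities
#'
#' @param name motif name.
#' @param mat 4 x L matrix of counts or probabilities, rows in A,C,G,T order
#'   (rownames used when present).
#' @param background length-4 background base frequencies (default uniform).
#' @param pseudocount smoothing constant, default 0.1; `pseudocount *
#'   background` is added to each column before renormalization.
#' @return A [PWMotif-class] object.
#' @examples
#' PWMotif("uniform4", matrix(1, 4, 4))
#' @export
PWMotif <- function(name, mat, background = rep(0.25, 4), pseudocount = 0.1) {
  mat <- as.matrix(mat)
  if (!is.null(rownames(mat))) {
    .assert(setequal(rownames(mat), DNA_BASES4),
            "PWM '", name, "': row labels must be A, C, G, T")
    mat <- mat[DNA_BASES4, , drop = FALSE]
  } else {
    .assert(nrow(mat) == 4, "PWM '", name, "' must have 4 rows (A,C,G,T)")
    rownames(mat) <- DNA_BASES4
  }
  .assert(all(mat >= 0), "PWM '", name, "': negative entries")
  zero <- colSums(mat) == 0
  .assert(!any(zero), "PWM '", name, "': all-zero column(s) at position(s) ",
          paste(which(zero), collapse = ", "))
  background <- background / sum(background)
  sm <- sweep(mat, 1, pseudocount * background, `+`)
  sm <- sweep(sm, 2, colSums(sm), `/`)
  colnames(sm) <- NULL
  new("PWMotif", name = name, probs = sm, background = background,
      pseudocount = pseudocount)
}

#' InteractionPairs: unordered chromatin-interaction anchor pairs
#'
#' Paired genomic anchors (e.g. ChIA-PET significant interactions) with a
#' score.  The pair is unordered: anchors are canonically sorted at
#' construction so that swapped input yields an identical object.
#'
#' @slot anchor1,anchor2 GRanges of equal length.
#' @slot score numeric per-interaction score.
#' @exportClass InteractionPairs
setClass("InteractionPairs",
  representation(anchor1 = "GRanges", anchor2 = "GRanges", score = "numeric"))

setValidity("InteractionPairs", function(object) {
  if (length(object@anchor1) != length(object@anchor2) ||
      length(object@score) != length(object@anchor1))
    return("anchor1, anchor2 and score must have equal length")
  TRUE
})

#' Construct InteractionPairs
#'
#' @param anchor1,anchor2 GRanges of equal length.
#' @param score numeric vector (default 0).
#' @return An [InteractionPairs-class] object with canonically ordered anchors.
#' @export
InteractionPairs <- function(anchor1, anchor2,
                             score = rep(0, length(anchor1))) {
  key <- function(gr) paste(GenomicRanges::seqnames(gr),
                            sprintf("%012d", GenomicRanges::start(gr)),
                            sprintf("%012d", GenomicRanges::end(gr)))
  swap <- key(anchor2) < key(anchor1)
  a1 <- anchor1; a2 <- anchor2
  if (any(swap)) {
    a1[swap] <- anchor2[swap]
    a2[swap] <- anchor1[swap]
  }
  new("InteractionPairs", anchor1 = a1, anchor2 = a2, score = as.numeric(score))
}
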