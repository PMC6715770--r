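# internal helpers shared across modules

# evaluate `code` under a fixed RNG seed, restoring the caller's RNG state
local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

.assert <- function(cond, ...) if (!isTRUE(cond)) stop(..., call. = FALSE)

DNA_BASES4 <- c("A", "C", "G", "T")

#' Construct a variant record
#'
#' A lightweight biallelic SNP descriptor used throughout the package
#' (proximity counting, interval overlap, eQTL scans).  Positions are 1-based.
#'
#' @param id variant identifier (e.g. an rs id).
#' @param chrom chromosome name, taken literally (no "chr" normalization).
#' @param pos 1-based position, `>= 1`.
#' @param ref,alt reference and alternate allele strings; must differ.
#' @return A list of class `VariantRecord`.
#' @examples
#' variantRecord("rs3903072", "chr11", 65583185, "T", "G")
#' @export
variantRecord <- function(id, chrom, pos, ref = "N", alt = "A") {
  .assert(is.character(id) && length(id) == 1L, "'id' must be a single string")
  .assert(length(pos) == 1L && is.finite(pos) && pos >= 1 && pos == round(pos),
          "'pos' must be a 1-based integer position")
  .assert(!identical(ref, alt), "ref and alt alleles must differ for ", id)
  structure(list(id = id, chrom = as.character(chrom), pos = as.integer(pos),
                 ref = ref, alt = alt),
            class = "VariantRecord")
}

#' @export
print.VariantRecord <- function(x, ...) {
  cat(sprintf("VariantRecord %s %s:%d %s>%s\n", x$id, x$chrom, x$pos, x$ref, x$alt))
  invisible(x)
}

# coerce a VariantRecord (or id present in a variant table) to a width-1 GRanges
.snp_granges <- function(snp) {
  GenomicRanges::GRanges(snp$chrom, IRanges::IRanges(snp$pos, snp$pos))
}
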