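# accessors, show and subset methods

#' @rdname HaplotypePanel-class
#' @export
setMethod("alleleMatrix", "HaplotypePanel", function(object) object@alleles)

#' @rdname HaplotypePanel-class
#' @export
setMethod("variantInfo", "HaplotypePanel", function(object) object@variants)

#' @rdname HaplotypePanel-class
#' @export
setMethod("sampleIds", "HaplotypePanel", function(object) object@samples)

#' @rdname HaplotypePanel-class
#' @export
setMethod("populations", "HaplotypePanel", function(object) object@population)

#' @rdname HaplotypePanel-class
#' @export
setMethod("nHaplotypes", "HaplotypePanel", function(object) nrow(object@alleles))

#' @rdname HaplotypePanel-class
#' @export
setMethod("nVariants", "HaplotypePanel", function(object) ncol(object@alleles))

#' @rdname HaplotypePanel-class
#' @param i,j haplotype (row) and variant (column) indices.
#' @param ...,drop ignored.
#' @export
setMethod("[", "HaplotypePanel", function(x, i, j, ..., drop = FALSE) {
  if (missing(i)) i <- seq_len(nrow(x@alleles))
  if (missing(j)) j <- seq_len(ncol(x@alleles))
  if (is.character(j)) j <- match(j, x@variants$id)
  HaplotypePanel(x@alleles[i, j, drop = FALSE], x@variants[j, , drop = FALSE],
                 samples = x@samples[i], population = x@population[i])
})

setMethod("show", "HaplotypePanel", function(object) {
  cat(sprintf("HaplotypePanel: %d haplotypes x %d variants (%d samples; populations: %s)\n",
              nrow(object@alleles), ncol(object@alleles),
              length(unique(object@samples)),
              paste(unique(object@population), collapse = ",")))
  if (ncol(object@alleles))
    cat("  variants:", paste(head(object@variants$id, 5), collapse = ", "),
        if (ncol(object@alleles) > 5) "..." else "", "\n")
})

#' @rdname CohortData-class
#' @export
setMethod("dosageMatrix", "CohortData", function(object) object@dosage)

#' @rdname CohortData-class
#' @export
setMethod("cnMatrix", "CohortData", function(object) object@cn)

#' @rdname CohortData-class
#' @export
setMethod("exprMatrix", "CohortData", function(object) object@expression)

#' @rdname CohortData-class
#' @export
setMethod("survivalTable", "CohortData", function(object) object@survival)

#' @rdname CohortData-class
#' @export
setMethod("geneInfo", "CohortData", function(object) object@genes)

#' @rdname CohortData-class
#' @export
setMethod("sampleIds", "CohortData", function(object) colnames(object@expression))

setMethod("show", "CohortData", function(object) {
  cat(sprintf("CohortData: %d samples, %d genes, %d genotyped variants\n",
              ncol(object@expression), nrow(object@expression), nrow(object@dosage)))
  ev <- sum(object@survival$event == 1, na.rm = TRUE)
  cat(sprintf("  survival: %d records, %d events\n", nrow(object@survival), ev))
})

#' @rdname GwasCatalog-class
#' @export
setMethod("catalogRecords", "GwasCatalog", function(object) object@records)

#' @rdname GwasCatalog-class
#' @export
setMethod("categoryLabels", "GwasCatalog",
          function(object) sort(unique(object@records$category)))

setMethod("show", "GwasCatalog", function(object) {
  cat(sprintf("GwasCatalog: %d associations, %d distinct SNPs\n",
              nrow(object@records), length(unique(object@records$snp_id))))
  cat("  categories:", paste(categoryLabels(object), collapse = ", "), "\n")
})

#' @rdname PWMotif-class
#' @export
setMethod("pwmProbs", "PWMotif", function(object) object@probs)

#' @rdname PWMotif-class
#' @export
setMethod("pwmBackground", "PWMotif", function(object) object@background)

#' @rdname PWMotif-class
#' @export
setMethod("pwmName", "PWMotif", function(object) object@name)

#' @rdname PWMotif-class
#' @export
setMethod("length", "PWMotif", function(x) ncol(x@probs))

#' @rdname PWMotif-class
#' @export
setMethod("consensusString4", "PWMotif", function(object)
  paste(DNA_BASES4[apply(object@probs, 2, which.max)], collapse = ""))

setMethod("show", "PWMotif", function(object) {
  cat(sprintf("PWMotif %s: length %d, consensus %s\n",
              object@name, ncol(object@probs), consensusString4(object)))
})

#' @rdname InteractionPairs-class
#' @export
setMethod("anchorOne", "InteractionPairs", function(object) object@anchor1)

#' @rdname InteractionPairs-class
#' @export
setMethod("anchorTwo", "InteractionPairs", function(object) object@anchor2)

#' @rdname InteractionPairs-class
#' @export
setMethod("interactionScores", "InteractionPairs", function(object) object@score)

#' @rdname InteractionPairs-class
#' @export
setMethod("length", "InteractionPairs", function(x) length(x@anchor1))

#' @rdname InteractionPairs-class
#' @export
setMethod("[", "InteractionPairs", function(x, i, j, ..., drop = FALSE)
  new("InteractionPairs", anchor1 = x@anchor1[i], anchor2 = x@anchor2[i],
      score = x@score[i]))

setMethod("show", "InteractionPairs", function(object) {
  cat(sprintf("InteractionPairs: %d unordered anchor pairs\n", length(object@anchor1)))
})
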