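# accessor generics

#' @rdname HaplotypePanel-class
#' @param object,x a package object.
#' @export
setGeneric("alleleMatrix", function(object) standardGeneric("alleleMatrix"))

#' @rdname HaplotypePanel-class
#' @export
setGeneric("variantInfo", function(object) standardGeneric("variantInfo"))

#' @rdname HaplotypePanel-class
#' @export
setGeneric("sampleIds", function(object) standardGeneric("sampleIds"))

#' @rdname HaplotypePanel-class
#' @export
setGeneric("populations", function(object) standardGeneric("populations"))

#' @rdname HaplotypePanel-class
#' @export
setGeneric("nHaplotypes", function(object) standardGeneric("nHaplotypes"))

#' @rdname HaplotypePanel-class
#' @export
setGeneric("nVariants", function(object) standardGeneric("nVariants"))

#' @rdname CohortData-class
#' @export
setGeneric("dosageMatrix", function(object) standardGeneric("dosageMatrix"))

#' @rdname CohortData-class
#' @export
setGeneric("cnMatrix", function(object) standardGeneric("cnMatrix"))

#' @rdname CohortData-class
#' @export
setGeneric("exprMatrix", function(object) standardGeneric("exprMatrix"))

#' @rdname CohortData-class
#' @export
setGeneric("survivalTable", function(object) standardGeneric("survivalTable"))

#' @rdname CohortData-class
#' @export
setGeneric("geneInfo", function(object) standardGeneric("geneInfo"))

#' @rdname GwasCatalog-class
#' @export
setGeneric("catalogRecords", function(object) standardGeneric("catalogRecords"))

#' @rdname GwasCatalog-class
#' @export
setGeneric("categoryLabels", function(object) standardGeneric("categoryLabels"))

#' @rdname PWMotif-class
#' @export
setGeneric("pwmProbs", function(object) standardGeneric("pwmProbs"))

#' @rdname PWMotif-class
#' @export
setGeneric("pwmBackground", function(object) standardGeneric("pwmBackground"))

#' @rdname PWMotif-class
#' @export
setGeneric("pwmName", function(object) standardGeneric("pwmName"))

#' @rdname PWMotif-class
#' @export
setGeneric("consensusString4", function(object) standardGeneric("consensusString4"))

#' @rdname InteractionPairs-class
#' @export
setGeneric("anchorOne", function(object) standardGeneric("anchorOne"))

#' @rdname InteractionPairs-class
#' @export
setGeneric("anchorTwo", function(object) standardGeneric("anchorTwo"))

#' @rdname InteractionPairs-class
#' @export
setGeneric("interactionScores", function(object) standardGeneric("interactionScores"))
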