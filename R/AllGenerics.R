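#' Accessors for pair containers
#'
#' \code{pairTable} returns the underlying data.frame of canonical gene
#' pairs; \code{nPairs} the number of pairs; \code{signatureGenes} the
#' sorted, deduplicated union of member genes.
#'
#' @param object a \code{StablePairSet}, \code{ReversalPairSet} or
#'   \code{PairSignature}.
#' @return \code{pairTable}: data.frame; \code{nPairs}: integer;
#'   \code{signatureGenes}: character vector.
#' @name pair-accessors
NULL

#' @rdname pair-accessors
#' @export
setGeneric("pairTable", function(object) standardGeneric("pairTable"))

#' @rdname pair-accessors
#' @export
setGeneric("nPairs", function(object) standardGeneric("nPairs"))

#' @rdname pair-accessors
#' @export
setGeneric("signatureGenes", function(object) standardGeneric("signatureGenes"))

#' @rdname pair-accessors
#' @export
setMethod("pairTable", "StablePairSet", function(object) object@pairs)
#' @rdname pair-accessors
#' @export
setMethod("pairTable", "ReversalPairSet", function(object) object@pairs)
#' @rdname pair-accessors
#' @export
setMethod("pairTable", "PairSignature", function(object) object@pairs)

#' @rdname pair-accessors
#' @export
setMethod("nPairs", "StablePairSet", function(object) nrow(object@pairs))
#' @rdname pair-accessors
#' @export
setMethod("nPairs", "ReversalPairSet", function(object) nrow(object@pairs))
#' @rdname pair-accessors
#' @export
setMethod("nPairs", "PairSignature", function(object) nrow(object@pairs))

#' @rdname pair-accessors
#' @export
setMethod("signatureGenes", "PairSignature", function(object)
  sort(unique(c(object@pairs$gene_a, object@pairs$gene_b)), method = "radix"))
#' @rdname pair-accessors
#' @export
setMethod("signatureGenes", "ReversalPairSet", function(object)
  sort(unique(c(object@pairs$gene_a, object@pairs$gene_b)), method = "radix"))

#' Stability threshold of a StablePairSet
#' @param object a \code{StablePairSet}.
#' @return numeric threshold in (0.5, 1].
#' @export
setGeneric("stabilityThreshold",
           function(object) standardGeneric("stabilityThreshold"))

#' @rdname stabilityThreshold
#' @export
setMethod("stabilityThreshold", "StablePairSet", function(object)
  object@threshold)

#' Phenotype label of a StablePairSet
#' @param object a \code{StablePairSet}.
#' @return character label.
#' @export
setGeneric("phenotypeLabel", function(object) standardGeneric("phenotypeLabel"))

#' @rdname phenotypeLabel
#' @export
setMethod("phenotypeLabel", "StablePairSet", function(object) object@phenotype)

#' Group labels of a ReversalPairSet
#' @param object a \code{ReversalPairSet}.
#' @return character(2).
#' @export
setGeneric("groupLabels", function(object) standardGeneric("groupLabels"))

#' @rdname groupLabels
#' @export
setMethod("groupLabels", "ReversalPairSet", function(object) object@groupLabels)

#' Build report of a PairSignature
#'
#' Per-stage pair counts recorded while the signature was built (stable pairs
#' per phenotype and platform, reversal pairs per platform, cross-platform
#' intersection, and the final filtered signature).
#'
#' @param object a \code{PairSignature}.
#' @return named list.
#' @export
setGeneric("buildReport", function(object) standardGeneric("buildReport"))

#' @rdname buildReport
#' @export
setMethod("buildReport", "PairSignature", function(object) object@buildReport)

#' Build configuration of a PairSignature
#' @param object a \code{PairSignature}.
#' @return named list of thresholds and options.
#' @export
setGeneric("buildConfig", function(object) standardGeneric("buildConfig"))

#' @rdname buildConfig
#' @export
setMethod("buildConfig", "PairSignature", function(object) object@buildConfig)

setMethod("show", "StablePairSet", function(object) {
  cat(sprintf(
    "StablePairSet: %d pairs | phenotype '%s' | support %s %.3g over %d samples\n",
    nrow(object@pairs), object@phenotype,
    if (object@strict) ">" else ">=", object@threshold, object@nSamples))
  if (nrow(object@pairs)) print(head(object@pairs, 4L), row.names = FALSE)
})

setMethod("show", "ReversalPairSet", function(object) {
  cat(sprintf("ReversalPairSet: %d pairs | groups '%s' vs '%s'\n",
              nrow(object@pairs), object@groupLabels[1L],
              object@groupLabels[2L]))
  if (nrow(object@pairs)) print(head(object@pairs, 4L), row.names = FALSE)
})

setMethod("show", "PairSignature", function(object) {
  cat(sprintf("PairSignature: %d pairs, %d unique genes\n",
              nrow(object@pairs), length(signatureGenes(object))))
  br <- object@buildReport
  if (length(br))
    cat("  build:", paste(names(br)[vapply(br, is.numeric, TRUE)],
        unlist(br[vapply(br, is.numeric, TRUE)]),
        sep = "=", collapse = " | "), "\n")
  if (nrow(object@pairs)) print(head(object@pairs, 4L), row.names = FALSE)
})
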