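#' @include AllClasses.R
NULL

#' Accessors for picmiscan classes
#'
#' Simple slot accessors: \code{genomeId}, \code{contigs}, \code{features},
#' \code{elementSeq}, \code{elementSpan}, \code{filterFlags}, \code{coreHits},
#' \code{repeatPair}, \code{subfamilies}, \code{identityMatrix},
#' \code{hitchhikerPct}.
#'
#' @param x an object of the matching picmiscan class
#' @param full for \code{hitchhikerPct}: return the full-precision percentage
#'   instead of the printed-convention integer
#' @return the slot value
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("genomeId", function(x) standardGeneric("genomeId"))
#' @rdname accessors
#' @export
setGeneric("contigs", function(x) standardGeneric("contigs"))
#' @rdname accessors
#' @export
setGeneric("features", function(x) standardGeneric("features"))
#' @rdname accessors
#' @export
setGeneric("elementSeq", function(x) standardGeneric("elementSeq"))
#' @rdname accessors
#' @export
setGeneric("elementSpan", function(x) standardGeneric("elementSpan"))
#' @rdname accessors
#' @export
setGeneric("filterFlags", function(x) standardGeneric("filterFlags"))
#' @rdname accessors
#' @export
setGeneric("coreHits", function(x) standardGeneric("coreHits"))
#' @rdname accessors
#' @export
setGeneric("repeatPair", function(x) standardGeneric("repeatPair"))
#' @rdname accessors
#' @export
setGeneric("subfamilies", function(x) standardGeneric("subfamilies"))
#' @rdname accessors
#' @export
setGeneric("identityMatrix", function(x) standardGeneric("identityMatrix"))
#' @rdname accessors
#' @export
setGeneric("hitchhikerPct", function(x, full = FALSE) standardGeneric("hitchhikerPct"))

setMethod("genomeId", "AnnotatedGenome", function(x) x@genomeId)
setMethod("contigs", "AnnotatedGenome", function(x) x@contigs)
setMethod("features", "AnnotatedGenome", function(x) x@features)
setMethod("genomeId", "PicmiCandidate", function(x) x@genomeId)
setMethod("coreHits", "PicmiCandidate", function(x) x@coreHits)
setMethod("filterFlags", "PicmiCandidate", function(x) x@filterFlags)
setMethod("elementSpan", "PicmiCandidate", function(x) x@span)
setMethod("elementSeq", "PicmiElement", function(x) x@elementSeq)
setMethod("elementSpan", "PicmiElement", function(x) c(x@elementStart, x@elementEnd))
setMethod("features", "PicmiElement", function(x) x@features)
setMethod("repeatPair", "PicmiElement", function(x) x@repeatPair)
setMethod("coreHits", "PicmiElement", function(x) x@candidate@coreHits)
setMethod("filterFlags", "PicmiElement", function(x) x@candidate@filterFlags)
setMethod("subfamilies", "SubfamilyAssignment", function(x) x@assignment)
setMethod("identityMatrix", "SubfamilyAssignment", function(x) x@identity)
setMethod("hitchhikerPct", "PackagingEstimate",
          function(x, full = FALSE) if (full) x@pctFull else x@pctPrinted)

setMethod("show", "AnnotatedGenome", function(object) {
  cat("AnnotatedGenome", object@genomeId, "\n")
  cat(" ", length(object@contigs), "contig(s),",
      sum(Biostrings::width(object@contigs)), "bp;",
      length(object@features), "feature(s)\n")
})

setMethod("show", "DetectionModel", function(object) {
  cat("PICMI DetectionModel\n")
  cat("  roles: int(", paste(object@integraseDomains, collapse = ","),
      ") alpA(", paste(object@alpaDomains, collapse = ","),
      ") prim(", paste(object@primaseDomains, collapse = ","),
      ") fis(", paste(object@fisDomains, collapse = ","), ") [",
      object@fisPolicy, "]\n", sep = "")
  cat("  maxGeneGap:", object@maxGeneGap,
      " maxElementLen:", object@maxElementLen,
      " minRepeatLen:", object@minRepeatLen, "\n")
})

setMethod("show", "PicmiCandidate", function(object) {
  roles <- GenomicRanges::mcols(object@coreHits)$role
  cat("PicmiCandidate", object@genomeId, "@", object@contigId, ":",
      object@span[1], "-", object@span[2], "\n")
  cat("  roles:", paste(sort(roles), collapse = ","),
      if (length(object@filterFlags))
        paste0(" flags:", paste(object@filterFlags, collapse = ",")) else
        " (retained)", "\n")
})

setMethod("show", "PicmiElement", function(object) {
  cat("PicmiElement", object@candidate@genomeId, "@",
      object@candidate@contigId, ":", object@elementStart, "-",
      object@elementEnd, "(", object@orientation, ")\n")
  cat(" ", nchar(object@elementSeq), "bp;",
      if (is.null(object@repeatPair)) "no direct repeat (fallback boundary)"
      else paste0(object@repeatPair@length, " bp direct repeats"),
      ";", length(object@features), "gene(s)\n")
})

setMethod("show", "PackagingEstimate", function(object) {
  cat("PackagingEstimate\n")
  cat("  normalized depth helper:", round(object@normHelper, 2),
      " satellite:", round(object@normSatellite, 2), "reads/bp\n")
  cat("  particle equivalents:", round(object@particleEquiv, 2),
      " hitchhiker:", object@pctPrinted, "% (printed),",
      sprintf("%.2f%%", object@pctFull), "(full)\n")
})

setMethod("show", "SubfamilyAssignment", function(object) {
  cat("SubfamilyAssignment:", length(object@assignment), "element(s),",
      length(unique(object@assignment)), "subfamilies at identity >=",
      object@threshold, paste0("(", object@linkage, " linkage)"), "\n")
})

setMethod("show", "IntNeighborCall", function(object) {
  cat("IntNeighborCall:", object@category,
      if (object@category == "iolg")
        paste0("overlap ", object@overlapNt, " nt (", object@overlapMotif, ")")
      else "", "\n")
})
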