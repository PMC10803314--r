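#' @import methods
#' @importFrom Biostrings DNAStringSet DNAString width
#' @importFrom GenomicRanges GRanges seqnames start end strand mcols
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors DataFrame
NULL

#' AnnotatedGenome: contigs plus ordered, labeled gene features
#'
#' The substrate of PICMI detection: a set of contig sequences together with
#' gene features carrying protein-domain labels (e.g. Pfam accessions assigned
#' by an upstream annotator). Features are held as a \code{GRanges} (1-based,
#' inclusive, the Bioconductor convention) sorted by contig then start, with
#' metadata columns \code{gene_id}, \code{product}, \code{domains}
#' (CharacterList) and \code{protein} (amino-acid sequence or \code{NA}).
#'
#' @slot genomeId single genome identifier
#' @slot contigs \code{DNAStringSet} of contig sequences (named, unique ids)
#' @slot features \code{GRanges} of gene features
#' @export
setClass("AnnotatedGenome",
  representation(genomeId = "character", contigs = "DNAStringSet",
                 features = "GRanges"))

setValidity("AnnotatedGenome", function(object) {
  msg <- character()
  cn <- names(object@contigs)
  if (length(object@genomeId) != 1L || !nzchar(object@genomeId))
    msg <- c(msg, "genomeId must be a single non-empty string")
  if (is.null(cn) || anyDuplicated(cn) || any(!nzchar(cn)))
    msg <- c(msg, "contig ids must be non-empty and unique")
  f <- object@features
  if (length(f)) {
    fc <- as.character(GenomicRanges::seqnames(f))
    bad <- setdiff(unique(fc), cn)
    if (length(bad))
      msg <- c(msg, paste0("feature references unknown contig ", bad[1]))
    else {
      lens <- setNames(Biostrings::width(object@contigs), cn)
      if (any(GenomicRanges::end(f) > lens[fc]) || any(GenomicRanges::start(f) < 1))
        msg <- c(msg, "feature outside contig bounds")
    }
    if (!all(as.character(GenomicRanges::strand(f)) %in% c("+", "-")))
      msg <- c(msg, "feature strand must be + or -")
    gid <- GenomicRanges::mcols(f)$gene_id
    if (is.null(gid) || anyDuplicated(gid))
      msg <- c(msg, "features need unique gene_id metadata")
    o <- order(match(fc, cn), GenomicRanges::start(f))
    if (!identical(o, seq_along(f)))
      msg <- c(msg, "features must be sorted by (contig, start)")
  }
  if (length(msg)) msg else TRUE
})

#' DetectionModel: the PICMI co-localization rule set
#'
#' Domain vocabularies for the four marker roles, the fis policy, the
#' co-localization gap, the size cap, the hallmark labels of other satellite
#' families used for exclusion, and repeat-search / extraction tuning.
#'
#' @slot integraseDomains,alpaDomains,primaseDomains,fisDomains Pfam-style
#'   domain accessions per role (version suffixes are ignored when matching)
#' @slot fisPolicy \code{"mandatory"} (default) or \code{"optional"}
#' @slot maxGeneGap max number of intervening genes between consecutive core
#'   components of one locus
#' @slot maxElementLen hard cap on element span (bp)
#' @slot otherFamilyHallmarks product labels marking PICI/cf-PICI/P4/PLE loci
#' @slot minRepeatLen minimum exact direct-repeat length (bp)
#' @slot fallbackMargin bp added past the integrase end when no repeat is found
#' @slot minAnchorIdentity minimum global protein identity of the anchor gene
#'   to the fis reference
#' @export
setClass("DetectionModel",
  representation(integraseDomains = "character", alpaDomains = "character",
                 primaseDomains = "character", fisDomains = "character",
                 fisPolicy = "character", maxGeneGap = "integer",
                 maxElementLen = "integer", otherFamilyHallmarks = "character",
                 minRepeatLen = "integer", fallbackMargin = "integer",
                 minAnchorIdentity = "numeric"))

setValidity("DetectionModel", function(object) {
  msg <- character()
  for (s in c("integraseDomains", "alpaDomains", "primaseDomains", "fisDomains"))
    if (!length(slot(object, s))) msg <- c(msg, paste(s, "must be non-empty"))
  if (!object@fisPolicy %in% c("mandatory", "optional"))
    msg <- c(msg, "fisPolicy must be 'mandatory' or 'optional'")
  if (object@maxGeneGap < 0L) msg <- c(msg, "maxGeneGap must be >= 0")
  if (object@maxElementLen <= 0L) msg <- c(msg, "maxElementLen must be > 0")
  if (object@minRepeatLen < 8L) msg <- c(msg, "minRepeatLen must be >= 8")
  if (length(msg)) msg else TRUE
})

#' PicmiCandidate: a co-localized marker locus before filtering
#'
#' @slot genomeId,contigId locus address (contigId is the contig of the
#'   integrase hit; individual hits record their own contig)
#' @slot coreHits \code{GRanges} of the role-assigned genes, metadata column
#'   \code{role} in int/alpA/prim/fis
#' @slot span start/end (bp, 1-based inclusive) covering all core hits
#' @slot interveningIds gene_ids lying inside the span without a role
#' @slot filterFlags subset of cross_contig / other_family / bad_fis_anchor /
#'   oversize; empty means retained
#' @export
setClass("PicmiCandidate",
  representation(genomeId = "character", contigId = "character",
                 coreHits = "GRanges", span = "integer",
                 interveningIds = "character", filterFlags = "character"))

setValidity("PicmiCandidate", function(object) {
  msg <- character()
  roles <- GenomicRanges::mcols(object@coreHits)$role
  if (!all(c("int", "alpA", "prim") %in% roles))
    msg <- c(msg, "int, alpA and prim hits are mandatory")
  if (length(object@span) != 2L || object@span[1] > object@span[2])
    msg <- c(msg, "span must be c(start, end) with start <= end")
  if (!all(object@filterFlags %in%
           c("cross_contig", "other_family", "bad_fis_anchor", "oversize")))
    msg <- c(msg, "unknown filter flag")
  if (length(msg)) msg else TRUE
})

#' DirectRepeat: an exact repeated pair flanking an integrated element
#'
#' @slot seq repeat sequence (identical at both copies)
#' @slot leftPos,rightPos 1-based start of the left and right copy on the contig
#' @slot length repeat length (bp)
#' @export
setClass("DirectRepeat",
  representation(seq = "character", leftPos = "integer", rightPos = "integer",
                 length = "integer"))

setValidity("DirectRepeat", function(object) {
  msg <- character()
  if (object@length != nchar(object@seq)) msg <- c(msg, "length != nchar(seq)")
  if (object@leftPos >= object@rightPos) msg <- c(msg, "leftPos must be < rightPos")
  if (length(msg)) msg else TRUE
})

#' PicmiElement: an extracted satellite locus
#'
#' Sequence reported in fis-forward orientation; internal features are given
#' in element coordinates (1-based on the oriented sequence).
#'
#' @slot candidate the retained \code{PicmiCandidate}
#' @slot repeatPair \code{DirectRepeat} or NULL when extraction fell back
#' @slot elementStart,elementEnd genomic span on the contig (1-based inclusive)
#' @slot orientation "fis_forward" or "fis_reverse" (strand of fis on the contig)
#' @slot elementSeq oriented element sequence
#' @slot features element-internal gene features (element coordinates)
#' @slot smallOrfs small ORFs found in non-coding stretches (element coords)
#' @export
setClass("PicmiElement",
  representation(candidate = "PicmiCandidate", repeatPair = "ANY",
                 elementStart = "integer", elementEnd = "integer",
                 orientation = "character", elementSeq = "character",
                 features = "GRanges", smallOrfs = "GRanges"))

setValidity("PicmiElement", function(object) {
  msg <- character()
  if (nchar(object@elementSeq) != object@elementEnd - object@elementStart + 1L)
    msg <- c(msg, "elementSeq length disagrees with [elementStart, elementEnd]")
  if (!object@orientation %in% c("fis_forward", "fis_reverse"))
    msg <- c(msg, "orientation must be fis_forward or fis_reverse")
  if (!is.null(object@repeatPair) && !is(object@repeatPair, "DirectRepeat"))
    msg <- c(msg, "repeatPair must be a DirectRepeat or NULL")
  if (length(msg)) msg else TRUE
})

#' PackagingCounts: per-element read counts for the hitchhiking arithmetic
#'
#' @slot readsHelper,readsSatellite,readsHybrid read counts
#' @slot lenHelper,lenSatellite element lengths (bp)
#' @slot concatemerCopies satellite copies per packaged concatemer
#' @export
setClass("PackagingCounts",
  representation(readsHelper = "numeric", readsSatellite = "numeric",
                 readsHybrid = "numeric", lenHelper = "numeric",
                 lenSatellite = "numeric", concatemerCopies = "integer"))

setValidity("PackagingCounts", function(object) {
  msg <- character()
  if (any(c(object@readsHelper, object@readsSatellite, object@readsHybrid) < 0))
    msg <- c(msg, "read counts must be >= 0")
  if (object@lenHelper <= 0 || object@lenSatellite <= 0)
    msg <- c(msg, "lengths must be > 0")
  if (object@concatemerCopies < 1L) msg <- c(msg, "concatemerCopies must be >= 1")
  if (length(msg)) msg else TRUE
})

#' PackagingEstimate: coverage-normalized hitchhiker quantification
#'
#' @slot normHelper,normSatellite reads per bp for helper and satellite
#' @slot particleEquiv normSatellite / concatemerCopies (particle equivalents)
#' @slot pctPrinted integer percentage following the two-decimal printed
#'   convention (intermediates rounded to 2 decimals, result truncated)
#' @slot pctFull full-precision percentage, 100 * particleEquiv / normHelper
#' @export
setClass("PackagingEstimate",
  representation(normHelper = "numeric", normSatellite = "numeric",
                 particleEquiv = "numeric", pctPrinted = "integer",
                 pctFull = "numeric"))

setValidity("PackagingEstimate", function(object) {
  msg <- character()
  if (object@particleEquiv > object@normSatellite + 1e-12)
    msg <- c(msg, "particleEquiv must be <= normSatellite")
  if (object@pctPrinted < 0L || object@pctPrinted > 100L)
    msg <- c(msg, "pctPrinted must lie in [0, 100]")
  if (length(msg)) msg else TRUE
})

#' SubfamilyAssignment: partition of elements at an identity threshold
#'
#' @slot assignment named integer vector, element id -> dense subfamily id
#'   (1 = largest subfamily)
#' @slot identity symmetric pairwise identity matrix with unit diagonal
#' @slot threshold identity threshold used
#' @slot linkage "single" or "complete"
#' @export
setClass("SubfamilyAssignment",
  representation(assignment = "integer", identity = "matrix",
                 threshold = "numeric", linkage = "character"))

setValidity("SubfamilyAssignment", function(object) {
  msg <- character()
  m <- object@identity
  if (nrow(m) != ncol(m) || max(abs(m - t(m))) > 1e-9)
    msg <- c(msg, "identity matrix must be symmetric")
  if (any(abs(diag(m) - 1) > 1e-9)) msg <- c(msg, "identity diagonal must be 1")
  if (length(object@assignment) != nrow(m))
    msg <- c(msg, "assignment length must match matrix")
  if (length(msg)) msg else TRUE
})

#' IntNeighborCall: typing of the gene between int and alpA
#'
#' @slot category "iolg" (overlaps int), "icg" (present, non-overlapping) or
#'   "absent"
#' @slot overlapNt size of the coordinate intersection with int (0 unless iolg)
#' @slot overlapMotif overlapping nucleotides, 5'->3' on the fis-forward strand
#' @export
setClass("IntNeighborCall",
  representation(category = "character", overlapNt = "integer",
                 overlapMotif = "character"))

setValidity("IntNeighborCall", function(object) {
  msg <- character()
  if (!object@category %in% c("iolg", "icg", "absent"))
    msg <- c(msg, "category must be iolg, icg or absent")
  if (object@category == "iolg" && object@overlapNt < 1L)
    msg <- c(msg, "iolg requires overlapNt >= 1")
  if (object@category != "iolg" &&
      (object@overlapNt != 0L || nzchar(object@overlapMotif)))
    msg <- c(msg, "non-iolg calls must have overlapNt 0 and empty motif")
  if (length(msg)) msg else TRUE
})
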