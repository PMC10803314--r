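#' @include AllClasses.R AllGenerics.R
NULL

#' Construct PackagingCounts
#'
#' @param readsHelper,readsSatellite,readsHybrid read counts
#' @param lenHelper,lenSatellite genome / element lengths (bp)
#' @param concatemerCopies satellite copies per packaged concatemer
#' @return \code{PackagingCounts}
#' @export
packagingCounts <- function(readsHelper, readsSatellite, lenHelper,
                            lenSatellite, concatemerCopies = 8L,
                            readsHybrid = 0L) {
  new("PackagingCounts", readsHelper = as.numeric(readsHelper),
      readsSatellite = as.numeric(readsSatellite),
      readsHybrid = as.numeric(readsHybrid),
      lenHelper = as.numeric(lenHelper), lenSatellite = as.numeric(lenSatellite),
      concatemerCopies = as.integer(concatemerCopies))
}

#' Coverage-normalized hitchhiker fraction
#'
#' Normalizes read counts on element size (reads/bp), converts the satellite
#' depth to particle equivalents by dividing by the concatemer copy number,
#' and expresses satellite-filled particles as a percentage of helper
#' particles. Two values are reported: the printed-convention percentage
#' (intermediates rounded to two decimals, result truncated to an integer,
#' reproducing 634,740/47,851 = 13.26, 108,219/6110 = 17.71, 17.71/8 = 2.21,
#' 2.21/13.26*100 -> 16) and the full-precision percentage.
#'
#' @param counts \code{PackagingCounts}
#' @return \code{PackagingEstimate}
#' @examples
#' est <- hitchhikerFraction(packagingCounts(634740, 108219, 47851, 6110, 8))
#' hitchhikerPct(est)               # 16
#' hitchhikerPct(est, full = TRUE)  # 16.67...
#' @export
hitchhikerFraction <- function(counts) {
  stopifnot(is(counts, "PackagingCounts"))
  if (counts@lenHelper <= 0 || counts@lenSatellite <= 0)
    stop("element lengths must be > 0")
  nh <- counts@readsHelper / counts@lenHelper
  ns <- counts@readsSatellite / counts@lenSatellite
  pe <- ns / counts@concatemerCopies
  pctFull <- if (nh > 0) 100 * pe / nh else 0
  pctPrinted <- if (round(nh, 2) > 0)
    as.integer(trunc(100 * round(pe, 2) / round(nh, 2))) else 0L
  new("PackagingEstimate", normHelper = nh, normSatellite = ns,
      particleEquiv = pe, pctPrinted = pctPrinted, pctFull = pctFull)
}

#' Headful concatemer copy number
#'
#' Number of satellite copies k >= 1 whose tandem concatemer best fills a
#' helper-sized capsid: minimizes |k * lenSatellite - lenHelper|, ties going
#' to the larger k (headful overshoot).
#'
#' @param lenHelper helper genome length (bp)
#' @param lenSatellite satellite element length (bp), must not exceed
#'   \code{lenHelper}
#' @return integer copy number
#' @examples
#' headfulCopyNumber(47851, 6110)  # 8
#' @export
headfulCopyNumber <- function(lenHelper, lenSatellite) {
  if (lenHelper <= 0 || lenSatellite <= 0) stop("lengths must be > 0")
  if (lenSatellite > lenHelper) stop("lenSatellite must be <= lenHelper")
  k <- max(1L, floor(lenHelper / lenSatellite))
  cand <- c(k, k + 1L)
  dev <- abs(cand * lenSatellite - lenHelper)
  as.integer(cand[which(dev == min(dev))[length(which(dev == min(dev)))]])
}

## best local alignment of a read (either strand) against a reference
bestLocalPlacement <- function(read, ref, minIdentity = 0) {
  score <- function(r) Biostrings::pairwiseAlignment(
    Biostrings::DNAString(r), ref, type = "local",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(2, -3, baseOnly = FALSE),
    gapOpening = 5, gapExtension = 2)
  alnF <- score(read)
  alnR <- score(revcomp(read))
  rc <- Biostrings::score(alnR) > Biostrings::score(alnF)
  aln <- if (rc) alnR else alnF
  sv <- Biostrings::subject(aln)
  list(aln = aln, rc = rc,
       start = Biostrings::start(sv), end = Biostrings::end(sv),
       width = length(strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]),
       matched = sum({
         p <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
         s <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
         p == s & p != "-"
       }),
       identity = alignmentIdentity(aln))
}

#' Classify reads as helper, satellite, hybrid or unassigned
#'
#' Each read is locally aligned (both strands) against the helper and the
#' satellite reference. A reference "anchors" the read when at least
#' \code{minAnchor} of its bases align with identity >= \code{minIdentity}.
#' Reads anchored by both references are hybrid; by one, that element; by
#' neither, unassigned.
#'
#' @param reads character vector / \code{DNAStringSet} of read sequences
#' @param helperRef,satelliteRef reference sequences (satellite reference may
#'   be a concatemer)
#' @param minAnchor minimum aligned bases per reference (default 50)
#' @param minIdentity identity floor of the local alignment (default 0.8)
#' @param concatemerCopies copy number stored in the returned counts
#' @return \code{PackagingCounts}; the per-read calls are attached as
#'   attribute \code{"calls"}
#' @export
classifyReads <- function(reads, helperRef, satelliteRef, minAnchor = 50L,
                          minIdentity = 0.8, concatemerCopies = 8L) {
  helperRef <- Biostrings::DNAString(toupper(as.character(helperRef)))
  satelliteRef <- Biostrings::DNAString(toupper(as.character(satelliteRef)))
  if (!length(helperRef) || !length(satelliteRef))
    stop("references must be non-empty")
  reads <- as.character(reads)
  calls <- vapply(reads, function(r) {
    h <- bestLocalPlacement(r, helperRef)
    s <- bestLocalPlacement(r, satelliteRef)
    hOk <- h$matched >= minAnchor && h$identity >= minIdentity
    sOk <- s$matched >= minAnchor && s$identity >= minIdentity
    if (hOk && sOk) "hybrid" else if (hOk) "helper" else if (sOk) "satellite"
    else "unassigned"
  }, character(1), USE.NAMES = FALSE)
  counts <- packagingCounts(
    readsHelper = sum(calls == "helper"),
    readsSatellite = sum(calls == "satellite"),
    lenHelper = length(helperRef), lenSatellite = length(satelliteRef),
    concatemerCopies = concatemerCopies,
    readsHybrid = sum(calls == "hybrid"))
  attr(counts, "calls") <- calls
  counts
}

#' Map long reads onto an artificial tandem concatemer reference
#'
#' Aligns each read (both strands, local alignment) to \code{nUnits} tandem
#' copies of the satellite unit and reports its placement and phase:
#' \code{phase_start = (start - 1) mod unit length} (0-based within the
#' unit). Reads whose alignment identity falls below \code{minIdentity}, or
#' whose alignment covers less than \code{minReadCoverage} of the read, are
#' dropped with a message.
#'
#' @param longReads character vector / \code{DNAStringSet} of reads
#' @param unitSeq satellite unit sequence
#' @param nUnits tandem copies in the artificial reference (default 13)
#' @param minIdentity identity floor (default 0.70)
#' @param minReadCoverage minimum fraction of the read that must align
#'   (default 0.5)
#' @return \code{data.frame} with read_id, start_on_ref, end_on_ref,
#'   phase_start, unit_len, n_units, strand, identity
#' @export
mapConcatemerReads <- function(longReads, unitSeq, nUnits = 13L,
                               minIdentity = 0.70, minReadCoverage = 0.5) {
  unitSeq <- toupper(as.character(unitSeq))
  if (!nzchar(unitSeq)) stop("unitSeq must be non-empty")
  reads <- as.character(longReads)
  unitLen <- nchar(unitSeq)
  refLen <- unitLen * nUnits
  tooLong <- nchar(reads) > refLen
  if (any(tooLong))
    stop("read longer than the ", nUnits, "-copy reference; increase nUnits ",
         "to at least ", ceiling(max(nchar(reads)) / unitLen))
  ref <- Biostrings::DNAString(strrep(unitSeq, nUnits))
  ids <- names(reads)
  if (is.null(ids)) ids <- sprintf("read_%04d", seq_along(reads))
  rows <- lapply(seq_along(reads), function(i) {
    pl <- bestLocalPlacement(reads[i], ref)
    if (pl$identity < minIdentity ||
        pl$matched / nchar(reads[i]) < minReadCoverage) return(NULL)
    start0 <- pl$start - 1L
    data.frame(read_id = ids[i], start_on_ref = start0,
               end_on_ref = pl$end, phase_start = start0 %% unitLen,
               unit_len = unitLen, n_units = as.integer(nUnits),
               strand = if (pl$rc) "-" else "+", identity = pl$identity,
               stringsAsFactors = FALSE)
  })
  dropped <- sum(vapply(rows, is.null, logical(1)))
  if (dropped)
    message(dropped, " read(s) dropped below identity floor ", minIdentity)
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out))
    out <- data.frame(read_id = character(), start_on_ref = integer(),
                      end_on_ref = integer(), phase_start = integer(),
                      unit_len = integer(), n_units = integer(),
                      strand = character(), identity = numeric(),
                      stringsAsFactors = FALSE)
  out
}

#' Chi-square test for random concatemer extremities
#'
#' Headful (pac-like) packaging from a concatemer produces molecule
#' extremities at effectively random positions on the unit, while cos-like
#' packaging produces fixed ends. The test bins the read start phases into
#' equal-width bins of the unit and performs a chi-square goodness-of-fit
#' test against the uniform distribution.
#'
#' @param reads data.frame from \code{\link{mapConcatemerReads}} (columns
#'   \code{phase_start}, \code{unit_len}) or a numeric vector of phases in
#'   \code{[0, unitLen)}
#' @param bins number of equal-width phase bins (default 20)
#' @param alpha significance level for the verdict (default 0.05)
#' @param unitLen unit length; required when \code{reads} is a bare vector
#' @return list with \code{statistic}, \code{p_value}, \code{verdict}
#'   ("random-extremities (pac-like)" or "fixed-extremities (cos-like)"),
#'   \code{bins}, \code{n}
#' @export
extremityRandomnessTest <- function(reads, bins = 20L, alpha = 0.05,
                                    unitLen = NULL) {
  if (is.data.frame(reads)) {
    phases <- reads$phase_start
    unitLen <- reads$unit_len[1]
  } else phases <- as.numeric(reads)
  if (is.null(unitLen)) stop("unitLen required for bare phase vectors")
  if (length(phases) < 20L)
    stop("fewer than 20 reads: the extremity test is underpowered")
  if (any(phases < 0 | phases >= unitLen)) stop("phases must lie in [0, unitLen)")
  cut_ <- pmin(floor(phases / unitLen * bins) + 1L, bins)
  obs <- tabulate(cut_, nbins = bins)
  ht <- suppressWarnings(stats::chisq.test(obs, p = rep(1 / bins, bins)))
  p <- as.numeric(ht$p.value)
  list(statistic = as.numeric(ht$statistic), p_value = p,
       verdict = if (p >= alpha) "random-extremities (pac-like)" else
         "fixed-extremities (cos-like)",
       bins = as.integer(bins), n = length(phases))
}

#' Estimate the planted hitchhiker fraction from packaging counts
#'
#' Inverts the read-sampling model: with a fraction f of particles carrying a
#' satellite concatemer of \code{copies * lenSatellite} bp and reads sampled
#' uniformly per base of packaged DNA, the satellite read share is
#' f Lc / (f Lc + (1 - f) Lh). Returns the point estimate and its delta-method
#' standard error.
#'
#' @param counts \code{PackagingCounts}
#' @return list with \code{fraction} and \code{se}
#' @export
estimateHitchhikerFraction <- function(counts) {
  stopifnot(is(counts, "PackagingCounts"))
  n <- counts@readsHelper + counts@readsSatellite
  if (n == 0) stop("no classified reads")
  Lc <- counts@concatemerCopies * counts@lenSatellite
  Lh <- counts@lenHelper
  ps <- counts@readsSatellite / n
  f <- function(p) (p * Lh / Lc) / (1 - p + p * Lh / Lc)
  est <- f(ps)
  h <- 1e-6
  grad <- (f(min(ps + h, 1)) - f(max(ps - h, 0))) / (min(ps + h, 1) - max(ps - h, 0))
  se <- abs(grad) * sqrt(ps * (1 - ps) / n)
  list(fraction = est, se = se)
}
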