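#' @include AllClasses.R AllGenerics.R
NULL

#' Global pairwise nucleotide identity
#'
#' End-to-end (Needleman-Wunsch) alignment with affine gaps (defaults match
#' +1 / mismatch -1 / gap open 4 / gap extend 1); identity is matches divided
#' by alignment columns, gap columns counted in the denominator. Symmetric in
#' its arguments.
#'
#' @param a,b DNA sequences (character or \code{DNAString}), non-empty
#' @param match,mismatch,gapOpening,gapExtension alignment scoring
#' @return identity fraction in [0, 1]
#' @examples
#' pairwiseIdentity("ACGTACGT", "ACGTACGT")  # 1
#' @export
pairwiseIdentity <- function(a, b, match = 1, mismatch = -1,
                             gapOpening = 4, gapExtension = 1) {
  a <- toupper(as.character(a)); b <- toupper(as.character(b))
  if (!nzchar(a) || !nzchar(b)) stop("empty sequence")
  if (a == b) return(1)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b), type = "global",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = match, mismatch = mismatch, baseOnly = FALSE),
    gapOpening = gapOpening, gapExtension = gapExtension)
  alignmentIdentity(aln)
}

#' Cluster elements into subfamilies by pairwise identity
#'
#' Builds the full pairwise identity matrix over the element sequences and
#' partitions at the identity threshold: single linkage takes the connected
#' components of the graph with edges where identity passes the threshold
#' (default >= 0.90); complete linkage agglomerates on 1 - identity and cuts
#' the tree at the threshold. Subfamily ids are dense integers ordered by
#' decreasing cluster size, ties by first element.
#'
#' @param elements named character vector (or \code{DNAStringSet}) of element
#'   sequences; names become element ids
#' @param identityThreshold identity cutoff (default 0.90)
#' @param linkage "single" (graph components) or "complete"
#' @param strict when TRUE the cutoff is exclusive (> threshold) rather than
#'   inclusive (>= threshold)
#' @param identity optional precomputed identity matrix (skips alignment)
#' @return \code{SubfamilyAssignment}
#' @export
clusterSubfamilies <- function(elements, identityThreshold = 0.90,
                               linkage = c("single", "complete"),
                               strict = FALSE, identity = NULL) {
  linkage <- match.arg(linkage)
  if (identityThreshold <= 0 || identityThreshold > 1)
    stop("identityThreshold must lie in (0, 1]")
  ids <- names(elements)
  seqs <- as.character(elements)
  n <- length(seqs)
  if (n < 1L) stop("need at least one element")
  if (is.null(ids)) ids <- sprintf("element_%02d", seq_len(n))
  if (is.null(identity)) {
    identity <- diag(1, n)
    if (n > 1L)
      for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
        identity[i, j] <- identity[j, i] <- pairwiseIdentity(seqs[i], seqs[j])
      }
  }
  dimnames(identity) <- list(ids, ids)
  pass <- if (strict) identity > identityThreshold else
    identity >= identityThreshold
  if (linkage == "single" || n == 1L) {
    edges <- which(pass & upper.tri(pass), arr.ind = TRUE)
    edgeList <- lapply(seq_len(nrow(edges)), function(k) as.integer(edges[k, ]))
    comp <- componentsFromEdges(n, edgeList)
  } else {
    hc <- stats::hclust(stats::as.dist(1 - identity), method = "complete")
    h <- 1 - identityThreshold
    comp <- stats::cutree(hc, h = if (strict) h - 1e-12 else h + 1e-12)
  }
  ## dense ids by descending cluster size, then first element
  sizes <- table(comp)
  ord <- order(-as.integer(sizes), vapply(names(sizes), function(g)
    min(which(comp == as.integer(g))), integer(1)))
  relabel <- setNames(seq_along(ord), names(sizes)[ord])
  assignment <- as.integer(relabel[as.character(comp)])
  names(assignment) <- ids
  new("SubfamilyAssignment", assignment = assignment, identity = identity,
      threshold = identityThreshold, linkage = linkage)
}

## local protein alignment summary for RBH
localHit <- function(a, b) {
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "local",
    substitutionMatrix = "BLOSUM62", gapOpening = 11, gapExtension = 1)
  p <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  s <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  ncol <- length(p)
  list(score = Biostrings::score(aln),
       identity = if (ncol) sum(p == s & p != "-") / ncol else 0,
       covQ = sum(p != "-") / nchar(a),
       covT = sum(s != "-") / nchar(b))
}

#' Reciprocal-best-hit gene families across element proteomes
#'
#' All-vs-all local protein alignment (BLOSUM62, affine gaps); a hit is valid
#' when identity >= \code{minIdentity} and the aligned region covers at least
#' \code{minCoverage} of both query and target. The best valid hit per
#' (query, target proteome) is selected by score, ties broken by identity then
#' lexicographic protein id; reciprocal best hits form edges and families are
#' the connected components. Proteins without a reciprocal partner are
#' singleton families. Output is invariant to the input order of proteomes and
#' proteins.
#'
#' @param proteomes named list: element id -> named character vector of
#'   protein sequences (names are protein ids, unique across the input)
#' @param minIdentity identity floor (default 0.20)
#' @param minCoverage coverage floor on query and target (default 0.50)
#' @return named integer vector protein id -> family id (dense, 1 = largest
#'   family, ties by first protein id alphabetically)
#' @export
rbhGeneFamilies <- function(proteomes, minIdentity = 0.20, minCoverage = 0.50) {
  if (minIdentity <= 0 || minIdentity > 1 || minCoverage <= 0 || minCoverage > 1)
    stop("thresholds must lie in (0, 1]")
  proteomes <- proteomes[order(names(proteomes))]
  proteomes <- lapply(proteomes, function(p) p[order(names(p))])
  prot <- unlist(unname(proteomes))
  pid <- unlist(lapply(proteomes, names))
  names(prot) <- pid
  if (anyDuplicated(pid)) stop("protein ids must be unique across proteomes")
  member <- rep(names(proteomes), lengths(proteomes))
  names(member) <- pid
  n <- length(prot)
  if (length(proteomes) < 2L || n < 2L)
    return(setNames(seq_len(n), pid))
  ## cache of valid hits: query id -> target id -> (score, identity)
  best <- list()  # best[[q]][[targetProteome]] = target id
  hitKey <- function(q, t) paste(q, t, sep = "\r")
  scores <- new.env(parent = emptyenv())
  for (qi in seq_len(n)) for (ti in seq_len(n)) {
    if (member[qi] == member[ti]) next
    h <- localHit(prot[qi], prot[ti])
    if (h$identity >= minIdentity && h$covQ >= minCoverage &&
        h$covT >= minCoverage)
      assign(hitKey(pid[qi], pid[ti]), h, envir = scores)
  }
  bestHit <- function(q, targetProteome) {
    tids <- sort(names(proteomes[[targetProteome]]))
    cand <- NULL
    for (t in tids) {
      h <- mget(hitKey(q, t), envir = scores, ifnotfound = list(NULL))[[1]]
      if (is.null(h)) next
      if (is.null(cand) || h$score > cand$h$score ||
          (h$score == cand$h$score && (h$identity > cand$h$identity ||
            (h$identity == cand$h$identity && t < cand$t))))
        cand <- list(t = t, h = h)
    }
    if (is.null(cand)) NA_character_ else cand$t
  }
  edges <- list()
  for (q in pid) for (tp in names(proteomes)) {
    if (member[q] == tp) next
    t <- bestHit(q, tp)
    if (is.na(t)) next
    if (identical(bestHit(t, member[q]), q) && q < t)
      edges[[length(edges) + 1L]] <- match(c(q, t), pid)
  }
  comp <- componentsFromEdges(n, edges)
  sizes <- table(comp)
  ord <- order(-as.integer(sizes), vapply(names(sizes), function(g)
    min(pid[comp == as.integer(g)]), character(1)))
  relabel <- setNames(seq_along(ord), names(sizes)[ord])
  setNames(as.integer(relabel[as.character(comp)]), pid)
}

#' Type the gene neighboring the integrase
#'
#' Examines the gene lying between the integrase and alpA on an element:
#' \code{iolg} when its coordinates overlap the integrase (overlap of 1, 4 or
#' 13 nt in known elements, the shared tetranucleotide most often ATGA),
#' \code{icg} when a gene is present but does not overlap, \code{absent} when
#' no gene lies between int and alpA. The overlap motif is reported 5'->3' on
#' the element's fis-forward strand.
#'
#' @param element \code{PicmiElement} whose features carry \code{role}
#'   annotations for int and alpA
#' @return \code{IntNeighborCall}
#' @export
classifyIntNeighbor <- function(element) {
  f <- element@features
  roles <- GenomicRanges::mcols(f)$role
  if (is.null(roles) || !"int" %in% roles || !"alpA" %in% roles)
    stop("element features must include int and alpA roles")
  int <- f[which(roles == "int")[1]]
  alpA <- f[which(roles == "alpA")[1]]
  lo <- min(GenomicRanges::end(int), GenomicRanges::end(alpA))
  hi <- max(GenomicRanges::start(int), GenomicRanges::start(alpA))
  other <- f[is.na(roles) | !(roles %in% c("int", "alpA"))]
  ## gene "between" int and alpA: midpoint inside the inter-role interval
  mids <- (GenomicRanges::start(other) + GenomicRanges::end(other)) / 2
  between <- other[mids > min(GenomicRanges::start(int), GenomicRanges::start(alpA)) &
                   mids < max(GenomicRanges::end(int), GenomicRanges::end(alpA))]
  if (!length(between))
    return(new("IntNeighborCall", category = "absent", overlapNt = 0L,
               overlapMotif = ""))
  ## nearest to int
  dInt <- pmin(abs(GenomicRanges::start(between) - GenomicRanges::end(int)),
               abs(GenomicRanges::end(between) - GenomicRanges::start(int)))
  g <- between[which.min(dInt)]
  ovS <- max(GenomicRanges::start(g), GenomicRanges::start(int))
  ovE <- min(GenomicRanges::end(g), GenomicRanges::end(int))
  ov <- max(0L, ovE - ovS + 1L)
  if (ov >= 1L) {
    motif <- substring(elementSeq(element), ovS, ovE)
    new("IntNeighborCall", category = "iolg", overlapNt = as.integer(ov),
        overlapMotif = motif)
  } else {
    new("IntNeighborCall", category = "icg", overlapNt = 0L,
        overlapMotif = "")
  }
}

#' Core / accessory gene-family table
#'
#' Summarizes gene families across elements: per family, the number of
#' elements carrying it and a core flag (present in every element); per
#' element, the ordered family string for synteny display.
#'
#' @param proteomes named list element id -> named protein vector (as passed to
#'   \code{\link{rbhGeneFamilies}})
#' @param families named integer vector from \code{\link{rbhGeneFamilies}}
#' @return list with data.frames \code{families} (family_id, n_elements,
#'   core, accessory) and \code{synteny} (element_id, family_string)
#' @export
coreAccessoryTable <- function(proteomes, families) {
  member <- rep(names(proteomes), lengths(proteomes))
  names(member) <- unlist(lapply(proteomes, names))
  byFam <- split(names(families), families)
  nEl <- length(proteomes)
  fam <- data.frame(
    family_id = as.integer(names(byFam)),
    n_proteins = lengths(byFam),
    n_elements = vapply(byFam, function(p) length(unique(member[p])), integer(1)),
    stringsAsFactors = FALSE)
  fam$core <- fam$n_elements == nEl
  fam$accessory <- !fam$core
  synteny <- data.frame(
    element_id = names(proteomes),
    family_string = vapply(names(proteomes), function(el) {
      p <- names(proteomes[[el]])
      paste(families[p], collapse = "-")
    }, character(1)),
    stringsAsFactors = FALSE)
  rownames(fam) <- rownames(synteny) <- NULL
  list(families = fam, synteny = synteny)
}
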