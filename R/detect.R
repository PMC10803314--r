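#' @include AllClasses.R AllGenerics.R genome-io.R
NULL

#' Construct a PICMI detection model
#'
#' Defaults encode the minimalist-island rule set: four marker roles defined by
#' protein-domain accessions — integrase (PF00589, PF00239, PF07508), AlpA
#' (PF05930, PF12728), primase (DUF3987/PF13148, DUF5906/PF19263) and the Fis
#' regulator (PF02954) — required to co-localize with at most \code{maxGeneGap}
#' intervening genes between consecutive markers. \code{fisPolicy} controls
#' whether fis is a mandatory marker (default) or an optional anchor label.
#' Domain accessions are matched case-insensitively with version suffixes
#' stripped.
#'
#' @param integraseDomains,alpaDomains,primaseDomains,fisDomains character
#'   vectors of domain accessions per role
#' @param fisPolicy "mandatory" or "optional"
#' @param maxGeneGap max intervening genes between consecutive markers
#' @param maxElementLen bp cap on a candidate span / extracted element
#' @param otherFamilyHallmarks product labels of other satellite families
#'   (PICI, cf-PICI, P4, PLE) that exclude a locus
#' @param minRepeatLen minimum exact direct-repeat length (bp)
#' @param fallbackMargin bp past the integrase end used when no repeat is found
#' @param minAnchorIdentity minimum global protein identity of the anchor gene
#'   to the fis reference (fraction)
#' @return validated \code{DetectionModel}
#' @export
picmiModel <- function(integraseDomains = c("PF00589", "PF00239", "PF07508"),
                       alpaDomains = c("PF05930", "PF12728"),
                       primaseDomains = c("PF13148", "PF19263"),
                       fisDomains = "PF02954",
                       fisPolicy = c("mandatory", "optional"),
                       maxGeneGap = 5L, maxElementLen = 50000L,
                       otherFamilyHallmarks = c("terS", "sid", "ppi", "psu"),
                       minRepeatLen = 15L, fallbackMargin = 1000L,
                       minAnchorIdentity = 0.30) {
  new("DetectionModel",
      integraseDomains = integraseDomains, alpaDomains = alpaDomains,
      primaseDomains = primaseDomains, fisDomains = fisDomains,
      fisPolicy = match.arg(fisPolicy), maxGeneGap = as.integer(maxGeneGap),
      maxElementLen = as.integer(maxElementLen),
      otherFamilyHallmarks = otherFamilyHallmarks,
      minRepeatLen = as.integer(minRepeatLen),
      fallbackMargin = as.integer(fallbackMargin),
      minAnchorIdentity = minAnchorIdentity)
}

## role ("int"/"alpA"/"prim"/"fis"/NA) of each feature under a model
featureRoles <- function(genome, model) {
  doms <- lapply(as.list(GenomicRanges::mcols(features(genome))$domains),
                 normalizeDomainLabel)
  sets <- list(int = normalizeDomainLabel(model@integraseDomains),
               alpA = normalizeDomainLabel(model@alpaDomains),
               prim = normalizeDomainLabel(model@primaseDomains),
               fis = normalizeDomainLabel(model@fisDomains))
  vapply(doms, function(d) {
    for (r in names(sets)) if (any(d %in% sets[[r]])) return(r)
    NA_character_
  }, character(1))
}

makeCandidate <- function(genome, contigId, hits, spanFeatures) {
  inSpan <- spanFeatures$gene_id[!spanFeatures$gene_id %in%
                                   GenomicRanges::mcols(hits)$gene_id]
  sp <- range(c(GenomicRanges::start(hits), GenomicRanges::end(hits)))
  new("PicmiCandidate", genomeId = genomeId(genome), contigId = contigId,
      coreHits = hits, span = as.integer(sp),
      interveningIds = inSpan, filterFlags = character())
}

## choose one hit per role minimizing the resulting span width
bestRoleAssignment <- function(feats, roles, roleNames) {
  idxByRole <- lapply(roleNames, function(r) which(roles == r))
  names(idxByRole) <- roleNames
  combos <- expand.grid(idxByRole, KEEP.OUT.ATTRS = FALSE)
  if (nrow(combos) > 20000L) combos <- combos[seq_len(20000L), , drop = FALSE]
  widths <- apply(combos, 1, function(ix) {
    ix <- as.integer(ix)
    max(GenomicRanges::end(feats)[ix]) - min(GenomicRanges::start(feats)[ix])
  })
  as.integer(combos[which.min(widths), ])
}

#' Scan a genome for PICMI candidate loci
#'
#' Finds every maximal locus where one gene matching each mandatory marker role
#' co-occurs on one contig with at most \code{maxGeneGap} intervening genes
#' between consecutive marker-bearing genes (order-agnostic, both strands).
#' Marker-bearing genes are chained; a chain containing all mandatory roles
#' becomes a candidate, with the closest-packed role assignment kept when a
#' role matches several genes. Incomplete chains at contig edges are paired
#' across contigs (draft-assembly splits); such merged candidates carry hits on
#' more than one contig and are flagged \code{cross_contig} by
#' \code{\link{filterCandidates}}.
#'
#' @param genome \code{AnnotatedGenome} with sorted features
#' @param model \code{DetectionModel}
#' @return list of \code{PicmiCandidate} (possibly empty)
#' @export
scanGenome <- function(genome, model = picmiModel()) {
  f <- features(genome)
  if (!length(f)) return(list())
  roles <- featureRoles(genome, model)
  mandatory <- c("int", "alpA", "prim",
                 if (model@fisPolicy == "mandatory") "fis")
  cands <- list()
  partial <- list()
  for (ct in names(contigs(genome))) {
    onCt <- which(as.character(GenomicRanges::seqnames(f)) == ct)
    if (!length(onCt)) next
    r <- roles[onCt]
    core <- which(!is.na(r))
    if (!length(core)) next
    breaks <- which(diff(core) - 1L > model@maxGeneGap)
    chainId <- cumsum(c(1L, seq_along(core)[-1] %in% (breaks + 1L)))
    for (ch in split(core, chainId)) {
      present <- unique(r[ch])
      featsCt <- f[onCt]
      if (all(mandatory %in% present)) {
        useRoles <- intersect(c("int", "alpA", "prim", "fis"), present)
        pick <- bestRoleAssignment(featsCt[ch], r[ch], useRoles)
        hits <- featsCt[ch][pick]
        GenomicRanges::mcols(hits)$role <- useRoles
        sp <- range(c(GenomicRanges::start(hits), GenomicRanges::end(hits)))
        spanF <- GenomicRanges::mcols(featsCt[GenomicRanges::start(featsCt) >= sp[1] &
                                              GenomicRanges::end(featsCt) <= sp[2]])
        cands[[length(cands) + 1L]] <- makeCandidate(genome, ct, hits, spanF)
      } else if (length(present)) {
        nearEdge <- ch[1] <= model@maxGeneGap + 1L ||
          ch[length(ch)] >= length(onCt) - model@maxGeneGap
        if (nearEdge)
          partial[[length(partial) + 1L]] <-
            list(contig = ct, idx = onCt[ch], roles = r[ch])
      }
    }
  }
  ## pair edge-adjacent incomplete chains across contigs
  if (length(partial) >= 2L) {
    used <- rep(FALSE, length(partial))
    for (i in seq_along(partial)) {
      if (used[i]) next
      for (j in seq_along(partial)) {
        if (j <= i || used[j]) next
        a <- partial[[i]]; b <- partial[[j]]
        if (a$contig == b$contig) next
        if (!all(mandatory %in% unique(c(a$roles, b$roles)))) next
        idx <- c(a$idx, b$idx)
        rr <- c(a$roles, b$roles)
        keep <- !duplicated(rr)
        hits <- f[idx[keep]]
        GenomicRanges::mcols(hits)$role <- rr[keep]
        intHit <- hits[GenomicRanges::mcols(hits)$role == "int"]
        ctInt <- as.character(GenomicRanges::seqnames(intHit))[1]
        onInt <- hits[as.character(GenomicRanges::seqnames(hits)) == ctInt]
        sp <- range(c(GenomicRanges::start(onInt), GenomicRanges::end(onInt)))
        cand <- new("PicmiCandidate", genomeId = genomeId(genome),
                    contigId = ctInt, coreHits = hits, span = as.integer(sp),
                    interveningIds = character(), filterFlags = character())
        cands[[length(cands) + 1L]] <- cand
        used[c(i, j)] <- TRUE
        break
      }
    }
  }
  cands
}

## protein sequence of one feature, translating from the contig if absent
featureProtein <- function(genome, feature) {
  p <- GenomicRanges::mcols(feature)$protein
  if (!is.null(p) && !is.na(p[1]) && nzchar(p[1])) return(p[1])
  ct <- as.character(GenomicRanges::seqnames(feature))[1]
  dna <- substring(as.character(contigs(genome)[[ct]]),
                   GenomicRanges::start(feature)[1],
                   GenomicRanges::end(feature)[1])
  if (as.character(GenomicRanges::strand(feature))[1] == "-") dna <- revcomp(dna)
  translateDna(substring(dna, 1, nchar(dna) - nchar(dna) %% 3))
}

#' Filter candidate loci by the exclusion rules
#'
#' Applies the exclusion filters to scanned candidates: \code{cross_contig}
#' when int/alpA/fis hits were joined from different contigs during a
#' multi-contig merge; \code{other_family} when any gene within the span
#' carries a hallmark product label of another satellite family (PICI,
#' cf-PICI, P4, PLE); \code{bad_fis_anchor} when the anchor gene's global
#' protein identity to the fis reference falls below
#' \code{minAnchorIdentity} or below its identity to any decoy anchor;
#' \code{oversize} when the span exceeds \code{maxElementLen}.
#'
#' @param cands list of \code{PicmiCandidate} from \code{\link{scanGenome}}
#' @param genome the scanned \code{AnnotatedGenome}
#' @param model \code{DetectionModel}
#' @param fisReference fis protein sequence (amino acids) used for the anchor
#'   identity check
#' @param decoyAnchors optional named character vector of decoy anchor
#'   proteins; the anchor must be closer to fis than to every decoy
#' @return list with components \code{retained} (flag-free candidates) and
#'   \code{flagged} (candidates with their \code{filterFlags} set)
#' @export
filterCandidates <- function(cands, genome, model = picmiModel(),
                             fisReference, decoyAnchors = NULL) {
  if (missing(fisReference) || !nzchar(fisReference))
    stop("fisReference protein sequence must be non-empty")
  hall <- tolower(model@otherFamilyHallmarks)
  f <- features(genome)
  out <- lapply(cands, function(cand) {
    flags <- character()
    hitCt <- unique(as.character(GenomicRanges::seqnames(cand@coreHits)))
    if (length(hitCt) > 1L) flags <- c(flags, "cross_contig")
    onCt <- f[as.character(GenomicRanges::seqnames(f)) == cand@contigId]
    inSpan <- onCt[GenomicRanges::end(onCt) >= cand@span[1] &
                   GenomicRanges::start(onCt) <= cand@span[2]]
    prod <- tolower(GenomicRanges::mcols(inSpan)$product)
    if (any(!is.na(prod) & prod %in% hall)) flags <- c(flags, "other_family")
    fisHit <- cand@coreHits[GenomicRanges::mcols(cand@coreHits)$role == "fis"]
    if (length(fisHit)) {
      anchorProt <- featureProtein(genome, fisHit[1])
      idFis <- proteinGlobalIdentity(anchorProt, fisReference)
      bad <- idFis < model@minAnchorIdentity
      if (!bad && length(decoyAnchors))
        bad <- any(vapply(decoyAnchors, function(d)
          proteinGlobalIdentity(anchorProt, d), numeric(1)) > idFis)
      if (bad) flags <- c(flags, "bad_fis_anchor")
    }
    if (diff(cand@span) + 1L > model@maxElementLen) flags <- c(flags, "oversize")
    cand@filterFlags <- flags
    cand
  })
  flagged <- vapply(out, function(x) length(x@filterFlags) > 0L, logical(1))
  list(retained = out[!flagged], flagged = out[flagged])
}

#' Find the longest exact direct-repeat pair between two regions
#'
#' Searches for the longest substring present exactly in both the anchor
#' region (near the fis 3' end) and the search region (int-distal flank).
#' Ties are broken by preferring the copy pair spanning the largest interval,
#' then the leftmost pair.
#'
#' @param contig contig sequence (\code{DNAString} or character)
#' @param anchorRegion,searchRegion integer \code{c(start, end)} (1-based
#'   inclusive) delimiting where each copy may lie
#' @param minLen minimum repeat length (bp, >= 8)
#' @return \code{DirectRepeat} or \code{NULL} when no pair reaches
#'   \code{minLen}
#' @export
findDirectRepeats <- function(contig, anchorRegion, searchRegion, minLen = 15L) {
  seqc <- toupper(as.character(contig))
  checkRegion <- function(r, nm) {
    if (r[1] > r[2]) stop("inverted ", nm, " region")
    if (r[1] < 1 || r[2] > nchar(seqc)) stop(nm, " region outside contig")
  }
  checkRegion(anchorRegion, "anchor"); checkRegion(searchRegion, "search")
  if (minLen < 8L) stop("minLen must be >= 8")
  a <- substring(seqc, anchorRegion[1], anchorRegion[2])
  b <- substring(seqc, searchRegion[1], searchRegion[2])
  kmers <- function(s, L) {
    n <- nchar(s) - L + 1L
    if (n < 1L) character() else substring(s, seq_len(n), seq_len(n) + L - 1L)
  }
  feasible <- function(L) length(intersect(kmers(a, L), kmers(b, L))) > 0L
  lo <- as.integer(minLen); hi <- min(nchar(a), nchar(b))
  if (hi < lo || !feasible(lo)) return(NULL)
  while (lo < hi) {       # invariant: feasible(lo); maximize L
    mid <- as.integer(ceiling((lo + hi) / 2))
    if (feasible(mid)) lo <- mid else hi <- mid - 1L
  }
  L <- lo
  ka <- kmers(a, L); kb <- kmers(b, L)
  common <- intersect(ka, kb)
  best <- NULL
  for (s in common) {
    posA <- which(ka == s) + anchorRegion[1] - 1L
    posB <- which(kb == s) + searchRegion[1] - 1L
    for (pa in posA) for (pb in posB) {
      left <- min(pa, pb); right <- max(pa, pb)
      if (left == right) next
      key <- c(-(right - left), left, right)   # larger interval, then leftmost
      if (is.null(best) || lexLess(key, best$key))
        best <- list(seq = s, left = left, right = right, key = key)
    }
  }
  if (is.null(best)) return(NULL)
  new("DirectRepeat", seq = best$seq, leftPos = as.integer(best$left),
      rightPos = as.integer(best$right), length = L)
}

lexLess <- function(a, b) {
  d <- which(a != b)
  if (!length(d)) FALSE else a[d[1]] < b[d[1]]
}

## anchor / search regions for the repeat hunt, oriented by the fis strand
repeatSearchRegions <- function(genome, cand, model, searchWindow = 2000L) {
  hits <- cand@coreHits
  fis <- hits[GenomicRanges::mcols(hits)$role == "fis"]
  int <- hits[GenomicRanges::mcols(hits)$role == "int"]
  clen <- Biostrings::width(contigs(genome))[match(cand@contigId,
                                                   names(contigs(genome)))]
  if (as.character(GenomicRanges::strand(fis))[1] == "+") {
    anchor <- c(max(1L, GenomicRanges::end(fis) - 20L),
                min(clen, GenomicRanges::end(fis) + 300L))
    search <- c(max(1L, GenomicRanges::end(int) - 20L),
                min(clen, GenomicRanges::end(int) + searchWindow))
  } else {
    anchor <- c(max(1L, GenomicRanges::start(fis) - 300L),
                min(clen, GenomicRanges::start(fis) + 20L))
    search <- c(max(1L, GenomicRanges::start(int) - searchWindow),
                min(clen, GenomicRanges::start(int) + 20L))
  }
  list(anchor = as.integer(anchor), search = as.integer(search))
}

#' Extract a PICMI element from a retained candidate
#'
#' The element runs from the first base of the fis gene to the end of the
#' boundary direct repeat on the int-distal side; the sequence is reported in
#' fis-forward orientation (reverse-complemented when fis lies on the minus
#' strand). When no repeat is supplied the element falls back to the span from
#' fis to the integrase end plus \code{fallbackMargin}.
#'
#' @param genome \code{AnnotatedGenome}
#' @param candidate retained \code{PicmiCandidate} (must carry a fis hit)
#' @param repeat_ \code{DirectRepeat} from \code{\link{findDirectRepeats}}, or
#'   \code{NULL} to use the fallback boundary
#' @param model \code{DetectionModel}
#' @return \code{PicmiElement} with element-internal features re-mapped to
#'   element coordinates
#' @export
extractElement <- function(genome, candidate, repeat_ = NULL,
                           model = picmiModel()) {
  hits <- candidate@coreHits
  fis <- hits[GenomicRanges::mcols(hits)$role == "fis"]
  if (!length(fis)) stop("extraction requires a fis anchor hit")
  int <- hits[GenomicRanges::mcols(hits)$role == "int"]
  ct <- candidate@contigId
  cseq <- as.character(contigs(genome)[[ct]])
  clen <- nchar(cseq)
  fwd <- as.character(GenomicRanges::strand(fis))[1] == "+"
  if (!is.null(repeat_)) {
    if (fwd) {
      s <- GenomicRanges::start(fis)[1]
      e <- repeat_@rightPos + repeat_@length - 1L
    } else {
      s <- repeat_@leftPos
      e <- GenomicRanges::end(fis)[1]
    }
  } else {
    if (fwd) {
      s <- GenomicRanges::start(fis)[1]
      e <- min(clen, GenomicRanges::end(int)[1] + model@fallbackMargin)
    } else {
      s <- max(1L, GenomicRanges::start(int)[1] - model@fallbackMargin)
      e <- GenomicRanges::end(fis)[1]
    }
  }
  if (e - s + 1L > model@maxElementLen)
    stop("oversize: element length ", e - s + 1L, " exceeds maxElementLen")
  eseq <- substring(cseq, s, e)
  if (!fwd) eseq <- revcomp(eseq)
  f <- features(genome)
  inEl <- f[as.character(GenomicRanges::seqnames(f)) == ct &
            GenomicRanges::start(f) >= s & GenomicRanges::end(f) <= e]
  if (length(inEl)) {
    if (fwd) {
      st <- GenomicRanges::start(inEl) - s + 1L
      en <- GenomicRanges::end(inEl) - s + 1L
      str <- as.character(GenomicRanges::strand(inEl))
    } else {
      st <- e - GenomicRanges::end(inEl) + 1L
      en <- e - GenomicRanges::start(inEl) + 1L
      str <- ifelse(as.character(GenomicRanges::strand(inEl)) == "+", "-", "+")
    }
    o <- order(st)
    elFeats <- GenomicRanges::GRanges("element", IRanges::IRanges(st, en),
                                      strand = str)
    GenomicRanges::mcols(elFeats) <- GenomicRanges::mcols(inEl)
    elFeats <- elFeats[o]
  } else elFeats <- GenomicRanges::GRanges()
  roleMap <- GenomicRanges::mcols(hits)$role
  names(roleMap) <- GenomicRanges::mcols(hits)$gene_id
  if (length(elFeats))
    GenomicRanges::mcols(elFeats)$role <-
      unname(roleMap[GenomicRanges::mcols(elFeats)$gene_id])
  new("PicmiElement", candidate = candidate, repeatPair = repeat_,
      elementStart = as.integer(s), elementEnd = as.integer(e),
      orientation = if (fwd) "fis_forward" else "fis_reverse",
      elementSeq = eseq, features = elFeats,
      smallOrfs = GenomicRanges::GRanges())
}

#' Scan non-coding stretches of an element for small ORFs
#'
#' Six-frame scan for ATG-initiated, stop-terminated open reading frames whose
#' product length lies in \code{[minAa, maxAa)} and which do not overlap any
#' annotated gene by more than \code{maxOverlap} bp. Each ATG is paired with
#' its nearest in-frame stop.
#'
#' @param element \code{PicmiElement} with sequence and internal features
#' @param minAa,maxAa product length bounds in amino acids (stop excluded);
#'   ORFs with \code{minAa <= length < maxAa} are reported
#' @param maxOverlap maximum tolerated overlap (bp) with an annotated gene
#' @return \code{GRanges} of small ORFs in element coordinates, with protein
#'   sequences in the metadata
#' @export
findSmallOrfs <- function(element, minAa = 30L, maxAa = 60L, maxOverlap = 30L) {
  seqf <- elementSeq(element)
  L <- nchar(seqf)
  hits <- list()
  scanStrand <- function(s, strand) {
    for (off in 0:2) {
      ncod <- (nchar(s) - off) %/% 3L
      if (ncod < 2L) next
      starts <- off + 1L + 3L * (seq_len(ncod) - 1L)
      cod <- substring(s, starts, starts + 2L)
      stops <- which(cod %in% c("TAA", "TAG", "TGA"))
      atgs <- which(cod == "ATG")
      if (!length(stops) || !length(atgs)) next
      nxt <- stops[findInterval(atgs, stops) + 1L]
      ok <- !is.na(nxt)
      aa <- nxt - atgs
      keep <- ok & aa >= minAa & aa < maxAa
      for (k in which(keep)) {
        nts <- starts[atgs[k]]
        nte <- starts[nxt[k]] + 2L
        if (strand == "+") {
          st <- nts; en <- nte
        } else {
          st <- L - nte + 1L; en <- L - nts + 1L
        }
        prot <- translateDna(if (strand == "+") substring(seqf, st, en)
                             else revcomp(substring(seqf, st, en)))
        hits[[length(hits) + 1L]] <<- data.frame(
          start = st, end = en, strand = strand, protein = prot,
          stringsAsFactors = FALSE)
      }
    }
  }
  scanStrand(seqf, "+")
  scanStrand(revcomp(seqf), "-")
  if (!length(hits)) return(GenomicRanges::GRanges())
  tab <- do.call(rbind, hits)
  tab <- tab[order(tab$start, tab$end), , drop = FALSE]
  orfs <- GenomicRanges::GRanges("element",
                                 IRanges::IRanges(tab$start, tab$end),
                                 strand = tab$strand)
  ann <- element@features
  if (length(ann)) {
    ov <- GenomicRanges::findOverlaps(orfs, ann)
    ow <- GenomicRanges::width(GenomicRanges::pintersect(
      orfs[S4Vectors::queryHits(ov)], ann[S4Vectors::subjectHits(ov)],
      ignore.strand = TRUE))
    bad <- unique(S4Vectors::queryHits(ov)[ow > maxOverlap])
    keep <- setdiff(seq_along(orfs), bad)
    orfs <- orfs[keep]
    tab <- tab[keep, , drop = FALSE]
  }
  if (!length(orfs)) return(GenomicRanges::GRanges())
  GenomicRanges::mcols(orfs) <- S4Vectors::DataFrame(
    gene_id = sprintf("sORF_%02d", seq_along(orfs)),
    product = rep("small_orf", length(orfs)),
    domains = IRanges::CharacterList(rep(list(character()), length(orfs))),
    protein = tab$protein)
  orfs
}

#' Detect, filter and extract PICMI elements from one genome
#'
#' Runs the full detection pipeline: co-localization scan, exclusion filters,
#' direct-repeat boundary search and element extraction, then the small-ORF
#' scan of non-coding stretches. Retained elements are ranked by increasing
#' span (minimalist prior); more than one retained element triggers a warning
#' (none is dropped).
#'
#' @param genome \code{AnnotatedGenome}
#' @param model \code{DetectionModel}
#' @param fisReference fis protein sequence for the anchor filter
#' @param decoyAnchors optional decoy anchor proteins
#' @param searchWindow bp searched past the integrase for the distal repeat
#' @return list with \code{elements} (list of \code{PicmiElement}),
#'   \code{candidates} (all scanned) and \code{flagged} (excluded candidates)
#' @export
detectElements <- function(genome, model = picmiModel(), fisReference,
                           decoyAnchors = NULL, searchWindow = 2000L) {
  cands <- scanGenome(genome, model)
  filt <- filterCandidates(cands, genome, model, fisReference, decoyAnchors)
  elements <- lapply(filt$retained, function(cand) {
    reg <- repeatSearchRegions(genome, cand, model, searchWindow)
    rep_ <- findDirectRepeats(contigs(genome)[[cand@contigId]],
                              reg$anchor, reg$search, model@minRepeatLen)
    el <- extractElement(genome, cand, rep_, model)
    el@smallOrfs <- findSmallOrfs(el)
    el
  })
  if (length(elements) > 1L) {
    elements <- elements[order(vapply(elements, function(e)
      nchar(e@elementSeq), integer(1)))]
    warning("more than one retained PICMI-like element in genome ",
            genomeId(genome), " (", length(elements), "); all reported, ",
            "ranked by increasing span")
  }
  list(elements = elements, candidates = cands, flagged = filt$flagged)
}
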