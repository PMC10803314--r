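#' @include AllClasses.R AllGenerics.R genome-io.R detect.R
NULL

## fixed per-role gene lengths (nt, stop included) for planted cassettes
.roleLens <- c(zntR = 240L, fis = 300L, up2 = 246L, prim = 1503L, up1 = 273L,
               alpA = 213L, iolg = 303L, int = 1203L, terS = 450L,
               filler = 300L)

.roleDomains <- list(fis = "PF02954", prim = "PF13148", alpA = "PF05930",
                     int = "PF00589")

## canonical fis gene, fixed independently of user seeds so that every
## generated genome carries the same anchor and the reference is stable
canonicalFisNt <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- withSeed(115115L, randomOrf(.roleLens[["fis"]]))
    cache
  }
})

#' Reference fis protein used by the anchor-identity filter
#'
#' The translated canonical fis gene planted by the synthetic-data generator.
#'
#' @return amino-acid string
#' @export
fisReferenceProtein <- function() translateDna(canonicalFisNt())

#' Simulation configuration for the synthetic-data generator
#'
#' Defaults mirror the prototype system: a 47,851 bp helper phage, a 6,110 bp
#' satellite with gene order fis - up2 - prim - up1 - alpA - iolg - int
#' flanked by 17 bp exact direct repeats, an iolg overlapping int by 4 nt
#' (shared tetranucleotide ATGA), 8 satellite copies per packaged concatemer,
#' and a chimera rate of 1e-4 of reads.
#'
#' @param seed integer controlling all generator randomness
#' @param nGenomes number of genomes for multi-genome suites
#' @param elementLen full element span (fis start to distal repeat end), bp
#' @param repeatLen direct repeat length, bp
#' @param geneOrder roles planted 5'->3' (must start with fis and contain
#'   prim, alpA, int)
#' @param iolgOverlapNt overlap of iolg with int: 0 (contiguous icg), 1, 4 or
#'   13 nt
#' @param decoys subset of \code{c("other_family", "scattered_cores",
#'   "cross_contig", "bad_fis_anchor")}: decoy loci added on extra contigs
#' @param plantElement set FALSE for pure negative-control genomes
#' @param elementStrand strand of the planted cassette
#' @param withinDivergence,betweenDivergence,nSubfamilies subfamily planting
#'   controls (pairwise within-subfamily divergence, founder divergence from
#'   the base cassette, number of subfamilies)
#' @param helperLen helper genome length, bp
#' @param hitchhikerFraction fraction of particles carrying a satellite
#'   concatemer
#' @param concatemerCopies satellite copies per concatemer
#' @param nReads short reads drawn for the packaging counts
#' @param readLen short read length, bp
#' @param chimeraRate fraction of reads simulated as helper/satellite chimeras
#' @param longReadMode "pac" (uniform random concatemer extremities) or "cos"
#'   (fixed extremity)
#' @param nLongReads,longReadLenMean,longReadLenSd long-read simulation
#' @return config list of class \code{PicmiSimConfig}
#' @export
simulationConfig <- function(seed = 1L, nGenomes = 1L, elementLen = 6110L,
                             repeatLen = 17L,
                             geneOrder = c("fis", "up2", "prim", "up1",
                                           "alpA", "iolg", "int"),
                             iolgOverlapNt = 4L, decoys = character(),
                             plantElement = TRUE, elementStrand = "+",
                             withinDivergence = 0.03,
                             betweenDivergence = 0.20, nSubfamilies = 5L,
                             helperLen = 47851L, hitchhikerFraction = 0.15,
                             concatemerCopies = 8L, nReads = 100000L,
                             readLen = 150L, chimeraRate = 1e-4,
                             longReadMode = c("pac", "cos"),
                             nLongReads = 500L, longReadLenMean = 15000L,
                             longReadLenSd = 3000L) {
  stopifnot(iolgOverlapNt %in% c(0L, 1L, 4L, 13L),
            geneOrder[1] == "fis",
            all(c("prim", "alpA", "int") %in% geneOrder),
            elementStrand %in% c("+", "-"),
            withinDivergence >= 0, withinDivergence < 1,
            betweenDivergence >= 0, betweenDivergence < 1)
  bad <- setdiff(decoys, c("other_family", "scattered_cores", "cross_contig",
                           "bad_fis_anchor"))
  if (length(bad)) stop("unknown decoy flag: ", bad[1])
  cfg <- list(seed = as.integer(seed), nGenomes = as.integer(nGenomes),
              elementLen = as.integer(elementLen),
              repeatLen = as.integer(repeatLen), geneOrder = geneOrder,
              iolgOverlapNt = as.integer(iolgOverlapNt), decoys = decoys,
              plantElement = plantElement, elementStrand = elementStrand,
              withinDivergence = withinDivergence,
              betweenDivergence = betweenDivergence,
              nSubfamilies = as.integer(nSubfamilies),
              helperLen = as.integer(helperLen),
              hitchhikerFraction = hitchhikerFraction,
              concatemerCopies = as.integer(concatemerCopies),
              nReads = as.integer(nReads), readLen = as.integer(readLen),
              chimeraRate = chimeraRate,
              longReadMode = match.arg(longReadMode),
              nLongReads = as.integer(nLongReads),
              longReadLenMean = as.integer(longReadLenMean),
              longReadLenSd = as.integer(longReadLenSd))
  class(cfg) <- "PicmiSimConfig"
  cfg
}

## integrase gene whose 5' end supports the configured iolg overlap:
## prefix "ATGAAACGTCTGAAA" carries ATGA at 1-4 (overlaps 1 and 4) and, for
## the 13 nt overlap, the alternative prefix places a stop at nt 11-13 in the
## shifted iolg frame without creating one in the int frame.
intPrefix <- function(overlap) {
  if (overlap == 13L) "ATGCAAAGCATGAGC" else "ATGAAACGTCTGAAA"
}

makeIntNt <- function(overlap) {
  pre <- intPrefix(overlap)
  rest <- .roleLens[["int"]] - nchar(pre)
  body <- randomOrf(rest + 6L)          # reuse ATG...TGA scaffold
  paste0(pre, substring(body, 4L, 3L + rest - 3L), "TGA")
}

hasInternalStop <- function(orf) {
  ncod <- nchar(orf) / 3
  cod <- substring(orf, 3 * (seq_len(ncod) - 1) + 1, 3 * seq_len(ncod))
  any(cod[-ncod] %in% c("TAA", "TAG", "TGA")) ||
    !cod[ncod] %in% c("TAA", "TAG", "TGA") || cod[1] != "ATG"
}

## iolg gene whose last `overlap` nt equal the int prefix while staying a
## clean ORF in its own frame
makeIolgNt <- function(overlap, intNt) {
  L <- .roleLens[["iolg"]]
  repeat {
    g <- randomOrf(L)
    if (overlap > 0L)
      g <- paste0(substring(g, 1L, L - overlap), substring(intNt, 1L, overlap))
    if (!hasInternalStop(g)) return(g)
  }
}

## Assemble the planted cassette: fis, left repeat, internal genes, right
## repeat. Returns the cassette sequence (fis start = position 1), relative
## feature table, repeat positions and role map.
buildCassette <- function(cfg) {
  ord <- cfg$geneOrder
  internal <- ord[-1]
  ov <- if ("iolg" %in% internal) cfg$iolgOverlapNt else 0L
  intNt <- makeIntNt(ov)
  geneSeqs <- lapply(internal, function(role) {
    if (role == "int") intNt
    else if (role == "iolg") makeIolgNt(ov, intNt)
    else randomOrf(.roleLens[[role]])
  })
  names(geneSeqs) <- internal
  glen <- vapply(geneSeqs, nchar, integer(1))
  physLen <- sum(glen) - ov                      # iolg/int share the overlap
  fixed <- .roleLens[["fis"]] + 2L * cfg$repeatLen + physLen
  nGaps <- length(internal) + 1L                 # DR1->g1, between genes, gN->DR2
  if ("iolg" %in% internal) nGaps <- nGaps - 1L  # iolg abuts int
  slack <- cfg$elementLen - fixed
  if (slack < 10L * nGaps)
    stop("inconsistent config: elementLen too small for the planted genes")
  gaps <- rep(slack %/% nGaps, nGaps)
  gaps[nGaps] <- gaps[nGaps] + slack %% nGaps
  dr <- randomDna(cfg$repeatLen)
  parts <- character(); feats <- list(); pos <- 1L
  emit <- function(s) { parts[[length(parts) + 1L]] <<- s; pos <<- pos + nchar(s) }
  addFeat <- function(id, role, product, start, end, domains, protein = NA) {
    feats[[length(feats) + 1L]] <<- data.frame(
      gene_id = id, role = role, product = product, start = start, end = end,
      stringsAsFactors = FALSE)
  }
  fisNt <- canonicalFisNt()
  addFeat("fis", "fis", "fis", pos, pos + nchar(fisNt) - 1L)
  emit(fisNt)
  drLeft <- pos
  emit(dr)
  gi <- 0L
  i <- 1L
  while (i <= length(internal)) {
    gi <- gi + 1L
    spacer <- randomDna(gaps[gi])
    if (gi == 1L) substring(spacer, 1L, 1L) <- "C"   # pin DR1 right flank
    emit(spacer)
    role <- internal[i]
    if (role == "iolg" && i < length(internal) && internal[i + 1L] == "int") {
      g <- geneSeqs[["iolg"]]
      addFeat("iolg", "iolg", "iolg", pos, pos + nchar(g) - 1L)
      if (ov > 0L) {
        emit(substring(g, 1L, nchar(g) - ov))
        addFeat("int", "int", "int", pos, pos + nchar(intNt) - 1L)
        emit(intNt)
      } else {
        emit(g)
        addFeat("int", "int", "int", pos, pos + nchar(intNt) - 1L)
        emit(intNt)
      }
      i <- i + 2L
    } else {
      g <- geneSeqs[[role]]
      addFeat(role, role, role, pos, pos + nchar(g) - 1L)
      emit(g)
      i <- i + 1L
    }
  }
  lastGap <- cfg$elementLen - (pos - 1L) - cfg$repeatLen
  if (lastGap < 0L) stop("inconsistent config: elementLen too small")
  spacer <- randomDna(lastGap)
  if (lastGap > 0L) substring(spacer, lastGap, lastGap) <- "T"  # pin DR2 left flank
  emit(spacer)
  drRight <- pos
  emit(dr)
  seqc <- paste(parts, collapse = "")
  stopifnot(nchar(seqc) == cfg$elementLen)
  ft <- do.call(rbind, feats)
  list(seq = seqc, features = ft, drLeft = drLeft, drRight = drRight,
       drSeq = dr)
}

featTableToGRanges <- function(ft, contig, strand = "+") {
  doms <- lapply(ft$role, function(r) {
    d <- .roleDomains[[r]]
    if (is.null(d)) character() else d
  })
  gr <- GenomicRanges::GRanges(contig, IRanges::IRanges(ft$start, ft$end),
                               strand = strand)
  GenomicRanges::mcols(gr) <- S4Vectors::DataFrame(
    gene_id = ft$gene_id, product = ft$product,
    domains = IRanges::CharacterList(doms),
    protein = rep(NA_character_, nrow(ft)))
  gr
}

#' Generate one annotated genome with a planted element and decoys
#'
#' Builds a random-background contig carrying a zntR-fis anchor followed by
#' the full satellite cassette between exact direct repeats (flanking bases
#' are pinned so that neither repeat copy extends by chance), plus any decoy
#' contigs requested: an other-family locus carrying a terS-labeled gene, core
#' genes scattered beyond the co-localization gap, an element split across two
#' contigs, or a cassette anchored at a fis-labeled gene whose protein is
#' unrelated to the fis reference.
#'
#' @param cfg \code{\link{simulationConfig}}
#' @param index genome index; offsets the seed so multi-genome suites differ
#' @return list with \code{genome} (\code{AnnotatedGenome}) and \code{truth}
#'   (planted coordinates, repeat positions, role map, decoy bookkeeping)
#' @export
generateGenome <- function(cfg, index = 1L) {
  stopifnot(inherits(cfg, "PicmiSimConfig"))
  withSeed(cfg$seed * 1000L + index, {
    gid <- sprintf("synth_genome_%03d", index)
    contigSeqs <- list(); featList <- list(); truth <- list(genomeId = gid)
    nextGene <- local({ i <- 0L; function(p) { i <<- i + 1L; sprintf("%s_%03d", p, i) } })
    bgGene <- function(contig, start) {
      g <- randomOrf(.roleLens[["filler"]])
      list(seq = g, feat = data.frame(gene_id = nextGene("bg"), role = "filler",
                                      product = NA_character_, start = start,
                                      end = start + nchar(g) - 1L,
                                      stringsAsFactors = FALSE))
    }
    if (cfg$plantElement) {
      cas <- buildCassette(cfg)
      bgL <- 1500L; bgR <- 1500L
      zntR <- randomOrf(.roleLens[["zntR"]])
      pre <- randomDna(bgL)
      gapA <- randomDna(60L)
      off <- bgL + nchar(zntR) + 60L          # cassette offset (0-based)
      post <- randomDna(bgR)
      ## pin bases flanking the repeat copies so neither extends by chance
      casSeq <- cas$seq
      substring(post, 1L, 1L) <- "G"
      contig <- paste0(pre, zntR, gapA, casSeq, post)
      ft <- cas$features
      ft$start <- ft$start + off; ft$end <- ft$end + off
      ft <- rbind(data.frame(gene_id = "zntR", role = "filler",
                             product = "zntR", start = bgL + 1L,
                             end = bgL + nchar(zntR), stringsAsFactors = FALSE),
                  ft)
      elStart <- off + 1L
      elEnd <- off + cfg$elementLen
      drL <- cas$drLeft + off; drR <- cas$drRight + off
      strand <- cfg$elementStrand
      if (strand == "-") {
        L <- nchar(contig)
        contig <- revcomp(contig)
        newStart <- L - ft$end + 1L; newEnd <- L - ft$start + 1L
        ft$start <- newStart; ft$end <- newEnd
        ft <- ft[order(ft$start), , drop = FALSE]
        tmp <- c(L - elEnd + 1L, L - elStart + 1L)
        elStart <- tmp[1]; elEnd <- tmp[2]
        tmp <- c(L - (drR + cfg$repeatLen - 1L) + 1L,
                 L - (drL + cfg$repeatLen - 1L) + 1L)
        drL <- tmp[1]; drR <- tmp[2]
      }
      contigSeqs$chrom <- contig
      featList$chrom <- cbind(ft, contig = "chrom", strand = strand,
                              stringsAsFactors = FALSE)
      truth$element <- list(
        contig = "chrom", start = elStart, end = elEnd,
        strand = strand, repeatLeft = drL, repeatRight = drR,
        repeatSeq = if (strand == "+") cas$drSeq else revcomp(cas$drSeq),
        repeatLen = cfg$repeatLen,
        roles = setNames(cas$features$gene_id, cas$features$role),
        iolgOverlapNt = if ("iolg" %in% cfg$geneOrder) cfg$iolgOverlapNt else 0L,
        seq = if (strand == "+") cas$seq else cas$seq)  # fis-forward cassette
    }
    mkLocusContig <- function(roleSeq, pad = 400L) {
      ## roleSeq: data.frame(role, product, labeled) in order; returns
      ## contig sequence + feature table with `pad` bp between genes
      parts <- list(randomDna(pad)); pos <- pad + 1L; rows <- list()
      for (k in seq_len(nrow(roleSeq))) {
        r <- roleSeq$role[k]
        g <- if (r == "fis" && isTRUE(roleSeq$canonical[k])) canonicalFisNt()
             else randomOrf(.roleLens[[if (r %in% names(.roleLens)) r else "filler"]])
        rows[[k]] <- data.frame(gene_id = nextGene(paste0("d", r)),
                                role = if (roleSeq$labeled[k]) r else "filler",
                                product = roleSeq$product[k],
                                start = pos, end = pos + nchar(g) - 1L,
                                stringsAsFactors = FALSE)
        parts[[length(parts) + 1L]] <- g
        gap <- randomDna(roleSeq$gap[k])
        parts[[length(parts) + 1L]] <- gap
        pos <- pos + nchar(g) + roleSeq$gap[k]
      }
      list(seq = paste(unlist(parts), collapse = ""), ft = do.call(rbind, rows))
    }
    if ("other_family" %in% cfg$decoys) {
      rs <- data.frame(role = c("fis", "prim", "alpA", "terS", "int"),
                       product = c("fis", "prim", "alpA", "terS", "int"),
                       labeled = c(TRUE, TRUE, TRUE, FALSE, TRUE),
                       canonical = c(TRUE, FALSE, FALSE, FALSE, FALSE),
                       gap = rep(120L, 5), stringsAsFactors = FALSE)
      loc <- mkLocusContig(rs)
      contigSeqs$decoy_other <- paste0(loc$seq, randomDna(400L))
      featList$decoy_other <- cbind(loc$ft, contig = "decoy_other",
                                    strand = "+", stringsAsFactors = FALSE)
      truth$decoy_other_family <- TRUE
    }
    if ("bad_fis_anchor" %in% cfg$decoys) {
      rs <- data.frame(role = c("fis", "prim", "alpA", "int"),
                       product = c("fis_like", "prim", "alpA", "int"),
                       labeled = TRUE, canonical = FALSE,
                       gap = rep(120L, 4), stringsAsFactors = FALSE)
      loc <- mkLocusContig(rs)
      contigSeqs$decoy_anchor <- paste0(loc$seq, randomDna(400L))
      featList$decoy_anchor <- cbind(loc$ft, contig = "decoy_anchor",
                                     strand = "+", stringsAsFactors = FALSE)
      truth$decoy_bad_anchor <- TRUE
    }
    if ("scattered_cores" %in% cfg$decoys) {
      scatterGap <- 350L
      roles <- c("fis", "prim", "alpA", "int")
      parts <- list(); rows <- list(); pos <- 1L
      for (r in roles) {
        g <- randomOrf(.roleLens[[r]])
        rows[[length(rows) + 1L]] <- data.frame(
          gene_id = nextGene(paste0("s", r)), role = r, product = r,
          start = pos, end = pos + nchar(g) - 1L, stringsAsFactors = FALSE)
        parts[[length(parts) + 1L]] <- g
        pos <- pos + nchar(g)
        for (k in seq_len(7L)) {          # 7 unlabeled genes > maxGeneGap 5
          f <- randomOrf(.roleLens[["filler"]])
          rows[[length(rows) + 1L]] <- data.frame(
            gene_id = nextGene("sbg"), role = "filler",
            product = NA_character_, start = pos, end = pos + nchar(f) - 1L,
            stringsAsFactors = FALSE)
          parts[[length(parts) + 1L]] <- f
          pos <- pos + nchar(f)
        }
      }
      contigSeqs$decoy_scatter <- paste0(paste(unlist(parts), collapse = ""),
                                         randomDna(scatterGap))
      featList$decoy_scatter <- cbind(do.call(rbind, rows),
                                      contig = "decoy_scatter", strand = "+",
                                      stringsAsFactors = FALSE)
      truth$decoy_scattered <- TRUE
    }
    if ("cross_contig" %in% cfg$decoys) {
      a <- mkLocusContig(data.frame(role = c("fis", "prim"),
                                    product = c("fis", "prim"), labeled = TRUE,
                                    canonical = c(TRUE, FALSE),
                                    gap = c(120L, 10L), stringsAsFactors = FALSE))
      b <- mkLocusContig(data.frame(role = c("alpA", "int"),
                                    product = c("alpA", "int"), labeled = TRUE,
                                    canonical = FALSE, gap = c(120L, 10L),
                                    stringsAsFactors = FALSE))
      contigSeqs$decoy_splitA <- a$seq
      featList$decoy_splitA <- cbind(a$ft, contig = "decoy_splitA",
                                     strand = "+", stringsAsFactors = FALSE)
      contigSeqs$decoy_splitB <- b$seq
      featList$decoy_splitB <- cbind(b$ft, contig = "decoy_splitB",
                                     strand = "+", stringsAsFactors = FALSE)
      truth$decoy_cross_contig <- TRUE
    }
    if (!length(contigSeqs)) {
      contigSeqs$chrom <- randomDna(3000L)
      featList <- list()
    }
    allFt <- if (length(featList)) do.call(rbind, featList) else NULL
    contigs <- Biostrings::DNAStringSet(unlist(contigSeqs))
    names(contigs) <- names(contigSeqs)
    feats <- if (!is.null(allFt)) {
      grs <- lapply(split(allFt, allFt$contig), function(d)
        featTableToGRanges(d[, c("gene_id", "role", "product", "start", "end")],
                           d$contig[1], d$strand))
      suppressWarnings(do.call(c, unname(grs)))
    } else GenomicRanges::GRanges()
    genome <- annotatedGenome(gid, contigs, feats)
    truth$nFeatures <- length(feats)
    list(genome = genome, truth = truth)
  })
}

#' Mutate an element sequence to a target divergence
#'
#' Applies random mutation events at an expected per-base divergence; a
#' configurable fraction of events (default 10 percent) are 1-3 bp indels,
#' the rest substitutions to a different base.
#'
#' @param elementSeq DNA string
#' @param divergence expected per-base divergence in [0, 0.5]
#' @param seed RNG seed for this mutation
#' @param indelFraction fraction of events realized as indels
#' @return list with \code{seq}, \code{nSub}, \code{nIndel} and
#'   \code{realizedEvents} (events per input base)
#' @export
mutateElement <- function(elementSeq, divergence, seed = 1L,
                          indelFraction = 0.10) {
  stopifnot(divergence >= 0, divergence <= 0.5)
  s <- strsplit(toupper(as.character(elementSeq)), "")[[1]]
  n <- length(s)
  if (divergence == 0) return(list(seq = paste(s, collapse = ""), nSub = 0L,
                                   nIndel = 0L, realizedEvents = 0))
  withSeed(seed, {
    nEvents <- stats::rbinom(1L, n, divergence)
    pos <- sort(sample.int(n, min(nEvents, n)))
    isIndel <- stats::runif(length(pos)) < indelFraction
    bases <- c("A", "C", "G", "T")
    out <- as.list(s)
    nSub <- 0L; nIndel <- 0L
    for (k in seq_along(pos)) {
      p <- pos[k]
      if (!isIndel[k]) {
        out[[p]] <- sample(setdiff(bases, s[p]), 1L)
        nSub <- nSub + 1L
      } else {
        w <- sample(1:3, 1L)
        if (stats::runif(1L) < 0.5) {
          drop <- p:min(n, p + w - 1L)
          for (d in drop) out[[d]] <- character(0)
        } else {
          out[[p]] <- c(paste(sample(bases, w, TRUE), collapse = ""), s[p])
        }
        nIndel <- nIndel + 1L
      }
    }
    list(seq = paste(unlist(out), collapse = ""), nSub = nSub,
         nIndel = nIndel, realizedEvents = length(pos) / n)
  })
}

#' Plant a divergence-controlled subfamily set
#'
#' Generates \code{nSubfamilies} founder variants of the base cassette (each
#' at \code{betweenDivergence} from the base, hence roughly twice that
#' between founders) and \code{membersPer} members per subfamily at pairwise
#' within-divergence \code{withinDivergence}.
#'
#' @param cfg \code{\link{simulationConfig}}
#' @param membersPer members per subfamily
#' @return list with \code{sequences} (named character vector) and
#'   \code{truth} (named integer vector of planted subfamily labels)
#' @export
generateSubfamilySet <- function(cfg, membersPer = 3L) {
  base <- withSeed(cfg$seed, buildCassette(cfg)$seq)
  seqs <- character(); labels <- integer()
  for (sf in seq_len(cfg$nSubfamilies)) {
    founder <- mutateElement(base, cfg$betweenDivergence,
                             seed = cfg$seed * 100L + sf)$seq
    for (m in seq_len(membersPer)) {
      v <- mutateElement(founder, cfg$withinDivergence / 2,
                         seed = cfg$seed * 1000L + sf * 10L + m)$seq
      id <- sprintf("sf%02d_m%02d", sf, m)
      seqs[id] <- v
      labels[id] <- sf
    }
  }
  list(sequences = seqs, truth = labels)
}

#' Simulate read sets from a phage/satellite particle mixture
#'
#' Particles carry either the helper genome or a satellite concatemer
#' (\code{concatemerCopies * elementLen} bp) with probability given by
#' \code{hitchhikerFraction}; short reads are drawn uniformly per base of
#' packaged DNA, so the per-read satellite probability is
#' f Lc / (f Lc + (1 - f) Lh). A configured fraction of reads are
#' helper/satellite chimeras. Long reads sample concatemer windows with
#' uniform (pac-like) or fixed (cos-like) start phase.
#'
#' @param cfg \code{\link{simulationConfig}}
#' @param emitSequences when TRUE also emit actual read sequences (keep
#'   \code{nReads}/\code{nLongReads} small in that case)
#' @return list with \code{counts} (\code{PackagingCounts}), \code{longReads}
#'   (data.frame with true \code{phase_start}), \code{truth}, and when
#'   requested \code{shortReadSeqs}, \code{longReadSeqs}, \code{helperRef},
#'   \code{unitRef}
#' @export
simulateReads <- function(cfg, emitSequences = FALSE) {
  stopifnot(inherits(cfg, "PicmiSimConfig"))
  withSeed(cfg$seed + 7L, {
    f <- cfg$hitchhikerFraction
    Lh <- cfg$helperLen
    Ls <- cfg$elementLen
    Lc <- cfg$concatemerCopies * Ls
    ps <- if (f > 0) f * Lc / (f * Lc + (1 - f) * Lh) else 0
    n <- cfg$nReads
    nChim <- stats::rbinom(1L, n, cfg$chimeraRate)
    nRest <- n - nChim
    nSat <- stats::rbinom(1L, nRest, ps)
    nHelp <- nRest - nSat
    counts <- packagingCounts(nHelp, nSat, Lh, Ls,
                              concatemerCopies = cfg$concatemerCopies,
                              readsHybrid = nChim)
    phases <- if (cfg$longReadMode == "pac")
      floor(stats::runif(cfg$nLongReads, 0, Ls)) else
      rep(0, cfg$nLongReads)
    lens <- pmax(1000L, round(stats::rnorm(cfg$nLongReads,
                                           cfg$longReadLenMean,
                                           cfg$longReadLenSd)))
    lr <- data.frame(read_id = sprintf("long_%04d", seq_len(cfg$nLongReads)),
                     phase_start = phases, length = lens, unit_len = Ls,
                     stringsAsFactors = FALSE)
    out <- list(counts = counts, longReads = lr,
                truth = list(fraction = f, mode = cfg$longReadMode,
                             nChimera = nChim, perRead = c(helper = nHelp,
                                                           satellite = nSat,
                                                           chimera = nChim)))
    if (emitSequences) {
      helperRef <- randomDna(Lh)
      unitRef <- withSeed(cfg$seed, buildCassette(cfg)$seq)
      conc <- strrep(unitRef, cfg$concatemerCopies)
      rl <- cfg$readLen
      sampleFrom <- function(ref, n) {
        if (n == 0L) return(character())
        starts <- sample.int(nchar(ref) - rl + 1L, n, replace = TRUE)
        substring(ref, starts, starts + rl - 1L)
      }
      shorts <- c(
        setNames(sampleFrom(helperRef, nHelp),
                 if (nHelp) sprintf("helper_%05d", seq_len(nHelp)) else NULL),
        setNames(sampleFrom(conc, nSat),
                 if (nSat) sprintf("sat_%05d", seq_len(nSat)) else NULL))
      if (nChim > 0L) {
        h <- sampleFrom(helperRef, nChim)
        s <- sampleFrom(conc, nChim)
        chim <- paste0(substring(h, 1L, rl %/% 2L),
                       substring(s, rl %/% 2L + 1L, rl))
        shorts <- c(shorts, setNames(chim, sprintf("chim_%05d", seq_len(nChim))))
      }
      maxStart <- nchar(conc)
      lrSeqs <- vapply(seq_len(nrow(lr)), function(i) {
        st <- lr$phase_start[i] + 1L
        en <- min(nchar(conc), st + lr$length[i] - 1L)
        substring(conc, st, en)
      }, character(1))
      names(lrSeqs) <- lr$read_id
      out$shortReadSeqs <- shorts
      out$longReadSeqs <- lrSeqs
      out$helperRef <- helperRef
      out$unitRef <- unitRef
    }
    out
  })
}
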