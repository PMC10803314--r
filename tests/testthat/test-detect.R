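model <- picmiModel()

test_that("the planted cassette yields one candidate with all four roles", {
  set.seed(1)
  g <- tiny_genome(list(
    list(role = "fis", domains = "PF02954"),
    list(role = "up2"),
    list(role = "prim", domains = "PF13148.9"),
    list(role = "up1"),
    list(role = "alpA", domains = "PF05930"),
    list(role = "iolg"),
    list(role = "int", domains = "PF00589.25")))
  cands <- scanGenome(g, model)
  expect_length(cands, 1)
  expect_setequal(mcols(coreHits(cands[[1]]))$role,
                  c("fis", "prim", "alpA", "int"))
})

test_that("unlabeled genomes yield no candidates", {
  set.seed(2)
  g <- tiny_genome(list(list(role = "a"), list(role = "b")))
  expect_length(scanGenome(g, model), 0)
})

test_that("the co-localization gap is enforced exactly at the boundary", {
  set.seed(3)
  mk <- function(n_between) {
    genes <- c(list(list(role = "fis", domains = "PF02954"),
                    list(role = "prim", domains = "PF13148"),
                    list(role = "alpA", domains = "PF05930")),
               replicate(n_between, list(role = "x"), simplify = FALSE),
               list(list(role = "int", domains = "PF00589")))
    tiny_genome(genes, gap_bp = 10)
  }
  gapN <- model@maxGeneGap
  expect_length(scanGenome(mk(gapN), model), 1)
  expect_length(scanGenome(mk(gapN + 1L), model), 0)
})

test_that("scan agrees with the quadratic window-enumeration oracle", {
  roles_pool <- list(list(role = "fis", domains = "PF02954"),
                     list(role = "prim", domains = "PF13148"),
                     list(role = "alpA", domains = "PF05930"),
                     list(role = "int", domains = "PF00589"),
                     list(role = "x"), list(role = "x"), list(role = "x"))
  for (seed in 1:8) {
    set.seed(seed)
    genes <- sample(rep(roles_pool, 3), sample(8:18, 1))
    g <- tiny_genome(genes, gap_bp = 12)
    got <- scanGenome(g, model)
    want <- oracle_scan_spans(g, model)
    expect_length(got, length(want))
    if (length(want)) {
      got_spans <- lapply(got, function(cand) cand@span)
      want_spans <- lapply(want, function(w) as.integer(w$span))
      expect_setequal(got_spans, want_spans)
    }
  }
})

test_that("exclusion filters flag other-family, cross-contig and bad anchors", {
  cfg <- simulationConfig(
    seed = 9, decoys = c("other_family", "cross_contig", "bad_fis_anchor"))
  g <- generateGenome(cfg, 1)
  cands <- scanGenome(g$genome, model)
  filt <- filterCandidates(cands, g$genome, model, fisReferenceProtein())
  expect_length(filt$retained, 1)
  expect_equal(filt$retained[[1]]@contigId, "chrom")
  flags <- lapply(filt$flagged, filterFlags)
  expect_true(any(vapply(flags, function(f) "other_family" %in% f, logical(1))))
  expect_true(any(vapply(flags, function(f) "cross_contig" %in% f, logical(1))))
  expect_true(any(vapply(flags, function(f) "bad_fis_anchor" %in% f, logical(1))))
})

test_that("an empty fis reference is rejected", {
  g <- generateGenome(simulationConfig(seed = 4))
  cands <- scanGenome(g$genome, model)
  expect_error(filterCandidates(cands, g$genome, model, ""), "non-empty")
})

test_that("scattered core genes are never called", {
  cfg <- simulationConfig(seed = 10, decoys = "scattered_cores",
                          plantElement = FALSE)
  g <- generateGenome(cfg, 1)
  res <- detectElements(g$genome, model, fisReferenceProtein())
  expect_length(res$elements, 0)
})

test_that("direct repeat search returns the longest planted pair", {
  set.seed(11)
  rep17 <- rand_dna(17)
  ctg <- paste0(rand_dna(100), rep17, rand_dna(400), rep17, rand_dna(100))
  dr <- findDirectRepeats(ctg, c(50, 200), c(400, 620), minLen = 15)
  expect_false(is.null(dr))
  expect_gte(dr@length, 17)
  expect_equal(substring(ctg, dr@leftPos, dr@leftPos + dr@length - 1),
               substring(ctg, dr@rightPos, dr@rightPos + dr@length - 1))

  # two planted repeats of different lengths: the longer pair wins
  set.seed(12)
  r15 <- rand_dna(15); r20 <- rand_dna(20)
  ctg2 <- paste0(rand_dna(60), r15, rand_dna(10), r20, rand_dna(300),
                 r15, rand_dna(10), r20, rand_dna(60))
  dr2 <- findDirectRepeats(ctg2, c(40, 130), c(380, 500), minLen = 15)
  expect_gte(dr2@length, 20)
  o <- oracle_lcs(substring(ctg2, 40, 130), substring(ctg2, 380, 500), 15)
  expect_equal(dr2@length, o$len)

  # absence case and inverted regions
  set.seed(13)
  ctg3 <- rand_dna(600)
  expect_null(findDirectRepeats(ctg3, c(1, 100), c(400, 600), minLen = 15))
  expect_error(findDirectRepeats(ctg3, c(100, 1), c(400, 600)), "inverted")
})

test_that("repeat search maximality matches the brute-force oracle", {
  for (seed in 1:5) {
    set.seed(seed * 7)
    core <- rand_dna(sample(10:14, 1) + 8)   # 18-22 bp planted repeat
    ctg <- paste0(rand_dna(80), core, rand_dna(250), core, rand_dna(80))
    dr <- findDirectRepeats(ctg, c(40, 140), c(280, nchar(ctg)), minLen = 8)
    o <- oracle_lcs(substring(ctg, 40, 140), substring(ctg, 280, nchar(ctg)), 8)
    expect_equal(dr@length, o$len)
  }
})

test_that("extraction recovers planted boundaries exactly, both strands", {
  for (strand in c("+", "-")) {
    cfg <- simulationConfig(seed = 14, elementStrand = strand)
    g <- generateGenome(cfg, 1)
    res <- detectElements(g$genome, model, fisReferenceProtein())
    expect_length(res$elements, 1)
    el <- res$elements[[1]]
    tr <- g$truth$element
    expect_equal(el@elementStart, tr$start)
    expect_equal(el@elementEnd, tr$end)
    expect_equal(nchar(elementSeq(el)), cfg$elementLen)
    expect_equal(el@orientation,
                 if (strand == "+") "fis_forward" else "fis_reverse")
    expect_equal(el@repeatPair@length, tr$repeatLen)
    # fis-forward sequence starts with the canonical fis start codon
    expect_equal(substring(elementSeq(el), 1, 3), "ATG")
  }
})

test_that("minus-strand extraction reverse-complements the contig slice", {
  cfg <- simulationConfig(seed = 15, elementStrand = "-")
  g <- generateGenome(cfg, 1)
  res <- detectElements(g$genome, model, fisReferenceProtein())
  el <- res$elements[[1]]
  slice <- substring(as.character(contigs(g$genome)[["chrom"]]),
                     el@elementStart, el@elementEnd)
  expect_equal(elementSeq(el),
               as.character(reverseComplement(DNAString(slice))))
})

test_that("extraction falls back to a margin when no repeat is given", {
  g <- generateGenome(simulationConfig(seed = 16), 1)
  cands <- scanGenome(g$genome, model)
  filt <- filterCandidates(cands, g$genome, model, fisReferenceProtein())
  el <- extractElement(g$genome, filt$retained[[1]], repeat_ = NULL, model)
  expect_null(repeatPair(el))
  hits <- coreHits(el)
  int_end <- end(hits[mcols(hits)$role == "int"])
  expect_equal(el@elementEnd,
               min(int_end + model@fallbackMargin,
                   width(contigs(g$genome))[1]))
})

test_that("oversized candidates are refused at extraction", {
  g <- generateGenome(simulationConfig(seed = 17), 1)
  cands <- scanGenome(g$genome, model)
  filt <- filterCandidates(cands, g$genome, model, fisReferenceProtein())
  small <- picmiModel(maxElementLen = 2000L)
  expect_error(extractElement(g$genome, filt$retained[[1]], NULL, small),
               "oversize")
})

test_that("small-ORF scan matches the six-frame oracle and length filter", {
  for (seed in c(21, 22)) {
    g <- generateGenome(simulationConfig(seed = seed), 1)
    el <- detectElements(g$genome, model, fisReferenceProtein())$elements[[1]]
    # unannotated copy of the element: every frame is 'non-coding'
    bare <- new("PicmiElement", candidate = el@candidate, repeatPair = NULL,
                elementStart = el@elementStart, elementEnd = el@elementEnd,
                orientation = el@orientation, elementSeq = elementSeq(el),
                features = GRanges(), smallOrfs = GRanges())
    got <- findSmallOrfs(bare, minAa = 30, maxAa = 60)
    want <- oracle_orfs(elementSeq(el), 30, 60)
    if (is.null(want)) {
      expect_length(got, 0)
    } else {
      expect_equal(start(got), want$start)
      expect_equal(end(got), want$end)
      expect_equal(as.character(strand(got)), want$strand)
    }
  }
})

test_that("planted intergenic ORFs are found with exact coordinates", {
  set.seed(23)
  orf35 <- picmiscan:::randomOrf(3 * 36)          # 35-aa product
  orf20 <- picmiscan:::randomOrf(3 * 21)          # 20-aa product, below floor
  left <- rand_dna(200); mid <- rand_dna(150); right <- rand_dna(200)
  eseq <- paste0(left, orf35, mid, orf20, right)
  cand <- new("PicmiCandidate", genomeId = "t", contigId = "c1",
              coreHits = {
                h <- GRanges("c1", IRanges(c(1, 10, 20), c(5, 15, 25)))
                mcols(h)$role <- c("int", "alpA", "prim")
                mcols(h)$gene_id <- c("a", "b", "c")
                h
              }, span = c(1L, 25L), interveningIds = character(),
              filterFlags = character())
  el <- new("PicmiElement", candidate = cand, repeatPair = NULL,
            elementStart = 1L, elementEnd = nchar(eseq),
            orientation = "fis_forward", elementSeq = eseq,
            features = GRanges(), smallOrfs = GRanges())
  got <- findSmallOrfs(el, minAa = 30, maxAa = 60)
  plus <- got[as.character(strand(got)) == "+"]
  expect_true(any(start(plus) == 201 & end(plus) == 200 + nchar(orf35)))
  # the 20-aa ORF stays below the reporting floor
  expect_false(any(start(got) == 200 + nchar(orf35) + 151))
  # an element fully covered by annotated genes reports nothing
  cover <- GRanges("element", IRanges(1, nchar(eseq)))
  mcols(cover) <- S4Vectors::DataFrame(
    gene_id = "big", product = NA_character_,
    domains = IRanges::CharacterList(list(character())),
    protein = NA_character_)
  el@features <- cover
  expect_length(findSmallOrfs(el), 0)
})

test_that("detection is idempotent on an extracted element", {
  g <- generateGenome(simulationConfig(seed = 24), 1)
  el <- detectElements(g$genome, model, fisReferenceProtein())$elements[[1]]
  f <- features(el)
  gr <- GRanges("element", ranges(f), strand = strand(f))
  mcols(gr) <- mcols(f)[c("gene_id", "product", "domains", "protein")]
  eg <- annotatedGenome("element_only",
                        c(element = elementSeq(el)), gr)
  again <- scanGenome(eg, model)
  expect_length(again, 1)
})

test_that("multiple retained elements warn and are ranked by span", {
  g1 <- generateGenome(simulationConfig(seed = 25), 1)
  # duplicate the element contig under another name
  ctg <- contigs(g1$genome)
  f <- features(g1$genome)
  dup <- c(as.character(ctg), dup_chrom = as.character(ctg[["chrom"]]))
  f2 <- GRanges("dup_chrom", ranges(f), strand = strand(f))
  mc <- mcols(f)
  mc$gene_id <- paste0("dup_", mc$gene_id)
  mcols(f2) <- mc
  g2 <- annotatedGenome("two_elements", dup, suppressWarnings(c(f, f2)))
  expect_warning(res <- detectElements(g2, model, fisReferenceProtein()),
                 "more than one")
  expect_length(res$elements, 2)
})
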