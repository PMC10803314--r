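# Internal helpers shared across modules.

#' @importFrom methods new is slot validObject
#' @importFrom stats setNames
NULL

## Pfam accessions arrive with or without version suffixes ("PF00589.25" vs
## "PF00589") and in mixed case; all label comparison happens on this
## normalized form.
normalizeDomainLabel <- function(x) {
  sub("\\.[0-9]+$", "", toupper(trimws(x)))
}

## Run `expr` under a fixed RNG state, restoring the caller's stream.
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(expr)
}

randomDna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

## Random open reading frame of `nt` nucleotides (multiple of 3, >= 9):
## ATG start, no internal stop, TGA stop.
randomOrf <- function(nt) {
  stopifnot(nt %% 3 == 0, nt >= 9)
  ncod <- nt / 3 - 2
  bases <- c("A", "C", "G", "T")
  codons <- character(0)
  if (ncod > 0) {
    codons <- paste0(sample(bases, ncod, TRUE), sample(bases, ncod, TRUE),
                     sample(bases, ncod, TRUE))
    bad <- which(codons %in% c("TAA", "TAG", "TGA"))
    while (length(bad)) {
      codons[bad] <- paste0(sample(bases, length(bad), TRUE),
                            sample(bases, length(bad), TRUE),
                            sample(bases, length(bad), TRUE))
      bad <- bad[codons[bad] %in% c("TAA", "TAG", "TGA")]
    }
  }
  paste0("ATG", paste(codons, collapse = ""), "TGA")
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

translateDna <- function(x) {
  n <- nchar(x) - nchar(x) %% 3
  if (n < 3) return("")
  cod <- substring(x, seq(1L, n, 3L), seq(3L, n, 3L))
  aa <- unname(Biostrings::GENETIC_CODE[cod])
  aa[is.na(aa)] <- "X"   # ambiguous codons (N runs)
  sub("\\*$", "", paste(aa, collapse = ""))
}

## Identity of a pairwise alignment as matches / alignment columns, gaps
## counted in the denominator (end-to-end for global alignments).
alignmentIdentity <- function(aln) {
  p <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  s <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  sum(p == s & p != "-") / length(p)
}

## Global protein identity (BLOSUM62, affine gaps), used by the fis-anchor
## filter and available to tests.
proteinGlobalIdentity <- function(a, b) {
  if (!nzchar(a) || !nzchar(b)) stop("empty protein sequence")
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "global",
    substitutionMatrix = "BLOSUM62", gapOpening = 11, gapExtension = 1)
  alignmentIdentity(aln)
}

## union-find over 1..n, returning component labels
componentsFromEdges <- function(n, edges) {
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (length(edges)) {
    for (e in edges) {
      ri <- find(e[1]); rj <- find(e[2])
      if (ri != rj) parent[ri] <- rj
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}
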