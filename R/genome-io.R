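#' @include AllClasses.R AllGenerics.R
NULL

#' Construct an AnnotatedGenome
#'
#' @param genomeId genome identifier
#' @param contigs named \code{DNAStringSet} (or named character vector)
#' @param features \code{GRanges} with metadata columns \code{gene_id},
#'   \code{product}, \code{domains} (CharacterList of domain accessions) and
#'   \code{protein}; missing columns are filled with empties. Features are
#'   sorted by (contig, start) on construction.
#' @return validated \code{AnnotatedGenome}
#' @export
annotatedGenome <- function(genomeId, contigs, features = GenomicRanges::GRanges()) {
  if (!is(contigs, "DNAStringSet")) contigs <- Biostrings::DNAStringSet(contigs)
  contigs <- Biostrings::DNAStringSet(toupper(as.character(contigs)))
  mc <- GenomicRanges::mcols(features)
  n <- length(features)
  if (is.null(mc$gene_id)) mc$gene_id <- sprintf("gene_%04d", seq_len(n))
  if (is.null(mc$product)) mc$product <- rep(NA_character_, n)
  if (is.null(mc$domains)) mc$domains <- IRanges::CharacterList(rep(list(character()), n))
  if (!is(mc$domains, "CharacterList")) mc$domains <- IRanges::CharacterList(mc$domains)
  if (is.null(mc$protein)) mc$protein <- rep(NA_character_, n)
  GenomicRanges::mcols(features) <- mc[, c("gene_id", "product", "domains", "protein")]
  if (n) {
    fc <- as.character(GenomicRanges::seqnames(features))
    bad <- setdiff(unique(fc), names(contigs))
    if (length(bad)) {
      feat <- mc$gene_id[match(bad[1], fc)]
      stop("unknown contig ", bad[1], " referenced by feature ", feat)
    }
    features <- features[order(match(fc, names(contigs)),
                               GenomicRanges::start(features))]
  }
  new("AnnotatedGenome", genomeId = genomeId, contigs = contigs,
      features = features)
}

## Scan raw GFF3 lines so malformed rows are reported with their line number
## before handing the file to rtracklayer.
checkGffLines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  inFasta <- FALSE
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (startsWith(ln, "##FASTA")) inFasta <- TRUE
    if (inFasta || !nzchar(ln) || startsWith(ln, "#")) next
    if (length(strsplit(ln, "\t", fixed = TRUE)[[1]]) != 9L)
      stop("unparseable GFF line ", i, " in ", path, ": expected 9 fields")
  }
  invisible(TRUE)
}

#' Read an annotated genome from FASTA + GFF3
#'
#' Contig sequences come from the FASTA; gene features from the GFF3 (1-based
#' inclusive coordinates, kept as such in the returned \code{GRanges}). Domain
#' labels are collected from \code{Dbxref} entries prefixed \code{Pfam:} plus a
#' configurable plain attribute (default \code{domain}); Pfam version suffixes
#' are retained verbatim but all matching in the detection model ignores them.
#'
#' @param fastaPath path to contig FASTA
#' @param gffPath path to GFF3 annotation (feature types \code{gene}/\code{CDS})
#' @param genomeId genome id; defaults to the FASTA basename
#' @param domainAttr GFF3 attribute holding additional domain labels
#' @param proteinPath optional protein FASTA named by gene_id
#' @return \code{AnnotatedGenome}
#' @examples
#' d <- tempfile(); dir.create(d)
#' g <- generateGenome(simulationConfig(seed = 1))$genome
#' p <- writeAnnotatedGenome(g, file.path(d, "g.fasta"), file.path(d, "g.gff3"))
#' readAnnotatedGenome(p["fasta"], p["gff"])
#' @export
readAnnotatedGenome <- function(fastaPath, gffPath, genomeId = NULL,
                                domainAttr = "domain", proteinPath = NULL) {
  if (!file.exists(fastaPath)) stop("missing FASTA: ", fastaPath)
  if (!file.exists(gffPath)) stop("missing GFF3: ", gffPath)
  contigs <- Biostrings::readDNAStringSet(fastaPath)
  names(contigs) <- sub("\\s.*$", "", names(contigs))
  checkGffLines(gffPath)
  gr <- rtracklayer::import(gffPath, format = "gff3")
  gr <- gr[as.character(gr$type) %in% c("gene", "CDS", "ORF")]
  mc <- GenomicRanges::mcols(gr)
  gid <- if (!is.null(mc$ID)) as.character(mc$ID) else sprintf("gene_%04d", seq_along(gr))
  asChr <- function(x, n) {
    if (is.null(x)) return(rep(NA_character_, n))
    vapply(as.list(x), function(v) {
      v <- as.character(v)
      if (!length(v) || all(is.na(v))) NA_character_ else v[1]
    }, character(1))
  }
  product <- asChr(mc$product, length(gr))
  doms <- rep(list(character()), length(gr))
  if (!is.null(mc$Dbxref)) {
    dbx <- as.list(mc$Dbxref)
    doms <- lapply(dbx, function(v) {
      v <- as.character(v)
      sub("^Pfam:", "", v[grepl("^Pfam:", v, ignore.case = TRUE)], ignore.case = TRUE)
    })
  }
  if (!is.null(mc[[domainAttr]])) {
    extra <- lapply(as.list(mc[[domainAttr]]), function(v) {
      v <- as.character(v)
      v[!is.na(v) & nzchar(v)]
    })
    doms <- mapply(function(a, b) unique(c(a, b)), doms, extra, SIMPLIFY = FALSE)
  }
  protein <- asChr(mc$protein, length(gr))
  if (!is.null(proteinPath)) {
    aa <- Biostrings::readAAStringSet(proteinPath)
    names(aa) <- sub("\\s.*$", "", names(aa))
    hit <- match(gid, names(aa))
    protein <- ifelse(is.na(hit), protein, as.character(aa)[hit])
  }
  out <- GenomicRanges::GRanges(
    seqnames = as.character(GenomicRanges::seqnames(gr)),
    ranges = IRanges::IRanges(GenomicRanges::start(gr), GenomicRanges::end(gr)),
    strand = ifelse(as.character(GenomicRanges::strand(gr)) == "-", "-", "+"))
  GenomicRanges::mcols(out) <- S4Vectors::DataFrame(
    gene_id = gid, product = product,
    domains = IRanges::CharacterList(doms), protein = protein)
  if (is.null(genomeId))
    genomeId <- sub("\\.(fa|fna|fasta)$", "", basename(fastaPath))
  annotatedGenome(genomeId, contigs, out)
}

## Deterministic GFF3 feature line: fixed column, attribute order and
## formatting so that read-then-write round-trips byte-identically.
gffFeatureLines <- function(gr, source = "picmiscan", type = "gene") {
  mc <- GenomicRanges::mcols(gr)
  vapply(seq_along(gr), function(i) {
    attrs <- paste0("ID=", mc$gene_id[i])
    if (!is.na(mc$product[i]) && nzchar(mc$product[i]))
      attrs <- paste0(attrs, ";product=", mc$product[i])
    d <- mc$domains[[i]]
    if (length(d))
      attrs <- paste0(attrs, ";domain=", paste(sort(d), collapse = ","))
    if (!is.null(mc$protein) && !is.na(mc$protein[i]) && nzchar(mc$protein[i]))
      attrs <- paste0(attrs, ";protein=", mc$protein[i])
    paste(as.character(GenomicRanges::seqnames(gr))[i], source, type,
          GenomicRanges::start(gr)[i], GenomicRanges::end(gr)[i], ".",
          as.character(GenomicRanges::strand(gr))[i], ".", attrs, sep = "\t")
  }, character(1))
}

#' Write an AnnotatedGenome to FASTA + GFF3
#'
#' @param genome \code{AnnotatedGenome}
#' @param fastaPath,gffPath output paths
#' @return named character vector of the written paths
#' @export
writeAnnotatedGenome <- function(genome, fastaPath, gffPath) {
  Biostrings::writeXStringSet(contigs(genome), fastaPath)
  writeLines(c("##gff-version 3", gffFeatureLines(features(genome))), gffPath)
  c(fasta = fastaPath, gff = gffPath)
}

#' Write detected elements to FASTA / GFF3 / TSV
#'
#' Emits one multi-FASTA of element sequences (fis-forward orientation), one
#' GFF3 of element-internal features in element coordinates, and one TSV
#' summary row per element.
#'
#' @param elements list of \code{PicmiElement}
#' @param outDir output directory (created if needed)
#' @return named character vector of the written paths
#' @export
writeElements <- function(elements, outDir) {
  if (!dir.exists(outDir) &&
      !dir.create(outDir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory ", outDir)
  ids <- make.unique(vapply(elements, function(e) e@candidate@genomeId,
                            character(1)), sep = "_")
  fa <- file.path(outDir, "elements.fasta")
  gff <- file.path(outDir, "elements.gff3")
  tsv <- file.path(outDir, "elements.tsv")
  seqs <- Biostrings::DNAStringSet(vapply(elements, elementSeq, character(1)))
  names(seqs) <- ids
  Biostrings::writeXStringSet(seqs, fa)
  lines <- "##gff-version 3"
  for (i in seq_along(elements)) {
    f <- elements[[i]]@features
    if (length(f)) {
      f <- GenomicRanges::GRanges(rep(ids[i], length(f)), IRanges::ranges(f),
                                  strand = GenomicRanges::strand(f))
      GenomicRanges::mcols(f) <- GenomicRanges::mcols(elements[[i]]@features)
      lines <- c(lines, gffFeatureLines(f))
    }
  }
  writeLines(lines, gff)
  rows <- lapply(seq_along(elements), function(i) {
    e <- elements[[i]]
    data.frame(element_id = ids[i], genome_id = e@candidate@genomeId,
               contig = e@candidate@contigId, start = e@elementStart,
               end = e@elementEnd, orientation = e@orientation,
               length = nchar(e@elementSeq),
               repeat_len = if (is.null(e@repeatPair)) 0L else e@repeatPair@length,
               repeat_seq = if (is.null(e@repeatPair)) "" else e@repeatPair@seq,
               n_genes = length(e@features),
               stringsAsFactors = FALSE)
  })
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(element_id = character(), genome_id = character(),
               contig = character(), start = integer(), end = integer(),
               orientation = character(), length = integer(),
               repeat_len = integer(), repeat_seq = character(),
               n_genes = integer(), stringsAsFactors = FALSE)
  utils::write.table(tab, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  c(fasta = fa, gff = gff, tsv = tsv)
}
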