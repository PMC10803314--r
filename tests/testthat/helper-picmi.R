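# Fixture builders and independent oracles used across the suite.

suppressPackageStartupMessages({
  library(Biostrings)
  library(GenomicRanges)
  library(IRanges)
})

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")

# Tiny genome builder: genes described as list(role=..., domains=..., len=...)
# laid out left to right with `gap_bp` of random sequence between them.
tiny_genome <- function(genes, gap_bp = 30, id = "tiny", pad = 100) {
  parts <- list(rand_dna(pad))
  pos <- pad + 1L
  rows <- list()
  for (k in seq_along(genes)) {
    g <- genes[[k]]
    len <- if (is.null(g$len)) 90L else g$len
    seqg <- rand_dna(len)
    rows[[k]] <- data.frame(
      gene_id = if (is.null(g$id)) sprintf("g%02d", k) else g$id,
      start = pos, end = pos + len - 1L,
      strand = if (is.null(g$strand)) "+" else g$strand,
      product = if (is.null(g$product)) NA_character_ else g$product,
      stringsAsFactors = FALSE)
    rows[[k]]$domains <- I(list(if (is.null(g$domains)) character() else g$domains))
    parts[[length(parts) + 1L]] <- seqg
    parts[[length(parts) + 1L]] <- rand_dna(gap_bp)
    pos <- pos + len + gap_bp
  }
  tab <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges("c1", IRanges::IRanges(tab$start, tab$end), strand = tab$strand)
  GenomicRanges::mcols(gr) <- S4Vectors::DataFrame(
    gene_id = tab$gene_id, product = tab$product,
    domains = IRanges::CharacterList(tab$domains),
    protein = rep(NA_character_, nrow(tab)))
  annotatedGenome(id, c(c1 = paste(unlist(parts), collapse = "")), gr)
}

# Oracle 1: quadratic window enumeration for the co-localization scan.
# A locus is every maximal run of role-bearing genes in which consecutive
# role-bearing genes are separated by at most `gap` intervening genes; it is
# reported when all mandatory roles occur inside it.
oracle_scan_spans <- function(genome, model = picmiModel()) {
  f <- features(genome)
  mand <- c("int", "alpA", "prim",
            if (model@fisPolicy == "mandatory") "fis")
  dom_sets <- list(int = model@integraseDomains, alpA = model@alpaDomains,
                   prim = model@primaseDomains, fis = model@fisDomains)
  dom_sets <- lapply(dom_sets, function(d) sub("\\.[0-9]+$", "", toupper(d)))
  out <- list()
  for (ct in names(contigs(genome))) {
    idx <- which(as.character(GenomicRanges::seqnames(f)) == ct)
    if (!length(idx)) next
    role <- vapply(idx, function(i) {
      d <- sub("\\.[0-9]+$", "", toupper(GenomicRanges::mcols(f)$domains[[i]]))
      for (r in names(dom_sets)) if (any(d %in% dom_sets[[r]])) return(r)
      NA_character_
    }, character(1))
    core <- which(!is.na(role))
    if (!length(core)) next
    # maximal runs via explicit O(n^2) pair checking
    linked <- matrix(FALSE, length(core), length(core))
    for (a in seq_along(core)) for (b in seq_along(core))
      linked[a, b] <- abs(core[a] - core[b]) - 1L <= model@maxGeneGap
    grp <- rep(NA_integer_, length(core)); gcur <- 0L
    for (a in seq_along(core)) {
      if (a == 1L || !linked[a - 1L, a]) gcur <- gcur + 1L
      grp[a] <- gcur
    }
    for (g in unique(grp)) {
      members <- core[grp == g]
      if (all(mand %in% role[members])) {
        # closest-packed role assignment: enumerate all combinations
        roles_here <- intersect(c("int", "alpA", "prim", "fis"),
                                unique(role[members]))
        cand_sets <- lapply(roles_here, function(r) members[role[members] == r])
        combos <- expand.grid(cand_sets)
        best <- Inf; best_span <- NULL
        for (ri in seq_len(nrow(combos))) {
          sel <- idx[as.integer(combos[ri, ])]
          sp <- c(min(GenomicRanges::start(f)[sel]), max(GenomicRanges::end(f)[sel]))
          if (diff(sp) < best) { best <- diff(sp); best_span <- sp }
        }
        out[[length(out) + 1L]] <- list(contig = ct, span = best_span)
      }
    }
  }
  out
}

# Oracle 2: brute-force longest common substring over all substring pairs.
oracle_lcs <- function(a, b, min_len) {
  best <- NULL
  na <- nchar(a); nb <- nchar(b)
  for (L in seq(min(na, nb), min_len)) {
    for (i in seq_len(na - L + 1L)) {
      sub_a <- substring(a, i, i + L - 1L)
      for (j in seq_len(nb - L + 1L)) {
        if (sub_a == substring(b, j, j + L - 1L)) {
          if (is.null(best) || L > best$len) best <- list(len = L, seq = sub_a)
        }
      }
    }
    if (!is.null(best)) return(best)
  }
  best
}

# Oracle 3: brute-force six-frame ORF scan, each ATG paired with its nearest
# in-frame stop; returns aa lengths and forward-strand coordinates.
oracle_orfs <- function(seqf, min_aa, max_aa) {
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seqf)))
  L <- nchar(seqf)
  res <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seqf else rc
    for (off in 0:2) {
      i <- off + 1L
      while (i + 5L <= nchar(s)) {
        if (substring(s, i, i + 2L) == "ATG") {
          j <- i + 3L
          while (j + 2L <= nchar(s) &&
                 !substring(s, j, j + 2L) %in% c("TAA", "TAG", "TGA")) j <- j + 3L
          if (j + 2L <= nchar(s)) {
            aa <- (j - i) / 3
            if (aa >= min_aa && aa < max_aa) {
              st <- i; en <- j + 2L
              if (strand == "-") { tmp <- st; st <- L - en + 1L; en <- L - tmp + 1L }
              res[[length(res) + 1L]] <- data.frame(start = st, end = en,
                                                    strand = strand, aa = aa)
            }
          }
        }
        i <- i + 3L
      }
    }
  }
  if (!length(res)) return(NULL)
  tab <- do.call(rbind, res)
  tab[order(tab$start, tab$end), , drop = FALSE]
}

# Oracle 4: connected components at a threshold via boolean reachability
# (transitive closure), independent of the package's union-find.
oracle_components <- function(idm, thr, strict = FALSE) {
  n <- nrow(idm)
  adj <- if (strict) idm > thr else idm >= thr
  diag(adj) <- TRUE
  reach <- adj
  for (k in seq_len(n)) reach <- reach | (reach %*% reach) > 0
  labels <- integer(n)
  nxt <- 0L
  for (i in seq_len(n)) {
    if (labels[i] == 0L) {
      nxt <- nxt + 1L
      labels[reach[i, ]] <- nxt
    }
  }
  labels
}

# Partition comparison up to label renaming.
same_partition <- function(a, b) {
  identical(as.integer(factor(a, levels = unique(a))),
            as.integer(factor(b, levels = unique(b))))
}

# Oracle 5: brute-force reciprocal best hit with the same alignment engine
# but independent looping/tie-break code.
oracle_rbh <- function(proteomes, min_id = 0.20, min_cov = 0.50) {
  pid <- unlist(lapply(proteomes, names))
  prot <- unlist(unname(proteomes)); names(prot) <- pid
  member <- rep(names(proteomes), lengths(proteomes)); names(member) <- pid
  hit <- function(q, t) {
    aln <- Biostrings::pairwiseAlignment(Biostrings::AAString(prot[[q]]), Biostrings::AAString(prot[[t]]),
                             type = "local", substitutionMatrix = "BLOSUM62",
                             gapOpening = 11, gapExtension = 1)
    p <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
    s <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
    idv <- if (length(p)) sum(p == s & p != "-") / length(p) else 0
    list(score = Biostrings::score(aln), id = idv,
         covq = sum(p != "-") / nchar(prot[[q]]),
         covt = sum(s != "-") / nchar(prot[[t]]))
  }
  best_of <- function(q, tp) {
    cand <- NULL
    for (t in sort(names(proteomes[[tp]]))) {
      h <- hit(q, t)
      if (h$id < min_id || h$covq < min_cov || h$covt < min_cov) next
      if (is.null(cand) || h$score > cand$h$score ||
          (h$score == cand$h$score &&
           (h$id > cand$h$id || (h$id == cand$h$id && t < cand$t))))
        cand <- list(t = t, h = h)
    }
    if (is.null(cand)) NA_character_ else cand$t
  }
  pairs <- list()
  for (q in pid) for (tp in names(proteomes)) {
    if (member[[q]] == tp) next
    t <- best_of(q, tp)
    if (!is.na(t) && identical(best_of(t, member[[q]]), q) && q < t)
      pairs[[length(pairs) + 1L]] <- c(q, t)
  }
  # connected components over the RBH graph
  lbl <- seq_along(pid); names(lbl) <- pid
  repeat {
    changed <- FALSE
    for (e in pairs) {
      m <- min(lbl[e]); if (any(lbl[e] != m)) { lbl[e] <- m; changed <- TRUE }
      # propagate
      for (e2 in pairs) lbl[e2] <- min(lbl[e2])
    }
    if (!changed) break
  }
  split(names(lbl), lbl)
}

# Random mutated protein at roughly the requested identity.
mutate_protein <- function(p, divergence) {
  aa <- strsplit(p, "")[[1]]
  alphabet <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  k <- round(divergence * length(aa))
  pos <- sample(seq_along(aa), k)
  for (i in pos) aa[i] <- sample(setdiff(alphabet, aa[i]), 1)
  paste(aa, collapse = "")
}

rand_protein <- function(n) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n, TRUE),
        collapse = "")
}
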