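test_that("pairwise identity handles exact copies and pure substitutions", {
  set.seed(31)
  a <- rand_dna(1000)
  expect_equal(pairwiseIdentity(a, a), 1.0)
  # 50 substitutions, no indels: the optimal alignment is gap-free,
  # so identity is exactly 950/1000
  s <- strsplit(a, "")[[1]]
  pos <- sample(1000, 50)
  for (p in pos) s[p] <- sample(setdiff(c("A", "C", "G", "T"), s[p]), 1)
  b <- paste(s, collapse = "")
  expect_equal(pairwiseIdentity(a, b), 0.95, tolerance = 1e-12)
  expect_error(pairwiseIdentity("", a), "empty")
})

test_that("pairwise identity is symmetric", {
  for (seed in 1:5) {
    set.seed(seed)
    a <- rand_dna(sample(200:400, 1))
    b <- mutateElement(a, runif(1, 0.02, 0.3), seed = seed)$seq
    expect_equal(pairwiseIdentity(a, b), pairwiseIdentity(b, a),
                 tolerance = 1e-12)
  }
})

test_that("subfamily partition follows the identity graph", {
  idm <- matrix(c(1, 0.95, 0.80,
                  0.95, 1, 0.80,
                  0.80, 0.80, 1), 3, 3,
                dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  sf <- clusterSubfamilies(c(A = "ACGT", B = "ACGT", C = "ACGT"),
                           identity = idm)
  expect_equal(unname(subfamilies(sf)[c("A", "B")]), c(1, 1))
  expect_equal(unname(subfamilies(sf)["C"]), 2)

  n <- 4
  sf2 <- clusterSubfamilies(setNames(rep("ACGTACGT", n), paste0("e", 1:n)))
  expect_equal(length(unique(subfamilies(sf2))), 1)
})

test_that("clustering equals the reachability oracle for n <= 8", {
  for (seed in 1:10) {
    set.seed(seed * 13)
    n <- sample(3:8, 1)
    idm <- matrix(runif(n * n, 0.6, 1), n, n)
    idm[lower.tri(idm)] <- t(idm)[lower.tri(idm)]
    diag(idm) <- 1
    ids <- paste0("e", seq_len(n))
    dimnames(idm) <- list(ids, ids)
    sf <- clusterSubfamilies(setNames(rep("A", n), ids), identity = idm,
                             identityThreshold = 0.9)
    expect_true(same_partition(subfamilies(sf),
                               oracle_components(idm, 0.9)))
  }
})

test_that("raising the threshold only refines the partition", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- 7
    idm <- matrix(runif(n * n, 0.7, 1), n, n)
    idm[lower.tri(idm)] <- t(idm)[lower.tri(idm)]
    diag(idm) <- 1
    ids <- paste0("e", 1:n); dimnames(idm) <- list(ids, ids)
    lo <- subfamilies(clusterSubfamilies(setNames(rep("A", n), ids),
                                         identity = idm,
                                         identityThreshold = 0.85))
    hi <- subfamilies(clusterSubfamilies(setNames(rep("A", n), ids),
                                         identity = idm,
                                         identityThreshold = 0.95))
    # every high-threshold cluster sits inside one low-threshold cluster
    for (cl in unique(hi))
      expect_length(unique(lo[names(hi)[hi == cl]]), 1)
  }
})

test_that("complete linkage breaks identity chains that single linkage keeps", {
  idm <- matrix(c(1, 0.95, 0.50,
                  0.95, 1, 0.95,
                  0.50, 0.95, 1), 3, 3,
                dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  seqs <- c(A = "ACGT", B = "ACGT", C = "ACGT")
  single <- clusterSubfamilies(seqs, identity = idm, linkage = "single")
  complete <- clusterSubfamilies(seqs, identity = idm, linkage = "complete")
  expect_equal(length(unique(subfamilies(single))), 1)
  expect_gt(length(unique(subfamilies(complete))), 1)
})

test_that("divergence straddling the threshold splits or merges as planted", {
  base <- withr::with_seed(33, rand_dna(2000))
  near <- mutateElement(base, 0.03, seed = 1, indelFraction = 0)$seq
  far <- mutateElement(base, 0.20, seed = 2, indelFraction = 0)$seq
  sf <- clusterSubfamilies(c(base = base, near = near, far = far),
                           identityThreshold = 0.90)
  a <- subfamilies(sf)
  expect_equal(a[["base"]], a[["near"]])
  expect_false(a[["base"]] == a[["far"]])
})

test_that("RBH families pair planted orthologs and respect the floors", {
  set.seed(41)
  pa <- setNames(lapply(1:4, function(i) rand_protein(120)),
                 paste0("A_p", 1:4))
  pb <- setNames(lapply(names(pa), function(n)
    mutate_protein(pa[[n]], 0.40)), paste0("B_p", 1:4))
  proteomes <- list(A = unlist(pa), B = unlist(pb))
  fam <- rbhGeneFamilies(proteomes)
  for (i in 1:4)
    expect_equal(fam[[paste0("A_p", i)]], fam[[paste0("B_p", i)]])
  expect_equal(length(unique(fam)), 4)

  # single proteome: all singletons
  fam1 <- rbhGeneFamilies(list(A = unlist(pa)))
  expect_equal(length(unique(fam1)), 4)

  # unrelated proteins fail the identity/coverage floors and stay singletons
  set.seed(42)
  px <- list(A = c(A_x = rand_protein(150)), B = c(B_y = rand_protein(150)))
  famx <- rbhGeneFamilies(px)
  expect_equal(length(unique(famx)), 2)
})

test_that("RBH agrees with the brute-force oracle and ignores input order", {
  for (seed in 1:4) {
    set.seed(seed * 11)
    base <- lapply(1:3, function(i) rand_protein(sample(90:140, 1)))
    pa <- setNames(unlist(base), paste0("A_p", 1:3))
    pb <- setNames(vapply(base, function(p) mutate_protein(p, 0.35),
                          character(1)), paste0("B_p", 1:3))
    # one extra unpairable protein per proteome
    pa <- c(pa, A_solo = rand_protein(100))
    pb <- c(pb, B_solo = rand_protein(100))
    proteomes <- list(A = pa, B = pb)
    fam <- rbhGeneFamilies(proteomes)
    want <- oracle_rbh(lapply(proteomes, as.list))
    got <- split(names(fam), fam)
    expect_setequal(unname(lapply(got, sort)), unname(lapply(want, sort)))

    shuffled <- list(B = pb[sample(length(pb))], A = pa[sample(length(pa))])
    fam2 <- rbhGeneFamilies(shuffled)
    expect_true(same_partition(fam[sort(names(fam))],
                               fam2[sort(names(fam2))]))
  }
})

test_that("int-neighbor typing reads the planted overlap and motif", {
  g <- generateGenome(simulationConfig(seed = 51, iolgOverlapNt = 4), 1)
  el <- detectElements(g$genome, picmiModel(), fisReferenceProtein())$elements[[1]]
  call <- classifyIntNeighbor(el)
  expect_equal(call@category, "iolg")
  expect_equal(call@overlapNt, 4L)
  expect_equal(call@overlapMotif, "ATGA")

  for (ov in c(1L, 13L)) {
    g <- generateGenome(simulationConfig(seed = 51 + ov, iolgOverlapNt = ov), 1)
    el <- detectElements(g$genome, picmiModel(),
                         fisReferenceProtein())$elements[[1]]
    call <- classifyIntNeighbor(el)
    expect_equal(call@category, "iolg")
    expect_equal(call@overlapNt, ov)
    expect_equal(nchar(call@overlapMotif), ov)
  }
})

test_that("contiguous and absent int neighbors are typed icg / absent", {
  g <- generateGenome(simulationConfig(seed = 61, iolgOverlapNt = 0), 1)
  el <- detectElements(g$genome, picmiModel(), fisReferenceProtein())$elements[[1]]
  call <- classifyIntNeighbor(el)
  expect_equal(call@category, "icg")
  expect_equal(call@overlapNt, 0L)
  expect_equal(call@overlapMotif, "")

  cfg <- simulationConfig(seed = 62,
                          geneOrder = c("fis", "up2", "prim", "up1",
                                        "alpA", "int"))
  g <- generateGenome(cfg, 1)
  el <- detectElements(g$genome, picmiModel(), fisReferenceProtein())$elements[[1]]
  expect_equal(classifyIntNeighbor(el)@category, "absent")

  bare <- el
  bare@features <- GRanges()
  expect_error(classifyIntNeighbor(bare), "int and alpA")
})

test_that("core/accessory table counts presence across elements", {
  set.seed(71)
  core1 <- rand_protein(120); core2 <- rand_protein(100)
  proteomes <- list(
    e1 = c(e1_int = core1, e1_alpA = core2, e1_acc = rand_protein(80)),
    e2 = c(e2_int = mutate_protein(core1, 0.2),
           e2_alpA = mutate_protein(core2, 0.2)),
    e3 = c(e3_int = mutate_protein(core1, 0.2),
           e3_alpA = mutate_protein(core2, 0.2),
           e3_only = rand_protein(90)))
  fam <- rbhGeneFamilies(proteomes)
  tab <- coreAccessoryTable(proteomes, fam)
  core_fams <- tab$families$family_id[tab$families$core]
  expect_length(core_fams, 2)
  expect_true(all(tab$families$n_elements[tab$families$core] == 3))
  singles <- tab$families[tab$families$n_proteins == 1, ]
  expect_true(all(singles$n_elements == 1))
  expect_equal(nrow(tab$synteny), 3)
})
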