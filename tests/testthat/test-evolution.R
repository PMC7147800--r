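test_that("pair counts implement pairwise deletion", {
  pc <- pairCounts("ACGT", "ACGT")
  expect_equal(pc$sites, 4)
  expect_equal(sum(diag(pc$counts)), 4)
  expect_equal(pairCounts("A-GT", "ACGT")$sites, 3)
  expect_equal(pairCounts("ANGT", "ACGT")$sites, 3)
  pc2 <- pairCounts("AG", "GA")
  expect_equal(pc2$sites, 2)
  expect_equal(pc2$counts["A", "G"] + pc2$counts["G", "A"], 2L)
  expect_error(pairCounts("ACG", "AC"), "equal length")
})

test_that("degenerate substitution patterns are flagged, not fatal", {
  aln <- Biostrings::DNAStringSet(c(a = "ACGTACGT", b = "ACGTACGT"))
  pat <- estimateSubstitutionPattern(aln)
  expect_true(is.na(tsTvRatio(pat)))
  expect_equal(pat@distance, 0)

  # A<->G differences only: transversion-free alignment -> R = Inf flag
  aln2 <- Biostrings::DNAStringSet(c(a = "AAAAGGGGCCTT", b = "GGAAAGGGCCTT"))
  pat2 <- estimateSubstitutionPattern(aln2)
  expect_true(is.infinite(tsTvRatio(pat2)))
})

test_that("rate percentages sum to 100 and k ratios are recovered", {
  tr <- ape::read.tree(text = "(a:0.1,b:0.1);")
  aln <- evolveAlignment(tr, k1 = 4, k2 = 2, length = 50000, seed = 42)
  pat <- estimateSubstitutionPattern(aln)
  off <- substitutionRates(pat)[row(substitutionRates(pat)) !=
                                  col(substitutionRates(pat))]
  expect_equal(sum(off), 100, tolerance = 1e-6)
  expect_equal(k1(pat), 4, tolerance = 0.4)
  expect_equal(k2(pat), 2, tolerance = 0.2)
  # equal-frequency expectation: R = (k1 + k2) / 4 ... scaled by freqs
  g <- baseFreqs(pat)
  expect_equal(tsTvRatio(pat),
               unname((k1(pat) * g["A"] * g["G"] + k2(pat) * g["C"] * g["T"]) /
                        ((g["A"] + g["G"]) * (g["C"] + g["T"]))))
})

test_that("distances: p-distance formula, TN93 >= p, and ape cross-check", {
  aln <- Biostrings::DNAStringSet(c(a = "AAAA", b = "AAAT", c = "AATT"))
  Dp <- distanceMatrix(aln, model = "p")
  expect_equal(Dp["a", "b"], 0.25)
  expect_equal(diag(Dp), setNames(rep(0, 3), c("a", "b", "c")))

  set.seed(601)
  tr <- ape::read.tree(text = "((a:0.08,b:0.08):0.04,(c:0.08,d:0.08):0.04);")
  aln2 <- evolveAlignment(tr, length = 20000, seed = 602)
  Dp2 <- distanceMatrix(aln2, model = "p")
  Dt2 <- distanceMatrix(aln2, model = "tn93")
  expect_true(all(Dt2 >= Dp2 - 1e-12))
  expect_true(isSymmetric(Dt2))

  # independent implementation: ape::dist.dna TN93
  bin <- ape::as.DNAbin(strsplit(setNames(as.character(aln2),
                                          names(aln2)), ""))
  Dref <- as.matrix(ape::dist.dna(bin, model = "TN93"))
  # (ape pools base frequencies over the whole alignment, we use per-pair
  # frequencies, hence agreement only to ~1e-4)
  expect_equal(Dt2[rownames(Dref), colnames(Dref)], Dref, tolerance = 1e-3)
})

test_that("neighbour joining recovers additive matrices exactly", {
  # worked 4-taxon example: d(A,B)=3, d(A,C)=5, d(A,D)=6, d(B,C)=6,
  # d(B,D)=7, d(C,D)=7 from tree ((A:1,B:2):1,(C:3,D:4))
  D <- matrix(c(0, 3, 5, 6,
                3, 0, 6, 7,
                5, 6, 0, 7,
                6, 7, 7, 0), 4, 4,
              dimnames = list(c("A", "B", "C", "D"), c("A", "B", "C", "D")))
  tr <- njTree(D)
  ref <- ape::read.tree(text = "((A:1,B:2):1,(C:3,D:4):0);")
  expect_phylo_equal(tr, ref)

  # three taxa: unique topology, three-point branch lengths
  D3 <- matrix(c(0, 2, 3, 2, 0, 3, 3, 3, 0), 3, 3,
               dimnames = list(letters[1:3], letters[1:3]))
  t3 <- njTree(D3)
  expect_equal(sort(t3$edge.length), c(1, 1, 2))

  # label permutation equivariance
  perm <- c("C", "A", "D", "B")
  tr2 <- njTree(D[perm, perm])
  expect_phylo_equal(tr, tr2)

  expect_error(njTree(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric|three")

  # random binary trees up to 12 leaves: exact topology + lengths
  set.seed(603)
  for (i in 1:40) {
    tree <- randomBinaryTree(sample(4:12, 1))
    got <- njTree(treeDistances(tree))
    expect_phylo_equal(got, tree, tolerance = 1e-6)
  }
})

test_that("bootstrap support is deterministic and saturates on clean splits", {
  tr <- ape::read.tree(text = "((a:0.02,b:0.02):0.3,(c:0.02,d:0.02):0.3);")
  aln <- evolveAlignment(tr, length = 2000, seed = 7)
  bs <- bootstrapSupport(aln, nReps = 100, seed = 7)
  expect_equal(nrow(bs$splits), 1L)   # single internal split in a quartet
  expect_equal(bs$splits$support, 1)
  bs2 <- bootstrapSupport(aln, nReps = 100, seed = 7)
  expect_identical(bs$splits, bs2$splits)
  bs1 <- bootstrapSupport(aln, nReps = 1, seed = 9)
  expect_true(all(bs1$splits$support %in% c(0, 1)))
})

test_that("LCA reconciliation counts duplications and losses", {
  st <- ape::read.tree(text = "(A,B);")
  gt <- ape::read.tree(text = "(A|g1,B|g1);")
  r <- reconcileTrees(gt, st)
  expect_equal(duplications(r), 0L)
  expect_equal(losses(r), 0L)
  expect_equal(paralogCount(r), 0L)

  gt2 <- ape::read.tree(text = "((A|g1,B|g1),(A|g2,B|g2));")
  r2 <- reconcileTrees(gt2, st)
  expect_equal(duplications(r2), 1L)
  expect_equal(losses(r2), 0L)
  expect_equal(paralogCount(r2), 4L)

  # a lost lineage: ((A,B),A) on (A,B) -> 1 duplication, 1 loss
  gt3 <- ape::read.tree(text = "((A|g1,B|g1),A|g2);")
  r3 <- reconcileTrees(gt3, st)
  expect_equal(duplications(r3), 1L)
  expect_equal(losses(r3), 1L)

  st4 <- ape::read.tree(text = "((A,B),(C,D));")
  gt4 <- ape::read.tree(text = "((A|g1,C|g2),(A|g3,B|g4));")
  expect_equal(losses(reconcileTrees(gt4, st4)), 3L)

  expect_error(reconcileTrees(ape::read.tree(text = "(A|g1,E|g2);"), st),
               "absent")
  expect_error(reconcileTrees(gt, ape::read.tree(text = "(A,B,C);")),
               "rooted|binary")
})

test_that("congruence iff zero duplications (exhaustive small oracle)", {
  set.seed(604)
  for (i in 1:25) {
    st <- randomBinaryTree(sample(3:6, 1))
    # congruent gene tree: one gene per species, same topology
    gt <- st
    gt$tip.label <- paste0(st$tip.label, "|g1")
    r <- reconcileTrees(gt, st)
    expect_equal(duplications(r), 0L)
    expect_equal(losses(r), 0L)
    # duplicated root: two congruent copies -> exactly one duplication
    t1 <- ape::write.tree(gt)
    merged <- ape::read.tree(text = paste0(
      "(", sub(";", "", t1), ",",
      sub(";", "", gsub("\\|g1", "|g2", t1)), ");"))
    expect_equal(duplications(reconcileTrees(merged, st)), 1L)
  }
})

test_that("gene-family generator ground truth matches reconciliation", {
  set.seed(605)
  for (i in 1:30) {
    st <- randomBinaryTree(sample(4:8, 1))
    d <- sample(0:5, 1)
    fam <- makeGeneFamily(st, nDuplications = d, seed = 605 + i)
    expect_equal(fam$truth$duplications, d)
    r <- reconcileTrees(fam$geneTree, st, fam$leafMap)
    expect_equal(duplications(r), d)
    expect_equal(losses(r), 0L)
  }
})

test_that("midpoint rooting never beats the exhaustive best rooting", {
  set.seed(606)
  st <- randomBinaryTree(5)
  for (i in 1:10) {
    fam <- makeGeneFamily(st, nDuplications = sample(1:3, 1), seed = 700 + i)
    # drop root direction, then compare midpoint vs exhaustive search
    un <- ape::unroot(fam$geneTree)
    un$edge.length <- runif(nrow(un$edge), 0.1, 1)
    mid <- phangorn::midpoint(un)
    if (!ape::is.binary(mid)) next
    rMid <- reconcileTrees(mid, st, fam$leafMap)
    best <- minDuplicationRoot(un, st, fam$leafMap)
    expect_gte(duplications(rMid), duplications(best$result))
    expect_lte(duplications(best$result), fam$truth$duplications)
  }
})
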