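test_that("basic clusters are maximal K/R runs", {
  cl <- findBasicClusters("KRPAATKKAGQAKKKK")
  expect_equal(cl$start, c(1L, 7L, 13L))
  expect_equal(cl$end, c(2L, 8L, 16L))
  expect_equal(nrow(findBasicClusters("AAAA")), 0L)
  expect_equal(findBasicClusters("KKKK"),
               data.frame(start = 1L, end = 4L, length = 4L))
})

test_that("taxonomy assigns the documented classes", {
  expect_equal(classifyNls("KKKK"), "mono_I")
  expect_equal(classifyNls(strrep("K", 15)), "mono_I")  # open upper bound
  expect_equal(classifyNls("KKAK"), "mono_II")
  expect_equal(classifyNls("KRPAATKKAGQAKKKK"), "bipartite")
  expect_equal(classifyNls("KKKAAAAAAKKAAAAAAAKKK"), "multipartite")
  expect_equal(classifyNls("KRAWGGAF"), "class_III")
  expect_equal(classifyNls("PGGKRK"), "class_IV")
  expect_equal(classifyNls("AAAAGGGG"), "unclassified")
  expect_warning(cl <- classifyNls("KK"), "shorter")
  expect_equal(cl, "unclassified")
})

test_that("classification is invariant to linker residue identity", {
  set.seed(401)
  nonBasic <- setdiff(AA20, c("K", "R"))
  base <- "KKKAAAAAAKKAAAAAAAKKK"   # all-K clusters: class III/IV need an R
  ref <- classifyNls(base)
  ch <- strsplit(base, "")[[1]]
  linkerPos <- which(!(ch %in% c("K", "R")))
  for (i in 1:50) {
    mut <- ch
    ix <- sample(linkerPos, sample(1:4, 1))
    mut[ix] <- sample(nonBasic, length(ix), replace = TRUE)
    expect_equal(classifyNls(paste(mut, collapse = "")), ref)
  }
  bip <- "KKKAAAAAAAAAAKKK"
  refB <- classifyNls(bip)
  expect_equal(refB, "bipartite")
  chB <- strsplit(bip, "")[[1]]
  for (i in 1:50) {
    mut <- chB
    ix <- sample(4:13, sample(1:4, 1))
    # avoid re-creating a basic residue or a class III/IV consensus core
    mut[ix] <- sample(setdiff(nonBasic, c("P", "W", "F", "Y")), length(ix),
                      replace = TRUE)
    expect_equal(classifyNls(paste(mut, collapse = "")), refB)
  }
})

test_that("linker collapse deletes non-basics, keeps order, idempotent", {
  expect_equal(collapseLinkers("KRPAATKKAGQAKKKK"), "KRKKKKKK")
  expect_equal(collapseLinkers("RKRRK"), "RKRRK")  # fixed point
  set.seed(402)
  for (i in 1:50) {
    s <- randomSeq(sample(5:40, 1))
    expect_equal(collapseLinkers(collapseLinkers(s)), collapseLinkers(s))
    expect_false(grepl("[^KR]", collapseLinkers(s)))
  }
})

test_that("terminal assignment uses the midpoint convention", {
  expect_equal(assignTerminal(5, 15, 100), "N")
  expect_equal(assignTerminal(80, 90, 100), "C")
  expect_equal(assignTerminal(45, 55, 100), "N")  # midpoint exactly half
  expect_error(assignTerminal(90, 110, 100), "outside")
})

test_that("signature census set arithmetic and conservation", {
  calls <- data.frame(signature = c("KKK", "KRK", "KKK"),
                      terminal = c("N", "N", "C"))
  cen <- signatureCensus(calls)
  expect_equal(cen$summary$n_shared, 1)
  expect_equal(cen$summary$n_only_N, 1)
  expect_equal(cen$summary$n_only_C, 0)
  expect_equal(sum(cen$signatures$count_n_terminal) +
                 sum(cen$signatures$count_c_terminal), nrow(calls))

  empty <- signatureCensus(data.frame(signature = character(),
                                      terminal = character()))
  expect_equal(unlist(empty$summary), setNames(rep(0L, 5),
               c("n_unique_N", "n_unique_C", "n_shared", "n_only_N",
                 "n_only_C")))
})

test_that("planted signature multisets are recovered exactly", {
  pr <- makeProteome(proteomeSpec(nNac = 12, nDecoys = 0, seed = 403,
                                  nlsPlan = c(mono_I = 8L, bipartite = 8L,
                                              multipartite = 8L)))
  tr <- pr$truth[pr$truth$feature == "nls", ]
  seqs <- as.character(pr$proteins)
  segs <- substring(seqs[tr$protein_id], tr$start, tr$end)
  planted <- sort(unname(collapseLinkers(segs)))
  lens <- nchar(seqs[tr$protein_id])
  calls <- data.frame(signature = collapseLinkers(segs),
                      terminal = assignTerminal(tr$start, tr$end, lens))
  cen <- signatureCensus(calls)
  got <- rep(cen$signatures$signature,
             cen$signatures$count_n_terminal + cen$signatures$count_c_terminal)
  expect_equal(sort(got), planted)
})

test_that("every planted class is recovered from truth coordinates", {
  pr <- makeProteome(proteomeSpec(
    nNac = 18, nDecoys = 0, seed = 404,
    nlsPlan = c(mono_I = 6L, mono_II = 6L, bipartite = 6L,
                multipartite = 6L, class_III = 6L, class_IV = 6L)))
  tr <- pr$truth[pr$truth$feature == "nls", ]
  seqs <- as.character(pr$proteins)
  segs <- substring(seqs[tr$protein_id], tr$start, tr$end)
  got <- vapply(segs, classifyNls, character(1), USE.NAMES = FALSE)
  expect_equal(got, tr$class)
})
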