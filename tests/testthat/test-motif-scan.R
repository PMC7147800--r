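test_that("pattern compilation handles the grammar and its errors", {
  p <- compilePattern("D-D/E-L-I/V")
  expect_equal(decompilePattern(p), "D-[DE]-L-[IV]")
  expect_identical(compilePattern(decompilePattern(p)), p)
  expect_equal(nrow(scanPattern("DDLI", p)), 1L)
  expect_equal(nrow(scanPattern("DELV", p)), 1L)
  expect_equal(nrow(scanPattern("DALI", p)), 0L)

  expect_equal(scanPattern("KAAK", "K-x(2)-K")[, c("start", "end")],
               data.frame(start = 1L, end = 4L))

  expect_error(compilePattern("K-x(3,2)-K"), "repeat")
  expect_error(compilePattern("K-[]-K"), "malformed|empty")
  expect_error(compilePattern("K-Z"), "unknown residue")
  expect_error(compilePattern("K--K"), "empty")

  # X in the sequence matches fixed elements but not classes
  expect_equal(nrow(scanPattern("XXLI", p)), 0L)  # [DE] not matched by X
  expect_equal(nrow(scanPattern("XDLI", p)), 1L)  # fixed D matched by X
})

test_that("scan placements match the worked examples", {
  h <- scanPattern("AAEWYFFAA", "E-W-Y-F-F")
  expect_equal(h$start, 3L); expect_equal(h$end, 7L)
  h2 <- scanPattern("MMHEYY", "M-H-E-Y")
  expect_equal(h2$start, 2L); expect_equal(h2$end, 5L)
  expect_equal(nrow(scanPattern("AAAA", "E-W-Y-F-F")), 0L)
  expect_error(scanPattern("ACGT-", "E-W"), "non-protein")

  # overlapping vs greedy non-overlapping selection
  ov <- scanPattern("KKKK", "K-K")
  expect_equal(ov$start, 1:3)
  nov <- scanPattern("KKKK", "K-K", overlapping = FALSE)
  expect_equal(nov$start, c(1L, 3L))
})

test_that("engine agrees with the brute-force matcher on random cases", {
  set.seed(101)
  for (i in 1:500) {
    pat <- randomPattern()
    seqlen <- sample(8:40, 1)
    s <- randomSeq(seqlen, alphabet = c(AA20, AA20, "X"))
    eng <- scanPattern(s, pat)
    bf <- bfScan(s, decompilePattern(compilePattern(pat)))
    expect_equal(nrow(eng), nrow(bf), info = paste(pat, s))
    if (nrow(bf)) {
      expect_equal(eng$start, unname(bf[, 1]), info = paste(pat, s))
      expect_equal(eng$end, unname(bf[, 2]), info = paste(pat, s))
    }
  }
})

test_that("NES detection follows the L-V-F-Y consensus and substitutes", {
  expect_equal(detectNes("ALVFYA")[, c("start", "end")],
               data.frame(start = 2L, end = 5L))
  expect_equal(detectNes("ALIFMA")[, c("start", "end")],
               data.frame(start = 2L, end = 5L))
  expect_equal(nrow(detectNes("ALVAYA")), 0L)
})

test_that("domain counting is exact on planted proteomes and shift-invariant", {
  pr <- makeProteome(proteomeSpec(nNac = 8, nDecoys = 0, seed = 31,
                                  domainCountWeights = c(.4, .3, .2, .1)))
  ds <- domainSummary(pr$proteins)
  dtr <- pr$truth[pr$truth$feature == "domain", ]
  planted <- tapply(dtr$protein_id, dtr$protein_id, length)
  called <- ds$nac_domain_count[match(names(planted), ds$protein_id)]
  expect_equal(unname(called), as.vector(planted))
  expect_true(all(ds$is_nac == (ds$nac_domain_count >= 1)))
  expect_true(all(ds$is_multi_domain == (ds$nac_domain_count >= 2)))

  # translation invariance: prepending 50 alanines shifts, never recounts
  s <- as.character(pr$proteins[[1]])
  before <- countNacDomains(s, seqId = "p")$nac_domain_count
  after <- countNacDomains(paste0(strrep("A", 50), s),
                           seqId = "p")$nac_domain_count
  expect_equal(before, after)

  expect_error(countNacDomains("MKV", catalog = nacMotifCatalog()[0, ]),
               "empty")
})

test_that("shuffled decoys almost never produce a domain call", {
  pr <- makeProteome(proteomeSpec(nNac = 2, nDecoys = 0, seed = 13))
  src <- strsplit(as.character(pr$proteins[[1]]), "")[[1]]
  set.seed(77)
  hits <- 0L
  n <- 200L
  for (i in seq_len(n)) {
    shuf <- paste(sample(src), collapse = "")
    if (countNacDomains(shuf, seqId = "d")$nac_domain_count > 0) hits <- hits + 1L
  }
  expect_lte(hits / n, 0.01)
})

test_that("chimeric partner motifs are flagged outside domain instances", {
  pr <- makeProteome(proteomeSpec(nNac = 1, nDecoys = 0, seed = 3,
                                  nlsPlan = c(mono_I = 1L)))
  s <- paste0(as.character(pr$proteins[[1]]), "GGGG", "WRKYGQK", "GGGG")
  d <- countNacDomains(s, seqId = "chim")
  expect_match(d$chimeric_partners, "wrky_core")
  expect_equal(d$nac_domain_count, 1L)
})
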