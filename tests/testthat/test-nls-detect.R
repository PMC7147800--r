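test_that("HmmParams validity catches malformed parameterizations", {
  h <- defaultNlsHmm()
  expect_s4_class(h, "HmmParams")
  bad <- h@transition; bad[1, ] <- c(0.5, 0.6)
  expect_error(HmmParams(h@initial, bad, h@emission), "sum to 1")

  # TSV round trip
  tf <- tempfile(fileext = ".tsv")
  writeHmmParams(h, tf)
  h2 <- readHmmParams(tf)
  expect_equal(h2@initial, h@initial)
  expect_equal(h2@transition, h@transition)
  expect_equal(h2@emission, h@emission)
})

test_that("viterbi respects forced paths and breaks ties toward background", {
  h <- defaultNlsHmm()
  em <- h@emission
  em["BG", "K"] <- 0
  em["BG", ] <- em["BG", ] / sum(em["BG", ])
  forced <- HmmParams(h@initial, h@transition, em)
  expect_equal(viterbiDecode("KKK", forced), rep("NLS", 3),
               ignore_attr = TRUE)

  # uniform emissions + transitions strongly favoring BG -> all BG
  em2 <- h@emission; em2[] <- 1 / 20
  tr2 <- matrix(c(0.99, 0.01, 0.99, 0.01), 2, byrow = TRUE,
                dimnames = dimnames(h@transition))
  lazy <- HmmParams(c(BG = 0.5, NLS = 0.5), tr2, em2)
  expect_equal(viterbiDecode(randomSeq(30), lazy), rep("BG", 30),
               ignore_attr = TRUE)

  # fully symmetric model: ties must resolve to BG
  trS <- matrix(0.5, 2, 2, dimnames = dimnames(h@transition))
  sym <- HmmParams(c(BG = 0.5, NLS = 0.5), trS, em2)
  expect_equal(viterbiDecode("MKV", sym), rep("BG", 3), ignore_attr = TRUE)

  # zero-probability sequence is an explicit error
  em3 <- h@emission; em3[, "W"] <- 0
  em3 <- em3 / rowSums(em3); em3[, "W"] <- 0
  em3 <- em3 / rowSums(em3)
  impossible <- HmmParams(h@initial, h@transition, em3)
  expect_error(viterbiDecode("WWW", impossible), "zero probability")
  expect_error(posteriorDecode("WWW", impossible), "zero probability")
})

test_that("posterior marginals are proper probabilities", {
  h <- defaultNlsHmm()
  em <- h@emission; em[] <- 1 / 20
  one <- HmmParams(c(BG = 0.5, NLS = 0.5),
                   matrix(0.5, 2, 2, dimnames = dimnames(h@transition)), em)
  expect_equal(as.numeric(posteriorDecode("K", one)), 0.5)

  emF <- h@emission; emF["BG", "K"] <- 0
  emF["BG", ] <- emF["BG", ] / sum(emF["BG", ])
  forced <- HmmParams(h@initial, h@transition, emF)
  p <- posteriorDecode("AKAKA", forced)
  expect_equal(as.numeric(p[c(2, 4)]), c(1, 1), tolerance = 1e-12)
})

test_that("viterbi and posterior match exhaustive path enumeration", {
  set.seed(301)
  for (i in 1:60) {
    h <- randomHmm()
    L <- sample(2:8, 1)
    s <- randomSeq(L)
    obs <- strsplit(s, "")[[1]]
    bf <- bfHmm(obs, h@initial, h@transition, h@emission)
    v <- viterbiDecode(s, h)
    expect_equal(attr(v, "logprob"), bf$bestLogProb, tolerance = 1e-9)
    p <- posteriorDecode(s, h)
    expect_equal(as.numeric(p), bf$marginals, tolerance = 1e-9)
    expect_equal(attr(p, "loglik"), bf$loglik, tolerance = 1e-9)
  }
})

test_that("interval calling applies the cutoff, run rule and min length", {
  # posterior vector (0.1,0.5,0.6,0.5,0.5,0.2), cutoff 0.4, min_len 4 -> 2..5
  fake <- c(0.1, 0.5, 0.6, 0.5, 0.5, 0.2)
  mask <- fake >= 0.4
  r <- rle(mask); ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  keep <- r$values & r$lengths >= 4
  expect_equal(c(starts[keep], ends[keep]), c(2, 5))

  # same rule through the real decoder on a planted high-basic segment
  s <- paste0(strrep("A", 20), strrep("K", 10), strrep("A", 20))
  calls <- callNls(s, seqId = "p1")
  expect_equal(nrow(calls), 1L)
  expect_true(calls$start <= 30 && calls$end >= 21)
  expect_true(all(calls$mean_posterior >= 0.4))

  # an extreme cutoff silences near-uniform posteriors
  expect_equal(nrow(callNls(randomSeq(50), cutoff = 0.99)), 0L)
  expect_error(callNls(s, cutoff = 1.5), "cutoff")

  # raising the cutoff never increases total called length
  set.seed(302)
  for (i in 1:20) {
    s <- randomSeq(80, alphabet = c(AA20, "K", "K", "R"))
    lens <- vapply(c(0.2, 0.4, 0.6, 0.8), function(ct) {
      cl <- callNls(s, cutoff = ct)
      if (nrow(cl)) sum(cl$end - cl$start + 1L) else 0L
    }, numeric(1))
    expect_true(all(diff(lens) <= 0))
  }

  # decoding is deterministic (no RNG involved)
  expect_identical(callNls(s), callNls(s))
})

test_that("forward and backward recursions agree on the likelihood", {
  set.seed(303)
  for (i in 1:20) {
    h <- randomHmm()
    s <- randomSeq(sample(5:40, 1))
    p <- posteriorDecode(s, h)
    # backward-only likelihood: P(x) = sum_s pi_s e_s(x1) beta_1(s)
    obs <- strsplit(s, "")[[1]]
    bf <- bfHmm(obs[seq_len(min(8, length(obs)))], h@initial, h@transition,
                h@emission)
    pShort <- posteriorDecode(substr(s, 1, min(8, nchar(s))), h)
    expect_equal(attr(pShort, "loglik"), bf$loglik, tolerance = 1e-9)
    expect_true(all(abs((p + (1 - p)) - 1) < 1e-9))
  }
})
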