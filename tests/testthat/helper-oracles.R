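# Independent oracles used by unit and acceptance tests. Each one is a
# deliberately naive reimplementation, kept structurally different from the
# package code it checks.

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
BASES <- c("A", "C", "G", "T")

## ---- brute-force PROSITE matcher ------------------------------------------

## parse a normalized pattern string into element list (independent parser,
## normalized grammar only: fixed / [..] / {..} / x, optional (n) or (n,m))
bfParse <- function(pat) {
  lapply(strsplit(pat, "-", fixed = TRUE)[[1L]], function(tok) {
    rep <- c(1L, 1L)
    if (grepl("\\(", tok)) {
      inside <- sub("^.*\\(([0-9,]+)\\)$", "\\1", tok)
      nums <- as.integer(strsplit(inside, ",")[[1L]])
      rep <- if (length(nums) == 2L) nums else c(nums, nums)
      tok <- sub("\\(.*$", "", tok)
    }
    if (tok == "x") list(kind = "any", set = NULL, rep = rep)
    else if (grepl("^\\[", tok))
      list(kind = "in", set = strsplit(gsub("\\[|\\]", "", tok), "")[[1L]],
           rep = rep)
    else if (grepl("^\\{", tok))
      list(kind = "notin", set = strsplit(gsub("\\{|\\}", "", tok), "")[[1L]],
           rep = rep)
    else list(kind = "eq", set = tok, rep = rep)
  })
}

bfCharOk <- function(ch, el) {
  switch(el$kind,
         any = TRUE,
         eq = ch == el$set || ch == "X",
         `in` = ch %in% el$set,
         notin = !(ch %in% el$set) && ch != "X")
}

## recursive enumeration: longest match end at position `pos` for elements
## k..K, or -1 when no match. Exponential, fine at test sizes.
bfMatchEnd <- function(chars, els, pos, k = 1L) {
  if (k > length(els)) return(pos - 1L)
  el <- els[[k]]
  best <- -1L
  for (r in el$rep[1L]:el$rep[2L]) {
    if (pos + r - 1L > length(chars)) break
    ok <- r == 0L || all(vapply(seq_len(r), function(i)
      bfCharOk(chars[pos + i - 1L], el), logical(1L)))
    if (!ok) next
    e <- bfMatchEnd(chars, els, pos + r, k + 1L)
    if (e > best) best <- e
  }
  best
}

## all (start, end) hits, longest per start
bfScan <- function(seq, pat) {
  chars <- strsplit(seq, "")[[1L]]
  els <- bfParse(pat)
  out <- NULL
  for (s in seq_along(chars)) {
    e <- bfMatchEnd(chars, els, s)
    if (e >= s) out <- rbind(out, c(s, e))
  }
  if (is.null(out)) matrix(integer(0), ncol = 2) else out
}

## random pattern generator for engine-vs-oracle fuzzing
randomPattern <- function() {
  nEl <- sample(2:5, 1L)
  toks <- vapply(seq_len(nEl), function(i) {
    kind <- sample(c("fixed", "class", "excl", "wild"), 1L,
                   prob = c(0.4, 0.25, 0.1, 0.25))
    tok <- switch(kind,
      fixed = sample(AA20, 1L),
      class = paste0("[", paste(sample(AA20, sample(2:3, 1L)), collapse = ""), "]"),
      excl = paste0("{", paste(sample(AA20, sample(1:2, 1L)), collapse = ""), "}"),
      wild = "x")
    if (runif(1) < 0.3) {
      n <- sample(0:2, 1L); m <- n + sample(0:2, 1L)
      tok <- if (n == m) sprintf("%s(%d)", tok, n)
             else sprintf("%s(%d,%d)", tok, n, m)
    }
    tok
  }, character(1L))
  paste(toks, collapse = "-")
}

## biased random sequence so patterns actually hit sometimes
randomSeq <- function(len, alphabet = AA20) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

## ---- brute-force HMM by path enumeration ----------------------------------

## joint probability of every state path for a 2-state HMM; returns
## list(bestLogProb, marginals (P(state2) per position))
bfHmm <- function(obs, initial, transition, emission) {
  L <- length(obs)
  paths <- as.matrix(expand.grid(rep(list(1:2), L)))
  probs <- apply(paths, 1L, function(st) {
    p <- initial[st[1L]] * emission[st[1L], obs[1L]]
    if (L > 1L) for (t in 2:L)
      p <- p * transition[st[t - 1L], st[t]] * emission[st[t], obs[t]]
    p
  })
  tot <- sum(probs)
  marg <- vapply(seq_len(L), function(t)
    sum(probs[paths[, t] == 2L]) / tot, numeric(1L))
  list(bestLogProb = log(max(probs)), marginals = marg, loglik = log(tot))
}

## random valid HmmParams
randomHmm <- function() {
  ini <- runif(2); ini <- ini / sum(ini)
  tr <- matrix(runif(4), 2); tr <- tr / rowSums(tr)
  em <- matrix(runif(40), 2); em <- em / rowSums(em)
  dimnames(tr) <- list(c("BG", "NLS"), c("BG", "NLS"))
  dimnames(em) <- list(c("BG", "NLS"), AA20)
  HmmParams(setNames(ini, c("BG", "NLS")), tr, em)
}

## ---- pI grid oracle -------------------------------------------------------

## argmin |netCharge| on a 1e-4 pH grid; two-stage (coarse then fine) is
## exact because the charge is strictly decreasing, so |charge| is unimodal.
gridPi <- function(seq) {
  coarse <- seq(0, 14, by = 0.01)
  qc <- abs(netCharge(seq, coarse))
  c0 <- coarse[which.min(qc)]
  fine <- seq(max(0, c0 - 0.02), min(14, c0 + 0.02), by = 1e-4)
  fine[which.min(abs(netCharge(seq, fine)))]
}

## ---- misc -----------------------------------------------------------------

## random rooted binary tree with branch lengths (own construction, not
## ape::rtree, so tree-shape conventions stay independent)
randomBinaryTree <- function(n, minLen = 0.1, maxLen = 2) {
  labs <- paste0("t", seq_len(n))
  nodes <- as.list(labs)
  while (length(nodes) > 1L) {
    ix <- sample.int(length(nodes), 2L)
    merged <- sprintf("(%s:%s,%s:%s)",
                      nodes[[ix[1L]]], format(runif(1, minLen, maxLen), digits = 6),
                      nodes[[ix[2L]]], format(runif(1, minLen, maxLen), digits = 6))
    nodes <- c(nodes[-ix], list(merged))
  }
  ape::read.tree(text = paste0(nodes[[1L]], ";"))
}

## tip-to-tip path distances of a phylo (independent of package code)
treeDistances <- function(tree) {
  m <- ape::cophenetic.phylo(tree)
  m[order(rownames(m)), order(colnames(m))]
}

expect_phylo_equal <- function(a, b, tolerance = 1e-8) {
  expect_equal(phangorn::RF.dist(ape::unroot(a), ape::unroot(b)), 0)
  expect_equal(treeDistances(a), treeDistances(b), tolerance = tolerance)
}
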