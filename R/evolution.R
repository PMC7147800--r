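# Tamura-Nei (TN93) substitution-pattern estimation, distances,
# neighbour-joining with bootstrap, and LCA reconciliation.

## ---- pair counts ----------------------------------------------------------

#' Aligned pair counts with pairwise deletion
#'
#' Tallies aligned base pairs between two equal-length aligned DNA
#' sequences, excluding every column where either sequence carries a gap
#' or an ambiguous base (pairwise deletion).
#'
#' @param a,b aligned DNA sequences (character or `DNAString`), equal
#'   length.
#' @return list with `sites` (comparable sites), `counts` (4x4 matrix,
#'   rows = base in `a`, cols = base in `b`) and `freqs` (pooled base
#'   frequencies over the comparable columns).
#' @examples
#' pairCounts("A-GT", "ACGT")$sites  # 3
#' @export
pairCounts <- function(a, b) {
  sa <- .asSeqString(a); sb <- .asSeqString(b)
  if (nchar(sa) != nchar(sb))
    stop("aligned sequences must have equal length")
  ca <- .splitChars(sa); cb <- .splitChars(sb)
  ok <- ca %in% .BASES & cb %in% .BASES
  ca <- factor(ca[ok], levels = .BASES)
  cb <- factor(cb[ok], levels = .BASES)
  counts <- table(ca, cb)
  counts <- matrix(as.integer(counts), 4, 4, dimnames = list(.BASES, .BASES))
  tot <- sum(counts)
  freqs <- if (tot) (rowSums(counts) + colSums(counts)) / (2 * tot)
           else setNames(rep(NA_real_, 4), .BASES)
  list(sites = tot, counts = counts, freqs = freqs)
}

## ---- TN93 machinery -------------------------------------------------------

## TN93 transition-probability matrix for branch length t (expected
## substitutions/site), rate ratios k1 (A<->G) and k2 (C<->T) relative to
## the transversion rate, and base frequencies (A,C,G,T). Closed form.
.tn93Pmatrix <- function(t, kk1, kk2, freqs) {
  g <- freqs; names(g) <- .BASES
  gR <- g["A"] + g["G"]; gY <- g["C"] + g["T"]
  # transversion rate beta scaled so mean substitution rate is 1
  mu <- 2 * (kk1 * g["A"] * g["G"] + kk2 * g["C"] * g["T"] + gR * gY)
  beta <- 1 / mu
  a1 <- kk1 * beta; a2 <- kk2 * beta
  e2 <- exp(-beta * t)
  e3 <- exp(-(gR * a1 + gY * beta) * t)
  e4 <- exp(-(gY * a2 + gR * beta) * t)
  P <- matrix(0, 4, 4, dimnames = list(.BASES, .BASES))
  for (i in .BASES) for (j in .BASES) {
    iR <- i %in% c("A", "G"); jR <- j %in% c("A", "G")
    if (iR != jR) {
      P[i, j] <- g[j] * (1 - e2)
    } else if (iR) {
      P[i, j] <- if (i == j) g[j] + g[j] * gY / gR * e2 + (1 - g[j] / gR) * e3
                 else g[j] + g[j] * gY / gR * e2 - (g[j] / gR) * e3
    } else {
      P[i, j] <- if (i == j) g[j] + g[j] * gR / gY * e2 + (1 - g[j] / gY) * e4
                 else g[j] + g[j] * gR / gY * e2 - (g[j] / gY) * e4
    }
  }
  P
}

#' Estimate the pattern of nucleotide substitution (TN93)
#'
#' Pools aligned pair counts over every sequence pair (composite
#' likelihood, pairwise deletion), then fits the TN93 divergence and the
#' purine/pyrimidine transition/transversion rate ratios `k1`, `k2` by
#' maximizing the pooled multinomial likelihood with empirical base
#' frequencies. The substitution-rate table is reported as percentages
#' summing to 100, and the overall transition/transversion bias as
#' `R = (k1 gA gG + k2 gC gT) / (gR gY)`.
#'
#' Zero divergence yields `NA` rates and `R`; an alignment with
#' transitions but no observed transversions reports `R = Inf` rather
#' than failing.
#'
#' @param alignment aligned `DNAStringSet` (>= 2 sequences, equal widths).
#' @return a [SubstitutionPattern-class].
#' @export
estimateSubstitutionPattern <- function(alignment) {
  n <- length(alignment)
  if (n < 2L) stop("need at least two aligned sequences")
  seqs <- as.character(alignment)
  F <- matrix(0, 4, 4, dimnames = list(.BASES, .BASES))
  sites <- 0
  for (i in 1:(n - 1L)) for (j in (i + 1L):n) {
    pc <- pairCounts(seqs[i], seqs[j])
    F <- F + pc$counts
    sites <- sites + pc$sites
  }
  if (sites == 0) stop("no comparable sites after pairwise deletion")
  Fs <- (F + t(F)) / 2  # direction is unidentifiable; symmetrize
  g <- rowSums(Fs) / sum(Fs)
  ndiff <- sum(Fs) - sum(diag(Fs))
  P1 <- (Fs["A", "G"] + Fs["G", "A"]) / sum(Fs)
  P2 <- (Fs["C", "T"] + Fs["T", "C"]) / sum(Fs)
  Q <- (ndiff / sum(Fs)) - P1 - P2
  rates <- matrix(NA_real_, 4, 4, dimnames = list(.BASES, .BASES))
  if (ndiff == 0) {
    return(methods::new("SubstitutionPattern", rates = rates,
                        k1 = NA_real_, k2 = NA_real_, tsTv = NA_real_,
                        baseFreqs = g, distance = 0, sites = sites))
  }
  if (Q == 0) {
    # transitions only: ratios diverge
    gR <- g["A"] + g["G"]; gY <- g["C"] + g["T"]
    return(methods::new("SubstitutionPattern", rates = rates,
                        k1 = Inf, k2 = Inf, tsTv = Inf,
                        baseFreqs = g, distance = NA_real_, sites = sites))
  }
  nll <- function(par) {
    t <- exp(par[1L]); kk1 <- exp(par[2L]); kk2 <- exp(par[3L])
    P <- .tn93Pmatrix(t, kk1, kk2, g)
    J <- g * P              # joint probability of an (i, j) pair
    J <- (J + t(J)) / 2
    if (any(J <= 0)) return(1e12)
    -sum(Fs * log(J))
  }
  init <- c(log(max(ndiff / sum(Fs), 1e-4)),
            log(max(P1 / max(Q, 1e-12), 0.1)),
            log(max(P2 / max(Q, 1e-12), 0.1)))
  fit <- stats::optim(init, nll, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
  t <- exp(fit$par[1L]); kk1 <- exp(fit$par[2L]); kk2 <- exp(fit$par[3L])
  # rate table: r_ij proportional to g_j (transversion), k*g_j (transition)
  for (i in .BASES) for (j in .BASES) {
    if (i == j) next
    coef <- 1
    if ((i == "A" && j == "G") || (i == "G" && j == "A")) coef <- kk1
    if ((i == "C" && j == "T") || (i == "T" && j == "C")) coef <- kk2
    rates[i, j] <- coef * g[j]
  }
  rates <- rates / sum(rates, na.rm = TRUE) * 100
  gR <- g["A"] + g["G"]; gY <- g["C"] + g["T"]
  R <- (kk1 * g["A"] * g["G"] + kk2 * g["C"] * g["T"]) / (gR * gY)
  methods::new("SubstitutionPattern", rates = rates, k1 = unname(kk1),
               k2 = unname(kk2), tsTv = unname(R), baseFreqs = g,
               distance = unname(t), sites = sites)
}

#' Pairwise distance matrix from an alignment
#'
#' `model = "p"` is the raw mismatch proportion; `model = "tn93"` is the
#' Tamura-Nei closed-form correction with empirical per-pair base
#' frequencies. Saturated pairs (logarithm of a non-positive number) are
#' reported as `NA` with a warning.
#'
#' @param alignment aligned `DNAStringSet` (>= 2 sequences).
#' @param model `"p"` or `"tn93"`.
#' @return symmetric numeric matrix with zero diagonal.
#' @export
distanceMatrix <- function(alignment, model = c("tn93", "p")) {
  model <- match.arg(model)
  n <- length(alignment)
  if (n < 2L) stop("need at least two sequences")
  labs <- names(alignment)
  D <- matrix(0, n, n, dimnames = list(labs, labs))
  seqs <- as.character(alignment)
  saturated <- FALSE
  for (i in 1:(n - 1L)) for (j in (i + 1L):n) {
    pc <- pairCounts(seqs[i], seqs[j])
    if (pc$sites == 0) { D[i, j] <- D[j, i] <- NA_real_; next }
    C <- pc$counts
    p <- (sum(C) - sum(diag(C))) / sum(C)
    if (model == "p") { D[i, j] <- D[j, i] <- p; next }
    g <- pc$freqs
    gR <- g["A"] + g["G"]; gY <- g["C"] + g["T"]
    P1 <- (C["A", "G"] + C["G", "A"]) / sum(C)
    P2 <- (C["C", "T"] + C["T", "C"]) / sum(C)
    Q <- p - P1 - P2
    c1 <- 2 * g["A"] * g["G"] / gR
    c2 <- 2 * g["C"] * g["T"] / gY
    c3 <- 2 * (gR * gY - g["A"] * g["G"] * gY / gR - g["C"] * g["T"] * gR / gY)
    w1 <- 1 - P1 / c1 - Q / (2 * gR)
    w2 <- 1 - P2 / c2 - Q / (2 * gY)
    w3 <- 1 - Q / (2 * gR * gY)
    if (w1 <= 0 || w2 <= 0 || w3 <= 0) {
      saturated <- TRUE
      D[i, j] <- D[j, i] <- NA_real_
    } else {
      D[i, j] <- D[j, i] <-
        unname(-c1 * log(w1) - c2 * log(w2) - c3 * log(w3))
    }
  }
  if (saturated) warning("saturated pair(s): distance reported as NA")
  D
}

## ---- neighbour joining ----------------------------------------------------

#' Neighbour-joining tree
#'
#' Saitou-Nei agglomeration on a symmetric non-negative distance matrix.
#' Ties in the rate-corrected criterion are broken toward the smallest
#' `(i, j)` index pair; negative branch lengths are clamped to zero with
#' the deficit moved to the sister branch.
#'
#' @param D symmetric distance matrix with row/col names (n >= 3).
#' @return an unrooted [ape::phylo] with branch lengths.
#' @export
njTree <- function(D) {
  if (!isSymmetric(unname(D))) stop("distance matrix must be symmetric")
  n <- nrow(D)
  if (n < 3L) stop("need at least three taxa")
  if (any(is.na(D))) stop("distance matrix contains NA")
  labs <- rownames(D)
  # node ids: tips 1..n; internal nodes appended from n+1
  active <- seq_len(n)         # row index -> node id
  nodeCount <- n
  edges <- matrix(integer(0), ncol = 2)
  lens <- numeric(0)
  Dw <- D
  while (length(active) > 2L) {
    m <- nrow(Dw)
    r <- rowSums(Dw)
    Qm <- (m - 2) * Dw - outer(r, r, "+")
    diag(Qm) <- Inf
    # smallest (i, j) tie-break, row-major upper triangle
    best <- c(NA_integer_, NA_integer_); bestVal <- Inf
    for (i in 1:(m - 1L)) for (j in (i + 1L):m) {
      if (Qm[i, j] < bestVal - 1e-12) { bestVal <- Qm[i, j]; best <- c(i, j) }
    }
    i <- best[1L]; j <- best[2L]
    li <- Dw[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    lj <- Dw[i, j] - li
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }
    nodeCount <- nodeCount + 1L
    new <- nodeCount
    edges <- rbind(edges, c(new, active[i]), c(new, active[j]))
    lens <- c(lens, li, lj)
    dNew <- (Dw[i, ] + Dw[j, ] - Dw[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    Dw2 <- rbind(cbind(Dw[keep, keep, drop = FALSE], dNew[keep]),
                 c(dNew[keep], 0))
    Dw <- Dw2
    active <- c(active[keep], new)
  }
  # join the last two nodes with a single edge
  edges <- rbind(edges, c(active[2L], active[1L]))
  lens <- c(lens, max(Dw[1L, 2L], 0))
  # convert to phylo numbering: tips 1..n, root/internal n+1..; ape expects
  # internal ids to start at n+1 with the "root" (basal) node first.
  allNodes <- sort(unique(as.vector(edges)))
  internal <- allNodes[allNodes > n]
  # relabel internal nodes so the basal node (last created / the one of the
  # final join) is n+1; ape accepts any consistent numbering where the
  # first internal id is the root of the edge table.
  childOf <- edges[, 2L]; parentOf <- edges[, 1L]
  rootId <- setdiff(parentOf, childOf)
  stopifnot(length(rootId) == 1L)
  map <- integer(max(allNodes))
  map[seq_len(n)] <- seq_len(n)
  ord <- c(rootId, setdiff(internal, rootId))
  map[ord] <- n + seq_along(ord)
  edge <- cbind(map[edges[, 1L]], map[edges[, 2L]])
  tr <- list(edge = edge, edge.length = unname(lens), tip.label = labs,
             Nnode = length(internal))
  class(tr) <- "phylo"
  tr <- ape::reorder.phylo(tr, "cladewise")
  ape::unroot(tr)
}

## canonical bipartitions of an (un)rooted phylo: for every internal edge,
## the tip-label set on the side away from tip 1, sorted and collapsed.
.treeSplits <- function(tree) {
  n <- length(tree$tip.label)
  pp <- ape::prop.part(tree)
  out <- character(0)
  for (k in seq_along(pp)) {
    tips <- tree$tip.label[pp[[k]]]
    if (length(tips) <= 1L || length(tips) >= n - 1L) next
    if (tree$tip.label[1L] %in% tips)
      tips <- setdiff(tree$tip.label, tips)
    out <- c(out, paste(sort(tips), collapse = "|"))
  }
  unique(out)
}

#' Bootstrap support for a neighbour-joining tree
#'
#' Resamples alignment columns with replacement, rebuilds the NJ tree for
#' each replicate, and reports for every internal split of the full-data
#' tree the fraction of replicate trees containing it. Deterministic given
#' `seed`.
#'
#' @param alignment aligned `DNAStringSet`.
#' @param nReps number of bootstrap replicates (>= 1; the classical
#'   default is 1000).
#' @param seed integer RNG seed.
#' @param model distance model (see [distanceMatrix()]).
#' @return list with `tree` (full-data NJ tree), `splits` (data.frame
#'   `split`, `support`).
#' @export
bootstrapSupport <- function(alignment, nReps = 1000L, seed = 1L,
                             model = "tn93") {
  if (nReps < 1L) stop("nReps must be >= 1")
  full <- njTree(distanceMatrix(alignment, model = model))
  target <- .treeSplits(full)
  hits <- setNames(numeric(length(target)), target)
  mat <- do.call(rbind, strsplit(as.character(alignment), ""))
  rownames(mat) <- names(alignment)
  L <- ncol(mat)
  set.seed(as.integer(seed))
  done <- 0L
  for (b in seq_len(nReps)) {
    cols <- sample.int(L, L, replace = TRUE)
    rep <- Biostrings::DNAStringSet(apply(mat[, cols, drop = FALSE], 1L,
                                          paste, collapse = ""))
    names(rep) <- rownames(mat)
    tr <- tryCatch(njTree(distanceMatrix(rep, model = model)),
                   error = function(e) NULL)
    if (is.null(tr)) next
    done <- done + 1L
    sp <- .treeSplits(tr)
    hits[target %in% sp] <- hits[target %in% sp] + 1
  }
  if (done == 0L) stop("all bootstrap replicates failed")
  list(tree = full,
       splits = data.frame(split = target, support = unname(hits / done),
                           stringsAsFactors = FALSE))
}

## ---- reconciliation -------------------------------------------------------

.checkBinaryRooted <- function(tree, what) {
  if (!ape::is.rooted(tree)) stop(what, " must be rooted")
  if (!ape::is.binary(tree)) stop(what, " must be binary")
  invisible(TRUE)
}

## parent vector and per-node depth (root = 0) for a phylo
.treeIndex <- function(tree) {
  n <- length(tree$tip.label)
  nn <- n + tree$Nnode
  parent <- integer(nn)
  parent[tree$edge[, 2L]] <- tree$edge[, 1L]
  root <- n + 1L
  depth <- integer(nn)
  ord <- ape::reorder.phylo(tree, "cladewise")$edge
  for (k in seq_len(nrow(ord)))
    depth[ord[k, 2L]] <- depth[ord[k, 1L]] + 1L
  list(n = n, nn = nn, parent = parent, root = root, depth = depth)
}

.lcaPair <- function(idx, a, b) {
  while (a != b) {
    if (idx$depth[a] >= idx$depth[b]) a <- idx$parent[a] else b <- idx$parent[b]
  }
  a
}

#' Reconcile a gene tree with a species tree (LCA mapping)
#'
#' Maps every gene-tree node to the lowest common ancestor of its leaf
#' species in the species tree. A node is a duplication when it maps to
#' the same species node as one of its children; losses are counted from
#' the species-tree path lengths between a node's mapping and its
#' children's mappings (the standard LCA loss formula). Paralogous genes
#' are those descending from at least one duplication node.
#'
#' @param geneTree rooted binary [ape::phylo] of genes.
#' @param speciesTree rooted binary [ape::phylo] of species.
#' @param leafMap named character vector gene-leaf -> species-leaf. By
#'   default the species is taken as the gene-id prefix up to the first
#'   `|`.
#' @return a [ReconciliationResult-class].
#' @examples
#' gt <- ape::read.tree(text = "((A|g1,B|g1),(A|g2,B|g2));")
#' st <- ape::read.tree(text = "(A,B);")
#' reconcileTrees(gt, st)  # 1 duplication
#' @export
reconcileTrees <- function(geneTree, speciesTree, leafMap = NULL) {
  .checkBinaryRooted(geneTree, "gene tree")
  .checkBinaryRooted(speciesTree, "species tree")
  if (is.null(leafMap))
    leafMap <- setNames(sub("\\|.*$", "", geneTree$tip.label),
                        geneTree$tip.label)
  missing <- setdiff(geneTree$tip.label, names(leafMap))
  if (length(missing))
    stop("unmapped gene leaf/leaves: ", paste(missing, collapse = ", "))
  badSp <- setdiff(unique(leafMap[geneTree$tip.label]),
                   speciesTree$tip.label)
  if (length(badSp))
    stop("species absent from species tree: ", paste(badSp, collapse = ", "))
  gIdx <- .treeIndex(geneTree)
  sIdx <- .treeIndex(speciesTree)
  spOfTip <- match(leafMap[geneTree$tip.label], speciesTree$tip.label)
  # post-order LCA mapping
  M <- integer(gIdx$nn)
  M[seq_len(gIdx$n)] <- spOfTip
  children <- split(geneTree$edge[, 2L], geneTree$edge[, 1L])
  post <- rev(unique(ape::reorder.phylo(geneTree, "cladewise")$edge[, 1L]))
  isDup <- logical(gIdx$nn)
  lossTotal <- 0L
  for (v in post) {
    ch <- children[[as.character(v)]]
    M[v] <- .lcaPair(sIdx, M[ch[1L]], M[ch[2L]])
  }
  for (v in post) {
    ch <- children[[as.character(v)]]
    isDup[v] <- any(M[ch] == M[v])
    for (c in ch) {
      k <- sIdx$depth[M[c]] - sIdx$depth[M[v]]
      lossTotal <- lossTotal + if (isDup[v]) k else k - 1L
    }
  }
  # paralogs: tips below any duplication node
  paraTips <- rep(FALSE, gIdx$n)
  if (any(isDup)) {
    for (v in which(isDup)) {
      tipset <- ape::extract.clade(geneTree, v)$tip.label
      paraTips[match(tipset, geneTree$tip.label)] <- TRUE
    }
  }
  internalIds <- (gIdx$n + 1L):gIdx$nn
  methods::new("ReconciliationResult",
               duplications = sum(isDup[internalIds]),
               losses = as.integer(lossTotal),
               paralogCount = sum(paraTips),
               nodeEvents = ifelse(isDup[internalIds],
                                   "duplication", "speciation"))
}

#' Root search minimizing duplications
#'
#' Midpoint rooting of an unrooted NJ tree is convenient but not
#' guaranteed to minimize the reconciliation duplication count; this
#' enumerates a rooting on every edge and returns the minimum.
#'
#' @param geneTree unrooted [ape::phylo].
#' @param speciesTree rooted binary species tree.
#' @param leafMap see [reconcileTrees()].
#' @return list with `tree` (the minimizing rooted gene tree) and
#'   `result` (its [ReconciliationResult-class]).
#' @export
minDuplicationRoot <- function(geneTree, speciesTree, leafMap = NULL) {
  best <- NULL; bestTree <- NULL
  for (e in seq_len(nrow(geneTree$edge))) {
    child <- geneTree$edge[e, 2L]
    rooted <- tryCatch({
      tips <- if (child <= length(geneTree$tip.label)) geneTree$tip.label[child]
              else ape::extract.clade(geneTree, child)$tip.label
      if (length(tips) >= length(geneTree$tip.label)) NULL
      else ape::root(geneTree, outgroup = tips, resolve.root = TRUE)
    }, error = function(e) NULL)
    if (is.null(rooted) || !ape::is.binary(rooted)) next
    res <- tryCatch(reconcileTrees(rooted, speciesTree, leafMap),
                    error = function(e) NULL)
    if (is.null(res)) next
    if (is.null(best) || duplications(res) < duplications(best)) {
      best <- res; bestTree <- rooted
    }
  }
  if (is.null(best)) stop("no valid rooting found")
  list(tree = bestTree, result = best)
}
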