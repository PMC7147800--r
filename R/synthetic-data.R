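# Seeded generators producing every input the pipeline needs, with ground
# truth recorded alongside. Each generator is a deterministic function of
# its spec + seed (single RNG stream, set.seed on entry).

## linker/background alphabet for planted NLS segments: no K/R (so the
## collapsed signature is exactly the planted basics) and none of the
## residues (R, P, W, F, Y) that could complete a non-canonical class
## III/IV consensus by accident.
.NLS_LINKER_ALPHABET <- c("A", "G", "S", "T")

## exemplar NLS segments per taxonomy class; returns list(segment, class)
.plantNlsSegment <- function(class) {
  lk <- function(n) paste(sample(.NLS_LINKER_ALPHABET, n, replace = TRUE),
                          collapse = "")
  seg <- switch(class,
    mono_I = strrep("K", sample(4:10, 1L)),
    mono_II = paste0("KK", lk(1L), "K"),
    bipartite = paste0(strrep("K", sample(3:4, 1L)),
                       lk(sample(5:20, 1L)),
                       strrep("K", sample(3:4, 1L))),
    multipartite = {
      k <- sample(3:4, 1L)  # number of clusters
      paste(c(rbind(replicate(k, strrep("K", sample(2:4, 1L))),
                    c(replicate(k - 1L, lk(sample(5:12, 1L))), ""))),
            collapse = "")
    },
    class_III = paste0("KR", lk(1L), sample(c("W", "F", "Y"), 1L),
                       lk(2L), "AF"),
    class_IV = paste0("P", lk(2L), "KR", sample(c("K", "R"), 1L)),
    stop("unknown NLS class '", class, "'"))
  seg
}

## exemplar instance of a compiled pattern: first residue of classes,
## 'A' for wildcards and non-excluded filler, minimal repeat counts
.patternExemplar <- function(pattern) {
  if (is.character(pattern)) pattern <- compilePattern(pattern)
  paste(vapply(pattern@elements, function(el) {
    res <- switch(el$type,
                  wildcard = "G",
                  fixed = el$residues,
                  class = el$residues[1L],
                  excluded = setdiff(.AA20, el$residues)[1L])
    strrep(res, el$min)
  }, character(1L)), collapse = "")
}

#' Specification for a synthetic proteome
#'
#' Defaults follow the census structure of large plant NAC surveys: mostly
#' single-domain factors with rare multi-domain architectures, roughly
#' 8.6% membrane-bound proteins, and protein lengths around the 350-residue
#' scale typical of NAC transcription factors.
#'
#' @param nNac number of NAC-like proteins (default 20).
#' @param nDecoys number of composition-matched decoys (default 20).
#' @param domainCountWeights weights over domain counts 1-4 (default
#'   `c(0.90, 0.07, 0.02, 0.01)`).
#' @param nlsPlan named integer vector: planted NLS count per taxonomy
#'   class.
#' @param tmFraction probability that a NAC protein carries a 23-residue
#'   hydrophobic stretch (default 0.0857).
#' @param lengthRange protein length range in residues (default
#'   `c(250, 500)`).
#' @param seed RNG seed.
#' @return a list with class `ProteomeSpec`.
#' @export
proteomeSpec <- function(nNac = 20L, nDecoys = 20L,
                         domainCountWeights = c(0.90, 0.07, 0.02, 0.01),
                         nlsPlan = c(mono_I = 5L, mono_II = 5L,
                                     bipartite = 5L, multipartite = 5L,
                                     class_III = 5L, class_IV = 5L),
                         tmFraction = 0.0857,
                         lengthRange = c(250L, 500L), seed = 1L) {
  if (nNac < 0L || nDecoys < 0L) stop("counts must be >= 0")
  if (any(domainCountWeights < 0) || sum(domainCountWeights) <= 0)
    stop("invalid domain count weights")
  structure(list(nNac = nNac, nDecoys = nDecoys,
                 domainCountWeights = domainCountWeights /
                   sum(domainCountWeights),
                 nlsPlan = nlsPlan, tmFraction = tmFraction,
                 lengthRange = lengthRange, seed = seed),
            class = "ProteomeSpec")
}

#' Generate a synthetic proteome with known ground truth
#'
#' NAC proteins carry exact planted instances of the full core motif
#' catalog in canonical order (one block per domain); NLS segments of the
#' requested taxonomy classes and 23-residue hydrophobic TM stretches are
#' planted at recorded positions in the inter-feature background; decoys
#' are composition-matched residue shuffles of the NAC proteins. The same
#' seed reproduces byte-identical output.
#'
#' @param spec a [proteomeSpec()].
#' @param catalog motif catalog (core rows are planted in order).
#' @return list with `proteins` (`AAStringSet`) and `truth` (data.frame
#'   `protein_id`, `feature` in `domain`/`nls`/`tm`, `class`, `start`,
#'   `end`).
#' @export
makeProteome <- function(spec, catalog = nacMotifCatalog()) {
  stopifnot(inherits(spec, "ProteomeSpec"))
  set.seed(as.integer(spec$seed))
  core <- catalog[catalog$role == "core", , drop = FALSE]
  domainBlock <- function() {
    # exemplar of every core motif, canonical order, short wildcard spacers
    # hydrophilic spacers: the real domain embeds its short hydrophobic
    # motifs in polar context, so shuffled decoys stay hydropathy-neutral
    paste(vapply(seq_len(nrow(core)), function(i)
      paste0(.patternExemplar(core$pattern[i]),
             paste(sample(c("G", "S", "T", "E", "Q", "D", "N"), 4L,
                          replace = TRUE), collapse = "")),
      character(1L)), collapse = "")
  }
  # distribute the NLS plan over NAC proteins round-robin
  nlsQueue <- rep(names(spec$nlsPlan), times = spec$nlsPlan)
  if (length(nlsQueue) && spec$nNac == 0L)
    stop("infeasible spec: NLS plan requires NAC proteins")
  owner <- if (length(nlsQueue))
    rep_len(seq_len(spec$nNac), length(nlsQueue)) else integer(0)
  seqs <- character(0); truth <- NULL
  # compositionally neutral background: uniform over the 20 residues
  bg <- function(n) if (n > 0L)
    paste(sample(.AA20, n, replace = TRUE), collapse = "") else ""
  for (p in seq_len(spec$nNac)) {
    id <- sprintf("nac%03d", p)
    L <- sample(spec$lengthRange[1L]:spec$lengthRange[2L], 1L)
    nDomains <- sample(1:4, 1L, prob = spec$domainCountWeights)
    feats <- lapply(seq_len(nDomains), function(d)
      list(feature = "domain", class = as.character(nDomains),
           seq = domainBlock()))
    for (q in which(owner == p)) {
      feats <- c(feats, list(list(feature = "nls", class = nlsQueue[q],
                                  seq = .plantNlsSegment(nlsQueue[q]))))
    }
    if (runif(1L) < spec$tmFraction) {
      feats <- c(feats, list(list(feature = "tm", class = "tm",
                                  seq = paste(sample(c("L", "I", "V", "F"),
                                                     23L, replace = TRUE),
                                              collapse = ""))))
    }
    featLen <- sum(vapply(feats, function(f) nchar(f$seq), integer(1L)))
    nGaps <- length(feats) + 1L
    minLen <- featLen + nGaps * 5L  # >= 5 background residues per gap
    if (minLen > spec$lengthRange[2L])
      stop("infeasible spec: features need ", minLen,
           " residues but lengthRange allows at most ",
           spec$lengthRange[2L], " (", id, ")")
    L <- max(L, minLen)  # drawn length is a floor under the planted load
    spare <- L - minLen
    extra <- if (spare > 0L) {
      cuts <- sort(sample.int(spare + nGaps - 1L, nGaps - 1L))
      diff(c(0L, cuts, spare + nGaps - 1L)) - 1L
    } else rep(0L, nGaps)
    gapLens <- 5L + extra
    pieces <- character(0); pos <- 0L
    for (k in seq_along(feats)) {
      g <- bg(gapLens[k])
      pieces <- c(pieces, g, feats[[k]]$seq)
      st <- pos + gapLens[k] + 1L
      en <- st + nchar(feats[[k]]$seq) - 1L
      truth <- rbind(truth, data.frame(protein_id = id,
                                       feature = feats[[k]]$feature,
                                       class = feats[[k]]$class,
                                       start = st, end = en,
                                       stringsAsFactors = FALSE))
      pos <- en
    }
    pieces <- c(pieces, bg(gapLens[nGaps]))
    seqs[id] <- paste(pieces, collapse = "")
  }
  # decoys: composition-matched shuffles of the NAC proteins
  for (d in seq_len(spec$nDecoys)) {
    src <- seqs[[((d - 1L) %% max(spec$nNac, 1L)) + 1L]]
    if (is.null(src) || !length(seqs))
      src <- paste(sample(.AA20, 300L, replace = TRUE), collapse = "")
    seqs[sprintf("decoy%03d", d)] <-
      paste(sample(.splitChars(src)), collapse = "")
  }
  if (is.null(truth))
    truth <- data.frame(protein_id = character(), feature = character(),
                        class = character(), start = integer(),
                        end = integer(), stringsAsFactors = FALSE)
  proteins <- Biostrings::AAStringSet(seqs)
  list(proteins = proteins, truth = truth)
}

#' Back-translate proteins into CDS with a target codon bias
#'
#' Samples synonymous codons per amino acid with the supplied per-family
#' weights (uniform by default) and appends a `UAA` stop, so that
#' [pairProteinCds()] passes for every record and [speciesCodonUsage()]
#' recovers the target RSCU in expectation.
#'
#' @param proteins `AAStringSet` (20-letter alphabet).
#' @param rscuTarget optional named numeric of per-codon weights (RNA or
#'   DNA labels); weights are normalized within each synonymous family.
#'   A needed family whose weights are all zero is an error.
#' @param seed RNG seed.
#' @return a `DNAStringSet` with the same names.
#' @export
makeCds <- function(proteins, rscuTarget = NULL, seed = 1L) {
  set.seed(as.integer(seed))
  w <- setNames(rep(1, 61L), .SENSE_RNA)
  if (!is.null(rscuTarget)) {
    names(rscuTarget) <- .toRna(names(rscuTarget))
    if (any(rscuTarget < 0)) stop("weights must be non-negative")
    w[intersect(names(rscuTarget), .SENSE_RNA)] <-
      rscuTarget[intersect(names(rscuTarget), .SENSE_RNA)]
  }
  famCodons <- split(.SENSE_RNA, .codonAA[.SENSE_RNA])
  dnaOf <- setNames(chartr("U", "T", .SENSE_RNA), .SENSE_RNA)
  out <- vapply(seq_along(proteins), function(i) {
    ch <- .splitChars(.asSeqString(proteins[i]))
    codons <- character(length(ch))
    for (aa in unique(ch)) {
      cands <- famCodons[[aa]]
      if (is.null(cands)) stop("cannot back-translate residue '", aa, "'")
      wt <- w[cands]
      if (sum(wt) <= 0)
        stop("zero-weight synonymous family for amino acid '", aa, "'")
      ix <- which(ch == aa)
      codons[ix] <- dnaOf[sample(cands, length(ix), replace = TRUE,
                                 prob = wt)]
    }
    paste(c(codons, "TAA"), collapse = "")
  }, character(1L))
  cds <- Biostrings::DNAStringSet(out)
  names(cds) <- names(proteins)
  cds
}

#' Evolve an alignment down a tree under TN93
#'
#' The root sequence is drawn from `baseFreqs`; sites evolve independently
#' along each branch with the closed-form TN93 transition matrix (branch
#' lengths in expected substitutions/site). No indels, so the leaf
#' sequences are an ungapped alignment.
#'
#' @param tree rooted [ape::phylo] with branch lengths.
#' @param k1,k2 purine / pyrimidine transition/transversion rate ratios
#'   (defaults 4 and 2).
#' @param baseFreqs base frequencies A,C,G,T (default uniform).
#' @param length alignment length in sites.
#' @param seed RNG seed.
#' @return `DNAStringSet` of leaf sequences, with the root sequence in
#'   attribute `root`.
#' @export
evolveAlignment <- function(tree, k1 = 4, k2 = 2,
                            baseFreqs = rep(0.25, 4), length = 1000L,
                            seed = 1L) {
  stopifnot(abs(sum(baseFreqs) - 1) < 1e-9, k1 > 0, k2 > 0)
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  if (is.null(tree$edge.length)) stop("tree must have branch lengths")
  set.seed(as.integer(seed))
  names(baseFreqs) <- .BASES
  n <- base::length(tree$tip.label)
  nn <- n + tree$Nnode
  seqIdx <- vector("list", nn)
  rootSeq <- sample.int(4L, length, replace = TRUE, prob = baseFreqs)
  seqIdx[[n + 1L]] <- rootSeq
  ord <- ape::reorder.phylo(tree, "cladewise")
  eo <- order(match(tree$edge[, 1L], ord$edge[, 1L]))  # parents first
  for (k in seq_len(nrow(tree$edge))) {
    e <- ord$edge[k, ]
    t <- ord$edge.length[k]
    P <- .tn93Pmatrix(t, k1, k2, baseFreqs)
    parent <- seqIdx[[e[1L]]]
    child <- integer(length)
    for (b in 1:4) {
      ix <- which(parent == b)
      if (base::length(ix))
        child[ix] <- sample.int(4L, base::length(ix), replace = TRUE,
                                prob = P[b, ])
    }
    seqIdx[[e[2L]]] <- child
  }
  leaves <- vapply(seq_len(n), function(i)
    paste(.BASES[seqIdx[[i]]], collapse = ""), character(1L))
  out <- Biostrings::DNAStringSet(leaves)
  names(out) <- tree$tip.label
  attr(out, "root") <- paste(.BASES[rootSeq], collapse = "")
  out
}

## phylo -> nested list (leaf = character label; internal = list of two)
.phyloToNested <- function(tree) {
  n <- length(tree$tip.label)
  children <- split(tree$edge[, 2L], tree$edge[, 1L])
  build <- function(v) {
    if (v <= n) return(tree$tip.label[v])
    ch <- children[[as.character(v)]]
    list(build(ch[1L]), build(ch[2L]))
  }
  build(n + 1L)
}

.nestedToNewick <- function(node) {
  if (is.character(node)) return(node)
  paste0("(", .nestedToNewick(node[[1L]]), ",",
         .nestedToNewick(node[[2L]]), ")")
}

#' Simulate a gene family on a species tree with known duplications
#'
#' Starts from one gene per species (a leaf-relabelled copy of the species
#' tree) and applies `nDuplications` subtree duplications at uniformly
#' chosen gene-tree nodes; each event creates a duplication node whose two
#' children are copies of the chosen subtree. Leaves are then pruned
#' independently with probability `lossProb` (a degenerate all-lost draw
#' is resampled, with bounded retries). Truth counts refer to duplication
#' events still observable in the emitted (pruned) tree, i.e. events with
#' surviving leaves on both sides.
#'
#' @param speciesTree rooted binary [ape::phylo].
#' @param nDuplications number of duplication events (>= 0).
#' @param lossProb per-leaf loss probability (default 0).
#' @param seed RNG seed.
#' @return list with `geneTree` (rooted binary `phylo`, leaf labels
#'   `SPECIES|g<k>`), `leafMap`, and `truth` (list `duplications`,
#'   `leavesLost`).
#' @export
makeGeneFamily <- function(speciesTree, nDuplications = 0L, lossProb = 0,
                           seed = 1L) {
  .checkBinaryRooted(speciesTree, "species tree")
  set.seed(as.integer(seed))
  counter <- new.env()
  assign("k", 0L, envir = counter)
  newGene <- function(sp) {
    k <- get("k", envir = counter) + 1L
    assign("k", k, envir = counter)
    paste0(sp, "|g", k)
  }
  relabel <- function(node) {
    if (is.character(node)) return(newGene(node))
    list(relabel(node[[1L]]), relabel(node[[2L]]))
  }
  # deep-copy a subtree, assigning fresh gene ids
  copySub <- function(node) {
    if (is.character(node)) return(newGene(sub("\\|.*$", "", node)))
    list(copySub(node[[1L]]), copySub(node[[2L]]))
  }
  gene <- relabel(.phyloToNested(speciesTree))
  nodeCountEnv <- function(node) {
    if (is.character(node)) 1L
    else 1L + nodeCountEnv(node[[1L]]) + nodeCountEnv(node[[2L]])
  }
  ## Eligible duplication targets are nodes whose subtree contains no
  ## earlier duplication node: copying a clade that already holds a
  ## duplication would silently plant an extra (mirrored) event, so the
  ## planted count would no longer equal the observable count.
  hasDupBelow <- function(node) {
    if (is.character(node)) return(FALSE)
    !is.null(attr(node, "dup")) || hasDupBelow(node[[1L]]) ||
      hasDupBelow(node[[2L]])
  }
  countEligible <- function(node) {
    if (hasDupBelow(node)) {
      if (is.character(node)) return(0L)
      return(countEligible(node[[1L]]) + countEligible(node[[2L]]))
    }
    nodeCountEnv(node)
  }
  for (d in seq_len(nDuplications)) {
    total <- countEligible(gene)
    if (total == 0L) stop("no eligible duplication target left")
    target <- sample.int(total, 1L)
    idx <- new.env(); assign("i", 0L, envir = idx)
    tag <- paste0("dup", d)
    dupAt <- function(node) {
      eligible <- !hasDupBelow(node)
      if (eligible) {
        i <- get("i", envir = idx) + 1L
        assign("i", i, envir = idx)
        if (i == target) {
          out <- list(node, copySub(node))
          attr(out, "dup") <- tag
          return(out)
        }
      }
      if (is.character(node)) return(node)
      n1 <- dupAt(node[[1L]])
      n2 <- dupAt(node[[2L]])
      out <- list(n1, n2)
      attributes(out) <- attributes(node)
      out
    }
    gene <- dupAt(gene)
  }
  leafSet <- function(node) {
    if (is.character(node)) return(node)
    c(leafSet(node[[1L]]), leafSet(node[[2L]]))
  }
  allLeaves <- leafSet(gene)
  survivors <- allLeaves
  if (lossProb > 0) {
    for (try in 1:100) {
      keep <- runif(length(allLeaves)) >= lossProb
      if (sum(keep) >= 2L) { survivors <- allLeaves[keep]; break }
      if (try == 100L) {
        warning("all-genes-lost draws; keeping full leaf set")
        survivors <- allLeaves
      } else warning("degenerate all-lost draw resampled")
    }
  }
  # prune: drop non-surviving leaves, collapse unary nodes; count observable
  # duplications (both sides retain >= 1 survivor)
  obsDup <- new.env(); assign("n", 0L, envir = obsDup)
  prune <- function(node) {
    if (is.character(node))
      return(if (node %in% survivors) node else NULL)
    a <- prune(node[[1L]]); b <- prune(node[[2L]])
    if (is.null(a) && is.null(b)) return(NULL)
    if (is.null(a)) return(b)
    if (is.null(b)) return(a)
    if (!is.null(attr(node, "dup")))
      assign("n", get("n", envir = obsDup) + 1L, envir = obsDup)
    list(a, b)
  }
  gene <- prune(gene)
  if (is.character(gene)) stop("gene family collapsed to a single gene")
  txt <- paste0(.nestedToNewick(gene), ";")
  geneTree <- ape::read.tree(text = txt)
  leafMap <- setNames(sub("\\|.*$", "", geneTree$tip.label),
                      geneTree$tip.label)
  list(geneTree = geneTree, leafMap = leafMap,
       truth = list(duplications = get("n", envir = obsDup),
                    leavesLost = length(allLeaves) - length(survivors)))
}
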