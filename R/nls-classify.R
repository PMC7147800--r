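# NLS taxonomy: monopartite class I/II, bipartite, non-canonical class
# III/IV, multipartite; linker-collapsed signatures and terminal census.

#' Find basic-residue clusters in a segment
#'
#' Maximal runs of K/R of length at least `minRun` (default 2), left to
#' right.
#'
#' @param segment protein segment (character).
#' @param minRun minimum run length (default 2).
#' @return data.frame with columns `start`, `end`, `length` (1-based,
#'   relative to the segment).
#' @examples
#' findBasicClusters("KRPAATKKAGQAKKKK")
#' @export
findBasicClusters <- function(segment, minRun = 2L) {
  ch <- .splitChars(.asSeqString(segment))
  basic <- ch %in% c("K", "R")
  r <- rle(basic)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= minRun
  data.frame(start = starts[keep], end = ends[keep],
             length = r$lengths[keep])
}

## Merge adjacent basic runs into clusters. A pair of neighbouring runs is
## merged when the gap between them is <= mergeGap AND at least one of the
## two raw runs has length >= 3: a basic doublet is only absorbed into a
## nearby substantial run, never into another doublet. This reproduces the
## canonical two-cluster reading of the bipartite consensus
## K-R-P-A-A-T-K-K-A-G-Q-A-K-K-K-K (KR | KK..KKKK).
.mergeBasicClusters <- function(runs, mergeGap = 4L) {
  if (nrow(runs) <= 1L) {
    runs$n_runs <- rep(1L, nrow(runs))
    return(runs)
  }
  groups <- integer(nrow(runs))
  g <- 1L
  groups[1L] <- g
  for (i in 2L:nrow(runs)) {
    gap <- runs$start[i] - runs$end[i - 1L] - 1L
    if (gap <= mergeGap && max(runs$length[i - 1L], runs$length[i]) >= 3L)
      groups[i] <- g
    else { g <- g + 1L; groups[i] <- g }
  }
  out <- do.call(rbind, lapply(split(seq_len(nrow(runs)), groups), function(ix)
    data.frame(start = runs$start[ix[1L]], end = runs$end[ix[length(ix)]],
               length = sum(runs$length[ix]), n_runs = length(ix))))
  rownames(out) <- NULL
  out
}

#' Collapse linker residues to the basic-residue signature
#'
#' Deletes every non-K/R residue, preserving order; idempotent.
#'
#' @param segment protein segment(s) (character vector).
#' @return signature string(s) over `{K, R}`.
#' @examples
#' collapseLinkers("KRPAATKKAGQAKKKK")  # "KRKKKKKK"
#' @export
collapseLinkers <- function(segment) {
  gsub("[^KR]", "", toupper(segment))
}

#' Classify an NLS segment
#'
#' Decision order (first match wins):
#' \enumerate{
#'   \item `class_III` when the non-canonical pattern
#'     `K-R-x-[WFY]-x(2)-A-F` matches anywhere in the segment;
#'   \item `class_IV` when `[PR]-x(2)-K-R-[KR]` matches;
#'   \item `multipartite` when the segment carries three or more basic
#'     clusters (after cluster merging, see Details);
#'   \item `bipartite` for exactly two clusters separated by a linker of
#'     `linkerBounds` residues (default 4-24);
#'   \item `mono_I` for a single cluster containing a run of at least four
#'     consecutive basic residues (open upper bound);
#'   \item `mono_II` when `K-[KR]-x-[KR]` matches;
#'   \item `unclassified` otherwise.
#' }
#'
#' Non-canonical patterns are checked first because they are
#' pattern-defined and would otherwise be absorbed by the cluster-count
#' geometry. Cluster merging absorbs a K/R doublet into a neighbouring run
#' of length >= 3 when separated by at most `mergeGap` residues.
#'
#' @param segment protein segment (length >= 3; shorter segments return
#'   `"unclassified"` with a warning).
#' @param mergeGap cluster-merge gap (default 4).
#' @param linkerBounds bipartite linker bounds, inclusive (default
#'   `c(4, 24)`; canonical linkers are 10-12, observed up to 24).
#' @param minRun minimum basic-run length for a cluster (default 2).
#' @return one of `"mono_I"`, `"mono_II"`, `"bipartite"`, `"class_III"`,
#'   `"class_IV"`, `"multipartite"`, `"unclassified"`.
#' @examples
#' classifyNls("KKKK")                # mono_I
#' classifyNls("KKAK")                # mono_II
#' classifyNls("KRPAATKKAGQAKKKK")    # bipartite
#' @export
classifyNls <- function(segment, mergeGap = 4L, linkerBounds = c(4L, 24L),
                        minRun = 2L) {
  s <- .asSeqString(segment)
  if (nchar(s) < 3L) {
    warning("segment shorter than 3 residues: unclassified")
    return("unclassified")
  }
  if (nrow(scanPattern(s, "K-R-x-[WFY]-x(2)-A-F"))) return("class_III")
  if (nrow(scanPattern(s, "[PR]-x(2)-K-R-[KR]"))) return("class_IV")
  runs <- findBasicClusters(s, minRun = minRun)
  clusters <- .mergeBasicClusters(runs, mergeGap = mergeGap)
  nc <- nrow(clusters)
  if (nc >= 3L) return("multipartite")
  if (nc == 2L) {
    linker <- clusters$start[2L] - clusters$end[1L] - 1L
    if (linker >= linkerBounds[1L] && linker <= linkerBounds[2L])
      return("bipartite")
  }
  if (nc == 1L) {
    # mono_I needs >= 4 *consecutive* basics within the cluster
    maxRun <- max(findBasicClusters(s, minRun = 1L)$length)
    if (maxRun >= 4L) return("mono_I")
  }
  if (nrow(scanPattern(s, "K-[KR]-x-[KR]"))) return("mono_II")
  "unclassified"
}

#' Assign an NLS interval to the N- or C-terminal region
#'
#' The paper-level taxonomy distinguishes N- and C-terminal signals but
#' never defines the split; the package convention is the protein
#' midpoint: an interval belongs to the N-terminal region when its
#' midpoint is at most half the protein length.
#'
#' @param start,end 1-based inclusive interval.
#' @param proteinLength protein length in residues.
#' @return `"N"` or `"C"` (vectorized).
#' @export
assignTerminal <- function(start, end, proteinLength) {
  if (any(start < 1L) || any(end > proteinLength) || any(end < start))
    stop("interval outside protein")
  ifelse((start + end) / 2 <= proteinLength / 2, "N", "C")
}

#' Annotate HMM NLS calls with taxonomy, signature and terminal
#'
#' @param seq the protein sequence the calls refer to.
#' @param calls data.frame of intervals as from [callNls()].
#' @param ... passed to [classifyNls()].
#' @return `calls` with added columns `segment`, `nls_class`, `signature`,
#'   `n_clusters`, `terminal`.
#' @export
annotateNlsCalls <- function(seq, calls, ...) {
  s <- .asSeqString(seq)
  L <- nchar(s)
  if (!nrow(calls)) {
    calls$segment <- character(0); calls$nls_class <- character(0)
    calls$signature <- character(0); calls$n_clusters <- integer(0)
    calls$terminal <- character(0)
    return(calls)
  }
  calls$segment <- substring(s, calls$start, calls$end)
  calls$nls_class <- vapply(calls$segment, classifyNls, character(1L),
                            ..., USE.NAMES = FALSE)
  calls$signature <- collapseLinkers(calls$segment)
  calls$n_clusters <- vapply(calls$segment, function(seg)
    nrow(.mergeBasicClusters(findBasicClusters(seg))), integer(1L),
    USE.NAMES = FALSE)
  calls$terminal <- assignTerminal(calls$start, calls$end, L)
  calls
}

#' Census of linker-collapsed NLS signatures by terminal region
#'
#' @param calls data.frame with columns `signature` and `terminal` (as from
#'   [annotateNlsCalls()]).
#' @return list with `signatures` (data.frame `signature`,
#'   `count_n_terminal`, `count_c_terminal`) and `summary` (named list
#'   `n_unique_N`, `n_unique_C`, `n_shared`, `n_only_N`, `n_only_C`).
#' @export
signatureCensus <- function(calls) {
  need <- c("signature", "terminal")
  if (!all(need %in% colnames(calls)))
    stop("calls must have columns signature, terminal")
  sigs <- sort(unique(calls$signature))
  cN <- vapply(sigs, function(s)
    sum(calls$signature == s & calls$terminal == "N"), integer(1L))
  cC <- vapply(sigs, function(s)
    sum(calls$signature == s & calls$terminal == "C"), integer(1L))
  df <- data.frame(signature = sigs, count_n_terminal = unname(cN),
                   count_c_terminal = unname(cC), stringsAsFactors = FALSE)
  uN <- df$signature[df$count_n_terminal > 0L]
  uC <- df$signature[df$count_c_terminal > 0L]
  list(signatures = df,
       summary = list(n_unique_N = length(uN),
                      n_unique_C = length(uC),
                      n_shared = length(intersect(uN, uC)),
                      n_only_N = length(setdiff(uN, uC)),
                      n_only_C = length(setdiff(uC, uN))))
}
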