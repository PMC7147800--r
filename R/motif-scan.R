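#' Compile a PROSITE-style pattern
#'
#' Grammar: elements separated by `-`; `x` is a wildcard, `x(n)` / `x(n,m)`
#' repeated wildcards; `[AB]` any-of; `{AB}` none-of; `A/B` is shorthand for
#' `[AB]` and is normalized on compilation. Repeat suffixes are accepted on
#' any element. An `X` residue in a scanned sequence matches any *fixed*
#' pattern element (unknown residue wildcard), and trivially matches
#' wildcards; it does not match residue classes.
#'
#' @param prosite pattern string, e.g. `"D-[DE]-L-[IV]"` or `"D-D/E-L-I/V"`.
#' @return a [Pattern-class] object.
#' @examples
#' compilePattern("K-x(2)-K")
#' @export
compilePattern <- function(prosite) {
  if (!is.character(prosite) || length(prosite) != 1L || !nzchar(prosite))
    stop("pattern must be a single non-empty string")
  tokens <- strsplit(prosite, "-", fixed = TRUE)[[1L]]
  if (any(!nzchar(tokens))) stop("empty pattern element in '", prosite, "'")
  rx <- "^(x|\\[([A-Za-z]+)\\]|\\{([A-Za-z]+)\\}|([A-Za-z])(/[A-Za-z])*)(\\((\\d+)(,(\\d+))?\\))?$"
  elements <- lapply(tokens, function(tok) {
    m <- regmatches(tok, regexec(rx, tok))[[1L]]
    if (!length(m)) stop("malformed pattern element '", tok, "'")
    body <- sub("\\(\\d+(,\\d+)?\\)$", "", tok)
    rep1 <- m[8L]; rep2 <- m[10L]
    mn <- if (nzchar(rep1)) as.integer(rep1) else 1L
    mx <- if (nzchar(rep2)) as.integer(rep2) else mn
    if (mn > mx) stop("malformed repeat range in '", tok, "' (n > m)")
    if (body == "x") {
      el <- list(type = "wildcard", residues = character(0))
    } else if (grepl("^\\[", body)) {
      res <- toupper(.splitChars(gsub("\\[|\\]", "", body)))
      if (!length(res)) stop("empty residue class in '", tok, "'")
      el <- list(type = "class", residues = res)
    } else if (grepl("^\\{", body)) {
      res <- toupper(.splitChars(gsub("\\{|\\}", "", body)))
      if (!length(res)) stop("empty excluded class in '", tok, "'")
      el <- list(type = "excluded", residues = res)
    } else if (grepl("/", body, fixed = TRUE)) {
      res <- toupper(strsplit(body, "/", fixed = TRUE)[[1L]])
      el <- list(type = "class", residues = res)
    } else {
      el <- list(type = "fixed", residues = toupper(body))
    }
    if (length(el$residues)) {
      bad <- setdiff(el$residues, .AA20)
      if (length(bad))
        stop("unknown residue letter(s) in '", tok, "': ",
             paste(bad, collapse = ","))
    }
    el$min <- mn; el$max <- mx
    el
  })
  obj <- methods::new("Pattern", source = .decompileElements(elements),
                      elements = elements)
  methods::validObject(obj)
  obj
}

.decompileElements <- function(elements) {
  paste(vapply(elements, function(el) {
    body <- switch(el$type,
                   wildcard = "x",
                   fixed = el$residues,
                   class = paste0("[", paste(el$residues, collapse = ""), "]"),
                   excluded = paste0("{", paste(el$residues, collapse = ""), "}"))
    if (el$min == 1L && el$max == 1L) body
    else if (el$min == el$max) sprintf("%s(%d)", body, el$min)
    else sprintf("%s(%d,%d)", body, el$min, el$max)
  }, character(1L)), collapse = "-")
}

#' Decompile a compiled pattern back to its normalized source string
#'
#' `compilePattern(decompilePattern(p))` reproduces `p` exactly.
#'
#' @param pattern a [Pattern-class].
#' @return normalized PROSITE-style string.
#' @export
decompilePattern <- function(pattern) {
  stopifnot(methods::is(pattern, "Pattern"))
  pattern@source
}

## Per-position membership of a sequence in an element's allowed set,
## including the X-matches-fixed rule.
.elementMembership <- function(chars, el) {
  switch(el$type,
         wildcard = rep(TRUE, length(chars)),
         fixed = chars == el$residues | chars == "X",
         class = chars %in% el$residues,
         excluded = !(chars %in% el$residues) & chars != "X")
}

## Longest match of `elements` anchored at each start position.
## Returns integer vector ends[s] = end position (1-based inclusive) of the
## longest match starting at s, or NA. Reachability DP over element list.
.matchEnds <- function(chars, elements) {
  L <- length(chars)
  ends <- rep(NA_integer_, L)
  # precompute membership and forward run lengths per element
  memb <- lapply(elements, function(el) .elementMembership(chars, el))
  runs <- lapply(memb, function(m) {
    r <- integer(L)
    nxt <- 0L
    for (i in L:1L) { nxt <- if (m[i]) nxt + 1L else 0L; r[i] <- nxt }
    r
  })
  for (s in seq_len(L)) {
    # reachable "next position to consume" set, 1-based
    pos <- s
    for (k in seq_along(elements)) {
      el <- elements[[k]]
      rl <- runs[[k]]
      newpos <- integer(0)
      for (p in pos) {
        avail <- if (p <= L) rl[p] else 0L
        hi <- min(el$max, avail)
        if (el$min <= hi)
          newpos <- c(newpos, p + el$min:hi)
        else if (el$min == 0L)
          newpos <- c(newpos, p)
      }
      pos <- unique(newpos)
      if (!length(pos)) break
    }
    if (length(pos)) {
      e <- max(pos) - 1L
      if (e >= s) ends[s] <- e
      else if (e == s - 1L) ends[s] <- NA_integer_  # zero-length match ignored
    }
  }
  ends
}

#' Scan a protein sequence with a compiled pattern
#'
#' Reports the longest match anchored at each matching start position.
#' With `overlapping = FALSE`, hits are selected greedily left-to-right
#' without overlap.
#'
#' @param seq a protein sequence (character, `AAString`, or length-1
#'   `AAStringSet`).
#' @param pattern a [Pattern-class] or PROSITE-style string.
#' @param overlapping keep overlapping hits (default `TRUE`).
#' @param seqId identifier used in the output (defaults to the sequence
#'   name or `"seq"`).
#' @param patternName pattern name for the output column.
#' @return data.frame with columns `protein_id`, `pattern_name`, `start`,
#'   `end` (1-based inclusive), `matched`.
#' @examples
#' scanPattern("AAEWYFFAA", "E-W-Y-F-F")
#' @export
scanPattern <- function(seq, pattern, overlapping = TRUE,
                        seqId = NULL, patternName = NULL) {
  if (is.character(pattern)) pattern <- compilePattern(pattern)
  if (is.null(seqId))
    seqId <- if (!is.null(names(seq)) && nzchar(names(seq)[1L])) names(seq)[1L] else "seq"
  if (is.null(patternName)) patternName <- pattern@source
  s <- .asSeqString(seq)
  ch <- .checkProtein(s, what = paste0("sequence '", seqId, "'"))
  ends <- .matchEnds(ch, pattern@elements)
  starts <- which(!is.na(ends))
  if (length(starts) && !overlapping) {
    keep <- integer(0)
    lastEnd <- 0L
    for (st in starts) {
      if (st > lastEnd) { keep <- c(keep, st); lastEnd <- ends[st] }
    }
    starts <- keep
  }
  matched <- if (length(starts)) substring(s, starts, ends[starts])
             else character(0)
  data.frame(protein_id = rep(seqId, length(starts)),
             pattern_name = rep(patternName, length(starts)),
             start = starts,
             end = if (length(starts)) unname(ends[starts]) else integer(0),
             matched = matched,
             stringsAsFactors = FALSE)
}

#' The NAC consensus-motif catalog
#'
#' The default catalog holds the conserved consensus motifs that mark the
#' N-terminal NAC DNA-binding domain, in their canonical N-to-C order,
#' plus the standalone hydrophobic `L-V-F-Y` repressor/export motif. It is
#' shipped as an editable data file
#' (`system.file("extdata", "nac_core_motifs.tsv", package = "nacprofiler")`).
#'
#' @param path optional path to a catalog TSV (`name`, `pattern`, `role`
#'   columns; `role` is `core` or `partner`).
#' @return data.frame with columns `name`, `pattern`, `role`; core rows are
#'   in canonical order.
#' @export
nacMotifCatalog <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "nac_core_motifs.tsv",
                        package = "nacprofiler")
  cat <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, quote = "")
  need <- c("name", "pattern", "role")
  if (!all(need %in% colnames(cat)))
    stop("catalog must have columns: ", paste(need, collapse = ", "))
  if (!nrow(cat)) stop("empty motif catalog")
  cat
}

#' Detect nuclear-export-signal motifs
#'
#' Scans for the hydrophobic `L-V-F-Y` motif and its substitute class
#' `L-[VI]-[FM]-[YM]`; duplicate hits are merged.
#'
#' @inheritParams scanPattern
#' @return data.frame of motif hits (see [scanPattern()]).
#' @examples
#' detectNes("ALVFYA")
#' @export
detectNes <- function(seq, seqId = NULL) {
  h1 <- scanPattern(seq, "L-[VI]-[FM]-[YM]", seqId = seqId,
                    patternName = "nes_lvfy")
  h2 <- scanPattern(seq, "L-V-F-Y", seqId = seqId, patternName = "nes_lvfy")
  out <- rbind(h1, h2)
  out <- out[!duplicated(out[, c("start", "end")]), , drop = FALSE]
  out[order(out$start), , drop = FALSE]
}

#' Count NAC domain instances in a protein
#'
#' A NAC domain instance is called where at least `minCoreMotifs` distinct
#' core catalog motifs co-occur in their canonical order within a window of
#' `window` residues. Instances are selected left-to-right without overlap
#' (leftmost start, then longest). Non-core (`partner`) catalog patterns
#' hitting outside called instances are reported as chimeric partners.
#'
#' @inheritParams scanPattern
#' @param catalog a motif catalog as returned by [nacMotifCatalog()].
#' @param minCoreMotifs minimum number of distinct core motifs per domain
#'   call (default 3).
#' @param window residue window for motif co-occurrence (default 200).
#' @return one-row data.frame with columns `protein_id`, `length`,
#'   `nac_domain_count`, `is_nac`, `is_multi_domain`, `chimeric_partners`
#'   (`;`-separated), `n_nes_hits`, `domain_intervals`; the full hit table
#'   is attached as attribute `hits` and NES hits as attribute `nes`.
#' @export
countNacDomains <- function(seq, catalog = nacMotifCatalog(),
                            minCoreMotifs = 3L, window = 200L,
                            seqId = NULL) {
  if (!nrow(catalog)) stop("empty motif catalog")
  if (is.null(seqId))
    seqId <- if (!is.null(names(seq)) && nzchar(names(seq)[1L])) names(seq)[1L] else "seq"
  s <- .asSeqString(seq)
  core <- catalog[catalog$role == "core", , drop = FALSE]
  partners <- catalog[catalog$role != "core", , drop = FALSE]
  hits <- do.call(rbind, lapply(seq_len(nrow(core)), function(i) {
    h <- scanPattern(s, core$pattern[i], seqId = seqId,
                     patternName = core$name[i])
    if (nrow(h)) h$motif_order <- i
    else h$motif_order <- integer(0)
    h
  }))
  if (is.null(hits))
    hits <- data.frame(protein_id = character(), pattern_name = character(),
                       start = integer(), end = integer(),
                       matched = character(), motif_order = integer())
  hits <- hits[order(hits$start, hits$motif_order), , drop = FALSE]
  instances <- .callDomainInstances(hits, minCoreMotifs, window)
  # chimeric partners: partner hits outside called instances
  chim <- character(0)
  partnerHits <- NULL
  if (nrow(partners)) {
    partnerHits <- do.call(rbind, lapply(seq_len(nrow(partners)), function(i)
      scanPattern(s, partners$pattern[i], seqId = seqId,
                  patternName = partners$name[i])))
    if (!is.null(partnerHits) && nrow(partnerHits)) {
      outside <- vapply(seq_len(nrow(partnerHits)), function(i) {
        st <- partnerHits$start[i]; en <- partnerHits$end[i]
        !any(instances$start <= en & instances$end >= st)
      }, logical(1L))
      chim <- sort(unique(partnerHits$pattern_name[outside]))
    }
  }
  nes <- detectNes(s, seqId = seqId)
  n <- nrow(instances)
  out <- data.frame(protein_id = seqId, length = nchar(s),
                    nac_domain_count = n, is_nac = n >= 1L,
                    is_multi_domain = n >= 2L,
                    chimeric_partners = paste(chim, collapse = ";"),
                    n_nes_hits = nrow(nes),
                    domain_intervals = .formatIntervals(instances),
                    stringsAsFactors = FALSE)
  attr(out, "hits") <- hits
  attr(out, "nes") <- nes
  attr(out, "instances") <- instances
  out
}

## Greedy left-to-right instance calling over core-motif hits: for the
## leftmost feasible anchor hit, take the chain (strictly increasing start
## and canonical motif order, all hits within `window` of the anchor start)
## with the most distinct motifs, then the largest end. Non-overlapping.
.callDomainInstances <- function(hits, minCoreMotifs, window) {
  inst <- data.frame(start = integer(), end = integer())
  if (!nrow(hits)) return(inst)
  avail <- hits
  repeat {
    if (!nrow(avail)) break
    called <- FALSE
    for (a in seq_len(nrow(avail))) {
      anchor <- avail[a, ]
      sub <- avail[avail$start >= anchor$start &
                   avail$end <= anchor$start + window - 1L, , drop = FALSE]
      sub <- sub[order(sub$start, sub$motif_order), , drop = FALSE]
      if (!nrow(sub)) next
      # chains must begin at the anchor
      ai <- which(sub$start == anchor$start & sub$motif_order == anchor$motif_order &
                  sub$end == anchor$end)[1L]
      # DP: longest chain of strictly increasing (start, motif_order)
      m <- nrow(sub)
      len <- integer(m); endpos <- integer(m)
      ord <- sub$motif_order; st <- sub$start; en <- sub$end
      for (i in seq_len(m)) {
        len[i] <- 1L; endpos[i] <- en[i]
        for (j in seq_len(i - 1L)) {
          if (st[j] < st[i] && ord[j] < ord[i] && len[j] + 1L > len[i]) {
            len[i] <- len[j] + 1L
          }
        }
      }
      # best chain that starts at the anchor: restricted DP maximizing the
      # number of distinct motifs; among equals, the most compact span, so
      # that a tandem second domain block is never swallowed
      reach <- rep(-1L, m); reach[ai] <- 1L
      bestEnd <- rep(NA_integer_, m); bestEnd[ai] <- en[ai]
      for (i in seq_len(m)) {
        if (i == ai || st[i] <= st[ai]) next
        for (j in seq_len(m)) {
          if (reach[j] > 0L && st[j] < st[i] && ord[j] < ord[i]) {
            cand <- reach[j] + 1L
            candEnd <- max(bestEnd[j], en[i])
            if (cand > reach[i] ||
                (cand == reach[i] && candEnd < bestEnd[i])) {
              reach[i] <- cand
              bestEnd[i] <- candEnd
            }
          }
        }
      }
      best <- max(reach)
      if (best >= minCoreMotifs) {
        iEnd <- min(bestEnd[which(reach == best)])
        inst <- rbind(inst, data.frame(start = anchor$start, end = iEnd))
        avail <- avail[avail$start > iEnd, , drop = FALSE]
        called <- TRUE
        break
      }
    }
    if (!called) break
  }
  inst
}

#' Domain summaries for a whole proteome
#'
#' Applies [countNacDomains()] to every sequence of a set.
#'
#' @param seqs an `AAStringSet`.
#' @inheritParams countNacDomains
#' @return data.frame, one row per protein (see [countNacDomains()]).
#' @export
domainSummary <- function(seqs, catalog = nacMotifCatalog(),
                          minCoreMotifs = 3L, window = 200L) {
  rows <- lapply(seq_along(seqs), function(i)
    countNacDomains(seqs[[i]], catalog = catalog,
                    minCoreMotifs = minCoreMotifs, window = window,
                    seqId = names(seqs)[i]))
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
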