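#' Read a FASTA file into a validated sequence set
#'
#' Thin wrapper around [Biostrings::readBStringSet()] that enforces the
#' package's sequence contract: one record per header, identifiers taken as
#' the first whitespace-delimited token (must be unique), residues
#' uppercased, and every residue drawn from the declared alphabet
#' (20 amino acids plus `X` for proteins; `A,C,G,T,N,-` for DNA). A single
#' terminal `*` in a protein record is treated as a stop marker and
#' stripped.
#'
#' @param path path to a FASTA file.
#' @param alphabet `"protein"` or `"dna"`.
#' @return an [Biostrings::AAStringSet] or [Biostrings::DNAStringSet] with
#'   ids as names and full header descriptions in `mcols(x)$description`.
#' @examples
#' tf <- tempfile(fileext = ".fa")
#' writeLines(c(">a demo", "MKV"), tf)
#' readFasta(tf, "protein")
#' @export
readFasta <- function(path, alphabet = c("protein", "dna")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- Biostrings::readBStringSet(path)
  if (length(raw) == 0L) stop("empty FASTA file: ", path)
  headers <- names(raw)
  ids <- sub("\\s.*$", "", headers)
  if (any(ids == "")) stop("FASTA record with empty identifier in ", path)
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicate FASTA id(s): ", paste(unique(dup), collapse = ", "))
  seqs <- toupper(as.character(raw))
  if (alphabet == "protein") {
    seqs <- sub("\\*$", "", seqs)  # tolerate one terminal stop marker
    allowed <- c(.AA_ALPHABET)
  } else {
    allowed <- .DNA_ALPHABET
  }
  for (i in seq_along(seqs)) {
    if (!nzchar(seqs[i])) stop("empty sequence for id '", ids[i], "'")
    ch <- .splitChars(seqs[i])
    bad <- which(!(ch %in% allowed))
    if (length(bad))
      stop(sprintf("record '%s': residue '%s' at position %d not in %s alphabet",
                   ids[i], ch[bad[1L]], bad[1L], alphabet))
  }
  out <- if (alphabet == "protein") Biostrings::AAStringSet(seqs)
         else Biostrings::DNAStringSet(seqs)
  names(out) <- ids
  desc <- sub("^\\S+\\s*", "", headers)
  S4Vectors::mcols(out) <- S4Vectors::DataFrame(description = desc)
  out
}

#' Write a sequence set to FASTA
#'
#' @param x an `XStringSet` (or named character vector) with unique names.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeFasta <- function(x, path) {
  if (is.character(x)) {
    x <- Biostrings::BStringSet(x)
  }
  if (is.null(names(x)) || anyDuplicated(names(x)))
    stop("sequences must carry unique names")
  Biostrings::writeXStringSet(x, filepath = path, width = 70L)
  invisible(path)
}

## Translate a CDS with the standard genetic code. Returns a protein string;
## codons containing N translate to X. One terminal stop is stripped before
## the caller compares; internal stops are kept as '*'.
.translateCds <- function(cds) {
  n <- nchar(cds)
  if (n %% 3L != 0L) return(NULL)
  codons <- substring(cds, seq(1L, n, by = 3L), seq(3L, n, by = 3L))
  gc <- Biostrings::GENETIC_CODE
  aa <- unname(gc[codons])
  aa[is.na(aa)] <- "X"  # ambiguous bases
  paste(aa, collapse = "")
}

#' Pair protein records with their coding sequences
#'
#' Matches records by id and checks that the standard-code translation of
#' the CDS (after dropping one terminal stop codon, if present) equals the
#' protein sequence, with `X` on either side matching any residue. A CDS
#' whose length is not divisible by 3, or that contains an internal stop,
#' yields `translation_ok = FALSE` with a reason rather than an error.
#'
#' @param proteins protein `AAStringSet` (as from [readFasta()]).
#' @param cds coding-sequence `DNAStringSet`.
#' @return data.frame with columns `id`, `protein_length`, `cds_length`,
#'   `translation_ok`, `reason`. Ids present in only one input are reported
#'   via a warning and the attribute `unmatched`.
#' @examples
#' p <- Biostrings::AAStringSet(c(g1 = "MG"))
#' d <- Biostrings::DNAStringSet(c(g1 = "ATGGGTTAA"))
#' pairProteinCds(p, d)
#' @export
pairProteinCds <- function(proteins, cds) {
  pid <- names(proteins); cid <- names(cds)
  if (is.null(pid) || is.null(cid)) stop("both inputs must be named")
  common <- sort(intersect(pid, cid))
  unmatched <- sort(c(setdiff(pid, cid), setdiff(cid, pid)))
  if (length(unmatched))
    warning("unmatched id(s): ", paste(unmatched, collapse = ", "))
  rows <- lapply(common, function(id) {
    p <- .asSeqString(proteins[id])
    d <- .asSeqString(cds[id])
    ok <- FALSE; reason <- ""
    if (nchar(d) %% 3L != 0L) {
      reason <- "cds length not divisible by 3"
    } else {
      aa <- .translateCds(d)
      # strip exactly one terminal stop
      if (substring(aa, nchar(aa)) == "*") aa <- substring(aa, 1L, nchar(aa) - 1L)
      if (grepl("*", aa, fixed = TRUE)) {
        reason <- "internal stop codon"
      } else if (nchar(aa) != nchar(p)) {
        reason <- sprintf("translated length %d != protein length %d",
                          nchar(aa), nchar(p))
      } else {
        pa <- .splitChars(p); ta <- .splitChars(aa)
        ok <- all(pa == ta | pa == "X" | ta == "X")
        if (!ok) reason <- "translation mismatch"
      }
    }
    data.frame(id = id, protein_length = nchar(p), cds_length = nchar(d),
               translation_ok = ok, reason = reason,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(out))
    out <- data.frame(id = character(), protein_length = integer(),
                      cds_length = integer(), translation_ok = logical(),
                      reason = character(), stringsAsFactors = FALSE)
  attr(out, "unmatched") <- unmatched
  out
}

#' Read / write a newick tree
#'
#' Wrappers around [ape::read.tree()] / [ape::write.tree()] with the
#' package's validation: exactly one tree per file, a hard parse error for
#' malformed newick, and optional enforcement of unique leaf labels.
#'
#' @param path file path.
#' @param uniqueLabels reject duplicate leaf labels (default `TRUE`).
#' @return an [ape::phylo] object.
#' @export
readNewickTree <- function(path, uniqueLabels = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  # ape silently truncates on some malformed inputs; check balance first
  n_open <- lengths(regmatches(txt, gregexpr("(", txt, fixed = TRUE)))
  n_close <- lengths(regmatches(txt, gregexpr(")", txt, fixed = TRUE)))
  if (n_open != n_close)
    stop("unbalanced parentheses in newick file: ", path)
  tr <- tryCatch(ape::read.tree(path), error = function(e) NULL)
  if (is.null(tr)) stop("failed to parse newick file: ", path)
  if (methods::is(tr, "multiPhylo")) {
    if (length(tr) != 1L) stop("expected a single tree in ", path)
    tr <- tr[[1L]]
  }
  if (uniqueLabels && anyDuplicated(tr$tip.label))
    stop("duplicate leaf label(s): ",
         paste(unique(tr$tip.label[duplicated(tr$tip.label)]), collapse = ", "))
  tr
}

#' @rdname readNewickTree
#' @param tree an [ape::phylo] object.
#' @export
writeNewickTree <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
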