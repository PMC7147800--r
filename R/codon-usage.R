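# Codon counting, average abundance and relative synonymous codon usage.

## 64 codons in a fixed order, DNA and RNA labels.
.CODONS_DNA <- local({
  b <- c("T", "C", "A", "G")
  paste0(rep(b, each = 16L), rep(rep(b, each = 4L), 4L), rep(b, 16L))
})
.toRna <- function(x) chartr("T", "U", x)
.CODONS_RNA <- .toRna(.CODONS_DNA)
.STOP_DNA <- c("TAA", "TAG", "TGA")
.SENSE_RNA <- .CODONS_RNA[!(.CODONS_DNA %in% .STOP_DNA)]

## amino acid per sense codon (RNA labels)
.codonAA <- local({
  gc <- Biostrings::GENETIC_CODE
  setNames(unname(gc[.CODONS_DNA]), .CODONS_RNA)
})

#' Count codons in a coding sequence
#'
#' Counts in-frame codons over the 61 sense and 3 stop codons. One terminal
#' stop codon is tolerated and counted; codons containing ambiguous bases
#' (`N`) are skipped and tallied separately. RNA input (`U`) is accepted
#' and normalized. Labels in the result use the RNA alphabet.
#'
#' @param cds coding sequence (character, `DNAString`, or length-1 set).
#' @param frame reading-frame offset (0, 1 or 2; default 0).
#' @return named integer vector of 64 codon counts with attribute
#'   `skipped` (number of ambiguous codons). A length (after the frame
#'   offset) not divisible by 3 is an error naming the record.
#' @examples
#' countCodons("ATGAAGTAA")
#' @export
countCodons <- function(cds, frame = 0L) {
  s <- chartr("U", "T", .asSeqString(cds))
  if (frame < 0L || frame > 2L) stop("frame must be 0, 1 or 2")
  s <- substring(s, frame + 1L)
  n <- nchar(s)
  if (n %% 3L != 0L)
    stop(sprintf("sequence length %d not divisible by 3 (frame %d)", n, frame))
  codons <- substring(s, seq(1L, n, by = 3L), seq(3L, n, by = 3L))
  known <- codons %in% .CODONS_DNA
  counts <- table(factor(codons[known], levels = .CODONS_DNA))
  out <- setNames(as.integer(counts), .CODONS_RNA)
  attr(out, "skipped") <- sum(!known)
  out
}

#' Relative synonymous codon usage
#'
#' For each sense codon, the observed count divided by the expected count
#' under uniform use within its synonymous family:
#' `rscu_c = count_c / (family_total / family_size)`. Families with zero
#' total get `NA`; single-codon families (AUG, UGG) have RSCU 1 whenever
#' the codon is present.
#'
#' @param counts named numeric vector of codon counts (RNA or DNA labels,
#'   64 or 61 entries; stop codons are ignored).
#' @return named numeric vector over the 61 sense codons.
#' @examples
#' cnt <- countCodons("GCTGCTGCCGCA")
#' rscu(cnt)[c("GCU", "GCC", "GCA", "GCG")]
#' @export
rscu <- function(counts) {
  names(counts) <- .toRna(names(counts))
  x <- setNames(numeric(61L), .SENSE_RNA)
  x[intersect(names(counts), .SENSE_RNA)] <-
    counts[intersect(names(counts), .SENSE_RNA)]
  fam <- split(names(x), .codonAA[names(x)])
  out <- setNames(rep(NA_real_, 61L), .SENSE_RNA)
  for (codons in fam) {
    tot <- sum(x[codons])
    if (tot > 0)
      out[codons] <- x[codons] / (tot / length(codons))
  }
  out
}

#' Per-species codon usage summary
#'
#' Aggregates per-gene codon counts into a [CodonUsageTable-class]:
#' total counts, average abundance per gene
#' (`avg_abundance_c = total count of c / n_genes`), presence flags and
#' RSCU over the pooled counts.
#'
#' @param cdsSet a `DNAStringSet` of coding sequences (>= 1 gene). Records
#'   whose length is not divisible by 3 are skipped with a warning, not
#'   fatal.
#' @param speciesId species identifier.
#' @return a [CodonUsageTable-class].
#' @export
speciesCodonUsage <- function(cdsSet, speciesId = "species") {
  if (length(cdsSet) < 1L) stop("need at least one gene")
  total <- setNames(integer(64L), .CODONS_RNA)
  skipped <- 0L
  used <- 0L
  for (i in seq_along(cdsSet)) {
    cnt <- tryCatch(countCodons(cdsSet[[i]]), error = function(e) {
      warning("record '", names(cdsSet)[i], "' skipped: ",
              conditionMessage(e))
      NULL
    })
    if (is.null(cnt)) next
    total <- total + cnt
    skipped <- skipped + attr(cnt, "skipped")
    used <- used + 1L
  }
  if (used == 0L) stop("no usable coding sequences")
  methods::new("CodonUsageTable", speciesId = speciesId,
               counts = total, nGenes = used,
               avgAbundance = total[.SENSE_RNA] / used,
               rscu = rscu(total), skipped = skipped)
}

#' Codon presence/absence across species
#'
#' @param summaries list of [CodonUsageTable-class] objects.
#' @return list with `presence` (species x codon logical matrix),
#'   `n_species` (per-codon count of species where the codon occurs) and
#'   `universal` (codons present in every species). Order of species does
#'   not affect the per-codon counts.
#' @export
codonPresenceMatrix <- function(summaries) {
  if (!length(summaries)) stop("need at least one species summary")
  ids <- vapply(summaries, function(s) s@speciesId, character(1L))
  pres <- t(vapply(summaries, function(s) s@counts > 0L, logical(64L)))
  dimnames(pres) <- list(ids, .CODONS_RNA)
  nsp <- colSums(pres)
  list(presence = pres, n_species = nsp,
       universal = names(nsp)[nsp == length(summaries)])
}
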