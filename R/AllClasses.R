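#' @title S4 classes used across the package
#' @description Central value objects: compiled motif patterns, HMM
#'   parameterizations, per-species codon usage tables, substitution-pattern
#'   estimates and reconciliation results.
#' @name nacprofiler-classes
NULL

#' Compiled PROSITE-style pattern
#'
#' A deterministic compilation of a PROSITE-style pattern string
#' (e.g. `"P-G-F-R-F-H-P-T-D-[DE]-L-[IV]"`) into an ordered list of match
#' elements. Each element is a list with fields `type` (one of `"fixed"`,
#' `"class"`, `"excluded"`, `"wildcard"`), `residues` (character vector),
#' `min` and `max` (repeat range).
#'
#' @slot source normalized pattern string (slash shorthand expanded).
#' @slot elements ordered list of match elements.
#' @exportClass Pattern
setClass("Pattern", representation(source = "character", elements = "list"))

setValidity("Pattern", function(object) {
  if (length(object@source) != 1L) return("source must be a single string")
  if (!length(object@elements)) return("pattern has no elements")
  TRUE
})

#' @describeIn Pattern compact display
#' @param object a `Pattern`
#' @export
setMethod("show", "Pattern", function(object) {
  cat("Pattern of", length(object@elements), "elements:",
      object@source, "\n")
})

#' Two-state HMM parameters for NLS detection
#'
#' States are `BG` (background) and `NLS`. Rows of `transition` and
#' `emission` are states; emission columns are the 20 amino acids.
#'
#' @slot initial named numeric of length 2 (`BG`, `NLS`), sums to 1.
#' @slot transition 2x2 row-stochastic matrix.
#' @slot emission 2x20 row-stochastic matrix over the amino-acid alphabet.
#' @exportClass HmmParams
setClass("HmmParams", representation(initial = "numeric",
                                     transition = "matrix",
                                     emission = "matrix"))

setValidity("HmmParams", function(object) {
  tol <- 1e-9
  states <- c("BG", "NLS")
  if (!identical(names(object@initial), states))
    return("initial must be named c(BG=, NLS=)")
  if (any(object@initial < 0) || abs(sum(object@initial) - 1) > tol)
    return("initial probabilities must be >= 0 and sum to 1")
  if (!identical(dim(object@transition), c(2L, 2L)) ||
      !identical(rownames(object@transition), states))
    return("transition must be a 2x2 matrix with rows BG, NLS")
  if (any(object@transition < 0) ||
      any(abs(rowSums(object@transition) - 1) > tol))
    return("transition rows must be >= 0 and sum to 1")
  if (!identical(rownames(object@emission), states) ||
      !identical(sort(colnames(object@emission)), sort(.AA20)))
    return("emission must have rows BG, NLS and the 20 amino-acid columns")
  if (any(object@emission < 0) ||
      any(abs(rowSums(object@emission) - 1) > tol))
    return("emission rows must be >= 0 and sum to 1")
  TRUE
})

#' @describeIn HmmParams compact display
#' @param object a `HmmParams`
#' @export
setMethod("show", "HmmParams", function(object) {
  cat("2-state HMM (BG/NLS)\n")
  cat("  initial:    BG", format(object@initial["BG"]),
      " NLS", format(object@initial["NLS"]), "\n")
  cat("  P(NLS->NLS) =", format(object@transition["NLS", "NLS"]),
      " P(BG->NLS) =", format(object@transition["BG", "NLS"]), "\n")
  top <- sort(object@emission["NLS", ], decreasing = TRUE)[1:3]
  cat("  top NLS emissions:",
      paste(names(top), format(top), collapse = ", "), "\n")
})

#' Per-species codon usage table
#'
#' Codon labels use the RNA alphabet (`AAG`, `UCU`, ...) to match how codon
#' tables are conventionally printed. `rscu` is defined over the 61 sense
#' codons; stop codons are counted but excluded from abundance and RSCU.
#'
#' @slot speciesId single species identifier.
#' @slot counts named integer vector of 64 codon counts (totals over genes).
#' @slot nGenes number of genes aggregated.
#' @slot avgAbundance per-codon mean count per gene (61 sense codons).
#' @slot rscu per-sense-codon relative synonymous codon usage (NA for
#'   families with zero total).
#' @slot skipped number of codons skipped for ambiguous bases.
#' @exportClass CodonUsageTable
setClass("CodonUsageTable", representation(speciesId = "character",
                                           counts = "integer",
                                           nGenes = "integer",
                                           avgAbundance = "numeric",
                                           rscu = "numeric",
                                           skipped = "integer"))

setValidity("CodonUsageTable", function(object) {
  if (length(object@counts) != 64L) return("counts must cover 64 codons")
  if (length(object@avgAbundance) != 61L || length(object@rscu) != 61L)
    return("avgAbundance and rscu must cover the 61 sense codons")
  if (object@nGenes < 1L) return("nGenes must be >= 1")
  TRUE
})

#' @describeIn CodonUsageTable compact display
#' @param object a `CodonUsageTable`
#' @export
setMethod("show", "CodonUsageTable", function(object) {
  cat("CodonUsageTable for", object@speciesId, "-", object@nGenes,
      "genes,", sum(object@counts), "codons counted\n")
  r <- object@rscu[!is.na(object@rscu)]
  if (length(r)) {
    top <- sort(r, decreasing = TRUE)[1L]
    cat("  highest RSCU:", names(top), format(round(top, 3)), "\n")
  }
})

#' Estimated pattern of nucleotide substitution (TN93)
#'
#' Off-diagonal `rates` entries are percentages summing to 100; `k1` and
#' `k2` are the purine and pyrimidine transition/transversion rate ratios
#' and `tsTv` the overall expected transition/transversion bias R.
#'
#' @slot rates 4x4 matrix (A,C,G,T), diagonal NA, off-diagonal percentages.
#' @slot k1 purine transition/transversion rate ratio.
#' @slot k2 pyrimidine transition/transversion rate ratio.
#' @slot tsTv overall transition/transversion bias R (may be `Inf` when no
#'   transversions were observed, `NA` at zero divergence).
#' @slot baseFreqs empirical base frequencies (A,C,G,T).
#' @slot distance composite-likelihood divergence estimate (subs/site).
#' @slot sites number of pairwise-comparable sites pooled.
#' @exportClass SubstitutionPattern
setClass("SubstitutionPattern", representation(rates = "matrix",
                                               k1 = "numeric",
                                               k2 = "numeric",
                                               tsTv = "numeric",
                                               baseFreqs = "numeric",
                                               distance = "numeric",
                                               sites = "numeric"))

setValidity("SubstitutionPattern", function(object) {
  if (!identical(dim(object@rates), c(4L, 4L)))
    return("rates must be 4x4")
  off <- object@rates[row(object@rates) != col(object@rates)]
  if (all(!is.na(off)) && abs(sum(off) - 100) > 1e-6)
    return("off-diagonal rates must sum to 100")
  TRUE
})

#' @describeIn SubstitutionPattern compact display
#' @param object a `SubstitutionPattern`
#' @export
setMethod("show", "SubstitutionPattern", function(object) {
  cat("TN93 substitution pattern over", object@sites, "pooled sites\n")
  cat("  k1 =", format(round(object@k1, 3)),
      " k2 =", format(round(object@k2, 3)),
      " R =", format(round(object@tsTv, 3)), "\n")
  print(round(object@rates, 2))
})

#' Gene-tree/species-tree reconciliation result
#'
#' @slot duplications number of duplication nodes under LCA mapping.
#' @slot losses implied losses (deleted gene lineages).
#' @slot paralogCount number of genes descending from >= 1 duplication node.
#' @slot nodeEvents character vector, one of `"speciation"`/`"duplication"`
#'   per internal gene-tree node (in `phylo` internal node order).
#' @exportClass ReconciliationResult
setClass("ReconciliationResult", representation(duplications = "integer",
                                                losses = "integer",
                                                paralogCount = "integer",
                                                nodeEvents = "character"))

#' @describeIn ReconciliationResult compact display
#' @param object a `ReconciliationResult`
#' @export
setMethod("show", "ReconciliationResult", function(object) {
  cat("Reconciliation:", object@duplications, "duplication(s),",
      object@losses, "loss(es),", object@paralogCount, "paralogous gene(s)\n")
})

## ---- generics + accessors -------------------------------------------------

#' Purine transition/transversion rate ratio
#' @param x a [SubstitutionPattern-class]
#' @return numeric scalar
#' @export
setGeneric("k1", function(x) standardGeneric("k1"))
#' Pyrimidine transition/transversion rate ratio
#' @param x a [SubstitutionPattern-class]
#' @return numeric scalar
#' @export
setGeneric("k2", function(x) standardGeneric("k2"))
#' Overall transition/transversion bias R
#' @param x a [SubstitutionPattern-class]
#' @return numeric scalar
#' @export
setGeneric("tsTvRatio", function(x) standardGeneric("tsTvRatio"))
#' Substitution-rate percentage table
#' @param x a [SubstitutionPattern-class]
#' @return 4x4 matrix of percentages
#' @export
setGeneric("substitutionRates", function(x) standardGeneric("substitutionRates"))
#' Empirical base frequencies
#' @param x a [SubstitutionPattern-class]
#' @return named numeric (A,C,G,T)
#' @export
setGeneric("baseFreqs", function(x) standardGeneric("baseFreqs"))

#' @rdname k1
#' @export
setMethod("k1", "SubstitutionPattern", function(x) x@k1)
#' @rdname k2
#' @export
setMethod("k2", "SubstitutionPattern", function(x) x@k2)
#' @rdname tsTvRatio
#' @export
setMethod("tsTvRatio", "SubstitutionPattern", function(x) x@tsTv)
#' @rdname substitutionRates
#' @export
setMethod("substitutionRates", "SubstitutionPattern", function(x) x@rates)
#' @rdname baseFreqs
#' @export
setMethod("baseFreqs", "SubstitutionPattern", function(x) x@baseFreqs)

#' Number of duplication events
#' @param x a [ReconciliationResult-class]
#' @return integer
#' @export
setGeneric("duplications", function(x) standardGeneric("duplications"))
#' Number of implied gene losses
#' @param x a [ReconciliationResult-class]
#' @return integer
#' @export
setGeneric("losses", function(x) standardGeneric("losses"))
#' Number of paralogous genes
#' @param x a [ReconciliationResult-class]
#' @return integer
#' @export
setGeneric("paralogCount", function(x) standardGeneric("paralogCount"))

#' @rdname duplications
#' @export
setMethod("duplications", "ReconciliationResult", function(x) x@duplications)
#' @rdname losses
#' @export
setMethod("losses", "ReconciliationResult", function(x) x@losses)
#' @rdname paralogCount
#' @export
setMethod("paralogCount", "ReconciliationResult", function(x) x@paralogCount)

#' Codon counts
#' @param x a [CodonUsageTable-class]
#' @return named integer vector (64 codons, RNA labels)
#' @export
setGeneric("codonCounts", function(x) standardGeneric("codonCounts"))
#' Average codon abundance per gene
#' @param x a [CodonUsageTable-class]
#' @return named numeric over the 61 sense codons
#' @export
setGeneric("avgAbundance", function(x) standardGeneric("avgAbundance"))
#' Relative synonymous codon usage values
#' @param x a [CodonUsageTable-class]
#' @return named numeric over the 61 sense codons (NA for empty families)
#' @export
setGeneric("rscuValues", function(x) standardGeneric("rscuValues"))

#' @rdname codonCounts
#' @export
setMethod("codonCounts", "CodonUsageTable", function(x) x@counts)
#' @rdname avgAbundance
#' @export
setMethod("avgAbundance", "CodonUsageTable", function(x) x@avgAbundance)
#' @rdname rscuValues
#' @export
setMethod("rscuValues", "CodonUsageTable", function(x) x@rscu)
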