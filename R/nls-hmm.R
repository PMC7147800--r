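# Two-state HMM NLS detector: Viterbi and posterior decoding.

#' Construct a two-state HMM parameterization
#'
#' @param initial named numeric `c(BG=, NLS=)`.
#' @param transition 2x2 row-stochastic matrix with dimnames
#'   `list(c("BG","NLS"), c("BG","NLS"))`.
#' @param emission 2x20 row-stochastic matrix, rows `BG`, `NLS`, columns
#'   the 20 amino acids.
#' @return a validated [HmmParams-class].
#' @export
HmmParams <- function(initial, transition, emission) {
  obj <- methods::new("HmmParams", initial = initial,
                      transition = transition,
                      emission = emission[, .AA20, drop = FALSE])
  methods::validObject(obj)
  obj
}

#' Default static NLS HMM parameters
#'
#' A replaceable prior capturing the basic-residue enrichment of nuclear
#' localization signals: the NLS state emits K and R at 0.30 each (the
#' remaining 18 residues uniformly), the background state is uniform.
#' Transitions keep the background sticky (BG->BG 0.99) and NLS segments
#' moderately persistent (NLS->NLS 0.90).
#'
#' @return a [HmmParams-class].
#' @export
defaultNlsHmm <- function() {
  states <- c("BG", "NLS")
  initial <- c(BG = 0.99, NLS = 0.01)
  transition <- matrix(c(0.99, 0.01, 0.10, 0.90), nrow = 2, byrow = TRUE,
                       dimnames = list(states, states))
  em <- matrix(0, nrow = 2, ncol = 20, dimnames = list(states, .AA20))
  em["BG", ] <- 1 / 20
  em["NLS", ] <- 0.4 / 18
  em["NLS", c("K", "R")] <- 0.30
  HmmParams(initial, transition, em)
}

#' Read / write HMM parameters as a section/key/value TSV
#'
#' Layout: three columns `section`, `key`, `value`; sections are
#' `initial` (key = state), `transition` (key = `FROM:TO`) and `emission`
#' (key = `STATE:RESIDUE`). Any file in this layout can be loaded, so
#' externally trained state frequencies can be swapped in. An editable
#' copy of the default parameterization ships at
#' `system.file("extdata", "nls_hmm_default.tsv", package = "nacprofiler")`.
#'
#' @param path file path.
#' @return a [HmmParams-class] for `readHmmParams`; `path` invisibly for
#'   `writeHmmParams`.
#' @export
readHmmParams <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  states <- c("BG", "NLS")
  ini <- setNames(rep(NA_real_, 2), states)
  tr <- matrix(NA_real_, 2, 2, dimnames = list(states, states))
  em <- matrix(NA_real_, 2, 20, dimnames = list(states, .AA20))
  for (i in seq_len(nrow(df))) {
    sec <- df$section[i]; key <- df$key[i]; val <- as.numeric(df$value[i])
    if (sec == "initial") ini[key] <- val
    else if (sec == "transition") {
      kk <- strsplit(key, ":", fixed = TRUE)[[1L]]
      tr[kk[1L], kk[2L]] <- val
    } else if (sec == "emission") {
      kk <- strsplit(key, ":", fixed = TRUE)[[1L]]
      em[kk[1L], kk[2L]] <- val
    } else stop("unknown section '", sec, "'")
  }
  if (anyNA(ini) || anyNA(tr) || anyNA(em))
    stop("incomplete HMM parameter file: ", path)
  HmmParams(ini, tr, em)
}

#' @rdname readHmmParams
#' @param params a [HmmParams-class].
#' @export
writeHmmParams <- function(params, path) {
  rows <- rbind(
    data.frame(section = "initial", key = names(params@initial),
               value = unname(params@initial)),
    data.frame(section = "transition",
               key = as.vector(outer(rownames(params@transition),
                                     colnames(params@transition),
                                     paste, sep = ":")),
               value = as.vector(params@transition)),
    data.frame(section = "emission",
               key = as.vector(outer(rownames(params@emission),
                                     colnames(params@emission),
                                     paste, sep = ":")),
               value = as.vector(params@emission)))
  writeTsv(rows, path)
}

## Emission probabilities per position; unknown residues (X) emit the row
## mean so they are uninformative for state inference.
.emissionSeq <- function(params, ch) {
  e <- params@emission
  out <- matrix(NA_real_, nrow = 2, ncol = length(ch),
                dimnames = list(rownames(e), NULL))
  known <- ch %in% colnames(e)
  out[, known] <- e[, ch[known], drop = FALSE]
  out[, !known] <- rowMeans(e)
  out
}

#' Viterbi decoding
#'
#' Maximum-probability state path in log space; ties are broken toward the
#' background state. A sequence with probability zero under the model is an
#' explicit error.
#'
#' @inheritParams scanPattern
#' @param params a [HmmParams-class].
#' @return character vector of states (`"BG"`/`"NLS"`), with the log
#'   probability of the path in attribute `logprob`.
#' @export
viterbiDecode <- function(seq, params = defaultNlsHmm()) {
  ch <- .checkProtein(.asSeqString(seq))
  L <- length(ch)
  em <- log(.emissionSeq(params, ch))
  lt <- log(params@transition)
  v <- matrix(-Inf, 2, L)
  ptr <- matrix(0L, 2, L)
  v[, 1L] <- log(params@initial) + em[, 1L]
  if (L > 1L) for (t in 2L:L) {
    for (s in 1:2) {
      cand <- v[, t - 1L] + lt[, s]
      # ties toward BG: BG is row 1, which.max picks the first maximum
      best <- which.max(cand)
      v[s, t] <- cand[best] + em[s, t]
      ptr[s, t] <- best
    }
  }
  if (all(!is.finite(v[, L])))
    stop("sequence has zero probability under the model")
  path <- integer(L)
  path[L] <- which.max(v[, L])  # tie -> BG (row 1 first)
  if (L > 1L) for (t in (L - 1L):1L) path[t] <- ptr[path[t + 1L], t + 1L]
  out <- c("BG", "NLS")[path]
  attr(out, "logprob") <- max(v[, L])
  out
}

#' Posterior decoding (forward-backward)
#'
#' Scaled forward-backward; per-position state marginals sum to one.
#'
#' @inheritParams viterbiDecode
#' @return numeric vector of per-position `P(NLS)`, with the sequence
#'   log-likelihood in attribute `loglik`.
#' @export
posteriorDecode <- function(seq, params = defaultNlsHmm()) {
  ch <- .checkProtein(.asSeqString(seq))
  L <- length(ch)
  em <- .emissionSeq(params, ch)
  A <- params@transition
  f <- matrix(0, 2, L); b <- matrix(0, 2, L)
  scale <- numeric(L)
  f[, 1L] <- params@initial * em[, 1L]
  scale[1L] <- sum(f[, 1L])
  if (scale[1L] == 0) stop("sequence has zero probability under the model")
  f[, 1L] <- f[, 1L] / scale[1L]
  if (L > 1L) for (t in 2L:L) {
    f[, t] <- (t(A) %*% f[, t - 1L]) * em[, t]
    scale[t] <- sum(f[, t])
    if (scale[t] == 0) stop("sequence has zero probability under the model")
    f[, t] <- f[, t] / scale[t]
  }
  b[, L] <- 1
  if (L > 1L) for (t in (L - 1L):1L) {
    b[, t] <- A %*% (em[, t + 1L] * b[, t + 1L]) / scale[t + 1L]
  }
  post <- f * b
  post <- sweep(post, 2L, colSums(post), "/")
  out <- post[2L, ]
  attr(out, "loglik") <- sum(log(scale))
  out
}

#' Call NLS intervals from HMM decoding
#'
#' With the posterior decoder, calls are maximal runs of positions whose
#' `P(NLS)` meets `cutoff`; with the Viterbi decoder, maximal runs of the
#' NLS state. Runs shorter than `minLen` are dropped. The mean posterior
#' over each interval is always reported.
#'
#' @inheritParams viterbiDecode
#' @param cutoff posterior cutoff in (0, 1) (default 0.4).
#' @param decoder `"posterior"` (default) or `"viterbi"`.
#' @param minLen minimum interval length (default 4, the shortest
#'   monopartite class-II signal).
#' @param seqId identifier for the output.
#' @return data.frame with columns `protein_id`, `start`, `end`,
#'   `decoder`, `mean_posterior`.
#' @export
callNls <- function(seq, params = defaultNlsHmm(), cutoff = 0.4,
                    decoder = c("posterior", "viterbi"), minLen = 4L,
                    seqId = NULL) {
  decoder <- match.arg(decoder)
  if (cutoff <= 0 || cutoff >= 1) stop("cutoff must be in (0, 1)")
  if (is.null(seqId))
    seqId <- if (!is.null(names(seq)) && nzchar(names(seq)[1L])) names(seq)[1L] else "seq"
  post <- posteriorDecode(seq, params)
  mask <- if (decoder == "posterior") post >= cutoff
          else viterbiDecode(seq, params) == "NLS"
  r <- rle(as.vector(mask))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= minLen
  starts <- starts[keep]; ends <- ends[keep]
  data.frame(protein_id = rep(seqId, length(starts)),
             start = starts, end = ends,
             decoder = rep(decoder, length(starts)),
             mean_posterior = vapply(seq_along(starts), function(i)
               mean(post[starts[i]:ends[i]]), numeric(1L)),
             stringsAsFactors = FALSE)
}
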