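# Shared constants and small helpers.

.AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
           "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
.AA_ALPHABET <- c(.AA20, "X")
.DNA_ALPHABET <- c("A", "C", "G", "T", "N", "-")
.BASES <- c("A", "C", "G", "T")

#' @importFrom methods new validObject is slot
#' @importFrom stats setNames runif optim
#' @importFrom utils write.table read.table head
NULL

.splitChars <- function(x) strsplit(x, "", fixed = TRUE)[[1L]]

## Accept an XString/XStringSet element or plain character; return one
## uppercase character string.
.asSeqString <- function(x) {
  if (methods::is(x, "XStringSet")) {
    if (length(x) != 1L)
      stop("expected a single sequence, got a set of length ", length(x))
    x <- x[[1L]]
  }
  toupper(as.character(x))
}

.checkProtein <- function(s, what = "sequence", allowX = TRUE) {
  ch <- .splitChars(s)
  allowed <- if (allowX) .AA_ALPHABET else .AA20
  bad <- which(!(ch %in% allowed))
  if (length(bad))
    stop(sprintf("%s contains non-protein residue '%s' at position %d",
                 what, ch[bad[1L]], bad[1L]))
  invisible(ch)
}

## Deterministic TSV writer used by every tabular output (UTF-8, header,
## tab-delimited, LF line endings) so reruns are byte-identical.
writeTsv <- function(df, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  txt <- c(paste(colnames(df), collapse = "\t"),
           if (nrow(df)) do.call(paste, c(lapply(df, function(col) {
             if (is.numeric(col)) format(col, trim = TRUE, digits = 15,
                                         scientific = FALSE)
             else as.character(col)
           }), sep = "\t")))
  writeLines(txt, con = con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

## 1-based inclusive interval formatting for reports ("12-40;55-80" or "").
.formatIntervals <- function(df) {
  if (is.null(df) || nrow(df) == 0L) return("")
  paste(sprintf("%d-%d", df$start, df$end), collapse = ";")
}

## Derive a bounded child seed from a user seed (keeps well below 2^31).
.childSeed <- function(seed, k) {
  (as.integer(seed) %% 1000003L) * 1009L + as.integer(k) %% 1009L
}
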