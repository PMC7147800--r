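# Molecular weight, isoelectric point and hydropathy-based TM calling.

## Average (not monoisotopic) residue masses, Da. Condensation: protein
## mass = sum(residue masses) + one water (18.02).
.RESIDUE_MASS <- c(A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886,
                   C = 103.1388, E = 129.1155, Q = 128.1307, G = 57.0519,
                   H = 137.1411, I = 113.1594, L = 113.1594, K = 128.1741,
                   M = 131.1926, F = 147.1766, P = 97.1167, S = 87.0782,
                   T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326)
.WATER_MASS <- 18.02

## Kyte-Doolittle hydropathy
.KD <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5,
         E = -3.5, G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9,
         M = 1.9, F = 2.8, P = -1.6, S = -0.8, T = -0.7, W = -0.9,
         Y = -1.3, V = 4.2)

.PKA_TABLES <- list(
  # EMBOSS iep defaults
  emboss = c(Nterm = 8.6, Cterm = 3.6, C = 8.5, D = 3.9, E = 4.1,
             H = 6.5, K = 10.8, R = 12.5, Y = 10.1),
  # free amino-acid values (Lehninger)
  lehninger = c(Nterm = 9.69, Cterm = 2.34, C = 8.18, D = 3.65, E = 4.25,
                H = 6.0, K = 10.53, R = 12.48, Y = 10.07))

#' Side-chain and terminal pKa tables
#'
#' @param name table name (`"emboss"`, the default used throughout, or
#'   `"lehninger"`).
#' @return named numeric vector of pKa values (`Nterm`, `Cterm`, `C`, `D`,
#'   `E`, `H`, `K`, `R`, `Y`).
#' @export
pkaTable <- function(name = "emboss") {
  if (!name %in% names(.PKA_TABLES))
    stop("unknown pKa table '", name, "'; available: ",
         paste(names(.PKA_TABLES), collapse = ", "))
  .PKA_TABLES[[name]]
}

#' Average molecular weight of a protein
#'
#' Sum of average residue masses plus one water mass (18.02 Da). `X` or
#' other non-standard residues are an error naming the offending position.
#'
#' @inheritParams scanPattern
#' @return molecular weight in daltons.
#' @examples
#' molecularWeight("G")  # 75.07
#' @export
molecularWeight <- function(seq) {
  s <- .asSeqString(seq)
  if (!nzchar(s)) stop("empty sequence")
  ch <- .checkProtein(s, allowX = FALSE)
  sum(.RESIDUE_MASS[ch]) + .WATER_MASS
}

#' Net charge of a protein at a given pH
#'
#' Henderson-Hasselbalch sum over the free N-terminus, C-terminus, and the
#' ionizable side chains (D, E, C, Y negative; K, R, H positive).
#'
#' @inheritParams scanPattern
#' @param ph pH value in `[0, 14]`.
#' @param pka a pKa table (see [pkaTable()]) or its name.
#' @return net charge in elementary charges.
#' @export
netCharge <- function(seq, ph, pka = "emboss") {
  if (is.character(pka)) pka <- pkaTable(pka)
  if (any(ph < 0 | ph > 14)) stop("ph must be within [0, 14]")
  s <- .asSeqString(seq)
  ch <- .checkProtein(s, allowX = FALSE)
  cnt <- table(factor(ch, levels = .AA20))
  pos <- function(pk) 1 / (1 + 10^(ph - pk))   # protonated fraction
  neg <- function(pk) 1 / (1 + 10^(pk - ph))   # deprotonated fraction
  charge <- pos(pka["Nterm"]) - neg(pka["Cterm"])
  charge <- charge + cnt["K"] * pos(pka["K"]) + cnt["R"] * pos(pka["R"]) +
    cnt["H"] * pos(pka["H"])
  charge <- charge - cnt["D"] * neg(pka["D"]) - cnt["E"] * neg(pka["E"]) -
    cnt["C"] * neg(pka["C"]) - cnt["Y"] * neg(pka["Y"])
  unname(charge)
}

#' Isoelectric point by bisection
#'
#' Root of [netCharge()] over pH in `[0, 14]`. The charge is strictly
#' decreasing in pH, so the root exists and is unique; bisection runs to a
#' pH tolerance of 1e-4 (refined to 1e-6 internally).
#'
#' @inheritParams netCharge
#' @return the isoelectric point (pH units).
#' @export
isoelectricPoint <- function(seq, pka = "emboss") {
  if (is.character(pka)) pka <- pkaTable(pka)
  lo <- 0; hi <- 14
  for (i in 1:40) {
    mid <- (lo + hi) / 2
    if (netCharge(seq, mid, pka) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Classify a pI as acidic or basic
#'
#' @param pi isoelectric point(s).
#' @param threshold boundary (default 7.0); values `< threshold` are acidic.
#' @return character vector of `"acidic"` / `"basic"`.
#' @export
classifyPi <- function(pi, threshold = 7.0) {
  ifelse(pi < threshold, "acidic", "basic")
}

#' Hydropathy-window transmembrane segment scan
#'
#' A documented stand-in for server-based TM predictors: positions are
#' covered by a candidate window when the mean Kyte-Doolittle hydropathy of
#' the `window` residues starting there is at least `threshold`; maximal
#' unions of overlapping qualifying windows are reported as segments. Every
#' reported segment is at least `window` residues long.
#'
#' @inheritParams scanPattern
#' @param window window length in residues (default 19).
#' @param threshold mean-hydropathy cutoff (default 1.6).
#' @return data.frame with columns `start`, `end` (1-based inclusive);
#'   zero rows when the sequence is shorter than `window` or has no
#'   qualifying window.
#' @export
tmScan <- function(seq, window = 19L, threshold = 1.6) {
  if (window < 1L) stop("window must be >= 1")
  s <- .asSeqString(seq)
  ch <- .checkProtein(s)
  L <- length(ch)
  if (L < window) return(data.frame(start = integer(), end = integer()))
  h <- .KD[ch]
  h[is.na(h)] <- 0  # X contributes 0 hydropathy
  cs <- c(0, cumsum(h))
  means <- (cs[(window + 1L):(L + 1L)] - cs[1:(L - window + 1L)]) / window
  ok <- which(means >= threshold - 1e-9)  # guard exact-boundary rounding
  if (!length(ok)) return(data.frame(start = integer(), end = integer()))
  # merge overlapping/adjacent qualifying windows
  starts <- ok; ends <- ok + window - 1L
  segS <- starts[1L]; segE <- ends[1L]
  outS <- integer(0); outE <- integer(0)
  if (length(ok) > 1L) for (i in 2L:length(ok)) {
    if (starts[i] <= segE + 1L) segE <- ends[i]
    else { outS <- c(outS, segS); outE <- c(outE, segE)
           segS <- starts[i]; segE <- ends[i] }
  }
  outS <- c(outS, segS); outE <- c(outE, segE)
  data.frame(start = unname(outS), end = unname(outE))
}

#' Physicochemical profile of a proteome
#'
#' Computes molecular weight, isoelectric point, acidic/basic class and
#' hydropathy-based TM segments for every protein. Records containing `X`
#' get `NA` weight/pI (with a warning) rather than failing the run.
#'
#' @param seqs an `AAStringSet`.
#' @param piThreshold acidic/basic boundary (default 7.0).
#' @param pka pKa table or name (see [pkaTable()]).
#' @param tmWindow,tmThreshold see [tmScan()].
#' @return data.frame with columns `id`, `length`, `mw_da`, `pi`,
#'   `charge_class`, `n_tm_segments`, `tm_segments_hydropathy`,
#'   `is_membrane_bound`.
#' @export
physchemProfile <- function(seqs, piThreshold = 7.0, pka = "emboss",
                            tmWindow = 19L, tmThreshold = 1.6) {
  if (is.character(pka)) pka <- pkaTable(pka)
  rows <- lapply(seq_along(seqs), function(i) {
    id <- names(seqs)[i]
    s <- .asSeqString(seqs[i])
    mw <- tryCatch(molecularWeight(s), error = function(e) NA_real_)
    pi <- if (is.na(mw)) NA_real_ else isoelectricPoint(s, pka)
    tm <- tmScan(s, window = tmWindow, threshold = tmThreshold)
    data.frame(id = id, length = nchar(s), mw_da = mw, pi = pi,
               charge_class = if (is.na(pi)) NA_character_
                              else classifyPi(pi, piThreshold),
               n_tm_segments = nrow(tm),
               tm_segments_hydropathy = .formatIntervals(tm),
               is_membrane_bound = nrow(tm) > 0L,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (any(is.na(out$mw_da)))
    warning(sum(is.na(out$mw_da)),
            " record(s) with non-standard residues: mw/pi set to NA")
  out
}
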