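# Orchestration: configuration validation and the end-to-end per-species
# run producing the summary report shaped like a genomic census table.

.CONFIG_DEFAULTS <- list(
  min_core_motifs = 3L,      # distinct core motifs per NAC domain call
  domain_window = 200L,      # residue window for motif co-occurrence
  pi_threshold = 7.0,        # acidic/basic pI boundary
  tm_window = 19L,           # hydropathy window
  tm_threshold = 1.6,        # mean Kyte-Doolittle cutoff
  nls_cutoff = 0.4,          # posterior prediction cut-off
  nls_decoder = "posterior", # or "viterbi"
  nls_min_len = 4L,          # shortest callable NLS
  cluster_merge_gap = 4L,    # basic-cluster merge gap
  bipartite_linker_min = 4L,
  bipartite_linker_max = 24L,
  bootstrap_reps = 1000L,    # classical bootstrap replicate count
  distance_model = "tn93",   # or "p"
  seed = 1L)

#' Validate and normalize a pipeline configuration
#'
#' Accepts a named list or a flat `key=value` file; unknown keys and
#' out-of-range values are rejected, missing keys are filled with the
#' package defaults.
#'
#' @param config named list, path to a `key=value` file, or `NULL` for
#'   pure defaults.
#' @return normalized named list of configuration values.
#' @examples
#' validateConfig(list(nls_cutoff = 0.5))$nls_cutoff
#' @export
validateConfig <- function(config = NULL) {
  if (is.character(config) && length(config) == 1L) {
    lines <- readLines(config, warn = FALSE)
    lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
    kv <- strsplit(lines, "=", fixed = TRUE)
    config <- setNames(lapply(kv, function(x) trimws(x[2L])),
                       trimws(vapply(kv, `[`, character(1L), 1L)))
  }
  if (is.null(config)) config <- list()
  unknown <- setdiff(names(config), names(.CONFIG_DEFAULTS))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  out <- .CONFIG_DEFAULTS
  for (k in names(config)) {
    tmpl <- .CONFIG_DEFAULTS[[k]]
    v <- config[[k]]
    if (is.character(tmpl)) v <- as.character(v)
    else if (is.integer(tmpl)) v <- as.integer(v)
    else v <- as.numeric(v)
    if (anyNA(v)) stop("invalid value for ", k)
    out[[k]] <- v
  }
  if (out$nls_cutoff <= 0 || out$nls_cutoff >= 1)
    stop("nls_cutoff must be in (0, 1)")
  if (!out$nls_decoder %in% c("posterior", "viterbi"))
    stop("nls_decoder must be 'posterior' or 'viterbi'")
  if (!out$distance_model %in% c("tn93", "p"))
    stop("distance_model must be 'tn93' or 'p'")
  if (out$min_core_motifs < 1L) stop("min_core_motifs must be >= 1")
  if (out$tm_window < 1L) stop("tm_window must be >= 1")
  if (out$nls_min_len < 1L) stop("nls_min_len must be >= 1")
  if (out$bootstrap_reps < 0L) stop("bootstrap_reps must be >= 0")
  if (out$bipartite_linker_min > out$bipartite_linker_max)
    stop("bipartite linker bounds out of order")
  if (out$pi_threshold < 0 || out$pi_threshold > 14)
    stop("pi_threshold must be within [0, 14]")
  out
}

#' Run the full characterization pipeline over per-species inputs
#'
#' For every species: motif scan and domain summary, physicochemical
#' profile, HMM NLS detection + taxonomy + signature census, codon usage
#' (when a CDS file is given), substitution-pattern estimation, NJ tree
#' and reconciliation against the species tree (when an alignment is
#' given). Per-gene TSV tables, one species-report row per species and a
#' run manifest are written under `outDir`. Reruns with the same inputs,
#' configuration and seed are byte-identical.
#'
#' @param species named list; each element is a list with `proteome`
#'   (FASTA path, required) and optional `cds` (FASTA path) and
#'   `alignment` (aligned CDS FASTA path).
#' @param outDir output directory (created if needed).
#' @param config see [validateConfig()].
#' @param speciesTree optional rooted binary species tree ([ape::phylo] or
#'   newick path) for duplication/loss counting.
#' @param hmm NLS HMM parameters (default [defaultNlsHmm()]).
#' @param catalog motif catalog (default [nacMotifCatalog()]).
#' @return data.frame of species report rows, invisibly; files under
#'   `outDir`.
#' @export
runAll <- function(species, outDir, config = NULL, speciesTree = NULL,
                   hmm = defaultNlsHmm(), catalog = nacMotifCatalog()) {
  cfg <- validateConfig(config)
  if (!length(species) || is.null(names(species)))
    stop("species must be a named list of input sets")
  if (is.character(speciesTree)) speciesTree <- readNewickTree(speciesTree)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  report <- NULL
  for (sp in names(species)) {
    inp <- species[[sp]]
    if (is.null(inp$proteome)) stop("species '", sp, "': proteome required")
    message("[", sp, "] reading proteome")
    prot <- readFasta(inp$proteome, "protein")
    message("[", sp, "] motif scan (", length(prot), " proteins)")
    dom <- domainSummary(prot, catalog = catalog,
                         minCoreMotifs = cfg$min_core_motifs,
                         window = cfg$domain_window)
    writeTsv(dom, file.path(outDir, paste0(sp, ".domains.tsv")))
    message("[", sp, "] physicochemical profile")
    phys <- suppressWarnings(
      physchemProfile(prot, piThreshold = cfg$pi_threshold,
                      tmWindow = cfg$tm_window,
                      tmThreshold = cfg$tm_threshold))
    writeTsv(phys, file.path(outDir, paste0(sp, ".physchem.tsv")))
    message("[", sp, "] NLS detection and taxonomy")
    nacIds <- dom$protein_id[dom$is_nac]
    calls <- NULL
    for (id in names(prot)) {
      cl <- callNls(prot[[id]], params = hmm, cutoff = cfg$nls_cutoff,
                    decoder = cfg$nls_decoder, minLen = cfg$nls_min_len,
                    seqId = id)
      if (nrow(cl))
        calls <- rbind(calls, annotateNlsCalls(
          prot[[id]], cl, mergeGap = cfg$cluster_merge_gap,
          linkerBounds = c(cfg$bipartite_linker_min,
                           cfg$bipartite_linker_max)))
    }
    if (is.null(calls))
      calls <- data.frame(protein_id = character(), start = integer(),
                          end = integer(), decoder = character(),
                          mean_posterior = numeric(), segment = character(),
                          nls_class = character(), signature = character(),
                          n_clusters = integer(), terminal = character(),
                          stringsAsFactors = FALSE)
    writeTsv(calls, file.path(outDir, paste0(sp, ".nls_calls.tsv")))
    census <- signatureCensus(calls)
    writeTsv(census$signatures,
             file.path(outDir, paste0(sp, ".nls_signatures.tsv")))
    codonRow <- NULL
    if (!is.null(inp$cds)) {
      message("[", sp, "] codon usage")
      cds <- readFasta(inp$cds, "dna")
      cu <- speciesCodonUsage(cds, speciesId = sp)
      codonDf <- data.frame(codon = .SENSE_RNA,
                            count = cu@counts[.SENSE_RNA],
                            avg_abundance = cu@avgAbundance,
                            rscu = cu@rscu, stringsAsFactors = FALSE)
      writeTsv(codonDf, file.path(outDir, paste0(sp, ".codon_usage.tsv")))
    }
    dups <- NA_integer_; loss <- NA_integer_; paralogs <- NA_integer_
    if (!is.null(inp$alignment)) {
      message("[", sp, "] substitution pattern and phylogeny")
      aln <- readFasta(inp$alignment, "dna")
      pat <- estimateSubstitutionPattern(aln)
      patDf <- data.frame(from = rep(.BASES, each = 4L),
                          to = rep(.BASES, 4L),
                          rate_pct = as.vector(t(substitutionRates(pat))),
                          stringsAsFactors = FALSE)
      patDf <- patDf[patDf$from != patDf$to, , drop = FALSE]
      patDf$k1 <- k1(pat); patDf$k2 <- k2(pat); patDf$R <- tsTvRatio(pat)
      writeTsv(patDf, file.path(outDir, paste0(sp, ".substitution.tsv")))
      if (length(aln) >= 3L) {
        tr <- njTree(distanceMatrix(aln, model = cfg$distance_model))
        if (cfg$bootstrap_reps > 0L) {
          bs <- bootstrapSupport(aln, nReps = cfg$bootstrap_reps,
                                 seed = cfg$seed,
                                 model = cfg$distance_model)
          writeTsv(bs$splits,
                   file.path(outDir, paste0(sp, ".bootstrap.tsv")))
        }
        writeNewickTree(tr, file.path(outDir, paste0(sp, ".nj.nwk")))
        if (!is.null(speciesTree)) {
          rooted <- phangorn::midpoint(tr)
          rec <- tryCatch(
            reconcileTrees(rooted, speciesTree),
            error = function(e) {
              message("[", sp, "] reconciliation skipped: ",
                      conditionMessage(e))
              NULL
            })
          if (!is.null(rec)) {
            dups <- duplications(rec); loss <- losses(rec)
            paralogs <- paralogCount(rec)
          }
        }
      }
    }
    nacCalls <- calls[calls$protein_id %in% nacIds, , drop = FALSE]
    classes <- c("mono_I", "mono_II", "bipartite", "class_III", "class_IV",
                 "multipartite", "unclassified")
    hist <- vapply(classes, function(cl)
      sum(nacCalls$nls_class == cl), integer(1L))
    row <- data.frame(
      species_id = sp,
      total_nac = sum(dom$is_nac),
      n_double_domain = sum(dom$is_multi_domain),
      n_chimeric = sum(dom$is_nac & nzchar(dom$chimeric_partners)),
      n_tm_bound = sum(dom$is_nac & phys$is_membrane_bound),
      n_with_nls = length(unique(nacCalls$protein_id)),
      t(hist),
      duplications = dups, losses = loss, paralogous_genes = paralogs,
      stringsAsFactors = FALSE)
    report <- rbind(report, row)
  }
  writeTsv(report, file.path(outDir, "species_report.tsv"))
  manifest <- data.frame(
    key = c("package", "version", names(cfg),
            paste0("input_md5_", unlist(lapply(names(species), function(sp)
              paste0(sp, ".", names(species[[sp]])))))),
    value = c("nacprofiler",
              as.character(utils::packageVersion("nacprofiler")),
              vapply(cfg, function(v) paste(as.character(v), collapse = ","),
                     character(1L)),
              unname(unlist(lapply(species, function(inp)
                vapply(unlist(inp), function(p)
                  unname(tools::md5sum(p)), character(1L)))))),
    stringsAsFactors = FALSE)
  writeTsv(manifest, file.path(outDir, "manifest.tsv"))
  invisible(report)
}
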