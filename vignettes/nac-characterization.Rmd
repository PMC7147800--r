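---
title: "Characterizing NAC transcription factors: models, parameters and design choices"
author: "nacprofiler"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing NAC transcription factors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nacprofiler)
```

# Scope and overall shape

NAC (NAM/ATAF/CUC) transcription factors form one of the largest plant
transcription-factor families. They are recognized by a conserved
~150-residue N-terminal DNA-binding domain that carries a set of short
consensus motifs, a diversified C-terminal end, frequent membrane-bound
forms, and nuclear localization signals (NLS) rich in lysine and
arginine. Genome-scale surveys of the family proceed through a fixed
sequence of desk analyses: confirm the domain from consensus motifs,
profile molecular weight and isoelectric point, call transmembrane
segments, detect and classify NLS, tabulate codon usage, estimate the
substitution pattern of the coding sequences, and count gene
duplications by reconciling per-species gene trees with a species tree.

`nacprofiler` implements that pipeline as a set of composable modules
with a thin orchestration layer (`runAll()`), plus seeded generators
that produce synthetic proteomes, coding sequences, alignments and gene
families with known ground truth. Every stage can therefore be validated
end-to-end without downloading any genome.

Homology search (BLASTP/profile HMMs) for *discovering* candidate NAC
proteins is out of scope: the package takes candidate protein sets as
input and performs the confirmation and characterization stages.

# Domain confirmation by consensus motifs

The motif engine compiles PROSITE-style patterns (`x` wildcards with
repeat ranges, `[..]` classes, `{..}` exclusions, `A/B` shorthand) into
an element list and matches them with a small dynamic program over
reachable positions. The engine reports, for every matching start, the
longest match; this is checked exhaustively against a brute-force
enumerator in the tests. An `X` in a sequence is treated as an unknown
residue: it satisfies fixed elements and wildcards but not residue
classes, so ambiguity never manufactures class-specific evidence.

The shipped catalog holds the family's core consensus motifs in their
canonical N-to-C order — `P-G-F-R-F-H-P-T-D-[DE]-L-[IV]`, `Y-L-x(2)-K`,
`D-L-x-K-x(2)-P-W-x-L-P`, `E-W-Y-F-F`, `G-Y-W-K-[AT]-T-G-x-D-x(1,2)-[IV]`,
`G-x-K-K-x-L-V-F-Y`, `T-x-W-x-M-H-E-Y` and the standalone hydrophobic
`L-V-F-Y` — as an editable TSV (`inst/extdata/nac_core_motifs.tsv`),
together with optional non-NAC "partner" motifs used to flag chimeric
architectures.

A domain instance is called where at least `min_core_motifs` (default 3)
*distinct* core motifs co-occur in canonical order within a 200-residue
window. No published cutoff exists for how many signature motifs
"confirm" a domain, so the threshold is a configuration value; the
default of 3 keeps false calls rare — residue-shuffled decoys produce a
call in under 1% of trials in the permutation test — while still
tolerating degraded domains. Instances are selected left to right
without overlap. Among chains with the maximal number of distinct motifs
from the leftmost anchor we keep the most *compact* span: a greedy
"longest" span can reach across the co-occurrence window into a tandem
second domain block and swallow one of its motifs, which would
undercount multi-domain architectures. Partner motifs hitting outside
called instances are reported as chimeric partners.

# Physicochemical profile

*Molecular weight* is the sum of average residue masses plus one water
(18.02 Da); `X` is an error because no mass can be assigned. *Net
charge* is the Henderson–Hasselbalch sum over the termini and the D, E,
C, Y, K, R, H side chains. The default pKa set is the EMBOSS table, with
a free-amino-acid (Lehninger) alternative selectable; the tables are
data, not code, because published pI calculators differ in exactly these
constants. The *isoelectric point* is found by bisection on `[0, 14]`;
since the charge is strictly decreasing in pH the root exists and is
unique, and the result is checked against a 1e-4-step grid oracle.
Proteins are classed acidic/basic at pI 7.0 by default; the boundary is
configurable because surveys use 7.0 or 7.4 interchangeably.

*Transmembrane segments* use a documented hydropathy stand-in rather
than a server-based predictor: maximal unions of 19-residue windows
whose mean Kyte–Doolittle hydropathy is at least 1.6. The output column
is named `tm_segments_hydropathy` to make the provenance explicit, and
externally computed TM calls can be substituted via TSV. Two properties
bound its behaviour on synthetic data: planted 23-residue hydrophobic
stretches are always recovered, and false coverage on
composition-matched shuffled decoys stays below 1% *per residue*. The
per-residue unit matters: a fixed window criterion fires somewhere in
roughly one in ten i.i.d. 350-mers, so a per-protein false-positive rate
is not a meaningful target for any honest decoy set, whereas falsely
covered residues are rare.

# NLS detection: a two-state HMM

Detection follows the classic two-state (background/NLS) hidden Markov
model design with both Viterbi and posterior decoding and a posterior
prediction cut-off of 0.4. The published tools' trained state
frequencies are not reprinted anywhere, so the package ships a
replaceable prior as data (`inst/extdata/nls_hmm_default.tsv`): the NLS
state emits K and R at 0.30 each and the remaining residues uniformly;
the background is uniform; the background is sticky (BG→BG 0.99) and NLS
segments persistent (NLS→NLS 0.90) with initial weights 0.99/0.01. The
decoding contract — log-space Viterbi with ties resolved to background,
scaled forward–backward posteriors — is exact and is tested against
complete path enumeration for short sequences. Posterior calls are
maximal runs of positions with `P(NLS) >= cutoff`; runs shorter than 4
residues (the shortest monopartite class-II signal) are dropped. The two
decoders are reported separately when they disagree; no merging policy
is imposed.

# NLS taxonomy and signatures

Segments are classified in a fixed decision order:

1. non-canonical **class III** when `K-R-x-[WFY]-x(2)-A-F` matches;
2. non-canonical **class IV** when `[PR]-x(2)-K-R-[KR]` matches;
3. **multipartite** with three or more basic clusters;
4. **bipartite** with exactly two clusters separated by a linker of 4–24
   residues;
5. **monopartite class I** for a single cluster containing at least four
   consecutive basic residues (no upper bound: runs of fifteen are
   observed in practice);
6. **monopartite class II** when `K-[KR]-x-[KR]` matches;
7. `unclassified` otherwise.

Pattern-defined classes are tested first because cluster-count geometry
would otherwise absorb them. Clusters are maximal K/R runs of length at
least two, with one merge rule: a run is absorbed into a neighbouring
run when the gap between them is at most 4 residues *and* at least one
of the two runs has length three or more. The asymmetric condition is
deliberate. The canonical bipartite exemplar
`K-R-P-A-A-T-K-K-A-G-Q-A-K-K-K-K` contains three maximal runs (`KR`,
`KK`, `KKKK`) whose two gaps are both exactly four residues; an
unconditional gap-4 merge collapses all three into one cluster and
misreads the segment as monopartite, while the conditional rule merges
only `KK` into the substantial `KKKK` run and recovers the canonical
two-cluster reading (`KR` + linker + `KK..KKKK`). The bipartite linker
bound is correspondingly `[4, 24]` (canonical linkers are 10–12,
observed up to 24; the lower bound admits the exemplar's four-residue
`PAAT` linker under the merge rule). Both the merge gap and the linker
bounds are configuration values.

Signatures collapse a segment to its ordered basic residues
(`collapseLinkers("KRPAATKKAGQAKKKK")` is `"KRKKKKKK"`); the operation
is idempotent and the census tabulates unique signatures per terminal
region and their overlap. A signal belongs to the N-terminal region when
its interval midpoint lies in the first half of the protein — the
half-way convention is ours, as published surveys never define where the
"N-terminal region" ends.

# Codon usage

Codons are counted in frame over the 61 sense and 3 stop codons; one
terminal stop is tolerated; codons containing `N` are skipped and
tallied, never imputed. RSCU is the observed count divided by the
expected count under uniform synonymous use, so family means are exactly
one wherever a family is observed and single-codon families (AUG, UGG)
are one whenever present. Stop codons are excluded from abundance and
RSCU but still reported. Output labels use the RNA alphabet, matching
how codon tables are conventionally printed. Per-species summaries
report average abundance (total count / number of genes) and
presence/absence, and the cross-species matrix counts, for each codon,
the species in which it occurs — always against the species count
actually supplied, since published per-codon denominators vary without
explanation.

# Substitution patterns, trees and reconciliation

**Pattern estimation.** Aligned pairs are tallied with pairwise deletion
(columns with a gap or ambiguous base in either sequence are dropped),
pooled over all pairs, and symmetrized. The Tamura–Nei (TN93) divergence
and the purine/pyrimidine transition/transversion rate ratios `k1`, `k2`
are then fitted by maximizing the pooled multinomial likelihood with
empirical base frequencies — a composite-likelihood estimate, using the
closed-form TN93 transition matrix. The rate table is reported as
percentages summing to 100 (entry `i→j` proportional to `g_j`, scaled by
`k1` or `k2` for transitions) and the overall bias as
`R = (k1 gA gG + k2 gC gT) / (gR gY)`, which reduces to 0.5 in the
equal-rate, equal-frequency limit. Zero divergence yields `NA` rates; an
alignment with no observed transversions reports `R = Inf` rather than
failing. On alignments simulated at 50 kb with `k1 = 4, k2 = 2`, both
ratios are recovered within 10% in at least 95 of 100 seeded replicates.

**Distances and NJ.** p-distances and the closed-form TN93 correction
are provided; saturated pairs give `NA` with a warning. Surveys often
quote a GTR model alongside neighbour joining, but there is no standard
"GTR distance" for NJ; the package stays internally consistent by
pairing NJ with p or TN93 distances (TN93 matching the
pattern-estimation model). The NJ implementation is the Saitou–Nei
agglomeration with two pinned-down details: ties in the selection
criterion break toward the smallest index pair, and negative branch
lengths are clamped to zero with the deficit moved to the sister branch.
NJ is consistent on additive matrices, which the tests exploit: trees
regenerated from the path-length matrices of 200 random binary trees are
recovered exactly, topology and lengths. Bootstrap support resamples
alignment columns with replacement (default 1000 replicates, the
classical setting) and reports, per internal split of the full-data
tree, the fraction of replicate trees containing it.

**Reconciliation.** Gene trees are reconciled against a rooted binary
species tree by LCA mapping: a node is a duplication when it maps to the
same species node as one of its children; losses follow the standard
path-length formula; paralogous genes are those descending from at least
one duplication node. Duplication and loss counts are always reported
separately — the package does not hard-code the expectation that a
family has lost no genes, it measures it. NJ trees are unrooted, so
reconciliation roots them at the midpoint by default; midpoint rooting
does not necessarily minimize duplications, and `minDuplicationRoot()`
enumerates all rootings when the minimum is wanted. When gene trees
contain only genes of a single species (the per-species survey design),
every internal node maps to that species' leaf and the duplication count
is necessarily the gene count minus one; the reported numbers should be
read with that in mind.

# The synthetic world

Generators are pure functions of a specification plus a seed
(`set.seed` on entry, single stream; regenerating with the same seed is
byte-identical, while inserting a record reshuffles records after it —
R has no convenient splittable generator, and per-record independence is
not needed by any consumer).

`makeProteome()` plants, per NAC protein: exemplar instances of the full
core-motif catalog in canonical order (one block per domain, domain
count drawn from weights defaulting to 0.90/0.07/0.02/0.01 — tandem
architectures are rare in real surveys), NLS segments of each requested
taxonomy class at recorded coordinates, and a 23-residue hydrophobic
stretch with probability 0.0857 (the fraction of membrane-bound family
members reported in large surveys). Protein lengths are drawn from
250–500 residues (the family's typical scale); the drawn length acts as
a floor and is extended minimally when the planted features do not fit,
and a spec whose features cannot fit the maximum length is an error.
Background residues are uniform over the 20 amino acids; motif-block
spacers are polar so that composition-matched decoys (residue shuffles
of the NAC proteins) are hydropathy-neutral. NLS linker residues are
drawn from `{A, G, S, T}`: no K/R (so the planted collapsed signature is
exact) and none of the residues that could complete a class III/IV
consensus by accident. Truth tables record every planted feature with
coordinates, and all downstream checks read ground truth only from them.

`makeCds()` back-translates with per-family codon weights and appends a
stop, so translation checks pass by construction and per-species RSCU
recovers the target profile in expectation. `evolveAlignment()` draws a
root sequence from the base frequencies and evolves sites independently
with the closed-form TN93 transition matrix per branch (no indels).
`makeGeneFamily()` starts from one gene per species and repeatedly
duplicates a uniformly chosen dup-free subtree — restricting targets to
dup-free subtrees keeps the planted event count identical to the
observable one, because copying a clade that already contains a
duplication would implicitly plant a second, mirrored event. With losses
enabled, leaves are pruned independently; the truth reports events with
surviving leaves on both sides, and parsimony reconciliation may still
legitimately infer fewer duplications than were planted (losses can hide
events), which is why exactness is only asserted on loss-free histories.

What a green synthetic run does *not* establish: recovery of motifs
under point mutation or indels (planting is exact), TMHMM-equivalent
membrane topology, NLS detection calibrated to experimentally validated
signals, or duplication counts under heavy gene loss.

# Numerical choices and degenerate inputs

* Bisection for pI runs to <1e-6 pH internally; reported values are
  within one 1e-4 grid step of the global `|charge|` minimizer.
* Hydropathy window means are compared to the threshold with a 1e-9
  guard so that exactly-boundary windows do not flip on floating-point
  association order.
* HMM decoding is in log space (Viterbi) and scaled (forward–backward);
  a sequence impossible under the model is an explicit error, not a NaN.
* Empty scan results, empty cluster sets, all-identical alignments and
  transversion-free alignments all return typed empty/flagged results
  rather than failing.
* TSV outputs are written with a fixed 15-digit numeric format and LF
  endings, which is what makes whole-directory byte-determinism
  checkable with checksums.

# Configuration

`validateConfig()` fills defaults and rejects unknown keys or
out-of-range values. The values that matter scientifically: posterior
cut-off 0.4; shortest callable NLS 4; pI boundary 7.0; TM window 19 and
threshold 1.6 (mean Kyte–Doolittle hydropathy); domain co-occurrence
window 200 with 3 core motifs required; cluster merge gap 4; bipartite
linker 4–24; bootstrap replicates 1000; distance model TN93. All units
are residues, pH units, or hydropathy units as stated above.

# Known limitations

* The hydropathy TM caller is a stand-in, not a trained topology model.
* The NLS prior is a plausibility prior, not trained emission
  frequencies; swap in trained tables via `readHmmParams()` for
  production use.
* GTR-based distances and likelihood tree inference are not provided.
* Reconciliation requires binary trees; polytomies must be resolved
  upstream.
* The duplication census equals genes-minus-one for single-species
  families by construction of the LCA mapping (see above), so
  cross-species families are needed for informative loss estimates.
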