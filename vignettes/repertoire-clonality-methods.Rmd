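---
title: "Methods: clonality and repertoire analysis of RNA-seq-derived clonotypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: clonality and repertoire analysis of RNA-seq-derived clonotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(repclonality)
```

## The problem

Every B or T lymphocyte carries a somatically recombined V(D)J
rearrangement whose junction — the CDR3-encoding region between the
conserved cysteine and the conserved tryptophan/phenylalanine — is a
sequence fingerprint of the clone. Bulk RNA-seq of a lymphocyte-derived
cell line therefore reveals, via tools such as MiXCR, a clonotype table:
which rearrangements are expressed and how strongly. `repclonality` takes
such tables and answers the downstream questions: Is the line monoclonal,
biallelic/biclonal, or oligo/polyclonal? Is the dominant receptor
productive? Do minor clonotypes look like somatic-hypermutation (SHM)
offspring of the dominant clone or like independent clones? Which
junctions recur across samples (identity fingerprints vs trace
contamination)? What do segment usage, CDR3 consensus and CDR3-distance
trees look like across a cohort?

## Clonotype model and filtering

A clonotype is identified by `(locus, v_gene, d_gene, j_gene,
junction_nt)`; junctions differing by a single nucleotide are different
clonotypes, and the reader merges duplicate keys by summing reads. Two
read thresholds matter:

* `min_reads = 30` — a clonotype is *retained* (treated as a real clone)
  only with at least 30 supporting reads; everything below is treated as
  noise or trace contamination. The boundary is inclusive.
* `index_min_reads = 100` — the stricter support used when summarising
  "index" rearrangements in large cohorts.

Expression is normalised as CPM = reads / total RNA-seq library reads ×
10^6; the denominator is the caller-supplied library size (the package
takes it as given and does not distinguish raw from mapped totals).
Clonal *fractions* default to a sample-wide denominator (all retained
clonotypes of the sample, all loci) because the published per-line tables
this package reproduces are mutually consistent only under a shared
denominator; a `per_locus` scope is available for per-chain views.
Fractions are kept unrounded internally; display rounding is half-up to
two decimals (`round_half_up()`), matching how such tables are printed.

## Clonality classification

Counting retained clonotypes per locus, the tiers are:

1. nothing retained → `no_rearrangement`;
2. ≥3 IGH, ≥3 IGL or ≥3 TRA — or >4 IGK, >4 TRB → `oligo_or_polyclonal`;
3. exactly one clonotype overall → `monoclonal`;
4. otherwise → `biallelic_or_biclonal`.

The IGK/TRB allowance is larger because those loci can legitimately
express up to four rearrangements per cell pair of alleles (secondary
rearrangement on both alleles), so only a fifth clonotype is evidence of
oligoclonality. The thresholds count *clonotypes at the locus*, not
distinct V genes: clonotypes are junction-defined, and the worked
examples the rule reproduces count rearrangements. TRG/TRD are not named
by the published rule; they follow the "≥3" family, which matches the
single-rearrangement-per-allele behaviour of those loci. `monoclonal`
is implemented as one clonotype overall (not one per locus pair); the
phrase it encodes is ambiguous in the source material, and the stricter
reading was chosen and flagged in the call structure so that reviewers
can relax it by combining `per_locus_counts` themselves.

The dominant clonotype is the highest-read retained clonotype, with a
deterministic tie-break (larger read count, then lexicographically
smallest junction). `prominent` marks dominants above 90% sample-wide
fraction; `light_chain_only` marks samples whose dominant is IGK/IGL
with no IGH reaching `min_reads` — the light-chain multiple myeloma
signature of a deleted or silenced heavy-chain locus.

## Productivity

A junction is nonproductive when its rendered amino-acid string carries
`_` (out of frame) or `*` (internal stop). `translate_junction()` uses
the standard genetic code (via seqinr) on full codons and appends a
single trailing `_` when the junction length is not a multiple of three.
The marker's *position* is a rendering convention; classification keys
only on marker *presence*, so externally rendered strings (which may
place `_` mid-string at the frameshift) classify identically. Ambiguity
codes are not supported: junctions assembled from RNA-seq consensus are
unambiguous.

## Subclones and fingerprints

Within a locus, clonotypes sharing an exact V-D-J pattern whose CDR3s lie
within `max_edit` (Levenshtein, via `utils::adist`) of the pattern's
dominant member form one cluster, labelled `shm_derived` when it has ≥2
members — "Pattern I", subclones plausibly derived from the dominant
clone by SHM point mutations. The default ceiling is `max(4, 30%` of the
dominant CDR3 length`)`: wide enough for observed SHM families (distances
1–3 on length-11 CDR3s) yet rejecting unrelated same-pattern junctions.
This label is a similarity heuristic — no mutation-model test is
performed, and the clustering is documented as such. Single-member
clusters are `independent` ("Pattern II") only when the locus carries
more distinct patterns than its biallelic allowance (2, or 4 for
IGK/TRB), because two patterns may simply be two alleles.

`find_shared_junctions()` groups clonotypes across samples by (locus, V,
J, junction) — amino-acid matching by default, nucleotide optionally.
Groups whose reads are below `low_read_ceiling` (default 30) in all or
all-but-one samples are flagged `suspected_contamination`: the signature
of index hopping / trace carry-over, as opposed to a genuine shared
rearrangement, which is the basis of repertoire-based cell-line
authentication.

## Usage matrices, consensus, trees

Segment-usage rows are one-hot on the dominant clone's segment
(`dominant` mode) or read-weighted proportions (`all_weighted`); both sum
to one per row, so cohort heatmaps compare composition, not depth.
Z-scoring is column-wise with the population (n) standard deviation —
the heatmap convention — and constant columns map to zero rather than
NaN. `log2` uses a pseudocount that must be positive when zeros are
present.

CDR3 sets are aligned with a deterministic center-star progressive
aligner (identity scoring: match +1, mismatch 0, gap −1; the center
minimises total pairwise edit distance, ties to the longest then
lexicographically smallest sequence; pairwise steps are Needleman–Wunsch
with a fixed diagonal-first traceback). At CDR3 lengths a full
guide-tree aligner adds nothing; with two sequences the result *is* the
optimal pairwise alignment, which the tests verify against a score
oracle. Markers align as ordinary symbols; `_` is excluded from length
statistics (it is an annotation, not a residue) while `*` occupies a
residue position. CDR3 lengths are junction lengths, anchors included.
Consensus calling takes the per-column majority, ties broken
alphabetically with the gap losing all ties.

Distances between aligned CDR3s are p-distances over gap-free columns
with Poisson multiple-hit correction `d = −ln(1 − p)` — the standard
amino-acid distance for such trees. Saturated pairs (p = 1) have no
finite correction and are set to the largest finite distance in the
matrix plus 1.0, with a warning. Trees are classical Saitou–Nei
neighbor joining: Q-criterion joins with a deterministic
smallest-index tie-break, closed-form termination at three taxa, a
midpoint split for two. Negative branch lengths are clamped to zero at
serialization only (topology unaffected); the newick string carries six
decimals, with a full-precision variant retained for numeric work such
as the additive-recovery tests (NJ is exact on additive matrices, which
the suite checks to 1e-9 on random trees).

## The synthetic generator

`generate_repertoire()` emulates the data structure the analysis
assumes, not the recombination machinery (no TdT insertions, trimming
distributions or selection): junctions are a cysteine codon, random
sense codons, and a W/F anchor; nonproductive junctions are made by
deleting 1–2 nt or injecting a stop, with probability `p_nonproductive`
(default 0.1 — clonal lines mostly express a productive dominant
receptor, with nonproductive alleles a minority); SHM offspring inherit
the dominant's V-D-J labels and acquire 1–3 point mutations, which
bounds their amino-acid edit distance by construction. Dominant clones
draw 60–95% of the repertoire reads (matching the "one highly expressed
dominant rearrangement" regime of clonally restricted lines); remaining
true clones receive a 30-read floor plus a symmetric Dirichlet(1) share
of the residual — same marginal shape as rejection sampling above the
floor, but always feasible. Repertoire depth is log-normal around 2×10^4
receptor reads in a 1.5×10^8-read library. Noise clones draw 1–29 reads,
below the retention threshold by construction, and an optional fixed
contamination junction is inserted into every sample at 1–29 reads.

Scenario truth labels are *recomputed from the emitted table* by an
independent recount, so a sample whose random draws cross a category
boundary is labelled by what the table actually implies. This is what
makes the recovery experiment (200 samples per scenario; ≥95% agreement
between `classify_clonality()` and truth) a test of the classifier, not
of the generator's intent. Gene names come from a built-in human
germline vocabulary; names are labels only, and loci whose germline has
few segments (TRG/TRD) simply have short lists.

What passing these tests does *not* show: real MiXCR output has
alignment artifacts, allele notation, chimeric junctions and
library-dependent depth profiles that the generator does not emulate;
recovery rates on synthetic data are a correctness check of the rules,
not a sensitivity/specificity estimate for real repertoires. Cohort
figures from the source study (hundreds of cell lines) require the
original RNA-seq and are out of scope here; the package reproduces the
per-line worked examples and the rule definitions instead.

## Pipeline and problem sizes

`run_pipeline()` sequences the stages (classify → subclones →
fingerprint → usage → consensus → tree) with a YAML or list config;
outputs are written stage by stage, so disabling a downstream stage
never changes upstream files, and reruns with the same config are
byte-identical on analytic outputs (the JSON report's timestamp is the
only varying field). The test suite and the acceptance script run at
desk scale by design — 200 samples per scenario for recovery, 100 random
trees of up to 8 taxa for the NJ oracle, 1000 random pairs/strings for
the edit-distance and translation oracles — sizes chosen as the smallest
that exercise every rule and tie-break while keeping the whole suite
under a minute.

## Known limitations

* Clonality calls are expression-based: non-transcribed rearrangements
  are invisible, and fraction accuracy degrades for sub-dominant clones
  in libraries without poly(A) selection.
* The SHM/independent labels are sequence-similarity heuristics.
* The center-star alignment is not guaranteed optimal for >2 sequences
  (it is a 2-approximation in total score); for CDR3-scale inputs this
  is immaterial, and determinism is guaranteed.
* The `mixcr_like` reader maps common export column names best-effort;
  unusual export presets should be converted to the native dialect.
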