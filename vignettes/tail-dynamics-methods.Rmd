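---
title: "Poly(A) tail calling, decay kinetics and time-course gene sets: methods"
author: "TailDynamics authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Poly(A) tail calling, decay kinetics and time-course gene sets: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(TailDynamics)
```

# Scope

TailDynamics implements the computational backbone of a deadenylation
study in mouse pluripotent stem cells: how the Ccr4-Not deadenylase
subunit Cnot8 clears naive-network mRNAs as embryonic stem cells (ESCs)
differentiate towards the formative, epiblast-like (EpiLC) state. Three
kinds of measurement meet in such a study, and the package covers the
bespoke computation behind each:

1. **Poly(A) tail lengths from long reads.** Full-length cDNA (CCS)
   reads carry the 3' poly(A) tail as a soft-clipped segment of the
   alignment; calling tails is soft-clip bookkeeping plus quality rules.
2. **mRNA decay kinetics.** Transcription-shutoff (actinomycin-D) time
   courses give first-order decay rates and half-lives per transcript.
3. **Expression time courses.** TPM matrices over an induction time
   course (0, 6, 12, 24, 48 h; WT and knockout) are reduced to
   threshold-based differential calls, temporal clusters, and named gene
   sets derived by explicit set algebra.

A fourth module simulates inputs for all three with recorded truth, so
every stage is verifiable without any external data deposit.

# Tail calling

## Model

A CCS read from a polyadenylated transcript aligns to the genome with
its tail left unaligned: for a plus-strand transcript the tail is the
trailing soft clip of the stored sequence; for a minus-strand transcript
the read is stored reverse-complemented and the tail is the leading soft
clip, read back through reverse complement. `extractSoftClipTail()`
implements exactly this; `callTails()` vectorises it over a read table.

Aligners often absorb the first tail bases into the reference match when
the annotated 3' end happens to be A-rich. `extendATract()` corrects
this by moving the maximal run of A's at the 3' end of the aligned query
suffix onto the front of the tail. Extension is applied unconditionally:
the underlying data gives no signal for deciding when misalignment
"was necessary", and unconditional extension is idempotent and
deterministic. Only the aligned *query* is scanned, never the reference,
so no genome sequence is needed.

Quality rules, applied in order by `classifyTail()`:

* no 3' soft clip at all — the transcript has no measurable tail
  (`REJECTED_NO_CLIP`);
* fewer than 4 A's among the first `min(8, length)` bases —
  a low-quality tail call (`REJECTED_LOW_A`). Exactly 4 A's passes.
  Tails shorter than 4 nt necessarily fail, which is the literal
  reading of the rule without padding; consequently every accepted
  tail is at least 4 nt.
* CCS pass count below `minPasses` (default 7, inclusive: a read with
  exactly 7 passes is kept) — `FILTERED_LOW_PASS`. The filter is
  applied uniformly to all reads, which is simpler and slightly
  stricter than filtering only unassigned reads; it can be disabled
  with `passFilter = FALSE`. Reads without a pass tag are never
  pass-filtered.

`N` counts as non-A everywhere: it never satisfies the 4-A rule and it
terminates an A-tract. A hard clip at the transcript 3' end means the
tail bases were physically removed from the record; such reads are
flagged and rejected as clipless.

## Per-gene statistics

Tail-length distributions within a gene are lognormal-like, so
`summarizeGeneTails()` reports the geometric mean,
`exp(mean(log(len)))`, over accepted tails, and only for genes with at
least `minTranscripts = 10` accepted transcripts — below that the
geometric mean is too noisy to compare between conditions.
`compareTailConditions()` then builds the standard two-condition view:
a pairwise table of per-gene geometric means restricted to genes
summarised in both conditions, condition medians over that pairwise
table, transcript-level fractions across length bins (default 5–90 and
90–200 nt), and the quantile-trimmed support of each distribution
(default 2% at each end), which is how shifted tail-length ranges are
usually presented.

Whether published pairwise medians were computed over per-gene
geometric means or pooled transcripts is not derivable from the text we
model; per-gene geometric means are used here, which is the
interpretation consistent with the per-gene filtering step.

## Gene assignment

Reads are assigned with `GenomicRanges::findOverlaps` on the aligned
reference span, strand-aware. A reverse-flagged alignment of a tailed
read implies a minus-strand transcript (its tail sits at the lowest
reference coordinates), so alignment strand is matched directly against
annotation strand. Among several overlapping genes the largest overlap
wins; exact ties resolve to the lexicographically smallest gene id —
an arbitrary but deterministic rule, recorded in the output rather than
hidden in hash order. Reads on references absent from the annotation
are unassigned, not errors.

Coordinates are 0-based half-open in the read table (SAM `POS` minus
one) and 1-based closed inside `GRanges`, with conversion confined to
the I/O layer (`readAlignments()`, `readAnnotation()`, `writeBed()`).
Secondary, supplementary and duplicate-flagged records are dropped on
read — the conventional de-duplication for this assay.

# Decay kinetics

After transcription shutoff, remaining mRNA follows
$dC/dt = -K_{decay} C$, hence $\ln(C/C_0) = -K_{decay}\,t$ and
$t_{1/2} = \ln 2 / K_{decay}$. `fitDecay()` estimates $K_{decay}$ as
the least-squares slope of $-\ln(C/C_0)$ on $t$ **through the origin**:
the model has no intercept, and forcing the fit through $(0, 0)$ keeps
the estimate consistent with the normalisation that sets the 0 h value
to 1. A free-intercept variant (`throughOrigin = FALSE`) exists for
diagnostics only. No weighting is applied — plain linear regression.
$R^2$ is reported relative to the fitted model (for the through-origin
fit, $1 - RSS/\sum y^2$).

Replicates are averaged per time point before fitting (one line per
gene over replicate means); `perReplicate = TRUE` fits each replicate
separately. A non-positive slope — a transcript that does not decay
within the chase — yields `t_half = Inf`, a flagged value rather than
an error, so stabilised transcripts survive table operations.
`ddctFoldChange()` implements the standard $2^{-\Delta\Delta Ct}$
relative quantification against an internal-control gene and a control
sample.

# Expression time courses

`computeTpm()` is the textbook length-normalised TPM; each sample
column sums to $10^6$. Differential calls (`callDegs()`) are pure
thresholds, deliberately mirroring the upstream analysis rather than a
shrinkage estimator: a gene is up when
$(TPM_{KO} + \varepsilon)/(TPM_{WT} + \varepsilon) > 1.5$ **and**
$\log_2 \max(TPM_{KO}, TPM_{WT}) > 1$. The pseudocount
$\varepsilon = 0.1$ guards zero division while leaving the ratio
essentially the TPM ratio for any expressed gene; the expression floor
is applied to the larger condition mean, the permissive reading when
the side is not specified. Replicates are averaged per (condition,
time point) before calling.

## Temporal clustering

The temporal clusters are produced by a deterministic sign-pattern
procedure (`clusterProfiles()`): each gene's per-interval change in
$\log_2(TPM + 1)$ is discretised into `-`, `0`, `+` using a threshold
(default 0.5 log2 units per interval), genes sharing a pattern form a
cluster, and the `nTop = 8` most populous patterns are retained along
with the covered fraction of the gene universe. This reproduces the
intended semantics — the continuous-downregulation cluster is exactly
the all-`-` pattern, returned by `degradationCluster()` — while being
auditable and free of tuning: published descriptions of the original
procedure name an HMM/Markov-style clustering without parameters, so a
parameter-free deterministic discretisation was chosen instead of
guessing at an unspecified model. The threshold of 0.5 log2 units per
interval is half of the smallest planted effect size we consider
meaningful (a 2-fold change per interval) and sits far above the noise
scale of replicate-averaged data.

## Gene-set algebra and the ledger

The named sets that define the biology — "degradation-dependent"
genes, "naive-GRN-like" genes — are chains of intersections, unions and
exclusions whose intermediate sizes are themselves results. The
`GeneSetLedger` records every operation with operand names and sizes;
recorded sizes always equal actual cardinalities, and disjoint unions
add exactly. `dependentDegradationSet()` intersects the union of
KO-upregulated genes with the degradation cluster and records the
resulting fraction; `deriveGrnLikeSet()` builds the four disjoint
late-upregulation categories (up at all four induction time points; up
at 24 h and 48 h but not all four; 24 h only; 48 h only), takes their
union and removes genes already up at 0 h. Categories are checked for
disjointness — any overlap is an internal error, not a warning.
The ledger has reference semantics (an environment inside the S4
object) so a derivation can be written linearly without re-threading
the object; mutation is confined to the `record*` API.

`pcaProjection()` centres and unit-scales genes (zero-variance genes
dropped), projects samples onto the top two principal axes and reports
explained-variance fractions; a constant matrix is degenerate and
raises an error.

# The simulators

`simulateTailedReads()` emits alignment records whose 3' soft clips
encode sampled tails. Per-read lengths are
$\mathrm{round}(\exp(\mathcal N(\ln gm_g, \sigma_{read})))$, truncated
at 1 nt — integer-valued and lognormal-like. Defaults describe a
desk-scale two-condition experiment: 500 genes, 200 reads per gene,
per-gene geometric means spread lognormally ($\sigma = 0.25$) around
85 nt, per-read spread $\sigma = 0.4$, 1% per-base substitution errors
confined to the tail, 20% of genes on the minus strand (exercising the
reverse-strand path end to end), 5% tail-less reads, Poisson(15) pass
counts. Substitution errors are applied to tail bases only and read
bodies end in a non-A base, so alignment stays trivial and error-free
input round-trips to exact truth — the simulator isolates the
tail-calling logic under test. What it does **not** emulate:
homopolymer-aware error profiles, quality strings, internal priming,
alternative polyadenylation sites, or reads spanning multiple genes;
passing recovery tests here demonstrates the correctness of the clip
arithmetic and filter logic, not robustness to every artefact of real
long-read data.

`simulateDecaySeries()` draws $C(t) = e^{-kt}$ with multiplicative
lognormal noise and renormalises $t=0$ to exactly 1.
`simulateExpressionTimecourse()` plants monotone-down (40%), flat
(30%) and monotone-up (30%) log2 templates with ±1 log2-unit steps per
interval and Gaussian noise ($\sigma = 0.2$) on the log2 scale, two
replicates per condition and time point. The flat cluster is placed
well above the others in absolute abundance so that library totals stay
nearly constant across time points: TPM is compositional, and without
that balance the renormalisation would distort the planted steps of the
minority clusters. A designated subset of down genes is "stabilised" in
the KO condition — their trajectory stops falling after 12 h — which is
the planted analogue of transcripts whose clearance requires the
deadenylase; these genes surface in the 24 h and 48 h up-called sets.

All generators take a single seed and restore the caller's RNG state;
identical seeds give byte-identical output.

# Numerical choices and problem sizes

* Geometric means are computed as `exp(mean(log(x)))`; lengths are
  integers ≥ 1 so no guard is needed beyond the accepted-tail floor.
* Tail-length bin fractions are computed over reads inside the covered
  bin range and sum to 1 per condition by construction.
* Tie-breaks are deterministic everywhere: largest overlap then
  lexicographic gene id in assignment; cluster size then pattern string
  in cluster retention.
* Test and verification sizes were chosen so the full suite runs in a
  few minutes on one CPU: 500 genes × 200 reads per condition for tail
  recovery (per-gene geometric means within 5% of truth; planted 85 vs
  113 nt condition medians within 5%), 1,000 decay series at
  $\sigma = 0.05$ (mean $k$ within 2% of 0.2/h), 1,000 genes for
  clustering (≥ 95% of planted down genes recovered in the all-`-`
  cluster). These tolerances are what the generators' own noise levels
  support; they are verified by the test suite and recomputed by
  `scripts/acceptance.R`, and no empirical claim is made here beyond
  what those runs compute.

# Known limitations

* The SAM reader requires a header with `@SQ` lines (conversion goes
  through Rsamtools); headerless fragments must be given a header
  first.
* Tail base composition (non-A residues inside tails) is extracted but
  not analysed; the package reports lengths only.
* The sign-pattern clustering is a deliberate, documented substitute
  for an unspecified HMM-style procedure; with very noisy single-
  replicate data its hard threshold will fragment clusters where a
  probabilistic model might not.
* Differential calls carry no significance testing — they reproduce a
  pure threshold rule by design and should not be read as inference.
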