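# TailDynamics

Poly(A) tail calling from aligned long reads, mRNA decay kinetics, and
time-course gene-set analysis — the computational toolkit for studying
how deadenylation clears transcripts during a cell-state transition,
built around the naive-to-formative differentiation of mouse embryonic
stem cells (ESCs to EpiLCs) under Ccr4-Not (Cnot8) perturbation.

## What it computes

**Tail calling.** A full-length cDNA (CCS) read keeps its 3' poly(A)
tail as a soft clip of the alignment. For each read the package
extracts the transcript-3' soft-clipped segment (strand-aware),
rescues aligner-absorbed A's at the boundary (A-tract extension), and
applies the quality rules: reads without a 3' clip are discarded,
tails with fewer than 4 A's among the first 8 bases are rejected, and
reads with fewer than 7 CCS passes are filtered. Per-gene tail length
is the geometric mean over accepted tails,

> gm(g) = exp( mean( ln L<sub>i</sub> ) ),

reported only for genes with ≥ 10 accepted transcripts, and
two-condition comparisons give pairwise per-gene tables, condition
medians, length-bin fractions and 2%-trimmed distribution supports.

**Decay kinetics.** After transcription shutoff (actinomycin-D chase),
dC/dt = −K<sub>decay</sub>·C, so ln(C/C₀) = −K<sub>decay</sub>·t and
t<sub>1/2</sub> = ln 2 / K<sub>decay</sub>. `fitDecay()` estimates
K<sub>decay</sub> as the through-origin least-squares slope of
−ln(C/C₀) on t; 2<sup>−ΔΔCt</sup> relative quantification is included.

**Expression dynamics.** TPM conversion, threshold differential calls
(fold change > 1.5 with pseudocount, log₂ TPM > 1 expression floor),
deterministic sign-pattern temporal clustering (the continuous
downregulation cluster is the all-`-` pattern), PCA projection, and a
gene-set ledger that records every intersection/union/exclusion with
operand sizes — the derivations behind "degradation-dependent" and
"naive-GRN-like" gene sets become auditable tables.

**Simulators.** Seeded generators with truth tables for all three
stages (SAM-encoded tailed reads, decay series, clustered two-condition
time courses), so every pipeline stage is verified by parameter
recovery rather than by fixtures.

## Worked example

Simulate two conditions (control tails around 85 nt, knockout around
113 nt), run the tail pipeline, and compare:

```r
library(TailDynamics)

simA <- simulateTailedReads(tailSimConfig(nGenes = 50, readsPerGene = 100,
                                          geomMean = 85, seed = 1))
simB <- simulateTailedReads(tailSimConfig(nGenes = 50, readsPerGene = 100,
                                          geomMean = 113, seed = 2))
resA <- runTailPipeline(simA$reads, simA$annotation)
resB <- runTailPipeline(simB$reads, simB$annotation)

resA$calls
#> TailCallSet with 5000 reads
#>   ACCEPTED           4694
#>   REJECTED_NO_CLIP   267
#>   REJECTED_LOW_A     0
#>   FILTERED_LOW_PASS  39
#>   min_passes: 7 | pass filter: TRUE

compareTailConditions(resA$summary, resB$summary, resA$calls, resB$calls)
#> TailComparison over 50 shared genes
#>   median geometric-mean tail: A = 84.8 nt, B = 108.7 nt
#>   trim quantile: 0.02
```

The status counts show where every read went (5% of simulated reads
carry no tail, a small tail of the Poisson pass-count distribution
falls under 7 passes). The condition medians recover the planted
geometric means; the per-condition bin fractions shift mass from the
5–90 nt bin into the 90–200 nt bin for the long-tailed condition, the
signature of impaired deadenylation.

Decay fitting on a chase series measured at 0, 2, 4 h:

```r
fitDecay(c(0, 2, 4), c(1, 0.42, 0.19))
#> DecayFit: k = 0.4189 /h, t1/2 = 1.65 h, R^2 = 1.000 (n = 3)
```

Gene-set bookkeeping:

```r
led <- GeneSetLedger()
addGeneSet(led, "ko_up", sprintf("g%03d", 1:60))
addGeneSet(led, "degradation_cluster", sprintf("g%03d", 31:130))
dependentDegradationSet(led, "ko_up", "degradation_cluster")
ledgerTable(led)
#>                   name size    operation                  operands
#>                  ko_up   60        input
#>    degradation_cluster  100        input
#>  degradation_dependent   30 intersection ko_up degradation_cluster
#>                                 detail
#>
#>
#>  30.0% of degradation_cluster (30/100)
```

A thin command-line wrapper over the same functions lives at
`inst/scripts/taildyn.R` (`synth`, `tailcall`, `compare`, `decay`,
`ddct` subcommands).

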