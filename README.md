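# loopscape

3D enhancer-network analysis for Hi-C and HiChIP data.

Gene regulation in mammalian cells depends on physical contact between
promoters and distal enhancers, organized within topologically associating
domains (TADs) whose boundaries insulate enhancer action. `loopscape` is an
R package for analysing how this 3D enhancer network rewires between two
cellular conditions — for example a resting versus a stimulated immune
cell, or wild-type versus an architectural-protein knockout. It targets the
joint analysis of in situ Hi-C (architecture), protein-directed conformation
capture (HiChIP, enhancer-centric loops), ChIP-seq peaks (enhancer activity
and TF binding), and RNA-seq counts (expression outcome).

## What it computes

**Architecture.** Per-chromosome binned contact matrices are balanced by
iterative correction and scanned with a sliding-square insulation score
(window *b* = 500 kb). TAD boundaries sit where the insulation delta
(mean over the 200 kb span left of a bin minus the span right of it)
crosses zero from + to − at a local insulation minimum; boundary strength
is the delta swing, and calls weaker than 0.1 are discarded. A/B
compartments come from the leading eigenvector of the
observed/expected correlation matrix at 100 kb.

**Loops.** 10-kb bin pairs with spans between 20 kb and 2 Mb are tested
against a distance-stratified background with multiplicative per-anchor
coverage bias. The p-value is the negative-binomial upper tail at the
pair's expected count, with stratum overdispersion moment-estimated from
the data; Benjamini–Hochberg correction across all tested pairs gives q-values,
and loops are kept at q < 1e-5 (acetylation assay) or q < 1e-2 (TF assay).

**Annotation.** Promoters are TSS ± 2.5 kb; enhancers are H3K27ac peaks not
overlapping a promoter; super-enhancers are ROSE-style stitched clusters
(12.5 kb) above the slope-1 tangent of the scaled signal-rank curve. Each
loop anchor gets exactly one label by the precedence
promoter > enhancer > CTCF > other.

**Dynamics.** A negative-binomial Wald engine tests loop counts, anchor
acetylation signal, and gene counts between conditions. Loops are
*gained*/*lost* at P < 0.1 and |log2FC| > 0.584963 (log2 1.5), *constant*
at P > 0.5 and |log2FC| < 0.378512 (log2 1.3); enhancers are
*inducible*/*repressed* at P < 0.1 and |log2FC| > 0.378512, *constitutive*
in the constant band. Promoter–enhancer loops then place genes into six
regulatory modes — (gained, inducible) = i, (constant, inducible) = ii,
(gained, constitutive) = iii, (lost, constitutive) = iv,
(constant, repressed) = v, (lost, repressed) = vi — with
(constant, constitutive) genes as controls, and each mode's RNA log2
fold-changes are compared to control by Welch t-tests.

**Integration.** Cross-boundary analysis flags gained loops that span a
reference-condition TAD boundary; TF target genes are classed as
promoter-only, promoter-and-distal, or distal-only through loop
connectivity; region-set enrichment is a one-sided Fisher exact test over
a region universe; virtual 4C tracks show −log10(q) of a viewpoint's
loops; and anchor-loop graphs are partitioned with Louvain communities
whose connectivity is the intra-community loop count.

**Synthetic data with planted truth.** `generate_genome()`,
`generate_truth()`, `generate_hic()`, `generate_hichip()`,
`generate_peaks()` and `generate_rna_counts()` produce a complete synthetic
input set — power-law distance decay with planted TADs, NB-sampled HiChIP
replicates with planted loops and coverage bias, condition-specific peak
signal, and NB gene counts wired to the mode taxonomy — with a
machine-readable truth table, so every downstream stage can be validated
end to end.

## Worked example

```r
library(loopscape)

cfg <- pipeline_config(seed = 1)   # 30 Mb chromosome, 100 genes,
                                   # 5 boundaries, 2 HiChIP replicates
st <- run_all(cfg, outdir = "demo_out")

st$recovery$boundary
#> $recall    [1] 1
#> $n_planted [1] 5
#> $n_called  [1] 5
#> $spurious  [1] 0

st$mode_summary
#>      mode  n     mean_lfc         t            p
#> 1       i 10  1.444449637  8.444168 8.754963e-08
#> 2      ii  7  0.966616802  4.118480 2.363386e-03
#> 3     iii  5  0.517213069  2.295996 5.764797e-02
#> 4      iv  9 -0.624987549 -2.865246 1.281547e-02
#> 5       v  6 -0.619039624 -1.573034 1.675485e-01
#> 6      vi  9 -1.467539610 -9.002495 4.235627e-08
#> 7 control 12 -0.009314649        NA           NA

st$recovery$crossing_fraction
#> [1] 0.3181818
```

The run recovers all five planted TAD boundaries with no spurious calls,
finds the planted loops at q < 1e-5, and reproduces the planted expression
ordering: genes gaining loops to newly activated enhancers (mode i) are the
most upregulated, control genes are unchanged, and genes losing loops from
deactivated enhancers (mode vi) are the most downregulated — each mode
tested against control with a Welch t-test. About a third of
gained loops cross a reference-condition boundary, mirroring how boundary
weakening licenses new enhancer–promoter contacts. All outputs (boundary
BEDs, loop tables, bedGraph tracks, mode tables, a manifest with file
hashes and the full parameter echo) land under `demo_out/`.

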