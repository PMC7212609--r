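# loopstitch

Differential ChIA-PET topology analysis of how an intruding fusion
transcription factor reorganises a CTCF-defined chromatin architecture and
represses transcription.

The package is written for analysts of protein-centric chromatin-interaction
experiments (ChIA-PET and kin) in perturbation designs: a factor is induced
(or depleted), and the question is what its binding and looping do to the
pre-existing topology and to transcription. The motivating biology is acute
promyelocytic leukaemia, where the t(15;17) fusion oncoprotein PML-RARα can
be switched on in a myeloid cell line and watched as it intrudes on the
CTCF scaffold, displaces RNA polymerase II, dismantles super-enhancers, and
silences myeloid differentiation genes — reversibly, since ATRA degrades
the fusion protein and rescues expression.

## What it computes

* **Reproducible binding sites** across three ChIA-PET anchor-peak
  datasets (factor@control, factor@induced, PML@induced). A site needs
  support from ≥ 2 of the 3 libraries; the support pattern classifies it as
  `FACTOR_SPECIFIC` (T,T,F), `SHARED` (T,T,T or T,F,T) or
  `FUSION_SPECIFIC` (F,T,T), with TSS-proximity annotation.
* **Contact domains from loop connectivity.** Loops are nodes; two loops
  are connected when their genomic spans overlap. Each connected component
  of ≥ `min_loops` loops is a domain spanning its members — applied to CTCF
  loops this yields CTCF contact domains (CCDs), the scaffold topology
  unit.
* **Stitch domains**: fusion-factor domains that enter two adjacent CCDs
  by ≥ 10 kb each, bridging them across a boundary into a larger "stitched
  CCD" (`find_stitch_domains()`, `stitched_ccd_spans()`), plus a rank-sum
  comparison of chromatin-contact load in stitch vs non-stitch domains.
* **Differential occupancy.** Per-site tag counts in two conditions are
  compared with the exact conditional binomial test — given
  `n = c_ctrl + c_trt`, the treated count is `Binomial(n, p0)` with
  `p0 = depth_trt/(depth_ctrl + depth_trt)` under the null — with
  Benjamini–Hochberg control and a ≥ 2-fold reduction requirement.
* **Super-enhancers**, ROSE-style: ±2 kb TSS exclusion, 12.5 kb stitching,
  rank-vs-signal curve scaled to [0,1] with the cutoff at the slope-1
  tangent; differential catalogs between conditions (50% reciprocal
  overlap, ≥ 2-fold signal collapse also counts as lost) and single-hop
  loop linkage of SEs to gene promoters.
* **Expression response**: pseudocount-guarded fold changes
  `(baseline + 0.1)/(treated + 0.1)`, classification of time courses into
  `REPRESSED_RESCUED` / `REPRESSED_ONLY` / `UNCHANGED` / `OTHER` (≥ 2-fold
  down at some induction timepoint; rescued when the best rescue value
  re-bounds to ≥ 1.5× the induction minimum), and selection of candidate
  direct-target genes whose promoters carry both reduced occupancy and
  fusion-side binding.
* A **seeded synthetic-data generator** (`sim_config()`,
  `simulate_dataset()`) that plants ground truth for every stage and a
  stage orchestrator (`run_pipeline()`) with per-stage manifests.

Everything is tibble-in/tibble-out and pipes cleanly; fitted results
(`occupancy_analysis()`, `call_super_enhancers()`) come with `tidy()`,
`glance()` and `autoplot()` methods.

## Worked example

Simulate the default study conditions (2 × 20 Mb toy genome, 24 planted
CCDs, 12 fusion domains of which 5 are stitches, 550 binding sites, 1000
genes with 146 repressed / 119 rescued) and run every stage:

```r
library(loopstitch)

cfg <- sim_config(seed = 1)
res <- run_pipeline("run1", config = cfg)

dplyr::count(res$sites, site_class)
#> # A tibble: 3 × 2
#>   site_class          n
#>   <chr>           <int>
#> 1 FACTOR_SPECIFIC   197
#> 2 FUSION_SPECIFIC   191
#> 3 SHARED            147
```

547 of the 550 planted sites survive the 1%-dropout reproducibility filter
with their class intact (197/147/191 vs planted 200/150/200). Domain
construction recovers the planted scaffold and the five stitches:

```r
dplyr::filter(res$stitch$calls, label == "STITCH")[, 1:6]
#> # A tibble: 5 × 6
#>   domain_id  chrom    start      end n_bridged bridged_ccds
#>   <chr>      <chr>    <int>    <int>     <int> <chr>
#> 1 chr1_F0002 chr1   2670154  3964588         2 chr1_C0002,chr1_C0003
#> 2 chr1_F0005 chr1   8142476  9749523         2 chr1_C0006,chr1_C0007
#> 3 chr1_F0007 chr1  16407406 17667747         2 chr1_C0011,chr1_C0012
#> 4 chr2_F0008 chr2   1839297  3475602         2 chr2_C0014,chr2_C0015
#> 5 chr2_F0011 chr2  10357424 12084759         2 chr2_C0019,chr2_C0020
```

Differential RNAPII occupancy concentrates at fusion-side sites — the
planted 20% reduction plus a few percent of overdispersion-driven calls —
while factor-only sites show only the single-digit background rate:

```r
stratify_by_class(tidy(res$diffocc))
#> # A tibble: 3 × 4
#>   stratum     n n_reduced pct_reduced
#>   <fct>   <int>     <int>       <dbl>
#> 1 fusion    350        91          26
#> 2 factor    200        17           9
#> 3 other       0         0          NA

res$se$control
#> <ls_se> 205 stitched regions, 5 super-enhancers (cutoff 79.8) [control]

res$expression$summary
#> # A tibble: 1 × 4
#>   n_genes n_repressed n_rescued rescue_pct
#>     <int>       <int>     <int>      <dbl>
#> 1    1000         146       120       82.2
```

All five planted super-enhancer clusters are called in the control
condition (and the three planted signal collapses are reported lost after
induction); of the 146 planted repressed genes, 120 classify as rescued
(119 planted, one noise flip), a rescue rate of 82.2%.

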