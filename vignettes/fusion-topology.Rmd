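---
title: "Differential ChIA-PET topology analysis with loopstitch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differential ChIA-PET topology analysis with loopstitch}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(loopstitch)
library(dplyr)
```

## The problem

Acute promyelocytic leukaemia is driven by the t(15;17) fusion oncoprotein
PML-RARα. In an inducible myeloid model (the PR9 line, a U937 derivative
carrying a zinc-inducible PML-RARα construct), the fusion protein can be
switched on and its effect on the three-dimensional genome watched as it
happens: CTCF ChIA-PET maps the scaffold topology, PML and RARα ChIA-PET
map the factor's own binding and looping before and after induction, RNAPII
ChIA-PET maps transcription-associated interactions, and RNA-seq time
courses measure the transcriptional output — including a "rescue" arm in
which ATRA degrades the fusion protein.

`loopstitch` packages the downstream analysis of such an experiment as a
set of composable, tibble-in/tibble-out functions:

1. **Reproducible binding sites** across the three ChIA-PET anchor-peak
   datasets (factor in the control condition, factor after induction, PML
   after induction), classified as factor-specific, shared, or
   fusion-specific, with TSS proximity.
2. **Loops and contact domains**: PET-count filtering, loop classification
   by the site classes at their anchors, and contact-domain construction
   from loop-span connectivity (applied to CTCF loops this yields CTCF
   contact domains, CCDs).
3. **Stitch domains**: fusion-factor domains whose span crosses the
   boundary between adjacent CCDs, weaving them into larger stitched CCDs.
4. **Differential occupancy** of RNAPII at classified loci between
   conditions, with exact conditional-binomial testing and BH control.
5. **Super-enhancers** from acetylation peaks (ROSE-style), their
   between-condition comparison, and loop-based gene linkage.
6. **Expression response**: repression-under-induction and
   rescue-under-ATRA classification of gene time courses.
7. A **seeded synthetic-data generator** that plants ground truth for every
   stage, so the whole pipeline is testable end to end without any
   download.

All coordinates are 0-based half-open (BED convention) internally; 1-based
inputs can be converted on read (`one_based = TRUE`). Strand is ignored
everywhere except when deriving a TSS from a gene body.

## Site calling and classification

A *reliable* binding site is one supported by at least two of the three
independent ChIA-PET datasets. `call_reproducible_sites()` merges the union
of all peaks (gap `<= merge_gap` merges, inclusive) and marks a merged
region as supported by a dataset when any of its peaks overlaps the region
by at least 1 bp. We deliberately use 1-bp overlap on merged regions rather
than a reciprocal-fraction rule: it is the simplest reproducible criterion,
and `merge_gap` is exposed for tuning.

The support triple `(factor@control, factor@induced, PML@induced)` maps
onto classes as:

| pattern | class |
|---|---|
| (T,T,F) | `FACTOR_SPECIFIC` |
| (T,T,T), (T,F,T) | `SHARED` |
| (F,T,T) | `FUSION_SPECIFIC` |
| fewer than 2 supports | `UNSUPPORTED` |

The `(T,F,T)` pattern — factor evidence before induction, PML evidence
after — is classed `SHARED` because it is consistent with either
co-occupancy or competition at the locus; `classify_support(tft_as_shared
= FALSE)` flips it to `FUSION_SPECIFIC` for users who prefer the
take-over reading. The factor-side catalog is `FACTOR_SPECIFIC + SHARED`,
the fusion-side catalog `SHARED + FUSION_SPECIFIC`; `catalog_sizes()`
reports both, and the partition identity (specific + shared = catalog) is
asserted in the tests.

TSS proximity uses a `window` of ±2500 bp by default (a conventional
promoter-window choice; no canonical value exists for this assay). A site
is proximal when its interval extended by the window contains a TSS, so a
TSS exactly `window` bp beyond the last base is proximal and one base
further is not.

## Contact domains from loop connectivity

`build_domains()` connects two loops when their genomic *spans*
(anchor-start to anchor-end footprints) overlap by more than
`boundary_gap` bp, and each connected component of at least `min_loops`
loops becomes a domain spanning its members. Span connectivity — rather
than anchor-to-anchor connectivity — is what reproduces the contact-domain
concept of contiguous loop coverage; anchor-only connectivity fragments
domains.

With `boundary_gap = 0`, domains of one factor are provably disjoint: a
chain of positively-overlapping spans covers its whole component span
without holes, so any overlap between two component spans would imply an
edge between the components. The implementation asserts this on every run.
Components smaller than `min_loops` are returned as singleton loop records
in an attribute, not as domains.

Defaults — `min_pet = 4` for high-confidence loops, `min_loops = 2`,
`boundary_gap = 0` — are package choices (no published thresholds exist for
this assay family at these steps); all are exposed in the stage parameters
and recorded in the run manifests. `extend_anchors()` (±250 bp) is provided
as a cheap approximation of anchor-extension clustering when inputs come
from a clusterer with narrow anchors.

## Stitch domains

`find_stitch_domains()` overlays factor domains on the (disjoint, sorted)
CCD scaffold. A factor domain is a *stitch* when it overlaps at least two
CCDs, each by at least `min_anchor_overlap` (default 10 kb — larger than a
typical anchor, so a stitch must genuinely enter both CCDs rather than
graze a boundary). Factor domains deep in a single CCD are `INTRA`; those
touching no CCD are `INTERGENIC`. Domains bridging more than two CCDs
count as one stitch with `n_bridged` reported. Bridged CCDs must be
consecutive in genomic order; this is asserted, and the assertion can only
fire when a CCD narrower than the overlap threshold sits inside a factor
domain. Adjacency places no cap on the gap between CCDs.

`stitched_ccd_spans()` chains stitch calls that share a CCD (union-find
over the shared-CCD relation) into maximal stitched-CCD spans, and
`stitch_contact_load()` compares PET totals of stitch vs non-stitch domains
with a one-sided Wilcoxon rank-sum test (stitches are expected to carry
more contacts).

## Differential occupancy

Tag counts at a locus in two unreplicated libraries are compared with the
conditional binomial test: given `n = c_ctrl + c_trt`, under the null of
equal underlying rates `c_trt ~ Binomial(n, p0)` with
`p0 = depth_trt / (depth_ctrl + depth_trt)`. The one-sided lower tail is
the p-value for reduction. This choice is exact at low counts, depth-aware,
and is the two-library Poisson comparison in disguise. Fold changes are
computed on depth-normalised counts with a +0.5 pseudocount per raw count.
A locus is called *reduced* when its BH q-value is at most `alpha` (0.05)
**and** the fold reduction reaches `min_fold` (2): significance alone can
flag biologically negligible shifts at high counts, and fold alone cannot
separate signal from sampling noise at low counts.

The test assumes Poisson sampling within each library; between-locus
biological overdispersion inflates its unconditional false-positive rate.
The synthetic generator deliberately draws counts from a negative binomial
(dispersion 0.1) so this inflation is visible in the default dataset: the
fusion-side stratum recovers the planted reduction rate plus a few
percentage points of overdispersion-driven calls, and the factor-only
stratum shows the same background rate in isolation (single-digit
percentages, the analysis-control behaviour one expects from systems
noise). The calibration tests, by contrast, simulate from the test's own
Poisson null — type-I error at `p <= 0.05` stays below 0.05 plus twice the
Monte-Carlo error over 2500 null sites, and planted 4-fold reductions at
mean count 100 are detected essentially always.

`stratify_by_class()` reports reduction rates for fusion-side loci
(fusion-specific or shared), factor-only loci, and everything else,
mirroring the three-panel view of this comparison.

## Super-enhancers

`stitch_enhancers()` removes acetylation peaks whose centre lies within
±2 kb of a TSS and merges survivors within 12.5 kb — the standard ROSE
parameters, kept because the method is cited without modification; both
are arguments. `rank_and_cut()` sorts regions by aggregate signal, scales
rank and signal to [0, 1], and places the cutoff at the slope-1 tangent of
the curve, computed discretely as the point minimising `y − x` (the point
of maximal depth below the diagonal). Ties break toward the higher-signal
point, which calls fewer super-enhancers — the conservative direction. A
flat curve (all signals equal) has slope below 1 everywhere and calls
none. Super-enhancers are the regions with signal strictly above the
cutoff, so the SE set is always an upper set of the signal ordering.

`differential_se()` matches catalogs by 50% reciprocal overlap; by default
a positionally matched SE whose signal collapses by more than 2-fold also
counts as *lost*, because a catalog comparison based on acetylation
signals should not count a hollowed-out region as conserved. Set
`fold_drop = NULL` for purely positional matching. `link_se_to_genes()`
links an SE to a gene when a single loop has one anchor on the SE and the
other within ±2.5 kb of the gene's TSS; linkage is deliberately single-hop
(no transitive chaining through intermediate anchors).

## Expression response

`fold_change()` is the pseudocount-guarded ratio
`(baseline + 0.1) / (treated + 0.1)` — the 0.1 RPKM guard keeps silent
genes finite and is recorded in output metadata. A gene is *repressed*
when the baseline-over-timepoint fold reaches 2 at some induction
timepoint, and *rescued* when its best rescue-timepoint RPKM re-bounds to
at least 1.5× its induction minimum. The repression threshold follows the
twofold convention used throughout this literature; the rescue re-bound
factor is a package choice (no published criterion exists), set between
"any flicker upward" (1×) and "full restoration" (back to baseline), and
both are arguments. Classification is monotone: deepening an induction dip
never removes a repression call, and raising a rescue value never demotes
a rescued gene.

`select_target_genes()` intersects three layers at promoters: a gene is a
candidate direct target when its TSS window overlaps both a
reduced-occupancy locus and a fusion-side binding site.

## The synthetic generator and what it does (not) show

`sim_config()` fixes the study conditions; `simulate_dataset()` writes
BED/BEDPE/TSV inputs plus a machine-readable `truth.json`. The defaults
describe a toy genome chosen so the full pipeline runs in seconds: 2
chromosomes × 20 Mb; 12 CCDs per chromosome (sizes 300-900 kb, loop-free
gaps ≥ 50 kb, 6 chained loops each so every CCD is one connected
component); 12 fusion domains of which 5 stitch adjacent CCD pairs
(entering 50 kb into each flank, i.e. 5× the detection threshold) and 7
sit strictly inside CCDs at least 20 kb from any boundary; 550 binding
sites (200/150/200 factor-specific/shared/fusion-specific) as 400-bp peaks
with ±50 bp jitter and a 1% per-dataset dropout — the reproducibility of
high-quality libraries, which leaves expected class recovery near 98%;
negative-binomial tag counts (mean 100, size 10) with a 4-fold reduction
planted at 20% of fusion-side sites; 205 enhancer regions of which 5 are
planted clusters of five 100×-signal peaks within stitching distance
(3 of the 5 collapse to background after induction, each cluster looped to
one gene's promoter); and 1000 genes with 146 planted repressed and 119 of
those rescued — so a noise-free run reports a 81.5% rescue rate, the
regime the method is meant to operate in. PET counts are floored at 4 so
that planted loops survive the default high-confidence filter; repression
is planted only on genes with ≥ 1 RPKM baseline, since a silent gene
cannot exhibit a measurable fold-down.

What passing these tests shows: the algorithms recover exactly the
structures they define, at realistic noise levels, deterministically. What
it does not show: performance on real ChIA-PET data, whose loop-span
geometry is far messier (nested and overlapping domains, distance-decaying
contact frequency, anchor-width heterogeneity), whose peak reproducibility
varies locus by locus, and whose counts carry locus-specific biases no
global dispersion parameter captures. The generator makes no attempt to
model contact-distance decay or read-level artefacts.

## Numerical conventions

* Reported percentages round half-up (`class_fraction()`), so printed
  worked examples reproduce exactly (e.g. 119/146 → 81.5).
* Gap thresholds are inclusive (`gap <= max_gap` merges); overlap
  thresholds on domain connectivity are exclusive (`overlap >
  boundary_gap`).
* Anchor-class ties (equal overlap with two sites) resolve toward the
  higher-priority class: fusion-specific > shared > factor-specific, then
  first site; the choice is logged in the loop table.
* Degenerate inputs: empty peak sets are legal everywhere; an empty TSS
  table marks all sites distal with a warning; fewer than 3 enhancer
  regions is an error (`CURVE_TOO_SHORT`); a both-zero count pair is
  `NOT testable` and excluded from BH.
* All randomness flows from the one root seed in `sim_config()`; each
  generator stage draws from an independent substream derived from it, so
  identical seed + configuration give byte-identical output files.

## Orchestration

`run_stage()`/`run_pipeline()` run the stages over a run directory with a
`manifest.json` per stage (command, parameter snapshot, input checksums,
seed, package version, record counts in/out), so every "records surviving
filter" number is auditable and reruns are verifiable. A thin command-line
wrapper over these functions ships in `inst/cli/loopstitch`.

```{r pipeline, eval = FALSE}
cfg <- sim_config(seed = 1)
res <- run_pipeline("run1", config = cfg, verbose = TRUE)
glance(res$diffocc)
autoplot(res$se$control)
```

## Known limitations

* No replicate-aware dispersion modelling in the occupancy test (the
  design it serves has no replicates); with replicates, a count model in
  the DESeq2/edgeR family is the right tool.
* Loop-level statistical significance (hypergeometric/FDR models of
  dedicated ChIA-PET callers) is out of scope; inputs are assumed to be
  already-clustered PET interactions.
* Domain disjointness is only guaranteed (and asserted) at
  `boundary_gap = 0`; positive gaps can admit overlapping domains from
  distinct components.
* SE-gene linkage is single-hop by construction and will miss genes
  reachable only through chained interactions.
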