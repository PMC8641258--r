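---
title: "Flagging empty droplets and damaged cells with the nuclear fraction"
author: "nfqc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Flagging empty droplets and damaged cells with the nuclear fraction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nfqc)
```

## The metric and its rationale

Droplet scRNA-seq protocols capture both mature cytoplasmic mRNA and
unspliced nuclear pre-mRNA; the two are distinguishable after alignment
because pre-mRNA reads fall in introns. Ambient RNA — the cell-free material
that fills otherwise empty droplets — consists predominantly of mature,
spliced transcripts, whether because it leaks from cells whose nuclear
envelope stays intact or because processed transcripts are more stable
outside the cell. A droplet containing a partially lysed (damaged) cell
shows the opposite signature: its cytoplasmic RNA has leaked away, so the
nucleus contributes a larger share of what remains, and its library is
smaller than that of intact cells of the same type.

The per-droplet **nuclear fraction**

$$NF_i = \frac{\sum IR_i}{\sum (IR_i + ER_i)}$$

(intronic over intronic-plus-exonic read counts) therefore separates three
populations when combined with the UMI count: empty droplets (low NF),
intact cells (intermediate NF), and damaged cells (high NF, low UMI).

Two assumptions matter. First, intron/exon boundaries must be well defined
in the annotation; poorly annotated genomes blur the metric. Second, cell
types differ in both their NF and UMI distributions, so damaged-cell calling
must be done per cell type — the labels are an *input* here, produced by
whatever annotation strategy the analyst trusts. Mislabeled or merged cell
types can masquerade as damaged/intact pairs. Special cases exist at both
ends: erythrocyte-like cells with almost no unspliced RNA can be mistaken
for empty droplets (the `umi_rescue` parameter exists for exactly this), and
heavily ambient-contaminated samples can hide damaged cells at low UMI.

## Counting reads

Both counting modes share the same read filter: unmapped, secondary,
supplementary and QC-fail records are excluded; duplicates are kept by
default because whether UMI pipelines mark them is inconsistent; the MAPQ
floor defaults to 0. All of this is surfaced in `read_filter()` since no
single convention is universal.

**Tag mode** trusts the aligner's region classification (Cell Ranger's
`RE:Z:` values `E`/`N`/`I`) and simply tallies reads per barcode. **Annotation
mode** classifies each read itself: the per-gene exon union (across all
isoforms) is computed from the GTF, introns are the gaps between consecutive
union intervals, and a read's aligned blocks (spliced `N` gaps excluded, so
a junction-jumping read is judged only on its matched bases) are tested for
overlap. The union-across-isoforms definition is deliberate: sequence that
is exonic in *any* isoform may derive from spliced mRNA, so only purely
intronic positions count as unspliced evidence. By the same logic the
default junction policy is *any intronic overlap wins* — intronic sequence
cannot come from mature mRNA, while exonic overlap is ambiguous. A
majority-overlap alternative is available (`junction_policy = "majority"`,
ties to intronic). Strandedness is ignored by default because common 3′ and
5′ chemistries differ; `strand_policy = "same"/"opposite"` serve stranded
protocols.

Coordinates follow one internal convention (0-based half-open, matching BAM)
with GTF input converted on parse; this removes a whole class of off-by-one
errors at the BED/GTF/BAM boundaries.

The genome is tiled into chunks (`partition_genome`) traversed
independently. A read is *owned* by the chunk containing its leftmost
aligned position, so reads spanning chunk boundaries are counted exactly
once and tallies are bit-identical for any chunk count — chunking is purely
a parallelism/memory device.

`NF` counts **reads**, not UMIs; the per-droplet UMI total is a separate
input (2-column TSV or an MTX directory, column-summed). Barcodes are
matched exactly — whitelist correction belongs upstream.

## Empty-droplet threshold

A Gaussian KDE is fitted to the defined NF scores on a 512-point grid over
[0, 1]; peaks and valleys are sign changes of the numerical first
difference, and the cutoff is the first valley after the first peak. Three
numerical choices deserve explanation:

* **Bandwidth.** The default selector is Sheather–Jones. The empty-droplet
  mode is typically much narrower than the cell modes, and a global
  rule-of-thumb bandwidth (Silverman) calibrated to the overall spread
  oversmooths it, dragging the detected valley toward the cell mode by
  roughly the bandwidth itself; on a bimodal reference mixture
  (0.3·N(0.05, 0.01²) + 0.7·N(0.5, 0.05²), n = 5000) Silverman places the
  valley near 0.22 where the true inter-mode density minimum is ≈ 0.13,
  while Sheather–Jones lands within ~0.01 of it. Sheather–Jones can fail on
  very sparse or heavily tied data, in which case the implementation falls
  back to Silverman automatically.
* **Prominence floor.** A grid point only counts as a peak if its density
  reaches 5% of the global maximum (`peak_floor`), suppressing noise bumps;
  with fewer than two qualifying peaks the distribution is treated as
  unimodal and no automatic cutoff is reported — the user must then supply
  `nf_rescue`.
* **Normalization.** The Gaussian kernel smooths some mass past 0 and 1;
  the density is rescaled to unit trapezoid mass on [0, 1]. This affects
  nothing about peak/valley locations but keeps the curve a proper density.

Automatic thresholding refuses to run below 50 defined scores. Two rescue
parameters override or temper the automatic cutoff: `nf_rescue` (manual
threshold) and `umi_rescue` (droplets above this UMI count are always kept
as cells). The input is sorted before estimation so results are invariant to
droplet order.

## Damaged-cell model

Per cell type, droplets currently flagged `cell` enter a Gaussian mixture
over $X = (\log_{10} UMI,\ NF)$:

$$P(X \mid \mu, \sigma, \alpha) = \alpha_1 N(X \mid \mu_1, \sigma_1^2)
  + \alpha_2 N(X \mid \mu_2, \sigma_2^2)$$

with diagonal covariance — per-component scalar variances per axis, matching
the scalar-σ² form of the model; the two axes are treated as conditionally
independent within a component. The fit is joint over both dimensions (a
per-axis 1-D alternative was considered and rejected: the damaged population
is defined by the *conjunction* of high NF and low UMI, which the joint fit
captures directly).

**Initialization** needs a hard partition the model itself does not define:
droplets are split at the median NF of the cell type (component 1 below,
component 2 above) — deterministic and seed-free — and the standard
count-based formulas give the starting parameters:
$\mu_k = \sum_i x_{i,k} / N_k$, $\sigma_k^2 = \sum_i (x_{i,k}-\mu_k)^2 / N_k$,
$\alpha_k = N_k / N$. EM then alternates the posterior (E) step

$$P(x_i \in k_j \mid x_i) = \frac{\alpha_j N(x_i \mid \mu_j, \sigma_j^2)}
  {\sum_k \alpha_k N(x_i \mid \mu_k, \sigma_k^2)}$$

computed in log space with log-sum-exp, and weighted refits (M step) with
$N_k$ replaced by summed posteriors.

**Convergence and model choice.** "Convergence by BIC" is ambiguous between
an iteration-stopping rule and model selection; BIC is a model-selection
criterion, so the implementation reads it as the latter: each EM run stops
when the relative log-likelihood change drops below `em_tol` (default 1e-6,
cap 1000 iterations), and the one- versus two-component decision is then
made by $BIC = -2\,\ell + p\,\ln n$ (p = 4 for k = 1; 9 for k = 2). This
reading also matches the model's role of finding the *minimum separation*
required before a second population is acknowledged.

**Degeneracy.** Variances are floored at 1e-6 per dimension; a fit whose
component collapses (vanishing weight or variance at the floor) is restarted
from a seeded random partition, a bounded number of times, before erroring.
The `seed` in `call_config()` is consumed *only* by these restarts — the
default path is fully deterministic.

**Labeling.** If k = 2 wins, the candidate damaged component is the one with
the higher mean NF. Droplets with posterior > 0.5 (maximum a posteriori; the
model gives no probability rule beyond assignment) are flagged only if both
gates hold: mean-NF excess ≥ `delta_nf` (default 0.15) and candidate mean
UMI ≤ `umi_ratio` (default 0.5) × intact mean UMI. The UMI comparison uses
geometric means (exponentiated mean log10), the model-consistent center in
log space; `umi_mean = "arithmetic"` switches to posterior-weighted linear
means. Cell types with fewer than `min_droplets_per_type` droplets (default
100 — mixture fits on tiny groups are unstable) are skipped with a warning.

The calling order is fixed: empty droplets first, then damaged cells among
the remaining `cell`-status droplets, so no droplet ever carries both flags.
Statuses are flags only; `drop_flagged()` is the explicit opt-in filter.

## What the synthetic generator emulates — and what it does not

The fixture generator draws droplet classes with NF geometry mirroring real
data: empty ~ Beta centred near 0.05, intact ~ truncated normal near 0.4
(sd 0.08), damaged ~ truncated normal near 0.75 with log-normal UMI counts
at ~30% of intact (defaults: 10% empty, 20% damaged per type across three
cell types). These are qualitative, field-realistic choices, not estimates
from any particular dataset. For BAM fixtures, each barcode's reads are
placed entirely inside known intron/exon-union intervals (or intergenic
space) on a toy 3×100 kb genome, with matching region tags, so the
generator's ledger is exact ground truth for both counting modes; an
optional junction-spanning fraction exercises the junction policy.

Passing tests on these fixtures demonstrates correctness of the counting
arithmetic, the threshold detection and the mixture machinery under the
stated geometry. They do *not* demonstrate robustness to what the generator
omits: ambient expression profiles, barcode errors, doublets, spliced-read
CIGAR diversity, chimeric or multi-mapped reads, cell-type NF overlap, or
annotation errors. Claims about real data rest on the method, not on these
tests.

## Problem sizes and tunables

Test and acceptance runs use deliberately modest sizes — 500-barcode /
~50 000-read BAM fixtures, 5 000-droplet populations, n = 1000–2000 mixture
fits, 100-replicate model-selection sweeps — chosen so the whole suite
completes in a few minutes while keeping every statistical check
well-powered. The parameters a user is most likely to touch:

| parameter | default | meaning |
|---|---|---|
| `nf_rescue` | none | manual NF cutoff (fraction, 0–1) |
| `umi_rescue` | none | UMI count above which droplets are always cells |
| `delta_nf` | 0.15 | minimum damaged-vs-intact mean NF excess |
| `umi_ratio` | 0.5 | maximum damaged/intact mean UMI ratio |
| `min_droplets_per_type` | 100 | smallest group fitted |
| `em_tol` / `em_max_iter` | 1e-6 / 1000 | EM stopping rule |
| `bw` / `peak_floor` | "SJ" / 0.05 | KDE bandwidth and peak prominence floor |

## Known limitations

* Counting assumes exact barcode matches and an annotation on the same
  genome build as the BAM (a chromosome-name compatibility check guards the
  common failure, not subtler build drift).
* The mixture is two-component and diagonal; more than one damaged
  subpopulation per cell type, or strongly correlated NF/UMI structure
  within a component, is outside the model.
* The KDE valley assumes the empty mode is the *first* peak; a sample with
  essentially no empty droplets but a low-NF cell type could be
  mis-thresholded and should be inspected with `plot()` and, if needed,
  overridden with `nf_rescue`.
* UMI totals are taken from the quantification pipeline, not recomputed;
  disagreement between the BAM and the matrix is not detected.
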