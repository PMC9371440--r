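---
title: "Temporal inference for single-nucleus embryogenesis atlases"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Temporal inference for single-nucleus embryogenesis atlases}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Staged embryo collections label every nucleus with nothing finer than a
2- to 4-hour collection window. Embryos within a collection are
asynchronous, so the window label understates what the data contain: a
nucleus's expression or accessibility profile carries information about
its *absolute* developmental age at far finer resolution. embryochron
implements the inference that exploits this — a regressor trained to
predict the center hour of the collection window from the profile — and
the downstream analyses that absolute ages unlock: minute-scale
pseudobulk dynamics around zygotic genome activation (ZGA), cell-state
lineage graphs across inferred time windows, non-negative least squares
(NNLS) integration of RNA and ATAC cluster profiles, germ-layer-resolved
transcription-factor (TF) activity models, and temporal gene modules by
dynamic time warping (DTW).

Everything is validated against a synthetic atlas generator with planted
ground truth, so the whole pipeline runs and is tested without any
external download.

## The age model

Cells from all windows are pooled; the regression target of cell $i$ is
the center hour $c_{w(i)}$ of its collection window. Because windows
overlap, a profile observed at an age covered by several windows is
trained against several center values, and the fitted conditional mean
interpolates between them — this is what turns interval supervision into
a continuous age estimate.

Preprocessing is frozen into the model and replayed at prediction time:
per-cell depth normalization to $10^4$, a pseudocount of 1, natural log
(ATAC-like input is binarized first), followed by selection of the
features whose normalized values correlate most strongly (absolute
Pearson) with the window center, computed on training cells only
(defaults: 2,000 features, capped at availability). Two regressors are
provided:

* **lasso** — L1-penalized linear regression (`glmnet`), penalty chosen
  by window-stratified cross-validation;
* **nn** — a feedforward network (two rectified hidden layers, default
  64 and 32 units, linear output) trained on squared-error loss with
  minibatch Adam, decoupled weight decay, and an internal 10% validation
  split.

Predictions are clipped to the embryogenesis span seen in training
(0–20 h by default); ages outside it are meaningless.

### Epoch selection targets calibration, not only MSE

The validation-MSE-optimal network is systematically *shrunken*: its
per-window mean predictions are compressed toward the global mean, which
is exactly the failure mode a user of absolute ages cares about. The
package therefore selects the training epoch in two stages: among all
epochs whose validation MSE is within 50% of the best (the accuracy
criterion has a wide margin; calibration does not), it picks the epoch
minimizing the largest per-window mean residual, monitored on the cells
the model is deployed on, with predictions clipped as at deployment and
a 5%-trimmed mean so the rare old-embryo contaminant tail does not
dominate the monitor. On the default synthetic atlas this yields a
maximum per-window calibration error of roughly 0.3–0.5 h across seeds,
against a structural floor of about 0.6 h for a purely
MSE-optimal center-hour predictor in the very last window (ages beyond
19 h are covered by a single window whose center is 18 h, so no
center-trained regressor can be unbiased there on held-out data).

### Evaluation

`evaluate_age()` reports the mean squared error against the window
center and the *proportion correct*. The literature does not pin down
the latter; here it defaults to the fraction of cells whose predicted
age falls inside their originating collection window (bounds inclusive)
— window membership is the only ground truth available for real nuclei
— with nearest-center agreement available via `mode = "nearest"`.

### Contamination, age filtering, and sex

Early collections are contaminated by older embryos (which contain far
more nuclei); `contamination_fraction()` quantifies the share of a
window's cells predicted at or beyond an age threshold (4 h for the
first window). One caveat discovered during validation and worth
stating: the *linear* model should be used for this quantity.
Contaminants are rare training cells carrying a wrong (window-center)
label, and a network trained long enough to be well calibrated has the
capacity to memorize them back to that wrong label, deflating the
estimate several-fold; a penalized linear model cannot memorize
individual cells and recovers the planted rate.

`filter_by_age()` drops cells with inferred age above 18 h (strictly)
before windowed analyses — predictions at the end of the sampled span
suffer edge effects. `classify_sex_gmm()` fits a two-component Gaussian
mixture to the per-nucleus chrX read fraction and labels the
higher-mean component XX.

## Fine-time dynamics and onsets

`fine_bins()` bins predicted ages into 1/5/10-minute increments
(floor indexing, right edge closed into the last bin);
`pseudobulk_profile()` sums counts per bin and normalizes each bin to a
common total, with empty bins flagged missing rather than zero — at
realistic sampling depth, early fine bins are often empty, and treating
them as zero would fabricate silence. Smoothing is a centered moving
average that skips missing bins.

The onset estimator is the left edge of the first bin where the
smoothed profile reaches half its maximum (window of 5 bins by
default). For ZGA-like analyses, profiles are kept on the normalized
linear scale (no log), where a logistic mean crosses half-maximum
exactly at its onset parameter. Aggregating accessibility over the
peaks linked to a gene (`aggregate_region_accessibility()`) and
comparing onsets at 1-minute bins recovers planted pioneer behaviour:
with a 0.5 h accessibility lead, the median expression-minus-
accessibility onset difference lands on 0.5 h.

## Lineage graphs across inferred windows

Cells are partitioned into non-overlapping 2-h windows by inferred age
(`window_partition()`, ages > 18 h excluded), clustered per window
(PCA of log-normalized expression or TF-IDF + SVD of binarized
accessibility, kNN graph, Louvain communities), and adjacent windows are
coembedded. For each child-state cell, the k nearest parent-window cells
are found in the joint embedding (Euclidean distance, ties broken by
cell index); the edge weight from a parent state is the **median** over
the child state's cells of the proportion of those neighbors in the
parent state. Per child state only the maximum-weight incoming edge is
kept, and only when strictly above 0.2 — yielding a forest-like acyclic
graph with in-degree at most one.

Unstated constants were fixed as: k = 30 neighbors, 30 embedding
components, states under 20 cells excluded from linking (medians over
tiny states are unstable). All are arguments.

## RNA-ATAC integration by NNLS

Gene activity scores sum accessibility over peaks overlapping the union
of the gene body and ±2 kb around the TSS (strand-aware; a peak counts
in full whenever it overlaps, since fragment-level truncation is not
recoverable from a peak-count matrix). Cluster profiles of expression
and of gene activity are decomposed over each other by non-negative
least squares in both directions; coefficients are rescaled to sum to
one per target so that 0.1 reads as a mixture proportion. A pair is
linked when it exceeds 0.1 in *both* directions (the single-direction
rule is available behind `rule = "either"`); the combined score is the
mean of the two directional coefficients.

## TF motif activity across germ layers and time

`motif_deviation()` computes a simplified chromVAR-style statistic: the
observed fraction of a cluster's reads in motif-hit peaks versus the
fraction expected under the pooled profile, z-scored against 50 random
peak sets matched on the decile of pooled accessibility. Synthetic
peaks carry no sequence, so the background matches accessibility only;
the interface accommodates a GC-matched drop-in. A motif hitting every
peak deviates exactly zero — a conservation check the tests enforce.

For nomination of stage- and layer-specific regulators, each
(TF, germ layer g, window w) is tested by OLS over the window's
clusters: deviation on expression plus an expression-by-layer
interaction, with the interaction coefficient as the effect.
Benjamini–Hochberg correction is applied once, jointly over all tests,
and significance requires adjusted p < 10⁻³. Windows with fewer than 4
clusters are skipped (few-cluster effect estimates are outlier-driven).
`consecutive_window_filter()` then demands at least three consecutive,
sign-consistent significant windows and reports the first window of the
run as the TF's activation point. Because one-vs-rest layer contrasts
produce mirror-image effects in the complementary layers on clean data,
each (TF, window) is first attributed to its single strongest
significant layer (`attribute = "top"`); the genuine layer always
carries the largest absolute effect, so on clean data the filter
returns exactly the planted pairs.

The activator/repressor readout is the correlation, across linked
cluster pairs, between a TF's expression and its motif deviation:
positive for activators, negative for repressors. In the panel
generator these two notions are controlled by `coupling`: `"global"`
(deviation tracks expression everywhere — what the correlation reads
out) and `"interaction"` (coupling restricted to the planted layer and
windows — what the interaction model detects).

## Temporal gene modules by DTW

The top-variable genes over inferred-time bins are min-max scaled per
gene and clustered by average-linkage hierarchical clustering on the
pairwise DTW distance matrix (classic dynamic program:
absolute-difference local cost, unit match/insert/delete steps, no band
by default; an optional Sakoe–Chiba band is exposed). Modules are
relabeled by ascending median onset. A caution established during
validation: DTW warps time, so it is nearly invariant to *pure onset
shifts* of one shape — temporal modules separate reliably when classes
differ in shape (decaying, switch-like, pulsed, biphasic), which is
exactly the regime of the four kinetic classes the generator plants.

`lag_compare()` overlays an expression curve and a gene-activity curve
binned into 100 equal-count partitions by inferred age, min-max scaled,
and reports the cross-correlation-maximizing shift in hours (positive =
accessibility precedes expression); a peak correlation below 0.5 flags
the estimate as low confidence.

## The synthetic atlas generator

`simulate_atlas()` is first-class, tested code, and defines the study
conditions the package is validated under:

* **Windows** — 11 overlapping collections covering 0–20 h: 0–2, 1–3,
  2–4, then 4-h windows stepping by 2 h from 3 h (the early 2-h windows
  capture the rapid pre-gastrulation transitions). The exact boundaries
  of the real design are not machine-readable, so this schedule is a
  documented, configurable stand-in with the same structure.
* **Kinetics** — each feature is maternal (exponential decay), zygotic
  (logistic onset), transient (Gaussian pulse), or constant; onsets are
  drawn uniformly on 0.5–19 h, since genes keep switching on through
  terminal differentiation and a time-silent late span would make late
  ages unlearnable in principle.
* **Counts** — negative-binomial noise (dispersion 0.5; Poisson at 0)
  around depth-scaled kinetic means, with a log-normal per-cell depth
  factor (sdlog 0.35) targeting a median of 399 UMIs per RNA-like cell
  and 5,206 reads per ATAC-like cell — the sparse regime the methods
  must survive.
* **Lineage** — a branching tree of states over 2-h epochs
  (1→3→6→12 states by default) with germ layers on the top-level
  branches; lineage-restricted features are active on a subtree, so
  marker signatures are inherited by descendants (without inheritance,
  no nearest-neighbor linking method could recover parentage).
* **Pioneer leads** — a configurable fraction of zygotic genes opens
  chromatin 0.5 h before expression onset.
* **Contamination** — 3% old-embryo contaminants (ages uniform from the
  window end to 20 h) in every window that has room for them.
* **Sex** — chrX read fractions from Normal(0.04, 0.004) for XX and
  Normal(0.02, 0.004) for XY, truncated to [0, 1]; bimodal and
  separable, arbitrary scale.
* **TF truth** — activators, repressors, and nulls with a germ layer
  and start window; active TFs multiply accessibility at their motif
  peaks up (or down) in their layer from their start window.

What the generator deliberately does **not** emulate: genome sequence
(motif hits are an input table, not a PWM scan), read-level artifacts,
doublets, batch effects, and cell-type-specific capture biases. Passing
tests therefore demonstrate the *inference machinery* — supervision
from overlapping windows, onset estimation, graph linking, NNLS
coupling, interaction testing, DTW grouping — not robustness to every
technical property of real embryo data.

`write_atlas()`/`read_atlas()` round-trip an atlas through plain-text
files (MatrixMarket counts, TSV metadata, 4-column BED peaks, 0-based
half-open coordinates throughout; TSS = interval start on the + strand,
end − 1 on the − strand).

## Problem sizes and numerical choices

The validation suite uses: a default atlas of ~20,000 RNA-like cells
(1,820 per window) by 1,020 genes and 3,300 ATAC-like cells by 2,500
peaks; a ZGA atlas of 12,000 RNA / 9,000 ATAC cells over a single 0–3 h
window; a 12-state lineage atlas of 800 cells per 2-h window; a
10-cluster matched-pair atlas of 1,500 cells per modality; TF panels of
20 TFs over 9 windows × 3 layers × 3 clusters; and 800 genes × 40 bins
for DTW modules. These sizes were chosen so every planted effect is
recovered with comfortable margins on a single CPU in minutes, and they
are the sizes the acceptance script re-runs. In the ZGA validation the
fine-time bins are formed from the generator-recorded ages, so that the
onset estimator is assessed in isolation; the age model's own accuracy
and calibration are validated separately on the default atlas.

Numerical conventions worth knowing: zero-variance features are
excluded before correlation ranking and before NNLS; feature-selection
ties break by feature id; nearest-neighbor ties break by ascending cell
index; even-length medians are the mean of the central pair (R's
default, matching the stated linking rule); empty fine-time bins are
missing, never zero; thresholds quoted as strict (edge weight > 0.2,
NNLS coefficient > 0.1, age filter > 18 h) are implemented strictly;
the two-cell degenerate case of the sex classifier falls back to a
two-center assignment; k-means uses 10 restarts under a fixed seed; and
all simulation and fitting entry points take explicit seeds and restore
the caller's RNG state.

## Known limitations

* Inferred ages inherit the structural bias of center-hour supervision
  at the extremes of the sampled span; the package mitigates
  (calibration-aware epoch selection, the 18-h filter, clipping) but
  cannot remove it on held-out data.
* The deviation statistic matches backgrounds on accessibility only;
  with real peaks a GC-matched background should be substituted.
* The interaction model is a per-window OLS with a single
  expression-by-layer term; it detects onset windows but does not model
  temporal autocorrelation across windows.
* DTW modules require shape differences; onset-only differences within
  one shape family are better separated by onset clustering
  (`temporal_gene_clusters()`).
* NNLS linkage assumes cluster profiles are approximately mixtures on a
  shared gene space; strong modality-specific depth structure outside
  the shared space is not modeled.
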