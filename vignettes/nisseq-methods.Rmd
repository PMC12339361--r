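---
title: "Genotyping and phenotyping optical pooled screens: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genotyping and phenotyping optical pooled screens: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

In an optical pooled CRISPR screen, every cell carries one guide RNA from
a lentiviral library, its phenotype is recorded by live microscopy, and
its guide identity is then read out *in situ*: the guide barcode is
amplified inside the nucleus by rolling-circle amplification (RCA) and
sequenced by synthesis over a series of imaging cycles. Each RCA product
appears as a bright sub-nuclear punctum whose colour in cycle *c* encodes
base *c* of the barcode. Because the readout sequences the strand
complementary to the guide spacer, the dictionary used for matching holds
the *reverse complements* of the library spacers.

`nisseq` implements the computational side of this experiment: from raw
multi-cycle image stacks and live phenotype images to per-nucleus barcode
calls, per-cell phenotype metrics, and per-gene screen statistics —
together with a fully ground-truthed synthetic scene generator used to
validate every stage, since real screens of this kind produce terabytes
of raw imagery.

## Genotyping pipeline

### Cycle registration

Stages drift between cycles, so each cycle's nuclear-stain image is
registered against cycle 1 by cross-correlation computed in the frequency
domain, and the recovered integer translation is applied to that cycle's
three sequencing channels (out-of-frame pixels zero-filled). The peak is
located on the full correlation surface and then validated against a
configurable bound (`max_shift`, default 50 px): a drift beyond the bound
raises an error naming the cycle rather than silently returning a clipped
estimate. Shifts are integer-pixel; the downstream 5×5 aggregation window
makes sub-pixel refinement unnecessary, and only translation is modelled
(one microscope, fixed sample — no rotation or scaling between cycles;
deformable tissue is out of scope).

### Spot detection and profile extraction

Candidate spots are local maxima of the high-pass-filtered sum of all
three sequencing channels over the first `n_detection_cycles = 3` cycles.
Two numerical choices matter here:

* The high-pass filter is an unsharp mask — the image minus its Gaussian
  blur (`highpass_sigma = 4` px) — with negative values set to zero when
  profiles are extracted. For *thresholding*, however, the signed
  difference is used: clipping negatives halves the noise distribution
  and would break a robust threshold. The detection threshold is
  `max(detect_floor, median + detect_k × MAD)` of the filtered detection
  image (`detect_k = 5`); no absolute value is inherent to the method
  because the per-nucleus intensity gate (below) is the hard filter.
* Local maxima are strict 8-neighbourhood maxima with a deterministic
  raster-scan tie-break, so plateaus contribute exactly one detection.

For every spot, each cycle/channel image is high-pass filtered, negatives
are removed, and intensities are summed over the 5×5 pixel window centred
on the spot (`spot_window = 5`); windows clipped by the image border are
flagged. A spot whose guide begins with three dark bases (see below)
emits no light in the detection window and is undetectable — an intrinsic
~1/64 loss of three-colour chemistry, not an implementation artifact.

### Crosstalk unmixing and base calling

Fluorophore emission bleeds between channels, so the measured channel
vector of a base is a fixed linear mixture of pure base signals. The
3×3 mixing matrix is estimated from the run itself: each bright
(spot, cycle) observation is provisionally called by its brightest raw
channel, channel vectors are averaged per base, columns are normalised to
peak 1, and one refinement pass repeats the call on unmixed intensities —
removing the bias that the bleed itself introduces into the provisional
calls. A fixed matrix can be supplied instead. Unmixing multiplies each
cycle's channel vector by the inverse matrix; negatives are retained
until calling.

Three-colour chemistry leaves one base dark (G by default; the
channel→base mapping `A = 477 nm`, `C = 546 nm`, `T = 638 nm` is
configurable because it is chemistry-specific). A cycle is called G when
all three unmixed intensities fall below `g_dark_fraction = 20%` of the
spot's maximum unmixed intensity across all cycles; otherwise the argmax
channel is called, with an exact top-two tie giving `N`. `N` counts as a
mismatch during dictionary matching.

### Dictionary matching

Called sequences are matched against the reverse-complement dictionary on
the prefix of length equal to the number of imaged cycles, allowing zero
or one mismatch and no ambiguities. Exact hits take priority over
distance-1 hits (standard barcode-correction semantics; anything stricter
would discard exact hits). Lookup enumerates the 3·L Hamming-1
neighbours against a hash of prefixes, O(L) per query; guides sharing a
spacer or a prefix form intrinsically ambiguous groups that can never be
assigned.

### Nucleus assignment

Matched spots accrue their total intensity — the sum of their positive
unmixed entries, a functional chosen because it reuses the already
computed profile and is scale-consistent — to their guide, inside the
segmented nucleus containing the spot centre. A nucleus is assigned its
top guide only if (i) that guide holds more than two-thirds of the
nucleus's total matched-spot intensity (`dominance_fraction = 2/3`), and
(ii) the brightest single-channel, single-cycle spot intensity reaches
`nucleus_intensity_threshold = 7e5` counts (`2e5` preset for low-signal
cell types). Ambiguously matched spots count toward the denominator but
toward no guide: they erode dominance rather than create it.
Multi-integration nuclei are rejected by the dominance rule, not
deconvolved.

Segmentation itself is a pluggable backend. The built-in fallback — Otsu
threshold, hole fill, distance-transform watershed — is deterministic and
used throughout the tests; learned segmenters can be registered by name
and their label images enter the same container. The package neither
bundles nor retrains any segmentation model.

## Phenotyping

z-stacks are collapsed by averaging. Two single-cell metrics are
provided:

* **Nuclear translocation**: the Pearson correlation, over each cell's
  pixels, between nuclear stain and reporter. Cytosolic reporters show a
  dark nucleus and anti-correlate; translocation drives *r* positive.
  Raw channels are used — Pearson is already affine-invariant.
* **Speck ratio**: mean high-pass-filtered reporter over mean reporter
  per cell, after local background subtraction, with negatives removed at
  each step. A diffuse reporter scores near zero; a micron-scale punctum
  dominates the high-frequency band. The speck filter uses a tight
  Gaussian (`speck_sigma = 2` px) because specks are small.

Local background subtraction follows a block scheme: the image is
downsampled 8×8-fold by block averaging, and each full-resolution pixel
has the minimum over the 9×9 closest downsampled pixels subtracted, with
negatives set to zero. Cells with low reporter expression are excluded;
the cutoff is a per-run percentile (`expression_percentile = 5`) since no
absolute value generalises across reporters and exposure settings.

## Linking modalities

Phenotype and sequencing images are acquired in separate sessions,
possibly at different magnifications. Candidate partners for each
phenotype field of view are the sequencing fields within one field width
by stage position; the phenotype image is rescaled by the magnification
ratio, candidates are ranked by cross-correlation at 8×8-downsampled
resolution, and the best is refined at 2×2. A minimum normalised
correlation of 0.2 gates acceptance (no value is canonical; this is
logged output metadata). Nuclei are then matched by centroid: accepted
when within 11.1 µm and when areas agree within two-fold after
magnification correction (areas scale with the squared pixel-size
ratio). Ambiguity is fatal on both sides — duplicate claims on one
sequencing nucleus exclude all involved, and a second candidate closer
than 1.2× the nearest distance (both inside the gate) excludes the
phenotype nucleus. The 1.2 ratio is the package's quantification of
"ambiguously mapping nuclei were excluded"; both rules are configurable.
For cell types whose live nuclear stain is unreliable, membrane-derived
cell outlines shrunk by 5 px stand in for nuclei; the matching operation
is identical, only the label source differs.

## Screen statistics

Cells are pooled per targeted gene (across guides) and each gene with at
least `min_cells_per_gene = 10` cells is tested against the pooled
non-targeting (NT) cells with a two-sided Wilcoxon–Mann–Whitney test,
followed by Benjamini–Hochberg adjustment across tested genes. Fold
changes are ratios of means reported as log2; metrics that can be
negative (translocation *r* ∈ [−1, 1]) are shifted by a recorded constant
(+1) before the ratio — the rank-based test is unaffected.

The test uses the exact null distribution for tie-free samples up to 12
observations combined. Larger tie-free samples use a
continuity-corrected normal approximation sharpened with an Edgeworth
term for the fourth cumulant of U,
κ₄ = −mn(N+1)(m²+n²+mn+m+n)/120 (the null is symmetric, so the kurtosis
term is the leading correction). This keeps the approximation within
two thousandths of the exact two-sided p already at six observations per
group, where the plain corrected normal approximation errs by up to
0.0155. Tied samples use the standard tie-corrected normal
approximation.

`downsample_power()` traces hit detection against cells per gene by
repeated seeded subsampling without replacement. Its hit rule is
FDR < 0.05 together with an estimate-side |log2 FC| filter (default 1).
One caveat worth knowing: when a planted effect lies exactly on the
filter boundary, the filter passes roughly half the replicates at large
cell counts (the estimate concentrates on the boundary), which can make
the curve non-monotone; for boundary effects, set `lfc = 0` and read
detection from the FDR criterion alone.

## The synthetic scene generator

`render_nis_scene()` emulates one field of view: nuclei as
non-overlapping Gaussian blobs (rejection-sampled with a 1.25× centre
separation factor), one RCA spot per transduced nucleus (two for
double-integration nuclei), per-cycle channel vectors formed from the
barcode base indicator through a configurable crosstalk matrix, optional
one-cycle phasing lag, per-cycle stage drift, constant background and
Gaussian read noise. Intensities are scaled so clean spots clear the
7×10⁵ assignment gate (spot amplitude 1.5×10⁵ ± 2×10⁴ counts peak, point
spread σ 1.5 px at 0.325 µm/px). The signal-to-noise ratio is defined at
the pixel level (peak amplitude over per-pixel noise σ); window
aggregation then improves the effective per-observation ratio, as it
does on a camera. `render_spot_field()` renders dense nucleus-free spot
grids for stress-testing the caller at scale;
`render_phenotype_scene()` renders the matched phenotype modality, with
cytosolic reporter drawn as an annulus (dark nucleus) so that the
translocation metric has a real dynamic range, and
`simulate_screen_table()` draws per-cell metrics directly (log-normal
null) for statistics-scale validation.

What the generator deliberately does **not** emulate: realistic nuclear
texture (Gaussian blobs keep the fallback segmenter exact), optics-grade
point-spread functions, camera-specific noise, illumination fields,
tissue deformation, or cell movement beyond a rigid jitter between
modalities. Passing tests therefore demonstrate correctness of the
algorithms under controlled conditions, not robustness to every
real-data pathology; the segmentation interface exists precisely so
stronger segmenters can be swapped in for real data.

## Validation scale

The test-suite and acceptance computations use: 1,000-spot fields
(1024² px, 6 cycles) for base calling, clean and at pixel SNR 10 with
25% crosstalk; 500 spots for crosstalk recovery; 10⁴ queries against a
10³-guide dictionary for oracle equivalence; drifts to ±20 px for
registration; a 200-nucleus scene (30% unbarcoded, 12 cycles, 210-guide
library — the desk-scale analogue of a genome-scale run, where guides
outnumber cells per guide) for end-to-end genotyping with a
scrambled-dictionary negative control; 330 jittered nuclei for
cross-modality matching; and 200-gene × 100-cell tables for null
calibration plus 20-replicate downsampling at 10/30/100 cells per gene.
These sizes were chosen so the whole suite validates every claim on a
single CPU in minutes.

## Known limitations

* Phasing is simulated as a stress factor but not corrected by the
  caller.
* No indel-tolerant or quality-weighted barcode matching.
* No cell tracking across live-imaging time series; z is averaged.
* The pipeline orchestrator processes one field of view per run; large
  screens are driven by iterating over fields externally.
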