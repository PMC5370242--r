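---
title: "Methods: from LC-MS/MS runs to 3D molecular maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from LC-MS/MS runs to 3D molecular maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`mscarto` turns dissected-organism LC-MS/MS surveys into three linked
products: an aligned MS1 feature matrix, a molecular network of consensus
MS/MS spectra, and per-spot intensity tables rendered on a scanned 3D
surface. This vignette explains the models and procedures behind each
stage, the parameters that matter, the choices made where the design was
genuinely open, and what the synthetic-data tests do and do not establish
about real data.

## The measurement model

Each sample is one LC-MS/MS injection: a sequence of MS1 survey scans (2 Hz
is the simulator's default, matching a modern QTOF) interleaved with
data-dependent MS2 scans of the most intense precursors. A metabolite
appears as a chromatographic peak — approximately Gaussian in time — at its
m/z, accompanied by a +1.003355 Da isotopologue of lower intensity, and (if
selected) by fragment spectra that are reproducible up to small m/z jitter
and intensity noise. Solvent and instrument background ions appear in every
injection including blanks; an internal standard spiked into the injection
solvent appears in every sample at constant abundance. All retention times
are stored in seconds internally; minute-based values in mzML are converted
on read.

## Feature finding

**Centroiding** (`detect_masses`). Points closer than 0.05 Da are treated
as one profile "island"; islands of one or two points pass through as stick
centroids, larger islands are reduced to local maxima with the apex m/z
refined by a quadratic through the apex and its neighbours (valid for
non-uniform m/z grids; the fit is rejected when it curves upward or lands
outside the bracket). Centroids below the signal threshold
(`noise_threshold`, default 2.0e6 counts) are discarded. The threshold is
applied to centroided intensity — for profile data that is the fitted apex,
the closest observable analogue of the peak's true height.

**Ion chromatograms** (`build_eics`, 10 ppm, 0.3 s minimum width). Each
centroid joins the open trace whose running intensity-weighted m/z center
is nearest in ppm (within tolerance); one centroid per trace per scan, and
unmatched centroids open new traces. Traces are not closed on gaps —
segmentation is the deconvolution step's job — and traces spanning less
than 0.3 s are dropped.

**Deconvolution** (`deconvolute`, baseline 1.0e4, maximum width 120 s).
Contiguous above-baseline stretches become candidate peaks, each reported
with apex time, apex height, and the trapezoidal area of the stretch.
Stretches wider than the maximum are split recursively at their deepest
interior valley. Two numerical choices here: the valley must be a genuine
dip (a local minimum strictly below at least one neighbour), and a stretch
with no such dip — a plateau or single flank — is reported whole even when
over-wide. Without the dip requirement a constant plateau would be shaved
one point at a time into hundreds of slivers; with it, splitting terminates
and only real valleys separate peaks. Trapezoidal integration at 2 Hz
sampling recovers the analytic area h·σ·√(2π) of a noiseless Gaussian to
well under 2 % for σ ≥ 1 s, which the test suite asserts.

**Isotope removal** (`remove_isotopes`). For each feature in ascending m/z,
features at +k·1.003355/z Da (k ≤ 3, z ≤ 2) within 10 ppm and 10 s whose
area does not exceed the parent's are removed; the lowest-m/z chain member
survives. Pure spacing only — no averagine-style intensity model — because
abundance ratios vary with elemental composition and the spacing rule alone
is already specific at 10 ppm.

**Alignment** (`align_features`, 10 ppm, 10 s). A greedy join: samples in
lexicographic id order, features within a sample by ascending m/z, each
feature joining the aligned row that minimises
(Δppm/10)² + (Δrt/10)² against the row's running area-weighted consensus
m/z and retention time, or opening a new row. Equal scores break to the
lower row index; when two features of one sample contend for a row, the
better score keeps it and the loser opens a new row. Evaluating tolerances
against the running consensus (rather than the founding feature) is what
makes the result independent of scan order and of the order run files are
supplied in — both properties are tested.

## MS/MS processing and similarity

Fragment spectra are cleaned twice before any scoring: peaks within ±17 Da
of the precursor are removed (residual precursor, its isotopes, and small
neutral losses would otherwise dominate every score), and only the 6 most
intense peaks per 50 Da window are kept. The window slides — it is centered
on each peak in turn — rather than using fixed bins anchored at 0 Da, so a
dense cluster straddling a bin boundary cannot retain 12 peaks. Intensity
ties rank the lower-m/z peak first, making the filter deterministic; both
filters are idempotent.

Similarity is the cosine on square-root-transformed intensities (the
standard variance-stabilising choice in molecular networking; an identity
transform is available). Candidate fragment pairs lie within 0.02 Da
directly, plus — for the *modified* cosine — within 0.02 Da of the
precursor mass difference, which is what lets a network edge connect two
analogs differing by a single modification. The score is defined by the
maximum-weight one-to-one matching over candidate pairs. The matching is
solved *exactly* by branch and bound up to 64 candidate pairs — enough to
cover every pair of 8-peak spectra, the regime in which the test suite
enforces bit-exact agreement with an exhaustive enumeration oracle — and by
descending-weight greedy above that. (Greedy alone differs from the optimum
on crowded spectra; the exact bound was widened from an initial 32 pairs
precisely because 8×8-peak spectra can generate up to 64 candidates.)
Unshifted cosine is used where identical structures are the target
(clustering, library search); the shifted form only for network edges.

## Networking

**Clustering** (`cluster_spectra`). A single greedy pass over spectra
sorted by (precursor m/z, sample id, scan id): each spectrum joins the
first cluster whose consensus precursor is within 0.02 Da and whose
consensus spectrum scores ≥ 0.7 unshifted cosine, else seeds a new cluster.
Consensus peaks are intensity-weighted mean m/z with summed intensities,
merged at 0.02 Da; the consensus precursor weights members by their total
ion current. Clusters with fewer than 2 members are discarded, and each
surviving consensus is re-filtered with the top-6/50 Da rule so its peak
density matches its inputs. The fixed sort order makes clustering a pure
function of the spectrum multiset — the iterative multi-round sweep of
full-scale clustering tools is deliberately simplified to one deterministic
pass, and the tests assert cluster recovery, not tool bit-equality.

**Edges and pruning** (`build_network`). All node pairs are scored with the
modified cosine; an edge needs cosine ≥ 0.7 and ≥ 4 matched peaks. The
matched-peak floor is implemented as *inclusive* ≥ 4, the parameter
convention of the networking services this mirrors; the stricter ≥ 5
reading is one argument away (`min_matched = 5`). Then mutual top-K: an
edge survives only if it ranks in the top 10 by cosine at *both* endpoints
(ties toward the lower partner id). Single-endpoint top-K would keep
asymmetric edge sets; the mutual rule is the documented behaviour of the
reference implementation and is tested against a brute-force oracle.

**Blank subtraction** (`subtract_blanks`). Any node with at least one
member scan from a blank sample is removed, with its incident edges. The
any-membership rule is the conservative reading — a compound seen in a
blank is background wherever else it appears; the alternative
(`mode = "exclusive"`, removing only blank-only nodes) is provided because
either interpretation is defensible when a genuine tissue compound
carries over into blanks.

**Library search** (`library_search`). Candidates within 0.02 Da of
precursor; hits need unshifted cosine ≥ 0.7, ≥ 4 matched peaks, and
|precursor mass error| ≤ 20 ppm relative to the library record; the
best-cosine hit per node is reported.

## Statistics and 3D mapping

The feature matrix is TIC-normalized (each sample column divided by its
sum) and binarized at area > 0 for the binary Jaccard distance
d(i,j) = 1 − |Pᵢ∩Pⱼ|/|Pᵢ∪Pⱼ| (two empty samples are at distance 0; an
optional minimum-area knob exists for noisier data). Normalizing before a
presence/absence metric is a mathematical no-op, and the package keeps both
steps and *tests* the no-op rather than silently dropping one — the
workflow it embodies runs them in that order.

PCoA is classical metric scaling: Gower double-centering of −d²/2,
symmetric eigendecomposition (delegated to `stats::cmdscale`), axes =
eigenvectors × √λ for positive eigenvalues in descending order. Negative
eigenvalues — expected for non-Euclidean Jaccard matrices — are reported
unmodified; no Cailliez/Lingoes correction is applied, and proportions
explained are taken over the positive-eigenvalue sum. Each axis is
sign-fixed so its largest-magnitude coordinate is positive, which makes
outputs identical across eigendecomposition backends. The independent
cross-checks in the tests are `ape::pcoa` and direct reconstruction of
seeded Euclidean configurations.

Venn counts bucket each feature into exactly one region of the k-tissue
partition (a feature belongs to a tissue if present in ≥ 1 of its samples);
regions sum to the union count, and the all-tissue region is also reported
as a percentage. The 'ili table writes one row per non-blank sample —
`name,X,Y,Z,radius` then one column per feature, labeled
`mz_<4 decimals>_rt_<1 decimal>s` — with raw areas by default, since the
viewer applies its own linear color scaling at render time (TIC and
per-feature-max scalings are options). Coordinates are validated against
the mesh bounding box expanded by one spot radius; the coordinates are
assumed to be in mesh model units, since scanned models carry no absolute
unit. Missing intensities are written as 0, not blank, because the viewer
maps numeric columns. The CSV dialect is fixed (comma, "." decimal, LF,
RFC-4180 quoting, full `%.17g` precision) so rewriting the same table is
byte-identical — determinism that the manifest-level tests rely on.

## The synthetic plant

`make_plant(seed)` builds, from one seeded generator (fixed RNG kind, so
results are platform-independent): an ellipsoid-union mesh with labeled
tissue patches (stem, leaf, flower, fruit by default), 6 sampling spots per
tissue on the patch surfaces, 2 blanks, and a 60-metabolite panel
partitioned into an all-tissue core (10 % of the panel, containing the
internal standard at multiplier 1 everywhere), tissue-exclusive sets, and
pairwise-shared sets. Two analog families of three metabolites share one
fragment template with precursors stepped by 14.0157 Da (a CH₂ homolog
series) within a single tissue. Per-metabolite elution width (σ 1–4 s) and
apex height (~10⁶·⁹–10⁸·³ counts) are drawn once at panel construction so
the ground-truth areas h·σ·√(2π) are known exactly; `render_runs` then
only evaluates those Gaussians. Background ions sit at ~3–8×10⁴ counts —
selectable by DDA (so blanks yield MS/MS nodes for subtraction to remove)
but a factor ~30 below the MS1 feature threshold, so the MS1 Venn center
equals the planted core size by construction.

`render_runs` simulates top-5 DDA with dynamic exclusion (excluded after 3
selections, released after 20 s), +1 isotopologues at a mass-proportional
ratio, multiplicative log-normal noise of relative width 1/SNR (default
SNR 100), and 10-minute runs at 2 Hz — the chromatographic regime of a
modern untargeted plant survey. `truth_report` derives the expected feature
matrix, Venn regions, tissue-exclusive sets and family memberships that the
end-to-end tests compare against.

What the simulator deliberately does **not** emulate: retention-time drift
between runs (the aligner uses fixed tolerances, so drift beyond 10 s would
fragment rows), adducts and in-source fragmentation (feature counts on real
data are inflated by both), isotope fine structure, chimeric MS2 from
co-isolation, and intensity-dependent m/z error. Passing the synthetic
end-to-end tests therefore demonstrates that the algorithms are implemented
correctly under their stated assumptions — not that the default tolerances
are optimal for any particular instrument.

## Problem sizes and determinism

The default study processed by the tests and by `scripts/acceptance.R` is
2 plants × 4 tissues × 6 spots plus 4 blanks — 52 runs of ~1200 MS1 scans
each, ~19 000 MS/MS spectra, 119 aligned feature rows — chosen so a full
pipeline pass completes in well under a minute on one CPU while still
exercising cross-plant alignment, blank subtraction and family linking at
realistic density. Unit fixtures are smaller (2 tissues × 2 spots, 10–12
metabolites). Every stochastic element flows through explicit seeds;
rerunning any pipeline on identical inputs reproduces manifest counts and
CSV artifacts byte for byte, and the CLI subcommands call exactly the
stage functions the single-shot `run` uses, so stepwise and single-shot
execution are identical by construction.

## Known limitations

- The greedy join aligner has no retention-time warping; studies with
  drift need upstream correction.
- Consensus clustering is single-pass; extremely heterogeneous clusters
  that would be refined by iterative reclustering stay as split nodes
  (redundant nodes for abundant compounds are normal in practice).
- Cosine matching above 64 candidate pairs is greedy, with exactness
  guaranteed (and tested) only below that bound.
- Mesh handling is deliberately minimal: exact-duplicate vertex merging,
  no repair, no texture — the viewer consumes the mesh as-is.
- PCoA on strongly non-Euclidean distance matrices reports negative
  eigenvalues but does not correct for them; interpret proportions
  explained accordingly.
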