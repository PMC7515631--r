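---
title: "Methods: profiling, enrichment, loop extrusion and contact decay"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: profiling, enrichment, loop extrusion and contact decay}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hetloop)
```

# The scientific question

A megabase-scale block of *S. pombe* DNA inserted into a mouse chromosome
becomes heterochromatinised (H3K9me3, HP1) and, in mitosis, looks thinner
and carries less DNA and histone per unit length than the flanking mouse
chromatin, while condensin levels stay even. The hypothesis this package
operationalises is that increased condensin loading over the
heterochromatic insert yields an array of *smaller* mitotic chromatin
loops: more condensin per bp, less chromatin per axial layer, an earlier
drop in Hi-C contact probability P(s), and a locally narrower chromosome.

`hetloop` implements the quantitative chain behind that argument —
metaphase intensity profiling with rule-based region statistics, ChIP-qPCR
enrichment, a region-dependent loop-extrusion simulator, and P(s) analysis
with drop-off detection — together with seeded generators for every input,
so the full pipeline is testable at desk scale.

# Chromosome intensity profiles

Line scans along a metaphase chromosome are expressed on a relative axis
(0 = centromere end, 1 = telomere end) and binned into `n_bins = 20`
half-open bins `[i/20, (i+1)/20)` (the last bin closed), i.e. 5% bins from
the centromeric 0–5% bin to the telomeric 95–100% bin. The paper behind
this design does not state how bin edges are handled; half-open bins with
the boundary sample `rel_pos = 1` clamped into the last bin is the
convention adopted here.

Images are the independent replicates: the profile mean in a bin is the
mean over images of the per-image bin means, and the SEM is the SD over
images divided by `sqrt(n_images)`. For a single image the SEM is defined
as 0. Pooling raw pixel samples instead would weight images by their
sample counts and understate between-image variability; per-image means
are the default throughout (this also fixes what "n" means in the KS
comparisons below). Profiles can be normalised to the 0–5% centromeric
reference bin (`normalize_to_reference_bin()`), and condensin:chromatin
ratios are per-bin quotients with first-order SEM propagation (relative
errors added in quadrature); bins with non-positive denominators are
flagged undefined rather than erroring, since a dipped DNA channel can
legitimately approach zero in noisy data.

# Region selection and KS comparison

The insert ("signal") region is the contiguous run of 2–5 bins centred on
the FISH maximum whose FISH intensity is at least 70% of that maximum.
Growth is symmetric outward from the argmax, each side stopping
independently at its first failing bin; argmax ties break toward the lower
bin index, and when a single slot remains under the 5-bin cap the
lower-index side wins. A run shorter than 2 bins is returned with an
undersize flag rather than an error.

Control regions have exactly the signal region's size, must not overlap
it, and every member bin must lie within one SD of the profile's overall
mean — which automatically excludes extreme bins such as the brighter
centromere. "Two distant controls" is operationalised as the pair of
admissible windows maximising the minimum pairwise gap among the two
controls and the signal window, found by exhaustive enumeration (at 20
bins this is trivially cheap and deterministic).

Equal-sized regions give equal sample counts for the two-sided two-sample
Kolmogorov–Smirnov test: the samples are the per-image per-bin means
(`n_images x region size` values each; slots undefined in either region
are dropped from both, preserving equal n). The p-value is the asymptotic
Kolmogorov tail at effective size `n_a n_b / (n_a + n_b)`. At the default
study scale (16 images, 3 bins, n = 48 per sample) D is discrete in steps
of 1/48 and the achievable test level just below nominal 0.05 is ~0.033;
the exact two-sample p-value yields the *same* rejection region there, so
the asymptotic form loses nothing. Significance stars are configurable
(`star_label()`), defaulting to `*` < 0.05 and `**` < 0.001, because
published figure legends use inconsistent mappings. No multiple-testing
correction is applied across channels or figures, matching the analyses
the package reproduces.

# ChIP-qPCR enrichment

Enrichment is percent of input under the standard dilution-adjusted
delta-Ct form with amplification efficiency 2 per cycle:

$$\%\,\mathrm{input} = 100 \cdot 2^{(Ct_{\mathrm{input}} - \log_2 d) - Ct_{\mathrm{IP}}},$$

with `d = 20` for a 1:20 input dilution. Values are normalised per
replicate to a positive-control locus (the mouse major satellite, maSat,
in the emulated design) and compared between loci with a two-sided
equal-variance Student's t-test across replicates (three replicates in the
emulated design). No-antibody records are parsed and flagged but excluded
from statistics. No standard-curve efficiency modelling is attempted.

A note on noise: each Ct carries independent measurement error, so a
percent-input value inherits `sqrt(2)` times the per-Ct log2 noise and a
ratio of two independently measured loci inherits twice that. With
0.2-cycle noise and 3 replicates the replicate-averaged *per-locus*
enrichment lands within 25% of truth in ~96% of simulated tables, whereas
any estimator of the *positive-normalised ratio* (mean of ratios, ratio of
means, geometric mean) does so in only ~86–88% — an inherent consequence
of the four independent Cts involved, worth remembering when interpreting
normalised ChIP-qPCR panels. The tests assert the per-locus round trip;
the acceptance script reports both rates.

# The loop-extrusion model

`simulate_extrusion()` is an event-driven stochastic simulation on a 1D
fiber. Condensins load as point loops by a Poisson process with rate
`loading_rate` per bp, multiplied by `het_multiplier` inside
heterochromatin intervals; loading inside an existing loop's anchor span
is forbidden (that chromatin is already extruded; this also enforces the
side-by-side, non-nested loop geometry). Anchors extrude two-sidedly at
`speed` bp per time unit per side; an anchor stalls while touching a
neighbour's anchor or a fiber end and resumes if the blocker unloads;
condensins unload at `off_rate`, releasing their loop. Loading times come
from exact thinning of a homogeneous proposal process and anchor motion is
continuous between events, so stall detection has no time-step artefacts.
Numerically, anchor contacts are snapped to the exact midpoint within
10^-3 bp to keep floating-point drift out of the disjointness invariant.

With unloading disabled and fixed load positions the final state has a
closed form — neighbouring anchors meet at the midpoints between load
positions and the outer anchors reach the fiber ends
(`collision_geometry_loops()`), which the tests use as an independent
oracle for the simulator.

Quantitative rates are not given by the source analyses (the model figure
is qualitative), so defaults are the package's own: speed 1000 bp/time,
off-rate 0, duration 1000 (long enough for full tiling). For loading rate
$\lambda$ and per-side speed $v$ the collision spacing scales as
$\sqrt{2v/\lambda}$; the scaling argument suggested $\lambda =$ 2e-7 for a
100 kb loop, a 12-seed calibration showed the true prefactor gives 79 kb,
and the default was set once to 1.25e-7, yielding a ~100 kb (observed
~95–110 kb) euchromatic mean loop — inside the 80–120 kb range reported
for mitotic loops. Doubling the loading rate shrinks loops by
$\sqrt{2}$, so a het multiplier of m yields het loops smaller by
$\approx \sqrt{m}$ with a matching increase in condensin per bp; at m = 1
het and eu regions are statistically indistinguishable by construction.
One condensin species is modelled: the analyses found the condensin I:II
ratio unchanged over the insert, and increased *loading* is the proposed
mechanism — altered residence (`off_rate`) and speed are exposed as
parameters but deliberately untuned alternatives.

`loop_statistics()` assigns each loop to the region containing its
midpoint and reports loop counts, mean sizes, condensin per bp and bp per
scaffold unit; in quiescent tiled states condensin density times mean loop
size is ~1 per region.

# Contact sampling and P(s)

The layer model maps position x to an axial coordinate a(x) = (index of
its containing loop) / `loops_per_layer`; loci in inter-loop gaps take the
nearest loop's index. Contact weight is
`exp(-|a(x) - a(y)| / layer_decay_scale) + intra_loop_weight` (the bonus
applying to same-loop pairs), sampled exactly by rejection against the
maximal weight. Contacts within one layer are thus very likely and
contacts across layers strongly suppressed — the verbal model the analyses
rest on. Defaults: 3 loops per layer, intra-loop weight 1, and
`layer_decay_scale = 2/3` layers, chosen analytically so that for uniform
loop size L the log-log slope of P(s) crosses -1.5 at
`s = 1.5 * (2/3) * k * L = k * L` — the drop-off detector then reads out
the chromatin-per-layer scale directly.

`ps_curve()` uses cis contacts only, log-spaced bins (8 per decade by
default; the binning is the package's choice), and divides each bin's
count by the number of available intra-contig locus pairs at that
separation, `sum over contigs of the integral of max(L - s, 0)` — the
explicit form of the contig-length bias correction that Hi-C toolchains
apply implicitly. Curves are normalised to unit sum over reported bins.
With `truncation = "n50"` no bin extending beyond the contig set's N50 is
reported: beyond that separation too few contigs contribute and the curve
becomes erratic, which is exactly why the original *S. pombe* curve was
truncated at its 500 kb assembly N50. The synthetic contig generator's
defaults (12.5 Mb in 42 Dirichlet(1) fragments) were calibrated once so
the median N50 is near 500 kb.

`dropoff_distance()` lightly smooths log10 P (3-bin running mean), takes
the discrete log-log derivative between consecutive bins, and returns the
geometric-mean separation of the first bin pair below a slope threshold of
-1.5 (mitotic P(s) plateaus near slope 0 before the drop, so -1.5 cleanly
separates plateau from collapse). The source analyses identify the drop
visually; a slope threshold is the package's operationalisation, and the
threshold is exposed. Detection lands systematically ~5–25% above k·L
(bin discreteness plus smoothing), within the 30% recovery band the tests
assert.

# What the generators emulate — and what they do not

* **Profiles** (`simulate_trace_set()`): piecewise-constant ground truth —
  DNA/IF baseline 100 a.u., a 30% dip over the insert at relative
  positions 0.65–0.80 (bins 13–15, the geometry of the emulated insert
  chromosome), a 2x brighter centromeric first 5%, FISH at 100 a.u. over
  the insert with a 2% positive background elsewhere (so a maximum always
  exists), i.i.d. Gaussian noise (sd 5 a.u.) clipped at zero, 16 images of
  200 samples. Real line scans have correlated noise along the scan,
  image-to-image length and orientation variation, and diffraction blur at
  region edges; none of that is modelled, so passing tests demonstrate the
  *statistical machinery*, not robustness to imaging artefacts. The
  magnitude of inter-image variability is not stated in the source
  analyses, so the noise amplitude is a configurable parameter rather than
  a fixed truth.
* **ChIP tables** (`simulate_chip_table()`): Cts constructed so the
  noiseless percent-input equals the planted pulldown exactly, input Cts
  near 25 cycles, 1:20 input dilution, independent Gaussian cycle noise on
  both Cts. Primer efficiency differences and plate effects are not
  modelled.
* **Contigs** (`fragment_genome()`): a symmetric Dirichlet(1) split of the
  total length, giving the heavy contig-size variation of a long-read
  de novo assembly; no repeat structure or misassembly.

# Problem sizes and numerical choices

The test and acceptance workloads use 3–6 Mb fibers with 1–2 Mb het
intervals (tens of loops per region), 6e4–2e5 contacts per curve, and
200–6000 simulated profile datasets per statistical check — sizes chosen
so every distributional claim is resolved with comfortable Monte Carlo
error while the whole suite stays desk-scale. Notable numerical choices:
bin means of empty bins are NA and propagate symmetrically into region
comparisons; anchor contacts snap to midpoints at 10^-3 bp; the KS
implementation delegates to `stats::ks.test` (the brute-force ECDF oracle
lives in the tests, independently); t-tests on zero-variance noiseless
data return t = 0, p = 1 when means agree and p = 0 otherwise rather than
erroring.

# Known limitations

* The simulator is 1D: no polymer physics, no chromosome width, no
  cohesin/CTCF interplay, no condensin I vs II distinction.
* The layer model's contact weight is phenomenological; its parameters
  (loops per layer, decay scale) are not inferred from data, so P(s)
  results are qualitative reproductions, not fits.
* Drop-off detection needs a well-sampled curve; with few loops per
  region (short regions) the detected distance is noisy and biased
  upward.
* The KS test level at study scale is bounded by the discreteness of D
  (achievable level ~0.033 at n = 48), a property of the test, not of the
  implementation.
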