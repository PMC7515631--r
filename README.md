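# hetloop

Quantitative analyses of how a large heterochromatin domain embedded in a
mammalian chromosome changes mitotic chromosome organisation. The package
is built around the hypothesis that heterochromatin recruits extra
condensin loading, which partitions the fiber into **smaller mitotic
chromatin loops**: more condensin per bp, less chromatin per axial layer,
an earlier drop-off in Hi-C contact probability P(s), and a locally
thinner chromosome.

It is aimed at chromosome biologists who want to run (or stress-test) the
full quantitative chain behind that argument on their own line scans,
ChIP-qPCR tables and contact lists — or entirely on the built-in synthetic
data generators, which emulate every input the pipeline consumes.

## What it computes

* **Metaphase intensity profiles** — line scans binned into twenty 5%
  bins from centromere to telomere, averaged over images with SEM,
  normalised to the centromeric 0–5% bin, and condensin:chromatin ratio
  profiles with error propagation.
* **Region statistics** — the insert region as the 2–5 contiguous bins at
  ≥ 70% of the FISH maximum; size-matched control regions within 1 SD of
  the profile mean, placed as far apart as possible; two-sample
  Kolmogorov–Smirnov comparison on equal numbers of per-image
  measurements, D = sup |ECDF₁ − ECDF₂|, asymptotic p at effective
  n = n₁n₂/(n₁+n₂).
* **ChIP-qPCR enrichment** — percent input
  `100·2^((Ct_input − log2 d) − Ct_IP)` with a 1:20 input dilution,
  per-replicate normalisation to a positive-control locus, and Student's
  t-tests between loci.
* **Loop extrusion** — an event-driven simulator: condensins load at a
  rate multiplied over heterochromatin, extrude two-sidedly until blocked
  by neighbours or fiber ends, optionally unload; per-region loop-size and
  condensin-density statistics.
* **Contact decay** — a layer model turning loop arrays into contact
  lists; P(s) on log-spaced bins with explicit pair-availability
  normalisation `Σ_contigs max(L − s, 0)`, truncation at the assembly N50,
  and drop-off detection via a −1.5 log-log slope threshold.

## Worked example

Synthetic profiles with the default insert geometry (a 30% DNA dip over
relative positions 0.65–0.80, FISH marking the insert), then the region
rules and KS test:

```r
library(hetloop)

ts    <- simulate_trace_set(profile_sim_config(seed = 7))
fish  <- channel_profile(ts, "FISH")
dna_b <- bin_traces(ts, "DNA")

sig   <- select_signal_region(fish)
ctrls <- select_control_regions(average_binned(dna_b), sig)
sig
#> <region> signal: bins 13-15 (3 bins)
ctrls[[1]]
#> <region> control1: bins 1-3 (3 bins)
region_ks_test(dna_b, sig, ctrls[[1]])
#> <ks_result> D = 1.0000, p = 0 (n = 48 vs 48) **
```

The FISH rule recovers exactly the planted insert bins (13–15, i.e.
65–80%), the controls sit on unremarkable mouse-like bins, and the DNA
dip is so clear at this noise level that the two samples of 48 per-image
bin means separate completely (D = 1).

Loop extrusion with 3-fold condensin loading over a 2 Mb het interval in a
6 Mb fiber, and the P(s) drop-off for each region:

```r
fib <- fiber_spec(6e6, het_intervals = list(c(2e6, 4e6)),
                  het_multiplier = 3, seed = 7)
arr <- simulate_extrusion(fib)
pool_loop_stats(loop_statistics(arr, fib))
#>   label length n_condensins mean_loop_size condensin_per_bp bp_per_scaffold_unit
#> 1    eu  4e+06           47       86148.94        1.175e-05             85106.38
#> 2   het  2e+06           34       57382.35        1.700e-05             58823.53

cl  <- sample_contacts(arr, contact_model(n_contacts = 2e5, seed = 8))
dropoff_distance(ps_curve(subset_contacts(cl, 2e6, 4e6, "het"),
                          contig_set(c(het = 2e6)))) / 1e3
#> [1] 177.1
dropoff_distance(ps_curve(subset_contacts(cl, 0, 2e6, "eu"),
                          contig_set(c(eu = 2e6)))) / 1e3
#> [1] 236.3
```

Het loops are ~√3-fold smaller than euchromatic ones (57 vs 86 kb here),
condensin density is correspondingly higher, and the het P(s) curve drops
off earlier (177 vs 236 kb) — less chromatin per layer over the
heterochromatic region.

`run_pipeline(pipeline_config(seed = 1))` chains all stages (profiles →
regions → KS → ChIP → extrusion → contacts → P(s) → drop-off), writes
every intermediate as TSV/BED/bedGraph/pairs text, and emits a
`report.json` with seeds and parameters; identical configurations
reproduce identical outputs.

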