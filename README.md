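# rhmapper

Radiation hybrid (RH) mapping toolkit for single-chromosome deletion
panels, built around the wheat chromosome 3B panel design: 92 lines
derived by 350 Gy gamma irradiation, scored for ~540 markers as retained
(1) / deleted (0) / missing.

RH mapping orders loci without meiosis: radiation-induced deletions remove
contiguous chromatin, so nearby loci are co-retained or co-deleted, and
one centiRay (cR) is one state difference between two adjacent loci per
100 lines screened.  The package covers the full analysis cycle:

* **Two-point statistics** — cR distances, breakage-probability estimates
  and linkage LODs under the haploid retention model
  (`two_point()`, `two_point_all()`).
* **Framework map construction** — co-segregation collapsing, iterative
  LOD-gated insertion (schedule 10, 8, 6, 3) with 2-opt/relocation/ripple
  polishing, per-arm linkage groups, anchor-based orientation and
  deletion-bin assignment (`build_framework_map()`, `assign_bins()`).
* **Deletion analysis** — per-line deletion calls as maximal deleted runs,
  midpoint-convention sizing in cR and Mb, per-bin summaries
  (`call_deletions()`, `cr_to_mb()`, `summarize_deletions()`).
* **Per-bin map statistics** — saturation, resolution (Mb cR⁻¹,
  Mb cM⁻¹), break/repair frequency BR = (cR/2)/Mb, crossing-over
  frequency CO = cM/Mb, uniformity folds, contig orientability
  (`compute_bin_metrics()`, `uniformity_fold()`, `contig_metrics()`).
* **Correlation layer** — Pearson r with two-tailed t tests at N−2 df
  over the BR/CO/deletion/centromere-distance panel
  (`pearson_cor()`, `correlation_suite()`).
* **Panel simulator** — a chromatin-openness-driven generative model
  (deletion count ~ openness, deletion size ~ 1/openness, shared openness
  driving both BR and CO) with a calibrated wheat-3B preset
  (`simulate_panel()`, `wheat3b_preset()`).
* **Reference tables** — the published per-bin and per-contig summaries
  for wheat 3B ship with the package (`load_wheat3b_tables()`,
  `wheat3b_reference_analysis()`).

## Worked example

```r
library(rhmapper)

# derived statistics of the published wheat 3B tables
ref <- wheat3b_reference_analysis()
round(ref$chromosome$resolution_rh, 2)
#> [1] 0.53                       # Mb per cR, chromosome average
round(ref$uniformity$rh_fold, 1); round(ref$uniformity$gen_fold, 1)
#> [1] 5.3                        # RH resolution spread across bins
#> [1] 30.2                       # genetic-map spread: ~6x less uniform
subset(ref$correlations, pair == "br_vs_co")[, c("r", "n", "p")]
#>           r  n            p
#> 1 0.8793295 10 0.0007999557  # the BR-CO interaction, 3BS2 excluded

# a simulated panel at the study conditions, mapped end to end
sim <- simulate_panel(wheat3b_preset(seed = 1))
map <- build_framework_map(sim$genotypes, sim$marker_info, bins = sim$bins)
map <- assign_bins(map, sim$marker_info)
map
#> RH map: 447 loci (4 framework), 540 markers, 369.0 cR

cls <- classify_lines(sim$genotypes,
                      sim$truth$markers$arm[match(colnames(sim$genotypes),
                                                  sim$truth$markers$marker_id)])
table(cls)
#> cls
#>         INTACT     WHOLE_LOSS SUPRA_ARM_LOSS    INFORMATIVE
#>             17             11              4             60
```

`run_pipeline()` chains simulate → map → deletions → metrics →
correlations into one seeded, byte-reproducible run that writes TSVs and
a Markdown report; `inst/cli/rhmap.R` exposes the same steps as a small
command-line script.

The deletion-size conversion behind the published worked examples:

```r
cr_to_mb(120.2, 1.2)   # largest deletion: 144.24 Mb
cr_to_mb(13.1, 0.1)    # smallest deletion: 1.31 Mb
```

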