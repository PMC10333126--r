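# gamkit

Analysis toolkit for **Genome Architecture Mapping (GAM)**, a ligation-free
method for mapping 3D chromatin contacts. GAM sequences the DNA content of
thin nuclear cryosections ("nuclear profiles", NPs, ~220 nm): loci that are
close in nuclear space land in the same slice more often than distant loci,
so contacts are read out from co-segregation across many slices instead of
from proximity ligation. In multiplex-GAM several NPs are pooled into one
sequencing tube, cutting cost and hands-on time; the statistics must then
account for the pooling.

`gamkit` is written for computational biologists who work with GAM
segregation tables and want to (i) infer chromatin interaction
probabilities with the SLICE statistical model, (ii) design GAM experiments
(how many tubes, how many NPs per tube), (iii) compare GAM and Hi-C contact
maps, and (iv) study multiway (triplet) contacts and contact complexity,
which ligation-based methods systematically under-sample.

## The model in brief

A segregation table is a boolean windows x samples matrix. For a locus pair
the SLICE model works with per-NP capture probabilities

- `v` — single-locus capture; for a spherical nucleus of radius `R` sliced
  by slabs of thickness `h`, `v = h / (2R + h)` (ellipsoidal nuclei are
  handled numerically; finite locus size adds to `h`),
- `t` — co-capture of two loci held within the slice thickness
  (interacting), `t(delta) = (h - delta/2) / (2R + h)`,
- `u` — co-capture of non-interacting loci, estimated per genomic distance
  from the data,

and mixes them through the interaction probability `Pi`:
`N2 = Pi t + (1 - Pi) u`. A tube pooling `X_NP` profiles (real-valued under
the mean-field treatment of merged datasets) detects neither, one, or both
loci with probabilities

```
M0 = (1 - 2v + N2)^X,  M1 = 2[(1 - v)^X - M0],  M2 = 1 - 2(1 - v)^X + M0 .
```

`Pi` is estimated by inverting the co-segregation ratio `M2 / (M1 + M2)`
(the fraction of non-empty tubes containing both loci) at its observed
value; significance comes from the exact conditional null distribution of
that ratio at `Pi = 0`, with Benjamini-Hochberg FDR control across pairs
(threshold 0.1). The same machinery extends to triplets (`Pi_ABC` via the
eight tube detection states) and to experimental design: `m*`, the minimum
number of tubes detecting a target `Pi` with given power. A nuclear-slicing
simulator (confined random-flight chains, slab cuts, ligation-competition
Hi-C) backs every statistical claim with a geometric oracle.

## Worked example

Simulate 600 nuclei with one planted contact (windows 3 and 9 co-located in
80% of cells), slice them into 200 three-NP tubes, and run SLICE:

```r
library(gamkit)
geom <- nuclear_geometry(radius = 4.5, h = 0.22)   # mESC geometry, um
cfg <- sim_config(n_cells = 600, n_windows = 12, x_np = 3, step = 0.3,
                  geometry = geom,
                  interactions = tibble::tibble(windows = list(c(3L, 9L)),
                                                pi = 0.8, contact_distance = 0.1))
cells <- simulate_configurations(cfg, seed = 1)
tubes <- slice_configurations(cells, cfg, seed = 2)
fit <- slice_pairs(tubes, geom, max_distance = 12 * 40000, min_pairs = 5)
dplyr::arrange(tidy(fit), p_value)
#> # A tibble: 66 x 9
#>   chrom  bin_a  bin_b distance pi_hat coseg_ratio_obs     p_value    q_value
#> 1 chr1   80000 320000   240000  1               0.636 0.000000145 0.00000814
#> 2 chr1  280000 400000   120000  0.457           0.333 0.0292      0.559
#> ...
glance(fit)
#>   n_pairs n_significant  x_np      v      t detection_efficiency fdr_threshold
#> 1      66             1     3 0.0239 0.0179                    1           0.1
```

The planted pair (bins 80000 and 320000, i.e. windows 3 and 9) is recovered
with `pi_hat = 1`, a p-value of 1.5e-7 and is the only FDR-significant
contact; `v = 0.0239` is the analytic capture probability 0.22/9.22.

Experimental design — how many three-NP tubes to detect `Pi >= 0.5`
contacts at level 0.05 with 80% power:

```r
design_m_star(pi_target = 0.5, geometry = geom, x_np = 3)
#>   m_star power_at_m_star      v        u      t
#> 1    105           0.816 0.0239 0.000569 0.0179
```

105 tubes (315 cells) suffice.

Other entry points: `insilico_multiplex()` (pool single-NP columns),
`linkage_matrix()` (D' contact matrices), `zscore_by_distance()` /
`delta_and_tails()` / `strong_and_common()` (GAM vs Hi-C differential
contacts), `annotate_contacts()` / `rank_pairs_random_forest()` (feature
pair enrichment), `slice_triplets()` / `complexity_profile()` (multiway
contacts), `insulation_profile()` / `call_boundaries()` (TAD calling on
matrices with negative entries), and the simulators under `simulate_*()`.
A thin command-line wrapper lives at `inst/cli/gamkit.R`.

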