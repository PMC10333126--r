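---
title: "Statistical methods behind gamkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical methods behind gamkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gamkit)
```

# The measurement model

Genome Architecture Mapping reads chromatin contacts from co-segregation of
genomic windows in thin nuclear cryosections. `gamkit` models one slice
("nuclear profile", NP) as a slab of thickness `h` cutting a nucleus of
mean radius `R` at an isotropic orientation, with its offset uniform over
the nuclear extent plus `h` along the slicing axis. Under this geometry a
point locus is captured with probability

$$v = \frac{h + d}{2R + h},$$

where `d` is an optional effective locus size. For an ellipsoidal nucleus
(ellipticity $\varepsilon$ = polar over equatorial semi-axis, volume held
fixed so the equatorial semi-axis is $R\,\varepsilon^{-1/3}$) the extent
depends on the slab orientation and the capture probability is averaged
numerically over orientations; at $\varepsilon = 1$ the closed form is
recovered to the integration tolerance (1e-9). Two loci held within
distance $\delta < h$ of one another are captured together with probability

$$t(\delta) = \mathbb{E}\big[(h - \delta\,|\cos\theta|)_+\big]/(2R+h)
            = \frac{h - \delta/2}{2R+h},$$

with $|\cos\theta|$ uniform on $[0,1]$ for isotropic slicing, so
$t(0) = v$ and $t(h^-) = v/2$. The default interacting separation is
$\delta = h/2$, the midpoint of the "within one slice thickness" regime;
it is a tunable argument everywhere it enters.

The defaults ($R = 4.5\,\mu m$, $h = 0.22\,\mu m$, $\varepsilon = 1$,
$d = 0$) are the mouse-embryonic-stem-cell conditions used throughout the
package's tests, giving $v = 0.22/9.22 \approx 0.0239$.

# The SLICE pair model

For a window pair at genomic distance $d_g$, the per-NP both-captured
probability mixes the interacting and background co-capture through the
interaction probability $Pi$:

$$N_2 = Pi \cdot t + (1 - Pi)\, u(d_g).$$

A tube pools $X_{NP}$ profiles. Because profiles are independent, the tube
misses a locus with probability $(1-v)^{X}$ and misses both with
$(1 - 2v + N_2)^{X}$; inclusion–exclusion gives the tube state
probabilities $M_0, M_1, M_2$ (neither / exactly one / both detected).
$X$ may be any positive real: merged datasets with different multiplexing
levels are handled by a mean-field exponent equal to the tube-weighted
average of the batch levels (`effective_nps()`), e.g. 481 one-NP plus 249
three-NP tubes give $X = 1228/730 \approx 1.68$. A detection efficiency
thins each captured locus independently ($v \to v\,\eta$,
$N_2 \to N_2\,\eta^2$) before the exponentiation; by default
`slice_pairs()` calibrates $\eta$ so the model's marginal detection rate
matches the table's mean window detection frequency.

**Which ratio is fitted.** The quantity inverted to estimate $Pi$ is the
fraction of non-empty tubes that contain *both* loci,
$r = M_2/(M_1+M_2)$. The complementary form $M_1/(M_1+M_2)$ also
circulates in the literature; only the $M_2$ numerator is monotone
*increasing* in $Pi$, which inversion requires, so it is the default and
the other form is available via `cosegregation_ratio(numerator =
"one_locus")`. Estimation clamps at the boundaries: observed ratios below
$r(Pi\!=\!0)$ return 0 (flag `floor`), above $r(Pi\!=\!1)$ return 1
(`ceiling`).

**Background estimation.** $u(d_g)$ is estimated from the segregation
table itself: the tube-level co-detection fraction of all pairs at
distance $d_g$ is summarised by its median — robust against the
interacting minority, which would inflate a mean — and inverted through
the tube model to the per-NP scale, clipped to $[0, v]$. A configurable
floor (default 30 pairs per distance in `background_coseg_from_table()`,
10 in the `slice_pairs()` driver, whose test tables are small) guards
against noisy strata.

# Exact null test and experimental design

Under the null ($Pi = 0$) the $m$ tubes are i.i.d. trinomial
$(M_0, M_1, M_2)$. Conditioning on the number of non-empty tubes
$n = K_1 + K_2 \sim \mathrm{Binom}(m, M_1 + M_2)$ makes
$K_2 \mid n \sim \mathrm{Binom}(n, M_2/(M_1+M_2))$, so the tail
probability of the ratio $R = K_2/n$ is an $O(m)$ sum of binomial tails —
a full exact enumeration of the trinomial without visiting $O(m^2)$
states. This exact path is used up to $m = 50{,}000$ tubes; beyond that a
seeded Monte-Carlo fallback (1e5 draws) takes over. For the discrete null,
"the observed ratio exceeds the null 95th percentile" is exactly the event
$P(R \ge r_{obs}) \le 0.05$, which is how significance is implemented.
Calibration is verified in the tests: the empirical type-I error over
2,000 null simulations at $m = 1000$ sits inside $[0.035, 0.065]$ at
$\alpha = 0.05$. Genome-wide discovery applies Benjamini–Hochberg with a
flag threshold of 0.1.

`design_m_star()` inverts the same machinery: for a candidate $m$, the
rejection region reduces to a single critical ratio (the null tail is
monotone in the threshold), found once by bisection; power is then the
alternative-trinomial mass beyond the per-$n$ critical counts, and the
minimal $m$ reaching the target power (default 0.8 — a conventional
choice; the power level is a free parameter) is found by doubling plus
bisection, exploiting monotonicity of power in $m$. When no segregation
table accompanies a design query, the background defaults to the
independent-locus floor $u = v^2$, appropriate for well-separated loci
(beyond ~100 kb) where linkage has decayed; a data-derived $u$ can be
passed explicitly. With the mESC defaults, $Pi = 0.5$, three NPs per tube,
$\alpha = 0.05$ and power 0.8, the calculator returns $m^* = 105$ tubes.

# Triplets

The triplet model tracks eight tube detection states. Per NP,
inclusion–exclusion over the subsets of $\{A, B, C\}$ uses the three
marginals $v$, the three pairwise $N_2^{(ij)}$ (taken from the pairwise
fits) and the all-three probability
$N_3 = Pi_{ABC}\, t_3 + (1 - Pi_{ABC})\, u_3$; raising the per-NP "miss
set $W$" probabilities to the $X$ exponent and Möbius-inverting yields the
tube states. $t_3$ treats three mutually co-located loci as sharing the
pairwise slab overlap ($t_3 = t(\delta)$); $u_3$ is the distance-matched
empirical triple background (median across triples in the same span
stratum, inverted to the per-NP scale). Since all-three capture implies
each pairwise capture, $N_3 \le \min_{ij} N_2^{(ij)}$; $Pi_{ABC}$ is
therefore identifiable only up to the $Pi$ at which $N_3$ reaches that
bound, and fits are clamped (and flagged) there. The fitted statistic is
the fraction of tubes detecting any of the three that detect all three;
its null distribution factorizes exactly as in the pair case.
Significance of a triplet is a p-value below 0.05 — the natural reading
of selecting "significant" triplets for complexity analysis; filtering on
small $Pi_{ABC}$ itself is also exposed, since both selectors are defensible
readings and downstream complexity counts accept either.

# GAM vs Hi-C comparison

Paired matrices are joined on (chromosome, bin pair) and masked jointly:
contacts beyond 4 Mb, with negative D', with zero Hi-C ligation counts,
or touching windows whose detection frequency lies outside [5%, 10%]
(over- or under-sampled) are removed from both sides. Within each
(chromosome, distance) band, values are z-scored with the sample (n−1)
standard deviation; observed-over-expected and dense-rank transforms are
provided as alternatives. The delta (GAM z minus Hi-C z) distribution is
fitted per chromosome by maximum likelihood — normal for z-score deltas
(closed form), logistic for observed-over-expected deltas
(`fitdistrplus`) — and the 5% (or 10%) fitted tails define GAM-specific
and Hi-C-specific contacts. Per-chromosome fitting follows the
per-chromosome processing of the rest of the pipeline; genome-wide
pooling is an option. Strong-and-common contacts are the top 5–10% per
chromosome, among $|\Delta| < 1$ candidates, ranked by the *weaker* of
the two z-scores; $|\Delta|$ rather than signed $\Delta$ keeps the set
symmetric between methods. Ties at any selection cutoff break by
(bin_a, bin_b) order, so results are bit-reproducible. Window preference
labels use the per-chromosome 90th percentile (linear-interpolation
quantiles, R type 7) of the absolute anchor-count difference; common
regions are a rank selection (top 10% of windows by strong-and-common
anchor count), and a window may carry both a preference and a common
label, reported in separate columns.

# Feature enrichment

Window-feature tables mark presence by any-overlap (≥ 1 bp; a mean-count
mode is kept for boundary profiles). With $n$ features there are
$n(n+1)/2$ unordered pairs (105 for 14); a contact carries pair $(i,j)$
if one anchor is positive for $i$ and the other for $j$ in either
orientation. Backgrounds resample, per permutation and per (chromosome,
distance) stratum, the foreground's count of contacts from the
complement; shortfalls take all available and are logged. The
discriminative ranking trains a random forest (`randomForest`; 500 trees,
`mtry = floor(sqrt(p))`, Gini criterion, no depth cap — mirroring common
practice) to separate GAM-specific from Hi-C-specific contacts on
pair-presence vectors, averaging the mean decrease in Gini impurity over
five cross-validation folds; averaging over folds, rather than one full
fit, was chosen so the importances come from models whose accuracy is
simultaneously measured. The top-10 selection first applies an abundance
floor — pairs rarer than the median pair abundance are omitted, a
configurable reading of "omit low-abundance pairs" since no explicit cut
is standard — and the top 3 pairs by Hi-C-over-GAM amplification are
appended. Class-combination enrichment compares observed combination
counts with label permutations within chromosomes, flagging combinations
outside the central 95% after Bonferroni widening across combinations.

# Complexity, transitivity and 3D-model triplets

Complexity counts significant triplets per window, per pair (number of
third windows completing a triplet), or per region (mean over member
windows). Hi-C transitivity triplets score $\min$ of the three pairwise
ligation values; 3D-model triplets score $\min$ over models of the
$\max$ pairwise distance, skipping models with missing bins. Both are
selected per span stratum — the triplet "distance" is taken as the span
$C - A$, a single scalar (the alternative $(d_{AB}, d_{BC})$
stratification sits behind a flag) — keeping the strongest (or tightest)
2% of strata holding at least 500 candidates, with canonical-order tie
breaks. The ligation-competition simulator shows the mechanism these
comparisons probe: when each window can ligate at most $k$ partners and a
ligation requires mutual selection, hub pairs are diluted roughly as
$1/\mathrm{degree}$ while isolated pairs are counted in every cell; with
unlimited $k$ the counts equal brute-force proximity counts exactly.

# TAD calling on matrices with negative entries

The insulation score of bin $i$ is the mean of the square spanning the
$s$ bins left of $i$ against the $s$ bins right of it (default square
400 kb). Normalization is `log2(score / chromosome mean)` for strictly
positive matrices and `score − chromosome mean` whenever negative values
occur — the adjustment that makes the method applicable to D' matrices,
where the log is undefined; the subtractive path makes boundary calls
invariant to adding a constant to the matrix, which the tests assert.
Boundaries sit at positive-to-negative zero crossings of the insulation
delta (one-sided means over a 200 kb span), are suppressed when the local
delta amplitude falls below the noise threshold 0.1, and are reported as
ranges of ±3 bins (the boundary margin of error) with the delta amplitude
as strength. The historical parameters `ids` and `yb` of the original
insulation implementation are accepted for interface compatibility but
inert, since their semantics are not specified by the sources this
implementation follows; only square size, delta span, noise threshold and
margin affect calls. Merging coalesces touching or overlapping ranges
keeping the maximum strength; matching pairs ranges within 1 bp,
bidirectionally. Boundary-centred feature profiles average a signal track
in 10-kb offset bins over a ±500 kb flank, with backgrounds from
chromosome-wise circular shifts (one random offset per chromosome per
shift), which preserve boundary counts and spacing.

# The simulator and what it does (and does not) emulate

`simulate_configurations()` grows a confined random-flight chain per cell
(fixed step, out-of-volume proposals resampled — resampling rather than
reflection keeps the step distribution isotropic), then co-locates
designated window tuples with the planted probability.
`slice_configurations()` cuts each cell with one isotropic slab, pools an
integer number of cells per tube (cells drawn without replacement, one
per NP), and thins detections. `simulate_state_level()` samples the
analytic trinomial directly and is the fast oracle used for calibration
and recovery tests; the geometric and state-level routes agree within
Monte-Carlo error, and end-to-end recovery of planted $Pi$ at $m = 5000$
tubes is within ±0.05.

What the simulator does **not** emulate: polymer physics (no
loop-extrusion or SBS energetics), sequence- or restriction-site-level
Hi-C artefacts, fixation and cryosectioning distortions, chromosome
territories, or between-cell variability in nuclear size. Passing tests
therefore demonstrate correctness of the inference machinery under the
model's own generative assumptions, not robustness to every property of
real data.

# Numerical choices and problem sizes

- Root finding (`uniroot`) with tolerance 1e-10 on the monotone ratio;
  noiseless round trips recover $Pi$ to better than 1e-6.
- Exact null path up to $m = 50{,}000$; seeded Monte-Carlo beyond.
- Quantiles are linear-interpolation (R type 7) throughout.
- Degenerate inputs yield missing values, not errors, wherever the
  quantity is undefined for a single pair (windows detected never or
  always, zero-variance z-score bands, empty complexity strata); genuine
  contract violations (non-binary tables, mismatched resolutions) abort.
- The finite-sample D' estimator is skewed away from detection frequency
  0.5 (its positive- and negative-D normalizers differ), so the
  independence property test pins coverage at 0.5; analyses of real
  tables should expect slightly negative mean D' at low coverage.
- Test problem sizes were chosen to exercise each property at
  comfortable statistical resolution on a laptop-class machine: tables of
  tens of windows by hundreds to thousands of samples, 1e6 draws for the
  geometric oracle, 2,000 null simulations for type-I calibration,
  $m = 5000$ tubes for recovery checks.

# Known limitations

- Inter-chromosomal SLICE inference is out of scope (the weakest contacts
  need more NPs than typical datasets provide).
- The ellipsoid capture average treats the slab-orientation and
  separation-projection angles as independent; for strongly flattened
  nuclei a coupled treatment could shift $t$ slightly.
- The triplet background $u_3$ is stratified by span only; triples with
  the same span but very different internal geometry share a background.
- `slice_triplets()` enumerates all triples and is intended for coarse
  (1 Mb) windows or small regions.
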