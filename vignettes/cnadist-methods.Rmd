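---
title: "Methods: copy-number profile distances, CNH, and the clonal-seeding simulator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: copy-number profile distances, CNH, and the clonal-seeding simulator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnadist)
```

# The problem

When a colorectal cancer and its metastases are profiled by shallow
whole-genome sequencing or SNP arrays, each lesion yields a segmented log2
copy-number profile. Two questions recur in studies of metastatic routes:

1. **How heterogeneous is one lesion?** A clonal tumor, corrected at its
   true purity and ploidy, has integer copy numbers; subclonal admixture
   pushes corrected segments off the integers.
2. **How far apart are two lesions?** If a metastasis is founded by many
   subclones of the primary (polyclonal seeding), its profile stays close
   to the primary's; if a single subclone seeds it (monoclonal seeding,
   with stringent clonal selection), the profiles diverge.

Both questions are confounded by nuisance parameters — tumor purity
$\alpha$ (fraction of tumor cells; contaminating normal cells are assumed
diploid) and mean tumor ploidy $\tau$ — that differ arbitrarily between
samples. `cnadist` removes them by exhaustive minimization over an explicit
purity $\times$ ploidy grid, the same tactic used by absolute copy-number
callers such as ASCAT and ABSOLUTE, but applied directly to the statistic
of interest.

# Model

## From log2 ratios to absolute copy number

A segment's observed relative copy number is $r = 2^{\log R}$. Under the
two-component mixture (tumor at purity $\alpha$ and ploidy $\tau$, diploid
normal), the absolute tumor copy number of the segment is the affine
inversion

$$q \;=\; \frac{r\,\bigl(\alpha\tau + 2(1-\alpha)\bigr) - 2(1-\alpha)}{\alpha}.$$

Properties the code and tests rely on: the transform is strictly increasing
in $r$; $r = 1$ maps to $q = \tau$ for every $\alpha$; and it is affine,
$q = A r + B$ with $A = \tau + b$, $B = -b$, $b = 2/\alpha - 2$, which is
what makes grid scans cheap (see *Numerical design*). Values are **not
clamped**: a mis-specified $(\alpha, \tau)$ may produce negative $q$, and
clamping would both break affinity and silently hide mis-fit.

Because circular-binary-segmentation output is centered by construction,
profiles are rescaled so the length-weighted mean of $r$ is exactly 1
before the transform (`normalize = TRUE`, switchable). On noise-free input
this is a no-op; on real data it removes residual off-centering so that the
"average segment maps to the ploidy" identity holds exactly.

## CNH: copy-number heterogeneity

For a candidate $(\alpha, \tau)$, CNH is the weighted mean distance of the
corrected segments to the nearest integers,
$$\mathrm{CNH}(\alpha,\tau) = \frac{\sum_i w_i\,\bigl|q_i - \mathrm{round}(q_i)\bigr|}{\sum_i w_i} \in [0, 0.5],$$
minimized over the search grid. Weights $w_i$ are segment lengths in bp by
default; marker counts are supported (`weights = "markers"`) because the
upstream platform's probe density is an equally defensible weighting and
neither choice is canonical.

## The inter-profile distance $d$

Two profiles are first **harmonized**: re-expressed on the union of their
breakpoints, keeping only regions covered by both. For candidate
corrections $(\alpha_1, \tau_1)$ and $(\alpha_2, \tau_2)$,

$$d(\theta) \;=\; \frac{\sum_j w_j\,|q_{1j} - q_{2j}| \,/\, \sum_j w_j}{s},$$

and the reported distance is $\min_\theta d(\theta)$ over the
four-dimensional grid. The denominator "the standard deviation" is read as
the **weight-pooled population standard deviation of the corrected values
of both profiles**. This reading is symmetric in the two samples, defined
when the profiles are identical, and scale-normalizing; the alternative
(SD of the per-segment differences) is 0/0 for identical profiles, which
is exactly the case the statistic must handle (self-distance must be 0).
A consequence worth knowing: two *flat but unequal* corrected profiles have
pooled SD $|\Delta|/2$, so $d = 2$ there — flatness only becomes degenerate
when the profiles also coincide. When the pooled SD falls below $10^{-9}$
the grid point contributes $d = 0$ if the mean absolute difference is also
below $10^{-9}$, else $+\infty$ (excluded from the minimization).

Patient-level aggregation is the arithmetic mean of $d$ over all
primary $\times$ metastasis cross pairs — within-lesion pairs are not
included because the reported quantity is specifically the
primary-versus-metastasis distance.

## The search grid

The default grid is purity $0.20, 0.21, \ldots, 1.00$ (81 values) by
ploidy $1.50, 1.51, \ldots, 5.00$ (351 values), for both the CNH
minimization (2-D) and the distance (4-D, $\approx 8.1\times10^8$ pairs).
Purity below 0.2 is excluded because the correction becomes ill-conditioned
($b = 2/\alpha - 2$ grows without bound); ploidy outside $[1.5, 5]$ is
outside the biologically plausible range for these tumors.

# Numerical design

**Tie-breaks.** The $(\alpha, \tau)$ ridge of equivalent minimizers is a
known identifiability feature (a whole-genome-doubled solution fits exactly
as well on noise-free data). Among minimizers within $10^{-12}$ of the
minimum, the package reports the smallest $\tau$, then the largest
$\alpha$ (for pairs: lexicographically smallest
$(\tau_1, -\alpha_1, \tau_2, -\alpha_2)$), and reports the tie count.
Output is therefore deterministic.

**Exact pooled moments.** Because the correction is affine, the pooled SD
for a grid-point pair has closed form in the weighted moments of $r$:
$m_k = A_k \bar r_k + B_k$, $V_k = A_k^2\,\mathrm{Var}(r_k)$, and
$s^2 = (V_1 + V_2)/2 + \bigl((m_1 - m_2)/2\bigr)^2$. This is exact algebra
(not an $E[x^2]-m^2$ shortcut, which would lose precision to cancellation),
so only the weighted mean absolute difference needs the per-segment loop.
The compiled scan is pinned against the naive per-pair R evaluator to
$10^{-12}$ in the test suite.

**Search strategies.** `exhaustive` evaluates every grid-point pair
exactly. `coarse_to_fine` (default) scans a strided coarse sub-grid
(every 5th purity index, every 25th ploidy index, endpoints always
included), then exhaustively refines the full grid within one coarse
stride in all four dimensions around each of the top-5 coarse candidates.
On grids where the complete scan is no more work than refinement
($\le$ 250,000 pairs) the complete scan is used directly, making the
result exact there. The compiled kernel additionally prunes with the
running best: the pruning threshold includes the tie tolerance, so minima
and tie-breaks are unaffected — only work is saved. Exactness on the
default grid is guaranteed only for `exhaustive`; the suite verifies
`coarse_to_fine` $\ge$ `exhaustive` there and exact agreement on reduced
grids.

**Degenerate inputs.** Flat profiles (see above); empty harmonization
(zero mutual coverage) is an error rather than a silent zero; groups with
all-identical distances short-circuit the omnibus test to $F = 0$,
$p = 1$ instead of dividing by a zero residual.

# The simulator: what it emulates, and what it does not

`simulate_patient()` generates ground truth the analysis can be scored
against:

* **Clones.** A diploid ancestor acquires `n_ancestral_events` (default 5)
  random events — uniform chromosome, uniform breakpoints snapped to a
  100-kb lattice, copy-number delta uniform on $\{-1, +1, +2\}$, whole-
  chromosome events with probability 0.3; each of `n_subclones` (default 3)
  subclones adds `n_events_per_subclone` (default 5) private events. Events
  that would drive a copy number below zero are resampled.
* **Mixtures.** The primary lesion mixes ancestor and subclones at
  $\mathrm{Dirichlet}(1,\ldots,1)$ fractions. Under **polyclonal** seeding
  the metastasis inherits the same clones with fractions re-drawn from a
  concentrated Dirichlet (concentration $50 \times$ the primary fractions —
  a small perturbation); under **monoclonal** seeding one subclone, chosen
  uniformly, founds the metastasis alone.
* **Observation.** Each sample draws an independent purity, uniform on
  $[0.4, 0.9]$ by default (realistic bulk-tumor purities, safely inside
  the searched range), and the profile is observed as
  $r = (\alpha q + 2(1-\alpha)) / (\alpha \tau^* + 2(1-\alpha))$,
  $\log R = \log_2 r + \mathcal N(0, \sigma)$, with $\sigma = 0.05$ log2
  units by default — segment-level noise of the order seen in shallow-WGS
  segment means. Noise is applied per segment, not per bin, because the
  analysis consumes segmented profiles and segment-mean error is the
  effective error model.
* **Reproducibility.** All randomness flows through R's Mersenne-Twister
  with explicit seeds; cohorts spawn per-patient seeds as master + patient
  index, so any patient can be regenerated alone. Identical seeds produce
  byte-identical SEG output (segment means are serialized at 6 decimals;
  in-memory values keep full precision so zero-noise identities hold to
  $10^{-9}$).

What the generator does **not** emulate: wave/GC artifacts and correlated
noise along the genome, segmentation errors (breakpoints are the truth's
own), focal amplifications beyond +2 per event, sex chromosomes, allele-
specific states, and single-cell karyotype data. A green test therefore
establishes correctness of the *statistics* under the stated generative
model, not robustness to platform artifacts.

`clone_with_ploidy()` exists for parameter-recovery experiments
specifically: an event-based clone's ploidy is implied by its events and is
generically *off* the 0.01 ploidy lattice, so "CNH $= 0$ at a true grid
point" would be unattainable. The helper constructs a clone whose
length-weighted mean copy number is exactly the requested grid value (100
equal genome units at $\lfloor\tau\rfloor$ or $\lfloor\tau\rfloor + 1$
copies, scattered randomly).

# Identifiability of the CNH mixing ladder

The property "CNH increases with the subclonal mixing fraction" holds only
in a regime the package's tests state explicitly, for two reasons intrinsic
to the statistic:

1. **Periodicity.** Distance-to-nearest-integer is periodic: a segment
   where the subclone differs by *two* copies, mixed at fraction 0.5, lands
   back on an integer. Monotonicity is therefore only well-posed for
   single-copy subclonal divergence, which the test constructs (disjoint
   $\pm 1$ runs).
2. **Ploidy aliases.** The corrected profile at $(\alpha', \tau')$ is an
   affine map $\lambda q + \mu$ of the truth; when $\lambda$ is an integer
   with $\lambda f \in \mathbb Z$, a fraction-$f$ mixture is mapped onto
   integers and CNH collapses. Aliases with $\lambda \ge 2$ are reachable
   whenever $\lambda (\tau^* + b^*) \le \tau_{\max} + b_{\max} = 13$. At
   observation purity 0.25 ($b^* = 6$, so $\tau^* + b^* \approx 8$) every
   $\lambda \ge 2$ alias is pushed outside the searchable range, which is
   why the ladder experiments observe at purity 0.25.

Both constraints are identifiability facts about grid-minimized CNH, not
tuning: at high purity the statistic genuinely cannot distinguish a 50/50
mixture from a clonal tumor of doubled ploidy, on noise-free data, inside
this grid.

# Group comparison

The omnibus test across patient groups is one-way ANOVA on the per-patient
mean distances, in all cases (with two groups this is equivalent to the
pooled-variance $t$ test). For three or more groups, all-pairs comparisons
use Tukey's honest-significant-difference adjustment; with exactly two
groups the pairwise entry is a two-sided Wilcoxon rank-sum test — the rank
test is the natural robust companion there, while Tukey's studentized range
adds nothing over the omnibus $F$. Gain/loss frequency tracks use log2-ratio
thresholds of $\pm 0.1$ by default (conventional shallow-WGS practice; the
choice is a package default, not a literature constant) on bins of 100 kb
(toy genome) or 1 Mb (real genomes).

# Known limitations

* The distance minimization rewards any affine alignment of the two
  profiles; with very few segments or near-flat profiles the minimum can be
  optimistically small. The pooled-SD denominator bounds, but does not
  eliminate, this.
* `coarse_to_fine` is exact only on small grids; on the default grid it is
  an upper bound (verified against `exhaustive` in the tests).
* Purity below the grid floor (0.2) is indistinguishable from higher-purity
  solutions of different ploidy; samples of lower purity should be excluded
  upstream.
* Marker-count weights on harmonized intervals are allocated proportionally
  to interval length and averaged between the two profiles — an
  approximation, since true per-interval probe counts are not in SEG input.
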