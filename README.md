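# cnadist

Comparing segmented somatic copy-number profiles of matched tumor lesions:
purity/ploidy-corrected absolute copy numbers, the copy-number
heterogeneity statistic (CNH), and a grid-minimized primary-versus-
metastasis clonality distance — plus a clonal-seeding simulator that
generates profiles with known ground truth.

## Who this is for

Groups profiling primary cancers and their metastases with shallow
whole-genome sequencing or SNP arrays. After circular binary segmentation,
each sample is a segmented log2-ratio profile; the biological questions —
*how subclonal is this lesion?* and *how far has this metastasis diverged
from its primary?* — are confounded by tumor purity α and mean ploidy τ,
which differ arbitrarily between samples. `cnadist` answers both with the
same tactic: transform to absolute copy number

    q = ( r·(ατ + 2(1−α)) − 2(1−α) ) / α ,   r = 2^log2-ratio

and minimize the statistic of interest over an explicit purity × ploidy
search grid (α ∈ {0.20, 0.21, …, 1.00}, τ ∈ {1.50, 1.51, …, 5.00}):

* **CNH** — length-weighted mean distance of corrected segments to the
  nearest integers, minimized over the 2-D grid. 0 for a clean clonal
  profile; grows with subclonal admixture.
* **Distance d** — weighted mean absolute difference of the two corrected
  profiles on harmonized breakpoints, divided by the pooled weighted
  standard deviation, minimized over the 4-D grid (α₁, τ₁, α₂, τ₂).
  Patient-level values average all primary × metastasis pairs; cohorts are
  compared by one-way ANOVA (Tukey HSD pairwise for ≥ 3 groups).
* **Simulator** — integer-copy-number clones, normal-cell dilution,
  Gaussian segment noise, and two metastatic seeding modes: *polyclonal*
  (metastasis inherits the primary's clone mixture — profiles stay close)
  versus *monoclonal* (one subclone founds the metastasis — profiles
  diverge).

See `vignettes/cnadist-methods.Rmd` for the model, numerical design, and
identifiability caveats.

## Worked example

A small synthetic cohort (2 polyclonal + 2 monoclonal patients on an
8-chromosome toy genome) ships in `inst/extdata/`:

```r
library(cnadist)
genome   <- toy_genome(8)
profiles <- read_seg(system.file("extdata", "synthetic_cohort.seg",
                                 package = "cnadist"), genome)
sheet    <- read_sample_sheet(system.file("extdata", "synthetic_samples.tsv",
                                          package = "cnadist"))

cnh_minimize(profiles[["POLY001_P1"]])
#> <cnh_result> CNH = 0.083111 at (alpha = 0.82, tau = 2.26), 1 tie(s)

pair_distance_minimize(profiles[["POLY001_P1"]], profiles[["POLY001_M1"]])
#> <pair_distance_result> POLY001_P1 vs POLY001_M1: d = 0.114642 (coarse_to_fine, 1262650 grid pairs)
#>   at a: (alpha = 0.98, tau = 1.78); b: (alpha = 0.87, tau = 1.77)

cd <- cohort_distances(sheet, profiles)
print(cd$patients, row.names = FALSE)
#>  patient_id      group n_pairs    mean_d
#>     MONO001 monoclonal       1 0.6940511
#>     MONO002 monoclonal       1 0.5694901
#>     POLY001 polyclonal       1 0.1146420
#>     POLY002 polyclonal       1 0.1173244

compare_groups(cd$patients)
#> <group_comparison> one-way ANOVA; pairwise Wilcoxon rank-sum (2 groups)
#>   omnibus F = 68.55, p = 0.01428
#>       group n    mean_d  median_d
#>  monoclonal 2 0.6317706 0.6317706
#>  polyclonal 2 0.1159832 0.1159832
```

Reading the numbers: the sample `POLY001_P1` carries moderate subclonal
signal (CNH ≈ 0.083 at its best-fitting purity 0.82, ploidy 2.26). Its
metastasis sits at distance d ≈ 0.11 — after the grid has removed purity
and ploidy differences, the profiles nearly coincide — while the
monoclonally seeded patients sit at d ≈ 0.57–0.69. The group contrast
(polyclonal mean 0.12 vs monoclonal 0.63) is the qualitative signature
that polyclonal seeding preserves, and monoclonal seeding erases, the
primary's clonal composition.

## Command line

```sh
Rscript -e 'cnadist::cnadist_cli()' simulate --out sim --seed 7 --patients-per-mode 5
Rscript -e 'cnadist::cnadist_cli()' run --out results --seed 7
Rscript -e 'cnadist::cnadist_cli()' distance --seg sim/cohort.seg \
    --sheet sim/samples.tsv --out results \
    --grid-alpha 0.2,1,0.01 --grid-tau 1.5,5,0.01 --strategy coarse_to_fine
```

Subcommands: `simulate`, `cnh`, `distance`, `frequency`, `run`; shared
flags `--seed`, `--grid-alpha min,max,step`, `--grid-tau min,max,step`,
`--strategy exhaustive|coarse_to_fine`, `--weights bp|markers`, `--out`,
`--log-level`, `--config <file>` (flat `key = value` defaults). The `run`
subcommand writes `distances.tsv`, `pairs.tsv`, `cnh.tsv`,
`frequency.tsv`, `comparison.tsv` and `run.log`; tables are byte-identical
across runs with the same configuration and seed.

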