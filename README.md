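# tbpAffinity

Estimate how strongly TATA-binding protein (TBP) binds a plant proximal
promoter — and compare that affinity between groups of plants — from
sequence alone.

TBP nucleates the transcription preinitiation complex by binding the TATA
box, which sits in a narrow window (about −70 to −20 relative to the
transcription start site) of the ~90 bp proximal promoter. Because promoter
affinity for TBP throttles basal expression, differences in mean TBP
affinity between promoter groups (for example, promoters of allergen-coding
genes in food versus non-food plants) are a sequence-level signature worth
testing for. `tbpAffinity` is aimed at regulatory genomicists who have
cohorts of 90 bp proximal promoters with species / gene-family / group
labels and want a reproducible affinity comparison.

## The model

Each 90 bp promoter is mapped to an equilibrium dissociation constant
K<sub>D</sub> (mol/L; reported in nM) through a calibrated three-step
binding model:

1. **Sliding** — TBP diffuses nonspecifically along the double helix; this
   sets the affinity ceiling K<sub>D</sub><sup>ns</sup> = 10⁻⁵ M.
2. **Recognition** — TBP stops on a TATA-like site. Every window of the
   position-weight-matrix width on both strands is scored by log-odds
   S = Σ<sub>j</sub> ln( p<sub>j</sub>(b<sub>j</sub>) / q(b<sub>j</sub>) ),
   and the best window's score is normalized by the consensus score:
   s\* = max(0, S / S<sub>max</sub>) ∈ [0, 1].
3. **Stabilization** — bending of the DNA locks the complex; together with
   recognition it is absorbed into a log-linear interpolation between the
   two anchors:

   ln K<sub>D</sub> = ln K<sub>D</sub><sup>ns</sup> +
   s\* · (ln K<sub>D</sub><sup>sp</sup> − ln K<sub>D</sub><sup>ns</sup>),
   with K<sub>D</sub><sup>sp</sup> = 10⁻⁹ M.

So a perfect consensus site yields exactly 10⁻⁹ M (1 nM), a promoter with
no site above background exactly 10⁻⁵ M (10⁴ nM), and everything else falls
log-linearly in between. Group comparisons use N, the arithmetic mean M₀
and the standard error Δ (SEM) of the per-promoter K<sub>D</sub> values,
and the difference-of-means Z-test

Z = |M₀⁽¹⁾ − M₀⁽²⁾| / √(Δ₁² + Δ₂²),

referred to the standard normal (two-sided; stars \*\*\* p&lt;0.001,
\*\* p&lt;0.01, \* p&lt;0.05).

See `vignettes/tbp-promoter-affinity.Rmd` for assumptions, calibration
choices and limitations.

## Worked example

Score one promoter carrying a near-consensus TATA box:

```r
library(tbpAffinity)
mat <- defaultTataMatrix()
promoter <- paste0(
  "GCTCTCCACCGTGCATCCCT", "GGCGGCCATAGCTATAAATA",
  "GGAGCCACGGCTCCACTCCA", "CTCGATCATCACCATCACCA", "CCTCCACCTC")
estimateKd(promoter, mat)
#> DataFrame with 1 row and 6 columns
#>                kd     ln_kd     kd_nM best_start best_strand best_score
#>         <numeric> <numeric> <numeric>  <integer> <character>  <numeric>
#> query 2.26657e-09   -19.905   2.26657         30     forward   0.911158
```

The best TATA-like window starts at position 30 on the forward strand and
scores 91% of the consensus, giving K<sub>D</sub> ≈ 2.27 nM — a strong
promoter, close to the specific-binding floor of 1 nM.

Compare two groups from their summaries (here: globulin-promoter means of
2.97 ± 0.21 nM over 74 food-plant promoters versus 2.15 ± 0.08 nM over 53
non-food promoters):

```r
food <- new("GroupSummary", label = "food", n = 74L, m0 = 2.97, sem = 0.21)
nonf <- new("GroupSummary", label = "non_food", n = 53L, m0 = 2.15, sem = 0.08)
fisherZTest(food, nonf)
#> Z-test: Z = 3.65, p = 0.000263 *** (direction +1)
```

The food-plant promoters have a significantly *larger* mean K<sub>D</sub>
(weaker TBP affinity) than the non-food ones.

Run the whole pipeline on a synthetic cohort (50 food + 50 non-food
promoters with planted TATA sites of strength 0.8 vs 0.4):

```r
out <- file.path(tempdir(), "demo-run")
bundle <- runPipeline(runConfig(out_dir = out, spec = cohortSpec(seed = 1)),
                      quiet = TRUE)
summarizeZPrintout(bundle)
#> family                Z            p
#> albumin            3.09      0.00197    **
#> beta_amylase       2.19       0.0289     *
#> globulin           2.57       0.0102     *
```

`out` now contains `per_promoter_kd.tsv`, `family_summary.tsv`,
`tests.tsv`, `run.log` and `manifest.json`; rerunning the same
configuration reproduces them byte-identically. A command-line wrapper
with the same capabilities is installed at
`system.file("scripts", "tbp-affinity-pipeline.R", package = "tbpAffinity")`.

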