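# valuewave

Tests whether an external variable maps onto the circular (circumplex)
structure of Schwartz's ten human value types in a sinusoidal pattern —
the structural signature the value circle predicts for any variable that
engages the whole motivational system at once. The package was built for
the case where the external variable is a personality trait score or a
polygenic score, so it also ships the supporting machinery: value-survey
scoring, generic trait-scale scoring, and polygenic score construction
from GWAS summary statistics.

## The model

Value types sit at positions `x = 1..K` around the motivational circle
(default order: conformity, tradition, benevolence, universalism,
self-direction, stimulation, hedonism, achievement, power, security).
For an external variable, the profile of Pearson correlations `y_k`
with the K types is fitted by the constrained sinusoid

    y = a + b * sin(c * x + d)

with `a, b ∈ [-1, 1]`, the frequency `c` bounded to 85–95% of one full
wave across the circle (`c ∈ [0.85, 0.95]·2π/K`; value spacing is not
assumed exactly equal), and the phase `d` free. Fit quality is the
**Sinusoidal Fit Index**,

    SFI = Σ(y_k − ŷ_k)² / Σ(y_k − ȳ)²,

0 for a perfect sinusoid, 1 for no improvement over the profile mean.
Significance is judged against a Monte-Carlo null: fit the same model to
a large number of random profiles (uniform on (−0.5, 0.5), or truncated
normal) and report the fraction that fit at least as well — the
false-positive rate at the observed SFI.

The polygenic module implements the standard summary-statistics score:
SNPs with GWAS p-value strictly below a threshold (default PT < 0.5) are
pruned for linkage disequilibrium by greedy pairwise `r² < 0.2`, dosages
are aligned to the effect allele, and the score is the per-SNP average
of dosages weighted by `ln(OR)`.

A synthetic-data module generates circumplex-structured survey
responses, traits with a target sinusoidal correlation profile, and
genotype/trait pairs with a target polygenic correlation, so the full
pipeline runs and is tested with no external data.

## Worked example

Simulate a cohort whose trait follows a sinusoidal value profile, fit
the sinusoid, and calibrate:

```r
library(valuewave)

resp   <- gen_value_responses(circumplex_spec(n_participants = 2000, seed = 7))
scores <- aggregate_value_types(ipsatize(resp))
trait  <- gen_external_trait(scores, trait_sim_spec(seed = 8))

prof <- correlate_profile(scores, trait)
round(prof$r, 3)
#>  [1]  0.227  0.116 -0.051 -0.189 -0.269 -0.256 -0.160 -0.035  0.124  0.229

fit <- fit_sine(prof)
fit
#> Constrained sinusoid fit (K = 10 points)
#>   y = -0.0034 + 0.2700 * sin(0.5795 * x + 1.5596)
#>   SSR = 0.000358036   SFI = 0.0011   (16/16 starts converged)

calib <- calibrate_sfi(null_spec("uniform", n_samples = 5000, seed = 9))
calib
#> SFI null calibration: uniform null, K = 10 , n = 5000 , seed = 9
#>  threshold fp_rate        mc_se    n fp_pct
#>       0.05  0.0004 0.0002827861 5000 0.040%
#>       0.10  0.0018 0.0005994598 5000 0.180%
#>       0.15  0.0038 0.0008701218 5000 0.380%
#>       0.20  0.0076 0.0012281889 5000 0.760%

empirical_pvalue(fit$sfi, calib)$p
#> [1] 0
```

Reading the output: the ten correlations rise on the conservation side
and dip at self-direction/stimulation — the planted wave. The fitted
SFI of 0.0011 means the sinusoid leaves 0.1% of the profile's variance
unexplained, and no random profile among 5,000 fitted as well, so the
empirical p-value is below 1/5000. The calibration table shows how
rarely random profiles reach each SFI threshold (under 1% at SFI
< 0.20).

The full file-based study — survey TSV, trait-scale TSV, dosage matrix
or VCF plus summary statistics, joined on participant id — runs through
`run_full_analysis()` (see the methods vignette) or the thin CLI in
`inst/scripts/valuewave.R` (`run-all`, `score-values`, `fit-sine`,
`calibrate`, `simulate`).

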