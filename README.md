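# condindex

Tools for estimating **body condition** from morphometric data — one row
per animal: body mass, one or more linear size measures, and optionally the
water/lean/fat decomposition of mass — and for stress-testing the condition
indices ecologists actually use.

## The science in brief

Condition indices try to separate the part of body mass explained by
structural size from the part that reflects energetic state.  The package
implements the three standard approaches and the allometric machinery they
depend on:

* **Scaled mass index (SMI).**  Standardizes each animal's mass to a fixed
  reference length `L0`:

  ```
  SMI_i = M_i * (L0 / L_i)^b_SMA
  ```

  where `b_SMA` is the scaling exponent of ln mass on ln length estimated
  by standardized major axis (model II) regression,
  `b_SMA = sign(r) * sd(ln M) / sd(ln L)`.  SMA treats both variables as
  error-prone; on the same data OLS returns exactly `r * b_SMA`, i.e. it
  *attenuates* the slope whenever `|r| < 1`.
* **Residual index.**  The standardized residual of the pooled OLS
  regression of ln mass on ln length.
* **Mass ANCOVA.**  ln mass modelled on the treatment factors plus ln
  length, after a homogeneity-of-slopes pre-test.

Because the three methods treat the mass–length slope differently, they can
disagree about which treatments affect condition on the *same* data.  The
package makes that disagreement reproducible: a synthetic-population
generator with a latent condition signal, bivariate measurement error and
an exact water + lean + fat decomposition, group tests for slopes
(two-group OLS interaction; maximum-likelihood common SMA slope with a
likelihood-ratio test) and elevations (adjusted means under a common
slope), correlation-based validation tables of indices against scaled body
components, and a three-way method comparison with its assumption pre-tests
(Levene homoscedasticity, homogeneity of slopes, Type II sums of squares on
unbalanced two-factor designs).

## Worked example

```r
library(condindex)

# A reference population: 103 females + 86 males on a common slope-2.642
# line, with the error structure SMA assumes.
pop <- generate_population(synth_preset("reference_gtex"), seed = 42)
x <- log(pop$pronotum); y <- log(pop$fresh_mass)

fit_ols(x, y)
#> OLS fit (n = 189): slope 2.0505 [1.8353, 2.2658], intercept -3.6889, r = 0.8085
fit_sma(x, y)
#> SMA fit (n = 189): slope 2.5361 [2.3299, 2.7605], intercept -4.2764, r = 0.8085

test_common_slope_sma(x, y, pop$sex)
#> sma_common_slope_lr: statistic = 3.186, df = 1, p = 0.07427
#>   common slope = 2.5265
```

OLS puts the scaling exponent at 2.05, SMA at 2.54 — the attenuation
`b_OLS = r * b_SMA` at work (0.8085 × 2.5361 ≈ 2.05).  The
likelihood-ratio test finds no evidence that the sexes need separate
slopes (p = 0.074), so a common slope is justified and condition scores
can be computed against it:

```r
b  <- test_common_slope_sma(x, y, pop$sex)$common_slope
smi <- scaled_mass_index(pop, b, L0 = reference_length(pop))
head(smi, 3)
#>           id       smi
#> 1 female_001 0.2460590
#> 2 female_002 0.3403654
#> 3 female_003 0.2785624
```

Each `smi` value is the mass (g) the animal would have at the population's
mean pronotum length — directly comparable across individuals of different
sizes.

On a factorial experiment (sex × diet, unbalanced cells 35/40/47/52, diet
shifting growth along the allometric line, sex shifting elevation), the
three methods tell three different stories.  Rates over 200 simulated
experiments (`analysis/05_method_comparison.R`):

```
    smi_sex    smi_diet   resid_sex  resid_diet  ancova_sex ancova_diet
      0.210       0.070       0.650       0.795       0.915       0.985
divergence pattern (residual flags sex, SMI flags neither, ANCOVA flags diet): 42.0%
```

The SMI — computed with the *reference* exponent — correctly reports that
diet does not change mass-at-size, while the residual index (attenuated
common slope) manufactures a sex effect and the ANCOVA converts the diet
size-shift into a condition effect.  Single experiments vary; the package's
tests assert this divergence as the modal outcome across replicates.

## Analysis workflow

The `analysis/` scripts run the full study pipeline on synthetic
populations, writing tables under `results/`:

| script | what it does |
|---|---|
| `01_simulate_reference.R` | simulate the two reference populations and the factorial experiment |
| `02_allometry.R` | per-sex and pooled OLS/SMA fits, slope-heterogeneity and common-slope tests |
| `03_condition_indices.R` | SMI and residual-index scores per individual |
| `04_validation_tables.R` | correlations of components vs size, and indices vs scaled components |
| `05_method_comparison.R` | the three-way method comparison plus a 200-replicate study |

Run them in order from the repository root: `Rscript analysis/01_simulate_reference.R`, etc.

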