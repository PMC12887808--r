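# cisiv — instrument selection and strength for cis-Mendelian randomization

cis-Mendelian randomization (cis-MR) uses genetic variants from a single
gene region as instruments for a molecular exposure — typically a circulating
protein — to estimate its causal effect on an outcome. Variants in a region
are correlated through linkage disequilibrium (LD), so instrument choice is
a trade-off: the lead variant alone is safe but under-powered whenever the
region carries several signals, while indiscriminately adding correlated
variants invites an ill-conditioned LD matrix and numerically unstable MR
estimates.

`cisiv` works entirely from GWAS summary statistics (per-variant effect
`β̂`, standard error, p-value) plus a signed LD correlation matrix, and
provides:

* **Four selection strategies** behind one fitting function,
  `select_instruments()`: standard LD-pruning; adjusted-R²-gated pruning
  (a candidate is kept only if it raises adjusted R² and keeps the selected
  LD submatrix non-singular); stepwise conditional selection on conditional
  p-values with a collinearity gate; sum-of-single-effects fine-mapping
  with 95% credible sets and purity filtering; and principal-component
  instruments from the z-weighted LD matrix `W = (zzᵀ) ∘ R`.
* **Instrument strength for correlated variants.** With `N` the GWAS sample
  size, `J` instruments, `z` the marginal z-statistics and `R` the LD
  submatrix, the joint effects are reconstructed as `γ̂ = S R⁻¹ z`
  (`Σ̂ = S R⁻¹ S`, `S = diag(se)`), and strength follows the chain
  `F = ((N−J−1)/J)·u/(1−u)` with `u = ρ̂ᵀR⁻¹ρ̂`,
  `ρ̂_j = z_j/√(N−2+z_j²)`, then `R² = JF/(N−J−1+JF)` and
  `R²_adj = 1 −(1−R²)(N−1)/(N−J−1)`. At `J = 1` this is exactly
  `F = z²`, `R² = z²/(N−2+z²)`.
* **Correlated-instrument IVW MR**: fixed-effects estimate
  `(γᵀΩ⁻¹γ)⁻¹γᵀΩ⁻¹Γ` with `Ω_ij = se_{y,i} se_{y,j} ρ_ij`, reducing to the
  Wald ratio at `J = 1`; ill-conditioned `Ω` is stabilized by adding
  `ε = −λ_min + 10⁻⁸` to its diagonal and flagged.
* **A self-contained simulator** of block-AR(1) genotype panels and traits
  with known variance explained, plus scenario runners (one/two causal
  variants, proxy-removal, directional pleiotropy) and a region-level
  method comparison (`compare_methods()`) reporting R² normalized by the
  lead-variant-only R².

## Worked example

A synthetic two-signal region (shipped under `inst/extdata/`, 40 variants,
two causal variants each explaining ~30% of the exposure, jointly ~39%):

```r
library(cisiv)

panel  <- simulate_panel(4000, 120, seed = 1)
trait  <- simulate_trait(panel, "two_causal", seed = 2)   # realized R² 0.396
region <- sumstats_from_panel(panel, trait)

compare_methods(region, grids = list(prune_modified = c(0.1, 0.4),
                                     cojo = 0.5, susie = NA, pca = 0.99))
#>           method tuning  J    F    r2 adj_r2 normalized_r2 rank
#> 1      lead_only     NA  1 1713 0.300  0.300          1.00    5
#> 2 prune_modified   0.10  2  892 0.309  0.308          1.03    4
#> 3 prune_modified   0.40  6  439 0.397  0.396          1.32    2
#> 4           cojo   0.50  2 1312 0.396  0.396          1.32    3
#> 5          susie     NA  2 1312 0.396  0.396          1.32    3
#> 6            pca   0.99 20  131 0.398  0.395          1.33    1
```

The lead variant alone explains 30.0% of the exposure; every strategy that
admits correlated non-lead variants recovers the full ~39.6% realized by
the two causal variants (a normalized R² of ~1.32), except pruning at
r² = 0.1, whose threshold is below the causal pair's correlation.

With outcome summary statistics the same selections drive MR; the
command-line wrapper prints the multi-instrument estimate next to the
recommended lead-only companion row:

```sh
Rscript inst/cli/cisiv.R harmonize \
  --sumstats inst/extdata/example_synthetic_exposure.tsv \
  --ld inst/extdata/example_synthetic_ld.tsv --out /tmp/demo
Rscript inst/cli/cisiv.R mr --region /tmp/demo \
  --outcome inst/extdata/example_synthetic_outcome.tsv \
  --method cojo --collinearity 0.5
#> method     tuning                                     J  estimate  se      ...
#> cojo       collinearity_threshold=0.5;p_cutoff=0.001  2  0.2417    0.0268
#> lead_only                                             1  0.2504    0.0309
```

Both estimates cover the simulated causal effect (0.25); the two-instrument
version is ~13% more precise, and its agreement with the lead-only row is
the recommended sanity check against numerical instability.

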