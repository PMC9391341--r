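# radsig

Radiation biodosimetry from blood gene-expression signatures in the mouse.

After an uncontrolled radiation exposure, absorbed dose has to be estimated
from biology. Gene expression in whole blood is a practical endpoint: a
group of transcripts rises with dose (p53/DNA-damage response genes such as
*Phlda3*, *Rhoc*, *Lrg1*) and another group falls (lymphocyte markers such
as *Cd19*, *Cxcr5*, *Ly6D*, *Ccr7*). `radsig` implements the complete
quantitative workflow around that observation:

1. **Signature discovery** — rank genes by Spearman correlation of
   log-scale expression with dose across merged studies, keep genes
   significant after Bonferroni correction, and select the top 20
   positively and top 10 negatively correlated genes.
2. **Net signal** — collapse the signature to one scalar per sample,
   `N = agg(up) − agg(down)` (median for arrays, geometric mean for qPCR
   ΔCt). N is exactly invariant to per-sample additive shifts.
3. **Microarray dose model** — `D = k1·N + k2·N² + k3·√T` (T = days after
   exposure, no intercept), fitted by Tukey-bisquare M-estimation (IRLS,
   c = 4.685, MAD scale) or OLS, with alternative time structures compared
   by test RMSE over repeated random half splits.
4. **qPCR calibration** — wells → ΔCt against the *Actb*/*Gapdh* mean →
   2^−ΔΔCt fold changes → net signal → quadratic regression
   `D = b0 + b1·N + b2·N²` with a screen for sex-interaction terms
   (male = 1, female = 0) that are dropped when non-significant.
5. **Validation** — 1000 random half-split refits (train R²/RMSE, test
   RMSE), and sensitivity of the dose correlation to signature group sizes.

Synthetic-data generators (`generate_array_study()`,
`generate_qpcr_cohort()`) invert the two dose models, so every stage can be
tested against known ground truth; parameter recovery is an exact check,
not a plausibility argument. See the vignette
(`vignettes/dose-reconstruction.Rmd`) for the model details and design
choices.

## Worked example

Simulate a merged multi-study microarray experiment (350 samples, 0–10 Gy,
0.25–7 days, 30 signature genes among 500), rediscover the signature, fit
the dose model and validate it:

```r
library(radsig)

em   <- generate_array_study(array_sim_config(samples_per_condition = 10, seed = 1))
cors <- rank_genes_by_dose_correlation(em)
sig  <- select_signature(bonferroni_filter(cors), n_up = 20, n_down = 10)
ns   <- net_signal_array(em, sig)
fit  <- fit_eq1(ns)
fit
#> <eq1_fit> D = k1*N + k2*N^2 + k3*sqrt(T)   [robust loss]
#>    estimate      se   p_value
#> k1   0.8748 0.07018 1.004e-29
#> k2   0.2323 0.01511 4.991e-41
#> k3   0.1985 0.03788 2.778e-07
#> n = 350 ; converged in 12 iteration(s)

repeated_split_evaluation(ns, n_splits = 1000, base_seed = 1001)
#> <split_evaluation> eq1_robust, 1000 random half splits (0 failed)
#>       metric      mean          sd
#> 1   r2_train 0.9535392 0.004244682
#> 2  rmse_test 0.7557227 0.032818485
#> 3 rmse_train 0.7437864 0.032157547
```

The fitted coefficients sit near the generating values (0.906, 0.274,
0.549); the time coefficient is pulled down because control and late-time
samples lie in the floored region where the model is deliberately
misspecified (see the vignette). Mean test RMSE within ~0.01 Gy of train
RMSE shows the fit is stable under resampling.

The qPCR arm, from raw Ct values to the reduced calibration:

```r
qcfg <- qpcr_sim_config(seed = 42)            # 5 mice/sex at 0..8 Gy, 24 h
ct   <- generate_qpcr_cohort(qcfg)
dct  <- delta_ct(ct)                          # vs geomean of Actb/Gapdh
nsq  <- net_signal_qpcr(dct, gene_signature(qcfg$up_genes, qcfg$down_genes))
red  <- reduce_model(fit_quadratic_sex_model(nsq))
red
#> <quad_dose_model> D = b0 + b_n*N + b_n2*N^2
#>      estimate       se   p_value
#> b0    2.61700 0.015600 1.191e-89
#> b_n  -0.78490 0.003597 2.761e-97
#> b_n2  0.04636 0.001131 3.589e-49

pred <- predict_dose_quadratic(red, nsq)
fit_metrics(pred$dose_raw, nsq$dose_gy)
#> # A tibble: 1 × 3
#>      r2   rmse n_samples
#>   <dbl>  <dbl>     <int>
#> 1 0.999 0.0898        70
```

No sex term reached significance, so `reduce_model()` refit the
three-parameter calibration; the recovered coefficients match the
generating (2.592, −0.785, 0.048) within their standard errors. The N
coefficient is negative because qPCR ΔCt falls as expression rises, so the
net signal decreases with dose. The near-perfect R² reflects that the
generator models technical noise only; real cohorts add biological
variability on top.

`run_pipeline()` chains either arm from files on disk and writes every
artifact with a manifest (config hash + seeds) for reproducibility.

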