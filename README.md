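# bigmolsol

Can models trained on small, Rule-of-5 drug molecules predict the intrinsic
aqueous solubility of *big* molecules — macrocycles, peptides and natural
products beyond the Rule of 5 (MW ≥ 800 Da)? `bigmolsol` packages the models
and diagnostics needed to study that question: the General Solubility
Equation, the Abraham solvation (ABSOLV) model, random-forest QSPR, the
SEBM enhancement index, and van't Hoff temperature normalization, together
with a 31-compound big-molecule reference set and a synthetic-data
generator for the small-molecule training regime.

It is aimed at physical-chemistry and DMPK scientists who need per-compound
solubility predictions with honest error metrics, and at method developers
who want a reproducible testbed for small-to-big extrapolation.

## The models

**General Solubility Equation (GSE).** From melting point (°C) and
octanol–water partition coefficient:

    log S0 = 0.5 − 0.01 (mp − 25) − log P

For big molecules the lipophilicity dependence flattens; the retrained
big-molecule form (preset `gse_big2020()`) is

    log S0 = −1.77 − 0.01 (mp − 25) − 0.4 clogP

**Abraham solvation equation (ABSOLV).** A linear free-energy relationship
on the five Abraham solute descriptors,

    log S0 = c0 + cA·A + cB·B + cS·Sπ + cE·E + cV·V + cAB·A·B  [+ cBz·B^z]

with A = H-bond acidity, B = H-bond basicity, Sπ = dipolarity/
polarizability, E = excess molar refraction, V = McGowan volume. The
optional nonlinear `B^z` term (fit by a PLS exponent scan, `z_scan()`)
amplifies the H-bond basicity contribution that dominates big-molecule
solubility. Fits are weighted by the estimated measurement SD of each
log S0 entry (`weighted_mlr()`, `pls_fit()`).

**SEBM.** The Solubility Enhancement–Big Molecules index,
`SEBM = S0_obs / S0_ABSOLV = 10^(obs − pred)`, measures how much more
soluble a big molecule is than a small-trained ABSOLV model predicts. Its
logarithm rises with rotatable-bond count; the resulting linear correction
(`fit_nrot_correction()`) removes most of the systematic bias.

**Temperature normalization.** With an enthalpy of solution ΔH_sol
(kJ/mol), `normalize_temperature()` moves log S0 between temperatures via
the van't Hoff relation; most big molecules have *negative* ΔH_sol and get
less soluble on warming.

## Worked example

```r
library(bigmolsol)

big <- big31_properties()            # 31-compound big-molecule reference set
summarize_properties(big)
#> Compound set summary (n = 31)
#>   mean log S0:   -4.52 log molar
#>   mean clogP :    3.17
#>   mean M_W   :    1034 Da

# classic GSE collapses on big molecules ...
gse <- predict_gse(big$mp, big$clogp)
evaluate_predictions(big$log_s0, gse, n_params = 2)
#> n = 31, RMSE = 2.96, r2 = 0.00, bias = -0.29, MPP = 13%

# ... and the small-trained ABSOLV model underpredicts them all
abs_pred <- predict_absolv(big)
sebm <- compute_sebm(big$log_s0, abs_pred, id = big$id)
sebm[sebm$compound_id == "cyclosporine-a", ]
#>      compound_id     sebm log_sebm sebm_printed
#> 4 cyclosporine-a 123.0524  2.09009          123

# flexibility explains the miss: residual = 0.75 + 0.13 nROT
fit_nrot_correction(big$log_s0, abs_pred, big$nrot)
#> residual = 0.75 +0.132 nROT  (r2 = 0.44, RMSE = 1.57)

# refit the GSE on the big set: the logP slope flattens to -0.4
fit_gse(big)$coefficients
#> GSE (fitted): log S0 = -1.77 -0.00977 (mp - 25) -0.4 logP
```

The RMSE of ~3 log units (r² floored at 0) says the classic GSE is worse
than predicting the mean for these compounds; the SEBM of 123 for
cyclosporine A says it is two orders of magnitude more soluble than a
small-molecule-trained model expects; the nROT line quantifies how that
enhancement grows with molecular flexibility.

`run_study()` drives the whole pipeline (load → predict → SEBM → metrics →
manifest) into an output directory.

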