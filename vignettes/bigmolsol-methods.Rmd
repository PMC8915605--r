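---
title: "Predicting big-molecule solubility from small-molecule models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting big-molecule solubility from small-molecule models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bigmolsol)
```

## The scientific problem

Most intrinsic-solubility training data come from small, Rule-of-5 drug
molecules. Macrocycles, peptides and complex natural products beyond that
space (here operationalized as molecular weight ≥ 800 Da) are increasingly
common drug candidates, and their aqueous solubility behaves differently:
lipophilicity matters less, H-bond basicity and conformational flexibility
matter more, and enthalpies of solution are typically negative so
solubility *falls* with temperature. `bigmolsol` implements the models
needed to quantify this small-to-big extrapolation gap on a packaged
31-compound big-molecule reference set, plus a synthetic-data generator
that stands in for the (non-public) small-molecule training database.

## Models and assumptions

### General Solubility Equation

`predict_gse()` evaluates `log S0 = c0 + c_mp (mp − 25) + c_logP logP`.
The classic constants (0.5, −0.01, −1) rest on three assumptions: Walden's
rule for the entropy of melting (0.0565 kJ mol⁻¹ K⁻¹, with
2.3RT = 5.706 kJ/mol at 25 °C, giving the −0.01 per-degree lattice term),
octanol as a proxy for the supercooled liquid solute, and ideal miscibility
of that liquid with octanol (the +0.5 intercept). Each assumption is
strained by large, flexible, self-associating molecules, which is why the
big-set refit (`gse_big2020()`: intercept −1.77, logP slope −0.4) departs
so strongly while the melting term survives essentially unchanged —
crystal-lattice contributions are similar in the two regimes and the
divergence is a solution-phase effect. `gse_crossover()` locates the logP
(≈ 3.78 between the classic and big presets) at which the two lines cross:
above it the classic GSE underpredicts big-molecule solubility, below it
overpredicts.

Melting points below 25 °C are accepted with a warning rather than
clamped: the reference set itself contains a 48 °C melter, and the formula
remains well defined, only its solid-phase premise weakens.

### Weighted regression

Published log S0 values carry very different uncertainties, so all model
fitting is weighted by `w = 1/max(sd, 0.05)²`. Inverse variance is the
standard choice when observation errors are heteroscedastic; the 0.05-log
floor prevents a single entry with an optimistically small SD from
dominating a fit. `weighted_mlr()` solves the weighted normal equations by
QR with an explicit rank check that names the dependent columns (a design
with constant clogP, or with A ≡ 0 in the ABSOLV design where the A·B
column then collapses, fails loudly rather than silently).

`pls_fit()` implements SIMPLS on SD-weighted, weighted-mean-centered data.
PLS is used where predictors are too collinear for MLR — in particular the
exponent scan, where `B` and `B^z` are nearly proportional. For a
univariate response SIMPLS coincides with other PLS1 algorithms, and with
all components on a full-rank design it reproduces the weighted MLR
solution to machine precision; both facts are asserted in the test suite
(the latter at 1e-8, the former against an independent PLS implementation).
The component count, when not given, is chosen by 10-fold cross-validated
weighted RMSE at a fixed seed, with ties broken toward fewer components.

### ABSOLV and the nonlinear basicity term

`predict_absolv()` evaluates the Abraham solvation solubility equation on
the five solute descriptors plus the A·B cross term. The packaged
small-molecule-trained preset `absolv_2020()` was pinned by
over-determined least squares against the 31 packaged reference
predictions (31 equations, 7 unknowns; every reference cell reproduced to
< 0.005 log), because the reference predictions — printed to 0.01 log —
determine the coefficient vector far more precisely than any transcription
could be verified. Its A·B weight is near zero, consistent with the cross
term contributing negligibly.

The nonlinear variant appends `c_Bz · B^z`. `z_scan()` fits a weighted PLS
for each exponent on a 0.90–2.00 grid (step 0.01) and takes the RMSE
minimum, ties toward the smaller exponent. `B^z` at `B = 0` is defined as 0
for every `z > 0` (the one-sided limit), avoiding `0^0`. The scan weights
the PLS by measurement SD, consistent with every other fit in the package;
passing `sd = NULL` data disables weighting.

On the big set, ABSOLV residuals grow linearly with rotatable-bond count.
`fit_nrot_correction()` fits that line by *unweighted* OLS — the
correction models a systematic structural bias of the predictions, not the
measurement process, so measurement weights are not applied. Applying the
fitted line (≈ 0.75 + 0.13·nROT on the reference set) halves the RMSE and
drives the bias to ~0.

### Random forest

`train_rfr()` wraps the classic `randomForest` implementation with its
near-optimal defaults (500 trees, p/3 candidate features per split, no
depth limit) behind a deterministic 70/30 split keyed to one seed.
Importance is mean decrease in node impurity, normalized to sum 1. The
published forest cannot be reconstructed — it was trained on a database
that is not redistributable — so the package treats RFR as a method to be
retrained on the user's (or synthetic) data, and the reference RFR column
in `big31_predictions()` is documentation, not a recomputable target. On
synthetic data the expected qualitative ordering (train r² > internal
validation r² > big-set extrapolation r²) is asserted in the tests.

### SEBM and zoning

`compute_sebm()` keeps the exact ratio `10^(obs − pred)` and its log, and
separately the integer table convention (`round` half away from zero,
ratios below 1 displayed as 1). `gse_zone()` classifies compounds as
enhancement/attenuation relative to the classic-GSE identity line, with
exact ties conservatively labeled attenuation, since a compound flagged
"attenuated" gets more formulation scrutiny.

### Temperature normalization and enthalpy

`normalize_temperature()` applies the van't Hoff correction
`log S0(T_ref) = log S0(T) − (ΔH_sol·1000 / (2.303·R)) (1/T_ref − 1/T)`
with R = 8.314 J mol⁻¹ K⁻¹. The ln-10 factor is carried as the
conventional 2.303 rather than `log(10)` to match the arithmetic of the
tabulated examples; the difference is below 0.001 log everywhere in the
reference set. The transformation is exactly invertible, and its sign
convention is fixed by the naproxen worked example (+29 kJ/mol measured at
37 °C gives a 0.2-log decrease when normalized to 25 °C).

`predict_dh_sol()` evaluates a linear enthalpy model on the Abraham
descriptors with optional ionization-class offsets (acid = reference
level). The shipped preset `dh_sol_big2020()` is *re-estimated* from the
packaged reference table (OLS of the tabulated ΔH_sol on the five
descriptors; r² = 0.984, residual RMSE 2.6 kJ/mol) rather than transcribed
from the originally published equations, whose exact coefficient values
and per-compound ionization classes are not part of the packaged data. Its
qualitative structure — strongly negative B and V terms — is what makes
big, H-bond-rich molecules exothermic dissolvers.

## The synthetic-data generator

The small-molecule training database behind the published ABSOLV/RFR
models is not public, so `generate_small_set()` / `generate_big_set()`
emulate its statistical structure: that is what makes every downstream
stage testable.

* **Marginals.** Small sets: lognormal MW around 280 Da (< 800),
  truncated-normal melting points on 40–350 °C (mean 135), clogP normal
  with mean 1.89 (SD 1.8). Big sets: lognormal MW ≥ 800 Da around
  1000 Da, clogP mean 3.17, melting mean 180 °C, rotatable bonds uniform
  on 3–53. Means are the documented profile of the two regimes; the SDs
  and the melting/MW shapes are the package's own choices of realistic
  spread, fixed once.
* **Descriptor correlation.** A, B, Sπ, E are gamma-distributed with
  scale proportional to a latent size factor (MW/280), and V tracks
  MW/130 with small noise. This reproduces the key structural fact that
  big molecules carry many more H-bond acceptors than donors, and keeps
  all descriptor invariants (A, B ≥ 0, V > 0) by construction.
* **Noise model.** Each entry draws a reported SD uniformly from
  `sd_range` (default 0.05–0.7 log) and a measurement error
  `N(0, sd · noise_sd/mean(sd_range))`, so `noise_sd` (default 0.5 log,
  the typical interlaboratory reproducibility) is the *mean* true error,
  `noise_sd = 0` gives exactly noiseless data, reported SDs stay inside
  `sd_range`, and inverse-variance weights are correct up to a constant —
  which makes weighted-fit standard errors consistent and parameter-
  recovery coverage experiments well-posed.
* **Random-number discipline.** Each draw category (MW, melting point,
  clogP, descriptors, nROT, SDs, noise) runs on its own stream derived
  from the seed, so adding a field never perturbs earlier draws and a
  fixed seed yields byte-identical tables.

What the generator does *not* emulate: real chemical structures, the true
joint distribution of descriptors (only marginal means/ranges and a
single size-driven correlation), multiple entries per compound, or
structure-derived 2D descriptor sets. Tests passing on synthetic data
therefore demonstrate the estimators' statistical correctness, not
chemical-space coverage.

## Problem sizes and numerical checks

The test suite and examples run at deliberately modest sizes chosen to
make the statistical checks decisive: parameter-recovery coverage uses
100 simulated big sets of n = 500 at 0.5-log noise (per-coefficient 95%
CI coverage ≥ 90%); exponent-scan recovery uses one n = 2000 set at
0.3-log noise (recovered z within 0.05 of the generating 1.3); the forest
ordering check trains on 2000 synthetic small molecules. Degenerate
inputs — empty tables, header-only CSVs, all-zero descriptor columns,
constant targets, duplicated design columns, ties on the identity line —
all have defined behavior exercised by tests.

## Known limitations

* The ABSOLV and enthalpy presets are anchored to a 31-compound
  big-molecule table; applying them far outside that space (or to charged
  species — all predictions are for the neutral form) is extrapolation.
* clogP itself is unreliable for very large molecules; the GSE inherits
  that error in full.
* The rotatable-bond correction is an empirical repair: nROT ignores
  flexibility from large rings, and adding it to the ABSOLV training
  descriptors does not improve the trained model — it is predictive only
  as a post-hoc residual trend.
* Melting points are inputs; no melting-point prediction is attempted.
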