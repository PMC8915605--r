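Package: bigmolsol
Title: Intrinsic Aqueous Solubility Models for Beyond-Rule-of-5 Molecules
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Models and diagnostics for predicting the intrinsic aqueous
    solubility (log S0, log molar) of large 'beyond Rule of 5' drug-like
    molecules (molecular weight >= 800 Da) from models trained on small
    molecules. Implements the General Solubility Equation (classic and
    big-molecule retrained forms), the Abraham solvation (ABSOLV) linear
    free-energy model with an optional nonlinear H-bond basicity term and
    exponent scan, SD-weighted multiple linear regression and SIMPLS partial
    least squares, random-forest QSPR regression, a rotatable-bond residual
    correction, the Solubility Enhancement-Big Molecules (SEBM) index,
    van't Hoff temperature normalization of solubility via enthalpies of
    solution, a 31-compound big-molecule reference table, and a synthetic
    data generator emulating the statistical structure of a heteroscedastic
    small-molecule solubility training database.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    randomForest,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mixOmics
Config/testthat/edition: 3
RoxygenNote: 7.3.3
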