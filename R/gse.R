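# General Solubility Equation: log S0 = c0 + c_mp (mp - 25) + c_logP logP.
# Classic constants derive from Walden's rule (entropy of melting
# 0.0565 kJ/mol.K, 2.3RT = 5.706 kJ/mol at 25 C) for the melting term and
# from octanol/water miscibility of the supercooled liquid for the rest.

#' GSE coefficient set
#'
#' @param intercept intercept (log molar units).
#' @param mp_coef melting-point coefficient (per degree C above 25).
#' @param logp_coef log P coefficient (dimensionless).
#' @param provenance `"classic"` for the textbook constants
#'   (0.5, -0.01, -1), `"fitted"` otherwise.
#' @return a `gse_coefficients` object.
#' @seealso [gse_classic()], [gse_big2020()]
#' @export
gse_coefficients <- function(intercept, mp_coef, logp_coef,
                             provenance = c("fitted", "classic")) {
  provenance <- match.arg(provenance)
  if (provenance == "classic" &&
      !isTRUE(all.equal(c(intercept, mp_coef, logp_coef), c(0.5, -0.01, -1)))) {
    stop("classic provenance requires coefficients (0.5, -0.01, -1)")
  }
  structure(list(intercept = intercept, mp_coef = mp_coef,
                 logp_coef = logp_coef, provenance = provenance),
            class = "gse_coefficients")
}

#' Classic (untrained) General Solubility Equation constants
#'
#' `log S0 = 0.5 - 0.01 (mp - 25) - log P`.
#' @return a `gse_coefficients` object.
#' @export
gse_classic <- function() {
  gse_coefficients(0.5, -0.01, -1, provenance = "classic")
}

#' Big-molecule retrained GSE constants
#'
#' SD-weighted refit of the GSE on big (MW >= 800 Da) molecules:
#' `log S0 = -1.77 - 0.01 (mp - 25) - 0.4 clogP`. The shallower log P
#' slope and the more negative intercept capture the weaker lipophilicity
#' dependence of big-molecule solubility; the melting-point coefficient
#' stays at the classic -0.01 per degree.
#' @return a `gse_coefficients` object.
#' @export
gse_big2020 <- function() {
  gse_coefficients(-1.77, -0.01, -0.4, provenance = "fitted")
}

#' @export
print.gse_coefficients <- function(x, ...) {
  cat(sprintf("GSE (%s): log S0 = %.3g %+.3g (mp - 25) %+.3g logP\n",
              x$provenance, x$intercept, x$mp_coef, x$logp_coef))
  invisible(x)
}

#' Predict intrinsic solubility with the General Solubility Equation
#'
#' `log S0 = intercept + mp_coef * (mp - 25) + logp_coef * logP`.
#' Melting points below 25 degrees C are used as-is but draw a warning,
#' since the crystalline-solid premise of the melting term weakens there.
#'
#' @param mp melting point(s), degrees C.
#' @param logp octanol-water (c)log P value(s).
#' @param coeffs a [gse_coefficients()] set; classic GSE by default.
#' @return predicted log S0 (log molar), vectorized over inputs.
#' @export
predict_gse <- function(mp, logp, coeffs = gse_classic()) {
  stopifnot(inherits(coeffs, "gse_coefficients"))
  if (any(!is.finite(mp)) || any(!is.finite(logp))) {
    stop("mp and logp must be finite")
  }
  if (any(mp < 25)) {
    warning("melting point below 25 C: solid-phase premise of the GSE ",
            "is weak; formula applied as-is", call. = FALSE)
  }
  coeffs$intercept + coeffs$mp_coef * (mp - 25) + coeffs$logp_coef * logp
}

#' Refit the GSE constants by SD-weighted regression
#'
#' Three-parameter weighted MLR of observed log S0 on
#' `(1, mp - 25, clogp)`, with inverse-variance weights from the
#' per-observation measurement SDs (see [weighted_mlr()]).
#'
#' @param data data frame with columns `log_s0`, `mp`, `clogp`, and
#'   optionally `sd`; at least 4 rows.
#' @param sd_floor SD floor for the weights (log units).
#' @return list of class `gse_fit`: `coefficients`
#'   (a `gse_coefficients`), `fit` (the underlying `weighted_fit`), and
#'   `metrics` (training [evaluate_predictions()] report, p = 3).
#' @export
fit_gse <- function(data, sd_floor = 0.05) {
  need <- c("log_s0", "mp", "clogp")
  if (!all(need %in% names(data))) {
    stop("data must contain columns: ", paste(need, collapse = ", "))
  }
  if (nrow(data) < 4) stop("need at least 4 compounds to fit the GSE")
  X <- cbind(intercept = 1, mp25 = data$mp - 25, clogp = data$clogp)
  fit <- weighted_mlr(X, data$log_s0, data$sd, sd_floor = sd_floor)
  cf <- fit$coefficients
  structure(list(
    coefficients = gse_coefficients(cf[[1]], cf[[2]], cf[[3]], "fitted"),
    fit = fit,
    metrics = evaluate_predictions(data$log_s0, fit$fitted, n_params = 3)
  ), class = "gse_fit")
}

#' @export
print.gse_fit <- function(x, ...) {
  print(x$coefficients); print(x$metrics)
  invisible(x)
}

#' Crossover point of two GSE parameterizations
#'
#' Solves for the log P at which two GSE lines predict the same
#' solubility at a given melting point — e.g. the point below which the
#' classic GSE underpredicts, and above which it overpredicts, relative
#' to the big-molecule refit.
#'
#' @param coeffs_a,coeffs_b two [gse_coefficients()] sets with different
#'   `logp_coef`.
#' @param mp melting point (degrees C) at which to intersect the lines.
#' @return list with `logp` and `log_s0` at the crossover.
#' @export
gse_crossover <- function(coeffs_a, coeffs_b, mp = 25) {
  stopifnot(inherits(coeffs_a, "gse_coefficients"),
            inherits(coeffs_b, "gse_coefficients"))
  dslope <- coeffs_a$logp_coef - coeffs_b$logp_coef
  if (abs(dslope) < 1e-12) {
    stop("no crossover: the two GSE lines have equal logP coefficients")
  }
  logp <- ((coeffs_b$intercept - coeffs_a$intercept) +
           (coeffs_b$mp_coef - coeffs_a$mp_coef) * (mp - 25)) / dslope
  list(logp = logp,
       log_s0 = suppressWarnings(predict_gse(mp, logp, coeffs_a)))
}
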