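# Abraham solvation (ABSOLV) solubility model:
#   log S0 = c0 + cA*A + cB*B + cS*S_pi + cE*E + cV*V + cAB*A*B [+ cBz*B^z]
# A: H-bond total acidity, B: H-bond total basicity, S_pi: dipolarity/
# polarizability, E: excess molar refraction /10, V: McGowan volume /100.

ABRAHAM_FIELDS <- c("A", "B", "S_pi", "E", "V")

#' ABSOLV coefficient set
#'
#' @param c0 intercept (log molar).
#' @param c_a,c_b,c_s,c_e,c_v coefficients of the five Abraham
#'   descriptors A, B, S_pi, E, V.
#' @param c_ab coefficient of the A*B cross term.
#' @param c_bz optional coefficient of the nonlinear `B^z` term.
#' @param z optional exponent of the nonlinear basicity term; must be
#'   supplied exactly when `c_bz` is.
#' @return an `absolv_coefficients` object.
#' @seealso [absolv_2020()]
#' @export
absolv_coefficients <- function(c0, c_a, c_b, c_s, c_e, c_v, c_ab,
                                c_bz = NULL, z = NULL) {
  if (is.null(c_bz) != is.null(z)) {
    stop("c_bz and z must be supplied together")
  }
  if (!is.null(z) && z <= 0) stop("z must be > 0")
  structure(list(c0 = c0, c_a = c_a, c_b = c_b, c_s = c_s, c_e = c_e,
                 c_v = c_v, c_ab = c_ab, c_bz = c_bz, z = z),
            class = "absolv_coefficients")
}

#' Small-molecule-trained ABSOLV solubility coefficients
#'
#' The SD-weighted small-molecule ABSOLV parameterization used as the
#' reference preset for big-molecule prediction and for the SEBM index.
#' The vector is pinned by over-determined least squares against the
#' packaged 31-compound reference predictions (31 equations, 7 unknowns;
#' every reference cell is reproduced to < 0.005 log), and the A*B cross
#' term carries a near-zero weight. Note the strong positive H-bond
#' basicity (B) term and negative volume (V) term.
#'
#' @return an `absolv_coefficients` object.
#' @export
absolv_2020 <- function() {
  absolv_coefficients(c0 = -0.01792503998413807,
                      c_a = 0.19982699727346423,
                      c_b = 1.78374033894154249,
                      c_s = -0.10847815432978275,
                      c_e = -1.16878926794955218,
                      c_v = -1.49290758362583786,
                      c_ab = 0.00828780225204735)
}

#' @export
print.absolv_coefficients <- function(x, ...) {
  cat(sprintf(paste0("ABSOLV: log S0 = %.3f %+.3f A %+.3f B %+.3f S_pi ",
                     "%+.3f E %+.3f V %+.4f A*B"),
              x$c0, x$c_a, x$c_b, x$c_s, x$c_e, x$c_v, x$c_ab))
  if (!is.null(x$c_bz)) cat(sprintf(" %+.3f B^%.2f", x$c_bz, x$z))
  cat("\n")
  invisible(x)
}

# B^z with the B = 0 limit defined as 0 for every z > 0
pow_b <- function(b, z) ifelse(b == 0, 0, b^z)

#' Predict intrinsic solubility with the ABSOLV model
#'
#' Evaluates the Abraham solvation solubility equation (plus the optional
#' nonlinear `B^z` term) for each row of a descriptor table.
#'
#' @param desc data frame (or `compound_table`) with numeric columns
#'   `A`, `B`, `S_pi`, `E`, `V`.
#' @param coeffs an [absolv_coefficients()] set; [absolv_2020()] by
#'   default.
#' @return predicted log S0 (log molar) vector.
#' @export
predict_absolv <- function(desc, coeffs = absolv_2020()) {
  stopifnot(inherits(coeffs, "absolv_coefficients"))
  missing_d <- setdiff(ABRAHAM_FIELDS, names(desc))
  if (length(missing_d) > 0) {
    stop("missing Abraham descriptor(s): ", paste(missing_d, collapse = ", "))
  }
  for (f in ABRAHAM_FIELDS) {
    if (any(is.na(desc[[f]]))) {
      stop("missing Abraham descriptor(s): ", f, " has NA values")
    }
  }
  out <- with(desc, coeffs$c0 + coeffs$c_a * A + coeffs$c_b * B +
                coeffs$c_s * S_pi + coeffs$c_e * E + coeffs$c_v * V +
                coeffs$c_ab * A * B)
  if (!is.null(coeffs$c_bz)) {
    out <- out + coeffs$c_bz * pow_b(desc$B, coeffs$z)
  }
  out
}

#' Fit the linear ABSOLV model by SD-weighted regression
#'
#' Weighted MLR of observed log S0 on `(1, A, B, S_pi, E, V, A*B)`.
#' Degenerate descriptor columns (e.g. `A` identically zero, which makes
#' both the A and A*B columns inestimable) surface as a rank-deficiency
#' error naming the dependent columns.
#'
#' @param data data frame with columns `log_s0`, the five Abraham
#'   descriptors, and optionally `sd`; at least 9 rows.
#' @param sd_floor SD floor for the weights (log units).
#' @return list of class `absolv_fit`: `coefficients`
#'   (an `absolv_coefficients`), `fit`, `metrics` (p = 7).
#' @export
fit_absolv <- function(data, sd_floor = 0.05) {
  need <- c("log_s0", ABRAHAM_FIELDS)
  if (!all(need %in% names(data))) {
    stop("data must contain columns: ", paste(need, collapse = ", "))
  }
  if (nrow(data) < 9) stop("need at least 9 compounds to fit ABSOLV")
  X <- with(data, cbind(c0 = 1, A = A, B = B, S_pi = S_pi, E = E, V = V,
                        A.B = A * B))
  fit <- weighted_mlr(X, data$log_s0, data$sd, sd_floor = sd_floor)
  cf <- unname(fit$coefficients)
  structure(list(
    coefficients = absolv_coefficients(cf[1], cf[2], cf[3], cf[4], cf[5],
                                       cf[6], cf[7]),
    fit = fit,
    metrics = evaluate_predictions(data$log_s0, fit$fitted, n_params = 7)
  ), class = "absolv_fit")
}

#' @export
print.absolv_fit <- function(x, ...) {
  print(x$coefficients); print(x$metrics)
  invisible(x)
}

#' Exponent scan for the nonlinear H-bond basicity term
#'
#' For each exponent `z` on the grid, appends a `B^z` column to the
#' ABSOLV design and fits an SD-weighted PLS regression; the best-fit
#' exponent is the minimum of the weighted training RMSE versus `z`
#' curve (ties resolved toward the smallest `z`). PLS is used because
#' `B` and `B^z` are strongly collinear.
#'
#' @param data data frame with `log_s0`, the five Abraham descriptors,
#'   and optionally `sd`; `B` must be positive for all rows.
#' @param z_grid exponent grid (default 0.90 to 2.00 in steps of 0.01).
#' @param n_components PLS components; `NULL` selects per-z by
#'   cross-validation with the fixed `seed`, so the scan is
#'   deterministic.
#' @param sd_floor SD floor for the weights.
#' @param seed seed for the component-selection folds.
#' @return list of class `z_scan`: `z_best` and `table`
#'   (data frame `z`, `rmse`, `components`).
#' @export
z_scan <- function(data, z_grid = seq(0.90, 2.00, by = 0.01),
                   n_components = NULL, sd_floor = 0.05, seed = 1) {
  if (length(z_grid) == 0) stop("z_grid must be non-empty")
  if (any(z_grid <= 0)) stop("z values must be > 0")
  if (any(data$B <= 0)) stop("z_scan requires B > 0 for all rows")
  w_sd <- data$sd
  base <- with(data, cbind(A = A, B = B, S_pi = S_pi, E = E, V = V,
                           A.B = A * B))
  rmse <- numeric(length(z_grid))
  comps <- integer(length(z_grid))
  w <- if (is.null(w_sd)) rep(1, nrow(base)) else 1 / pmax(w_sd, sd_floor)^2
  for (i in seq_along(z_grid)) {
    X <- cbind(base, Bz = data$B^z_grid[i])
    fit <- pls_fit(X, data$log_s0, w_sd, n_components = n_components,
                   sd_floor = sd_floor, seed = seed)
    rmse[i] <- sqrt(sum(w * fit$residuals^2) / sum(w))
    comps[i] <- fit$pls_components
  }
  structure(list(z_best = z_grid[which.min(rmse)],
                 table = data.frame(z = z_grid, rmse = rmse,
                                    components = comps)),
            class = "z_scan")
}

#' @export
print.z_scan <- function(x, ...) {
  cat(sprintf("exponent scan over %d grid points: z_best = %.2f (RMSE %.4f)\n",
              nrow(x$table), x$z_best, min(x$table$rmse)))
  invisible(x)
}

#' Rotatable-bond correction of ABSOLV residuals
#'
#' The systematic underprediction of big-molecule solubility by the
#' small-trained ABSOLV model correlates with molecular flexibility.
#' This fits the unweighted OLS line
#' `(obs - pred) = intercept + slope * nROT` over big compounds; the
#' correction is then applied as `pred + intercept + slope * nROT`.
#'
#' @param obs observed log S0.
#' @param pred ABSOLV-predicted log S0.
#' @param nrot rotatable-bond counts (same length, >= 2 values, not all
#'   equal).
#' @return list of class `nrot_correction`: `intercept`, `slope`,
#'   `r2`, `rmse`, and the underlying `lm` fit.
#' @export
fit_nrot_correction <- function(obs, pred, nrot) {
  if (length(obs) != length(pred) || length(obs) != length(nrot)) {
    stop("obs, pred and nrot must have equal length")
  }
  if (length(obs) < 2) stop("need at least 2 compounds with nROT")
  if (length(unique(nrot)) < 2) {
    stop("singular fit: all nROT values are equal")
  }
  resid <- obs - pred
  fit <- lm(resid ~ nrot)
  ss_tot <- sum((resid - mean(resid))^2)
  structure(list(intercept = unname(coef(fit)[1]),
                 slope = unname(coef(fit)[2]),
                 r2 = if (ss_tot > 0) summary(fit)$r.squared else 0,
                 rmse = sqrt(mean(residuals(fit)^2)),
                 lm = fit),
            class = "nrot_correction")
}

#' @export
print.nrot_correction <- function(x, ...) {
  cat(sprintf("residual = %.2f %+.3f nROT  (r2 = %.2f, RMSE = %.2f)\n",
              x$intercept, x$slope, x$r2, x$rmse))
  invisible(x)
}

#' Apply a rotatable-bond correction to ABSOLV predictions
#'
#' @param correction an [fit_nrot_correction()] result.
#' @param pred uncorrected predicted log S0.
#' @param nrot rotatable-bond counts.
#' @return corrected log S0 vector.
#' @export
apply_nrot_correction <- function(correction, pred, nrot) {
  stopifnot(inherits(correction, "nrot_correction"))
  pred + correction$intercept + correction$slope * nrot
}
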