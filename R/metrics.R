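# Weighted regression and the shared metric suite.

#' SD-weighted multiple linear regression
#'
#' Minimizes the weighted residual sum of squares
#' `sum_i w_i (y_i - X_i c)^2` with inverse-variance weights
#' `w_i = 1 / max(sd_i, sd_floor)^2`. The floor keeps a single
#' ultra-precise measurement from dominating the fit. With `sd = NULL`
#' all observations receive equal weight (ordinary least squares).
#'
#' @param X design matrix, including an intercept column if one is wanted.
#' @param y response vector (log S0).
#' @param sd per-observation estimated measurement SD (log units), or
#'   `NULL` for an unweighted fit.
#' @param sd_floor lower bound applied to `sd` before inversion
#'   (log units; default 0.05).
#' @return a `weighted_fit`: `coefficients`, `se` (standard errors),
#'   `weights`, `method = "MLR"`, `fitted`, `residuals`, `df_residual`.
#' @export
weighted_mlr <- function(X, y, sd = NULL, sd_floor = 0.05) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n) stop("rows(X) must equal length(y)")
  if (!is.null(sd) && length(sd) != n) stop("length(sd) must equal rows(X)")
  if (n <= p) stop("need more observations than design columns")
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(p))
  w <- if (is.null(sd)) rep(1, n) else 1 / pmax(sd, sd_floor)^2

  Xs <- X * sqrt(w)
  qrx <- qr(Xs)
  if (qrx$rank < p) {
    dep <- colnames(X)[qrx$pivot[(qrx$rank + 1):p]]
    stop("design matrix is rank deficient; dependent column(s): ",
         paste(dep, collapse = ", "))
  }
  fit <- lm.wfit(X, y, w)
  cf <- fit$coefficients
  sigma2 <- sum(w * fit$residuals^2) / (n - p)
  XtX_inv <- chol2inv(qr.R(qrx)[seq_len(p), seq_len(p), drop = FALSE])
  se <- sqrt(diag(XtX_inv) * sigma2)
  names(se) <- names(cf) <- colnames(X)
  structure(list(coefficients = cf, se = se, weights = w, method = "MLR",
                 fitted = drop(X %*% cf), residuals = y - drop(X %*% cf),
                 df_residual = n - p, sigma2 = sigma2),
            class = "weighted_fit")
}

#' @export
print.weighted_fit <- function(x, ...) {
  cat(sprintf("%s fit (%d residual df%s)\n", x$method, x$df_residual,
              if (!is.null(x$pls_components))
                paste0(", ", x$pls_components, " PLS component(s)") else ""))
  print(round(rbind(coefficient = x$coefficients, se = x$se), 4))
  invisible(x)
}

#' SD-weighted partial least squares (SIMPLS) regression
#'
#' PLS1 regression on SD-weighted, weighted-mean-centered data, for designs
#' whose predictors are too collinear for MLR. Weighting follows the same
#' inverse-variance rule as [weighted_mlr()]. With `n_components =
#' ncol(X)` on a full-rank design the coefficients coincide with the
#' weighted MLR solution; with fewer components the fit is shrunk along
#' the dominant covariance directions, and collinear (even duplicated)
#' columns never cause a singularity.
#'
#' @param X predictor matrix *without* an intercept column (the intercept
#'   is handled by centering and returned as the first coefficient).
#' @param y response vector.
#' @param sd per-observation SD, or `NULL` for equal weights.
#' @param n_components number of latent components, in
#'   `1..ncol(X)`; `NULL` selects by cross-validation via
#'   [choose_pls_components()].
#' @param sd_floor SD floor, as in [weighted_mlr()].
#' @param seed seed for the cross-validated component selection (ignored
#'   when `n_components` is given).
#' @return a `weighted_fit` with `method = "PLS"` and `pls_components`;
#'   `coefficients` is `c(intercept, slopes)`.
#' @export
pls_fit <- function(X, y, sd = NULL, n_components = NULL, sd_floor = 0.05,
                    seed = 1) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n) stop("rows(X) must equal length(y)")
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(p))
  if (is.null(n_components)) {
    n_components <- choose_pls_components(X, y, sd, sd_floor = sd_floor,
                                          seed = seed)$n_components
  }
  if (n_components < 1 || n_components > p) {
    stop("n_components must be between 1 and ncol(X) = ", p)
  }
  w <- if (is.null(sd)) rep(1, n) else 1 / pmax(sd, sd_floor)^2
  cf <- simpls_coefficients(X, y, w, n_components)
  fitted <- cf[1] + drop(X %*% cf[-1])
  structure(list(coefficients = setNames(cf, c("(intercept)", colnames(X))),
                 se = rep(NA_real_, p + 1), weights = w, method = "PLS",
                 pls_components = n_components, fitted = fitted,
                 residuals = y - fitted, df_residual = n - n_components - 1),
            class = "weighted_fit")
}

# SIMPLS for a univariate response on sqrt(w)-scaled, weighted-centered
# data. Returns c(intercept, slopes). Components whose score norm
# underflows (design rank exhausted) are dropped silently.
simpls_coefficients <- function(X, y, w, ncomp) {
  sw <- sqrt(w / sum(w))
  xm <- colSums(X * w) / sum(w)
  ym <- sum(y * w) / sum(w)
  Xc <- sweep(X, 2, xm) * sw
  yc <- (y - ym) * sw
  p <- ncol(X)
  R <- matrix(0, p, ncomp); V <- matrix(0, p, ncomp); Q <- numeric(ncomp)
  s <- crossprod(Xc, yc)
  used <- 0L
  for (a in seq_len(ncomp)) {
    r <- s
    t <- Xc %*% r
    nt <- sqrt(sum(t * t))
    if (nt < 1e-12) break
    t <- t / nt; r <- r / nt
    pv <- crossprod(Xc, t)
    v <- pv
    if (a > 1) {
      Vp <- V[, seq_len(a - 1L), drop = FALSE]
      v <- v - Vp %*% crossprod(Vp, pv)
    }
    v <- v / sqrt(sum(v * v))
    s <- s - v %*% crossprod(v, s)
    R[, a] <- r; V[, a] <- v; Q[a] <- sum(yc * t)
    used <- a
  }
  b <- if (used > 0) {
    drop(R[, seq_len(used), drop = FALSE] %*% Q[seq_len(used)])
  } else {
    rep(0, p)
  }
  c(ym - sum(xm * b), b)
}

#' Choose the PLS component count by cross-validation
#'
#' K-fold cross-validated weighted RMSE over component counts
#' `1..ncol(X)`; ties (within 1e-9) are broken toward fewer components.
#' The fold assignment is drawn from `seed` so the choice is
#' deterministic.
#'
#' @inheritParams pls_fit
#' @param folds number of cross-validation folds (default 10).
#' @return list with `n_components` and the per-count `cv_rmse` vector.
#' @export
choose_pls_components <- function(X, y, sd = NULL, folds = 10, seed = 1,
                                  sd_floor = 0.05) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  folds <- min(folds, n)
  w <- if (is.null(sd)) rep(1, n) else 1 / pmax(sd, sd_floor)^2
  set.seed(seed)
  fold_id <- sample(rep(seq_len(folds), length.out = n))
  sse <- numeric(p); swt <- numeric(p)
  for (k in seq_len(folds)) {
    hold <- fold_id == k
    for (nc in seq_len(p)) {
      cf <- simpls_coefficients(X[!hold, , drop = FALSE], y[!hold],
                                w[!hold], nc)
      pred <- cf[1] + drop(X[hold, , drop = FALSE] %*% cf[-1])
      sse[nc] <- sse[nc] + sum(w[hold] * (y[hold] - pred)^2)
      swt[nc] <- swt[nc] + sum(w[hold])
    }
  }
  cv_rmse <- sqrt(sse / swt)
  best <- min(cv_rmse)
  list(n_components = which(cv_rmse <= best + 1e-9)[1], cv_rmse = cv_rmse)
}

#' Prediction-performance metrics for a solubility model
#'
#' The shared metric suite: root-mean-square error, squared correlation
#' coefficient floored at zero (a model can be worse than the mean of the
#' observations), mean residual (bias), the population SD of the
#' observations, the F-statistic `((n-p-1)/p) * SStot/SSres` when the
#' parameter count is supplied, and MPP — the percentage of absolute
#' residuals at or below `threshold` log units.
#'
#' Residuals are `obs - pred` throughout, so a positive bias means the
#' model underpredicts solubility.
#'
#' @param obs observed log S0 vector.
#' @param pred predicted log S0 vector (same length).
#' @param n_params number of regression parameters `p` for the
#'   F-statistic; `NA` F is reported when omitted.
#' @param threshold residual threshold for MPP (log units, default 0.5).
#' @return a `metrics_report` list: `n`, `rmse`, `r2`, `bias`, `sd`,
#'   `f_stat`, `mpp`.
#' @export
evaluate_predictions <- function(obs, pred, n_params = NULL,
                                 threshold = 0.5) {
  if (length(obs) != length(pred)) stop("obs and pred must have equal length")
  if (length(obs) < 1) stop("need at least one observation")
  res <- obs - pred
  n <- length(obs)
  ss_res <- sum(res^2)
  ss_tot <- sum((obs - mean(obs))^2)
  r2 <- if (ss_tot > 0) max(0, 1 - ss_res / ss_tot) else 0
  f_stat <- if (!is.null(n_params) && ss_res > 0) {
    (n - n_params - 1) / n_params * ss_tot / ss_res
  } else {
    NA_real_
  }
  structure(list(n = n,
                 rmse = sqrt(ss_res / n),
                 r2 = r2,
                 bias = mean(res),
                 sd = sqrt(ss_tot / n),
                 f_stat = f_stat,
                 mpp = 100 * mean(abs(res) <= threshold)),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("n = %d, RMSE = %.2f, r2 = %.2f, bias = %.2f, MPP = %.0f%%\n",
              x$n, x$rmse, x$r2, x$bias, x$mpp))
  invisible(x)
}

#' Serialize a metrics report to a flat JSON file
#'
#' @param report a `metrics_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_metrics <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, null = "null", na = "null")
  invisible(path)
}
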