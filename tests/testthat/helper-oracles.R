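# Independent oracles and small fixture builders shared across tests.

# Weighted least squares by explicit normal equations: the independent
# reference for weighted_mlr on small designs.
wls_normal_equations <- function(X, y, sd = NULL, sd_floor = 0.05) {
  X <- as.matrix(X)
  w <- if (is.null(sd)) rep(1, nrow(X)) else 1 / pmax(sd, sd_floor)^2
  W <- diag(w)
  XtWX <- t(X) %*% W %*% X
  beta <- solve(XtWX, t(X) %*% W %*% y)
  resid <- y - X %*% beta
  sigma2 <- sum(w * resid^2) / (nrow(X) - ncol(X))
  list(coefficients = drop(beta), se = sqrt(diag(solve(XtWX)) * sigma2))
}

# tiny hand-buildable compound table
toy_compounds <- function(mw = c(500, 900), ...) {
  n <- length(mw)
  as_compound_table(data.frame(
    id = paste0("c", seq_len(n)), log_s0 = rep(-3, n), mp = rep(150, n),
    clogp = rep(2, n), mw = mw, ..., stringsAsFactors = FALSE))
}

fixture_properties <- big31_properties()
fixture_predictions <- big31_predictions()
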