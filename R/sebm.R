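# Solubility Enhancement-Big Molecules: SEBM = S0_obs / S0_absolv,
# the factor by which a big molecule is more soluble than the
# small-molecule-trained ABSOLV model predicts.

#' Compute the SEBM index
#'
#' `SEBM = 10^(obs - pred_absolv)`. The exact ratio and its log are
#' retained at full precision; `sebm_printed` is the integer
#' table-display convention (round half away from zero, with ratios
#' below 1 displayed as 1).
#'
#' @param obs observed log S0.
#' @param pred_absolv ABSOLV-predicted log S0 (same length).
#' @param id optional compound identifiers.
#' @return data frame of class `sebm_table` with columns `compound_id`,
#'   `sebm`, `log_sebm`, `sebm_printed`.
#' @export
compute_sebm <- function(obs, pred_absolv, id = NULL) {
  if (length(obs) != length(pred_absolv)) {
    stop("obs and pred_absolv must have equal length")
  }
  if (any(!is.finite(obs)) || any(!is.finite(pred_absolv))) {
    stop("obs and pred_absolv must be finite")
  }
  log_sebm <- obs - pred_absolv
  sebm <- 10^log_sebm
  out <- data.frame(
    compound_id = if (is.null(id)) as.character(seq_along(obs)) else id,
    sebm = sebm,
    log_sebm = log_sebm,
    sebm_printed = pmax(1, round_half_away(sebm)),
    stringsAsFactors = FALSE
  )
  class(out) <- c("sebm_table", "data.frame")
  out
}

# round-half-away-from-zero (table convention; base round() is half-even)
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' GSE enhancement/attenuation zoning
#'
#' Classifies each compound relative to the classic-GSE identity line:
#' `"enhancement"` when the observed solubility exceeds the GSE
#' prediction, `"attenuation"` otherwise. Exact ties are labeled
#' attenuation (the conservative flag for formulation risk) with a note.
#'
#' @param obs observed log S0.
#' @param pred_gse GSE-predicted log S0.
#' @return character vector of `"enhancement"` / `"attenuation"`.
#' @export
gse_zone <- function(obs, pred_gse) {
  if (length(obs) != length(pred_gse)) {
    stop("obs and pred_gse must have equal length")
  }
  if (any(!is.finite(obs)) || any(!is.finite(pred_gse))) {
    stop("obs and pred_gse must be finite")
  }
  ties <- obs == pred_gse
  if (any(ties)) {
    message(sum(ties), " tie(s) on the identity line labeled 'attenuation'")
  }
  ifelse(obs > pred_gse, "enhancement", "attenuation")
}

#' log SEBM versus rotatable-bond count trend
#'
#' The flexibility trend behind the rotatable-bond correction: an
#' unweighted OLS line of `log SEBM = obs - pred_absolv` against nROT,
#' sharing its implementation with [fit_nrot_correction()], plus a
#' plot-ready scatter table.
#'
#' @param obs observed log S0.
#' @param pred_absolv ABSOLV-predicted log S0.
#' @param nrot rotatable-bond counts.
#' @param id optional compound identifiers.
#' @return list with `table` (data frame `compound_id`, `nrot`,
#'   `log_sebm`) and `fit` (an `nrot_correction`).
#' @export
sebm_nrot_trend <- function(obs, pred_absolv, nrot, id = NULL) {
  fit <- fit_nrot_correction(obs, pred_absolv, nrot)
  list(table = data.frame(
         compound_id = if (is.null(id)) as.character(seq_along(obs)) else id,
         nrot = nrot,
         log_sebm = obs - pred_absolv,
         stringsAsFactors = FALSE),
       fit = fit)
}
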