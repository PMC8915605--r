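# Study orchestrator: load/simulate -> predict -> SEBM -> metric reports,
# with a run manifest sufficient to replay the run.

#' Run the big-molecule prediction study pipeline
#'
#' Loads a compound table (the packaged 31-compound reference set by
#' default), applies the requested solubility models, computes the SEBM
#' index and GSE zoning, evaluates every model against the observed
#' values, and writes the prediction table, per-model metric reports,
#' the log-SEBM/nROT trend table and a run manifest into `outdir`.
#' Outputs are deterministic for a fixed configuration (the timestamp
#' lives only inside the manifest).
#'
#' @param outdir output directory (created if absent).
#' @param input path to a compound CSV, a `compound_table`, or `NULL`
#'   for the packaged reference set.
#' @param models model columns to compute: subset of
#'   `"gse"`, `"absolv"`, `"rfr"`.
#' @param gse_coeffs GSE preset (default [gse_classic()]).
#' @param absolv_coeffs ABSOLV preset (default [absolv_2020()]).
#' @param rfr_model a trained [train_rfr()] model; required when
#'   `"rfr"` is requested (there is no redistributable reference
#'   forest).
#' @param nrot_correct also emit rotatable-bond-corrected ABSOLV
#'   predictions and their metrics (default TRUE when ABSOLV is run and
#'   `nrot` is available).
#' @param threshold MPP residual threshold (log units).
#' @param seed seed recorded in the manifest and used for any
#'   stochastic stage.
#' @return invisibly, a list with the computed tables, metric reports
#'   and output paths.
#' @export
run_study <- function(outdir, input = NULL,
                      models = c("gse", "absolv"),
                      gse_coeffs = gse_classic(),
                      absolv_coeffs = absolv_2020(),
                      rfr_model = NULL, nrot_correct = TRUE,
                      threshold = 0.5, seed = 1) {
  if (length(models) > 0) {
    models <- match.arg(models, c("gse", "absolv", "rfr"),
                        several.ok = TRUE)
  }
  if ("rfr" %in% models && is.null(rfr_model)) {
    stop("models includes 'rfr' but no trained rfr_model was supplied")
  }
  records <- if (is.null(input)) {
    big31_properties()
  } else if (is.character(input)) {
    read_compound_table(input)
  } else {
    as_compound_table(input)
  }
  if (nrow(records) == 0) stop("input table has no valid rows")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

  tab <- data.frame(id = records$id, obs = records$log_s0,
                    stringsAsFactors = FALSE)
  metrics <- list()
  if ("gse" %in% models) {
    tab$gse <- suppressWarnings(
      predict_gse(records$mp, records$clogp, gse_coeffs))
    tab$gse_zone <- gse_zone(tab$obs, tab$gse)
    metrics$gse <- evaluate_predictions(tab$obs, tab$gse,
                                        threshold = threshold)
  }
  trend <- NULL
  if ("absolv" %in% models) {
    tab$absolv <- predict_absolv(records, absolv_coeffs)
    metrics$absolv <- evaluate_predictions(tab$obs, tab$absolv,
                                           threshold = threshold)
    sebm <- compute_sebm(tab$obs, tab$absolv, id = tab$id)
    tab$sebm <- sebm$sebm
    tab$sebm_printed <- sebm$sebm_printed
    if (nrot_correct && "nrot" %in% names(records)) {
      corr <- fit_nrot_correction(tab$obs, tab$absolv, records$nrot)
      tab$absolv_nrot <- apply_nrot_correction(corr, tab$absolv,
                                               records$nrot)
      metrics$absolv_nrot <- evaluate_predictions(tab$obs, tab$absolv_nrot,
                                                  threshold = threshold)
      trend <- sebm_nrot_trend(tab$obs, tab$absolv, records$nrot,
                               id = tab$id)
    }
  }
  if ("rfr" %in% models) {
    feats <- build_descriptor_table(records)
    tab$rfr <- predict_rfr(rfr_model, feats)
    metrics$rfr <- evaluate_predictions(tab$obs, tab$rfr,
                                        threshold = threshold)
  }

  paths <- list(predictions = file.path(outdir, "predictions.csv"),
                manifest = file.path(outdir, "manifest.json"))
  write.csv(tab, paths$predictions, row.names = FALSE, quote = FALSE)
  for (mname in names(metrics)) {
    paths[[paste0("metrics_", mname)]] <-
      file.path(outdir, paste0("metrics_", mname, ".json"))
    write_metrics(metrics[[mname]], paths[[paste0("metrics_", mname)]])
  }
  if (!is.null(trend)) {
    paths$sebm_trend <- file.path(outdir, "sebm_nrot_trend.csv")
    write.csv(trend$table, paths$sebm_trend, row.names = FALSE,
              quote = FALSE)
  }
  manifest <- list(
    package = "bigmolsol",
    version = as.character(packageVersion("bigmolsol")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    input = if (is.character(input)) input else
      if (is.null(input)) "packaged big-molecule reference set" else
        "in-memory compound table",
    n_compounds = nrow(records),
    models = models,
    gse_preset = unclass(gse_coeffs),
    absolv_preset = unclass(absolv_coeffs),
    threshold = threshold,
    seed = seed)
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(list(predictions = tab, metrics = metrics, trend = trend,
                 manifest = manifest, paths = paths))
}
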