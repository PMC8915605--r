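#' @keywords internal
IONIZATION_CLASSES <- c("acid", "base", "neutral", "ampholyte")

# canonical column set for a compound table; one row couples a compound
# record with its (source-averaged) solubility entry
COMPOUND_REQUIRED <- c("id", "log_s0", "mp", "clogp", "mw")
COMPOUND_NUMERIC <- c("log_s0", "sd", "n_sources", "mw", "mp", "clogp",
                      "dh_sol", "nha", "nhd", "nrot",
                      "A", "B", "S_pi", "E", "V", "temperature")
COMPOUND_COUNTS <- c("nha", "nhd", "nrot")

#' Validate a compound/solubility table
#'
#' Checks the invariants of the data model: positive molecular weight,
#' non-negative integer H-bond and rotatable-bond counts, a recognised
#' ionization class, finite `log_s0`, non-negative measurement SD, and
#' non-negative Abraham descriptors with `V > 0`. Rows violating an
#' invariant are dropped with a per-row diagnostic; structural problems
#' (missing required columns) are errors.
#'
#' @param x data frame with at least columns `id`, `log_s0`, `mp`,
#'   `clogp`, `mw`; optional columns `name`, `sd`, `n_sources`, `nha`,
#'   `nhd`, `nrot`, `A`, `B`, `S_pi`, `E`, `V`, `ionization`, `dh_sol`,
#'   `temperature`, `source`.
#' @return the validated table, classed `"compound_table"`, with a derived
#'   `size_class` column (`"big"` iff `mw >= 800`). Rejected rows are kept
#'   in the `"rejected"` attribute together with the reason.
#' @export
as_compound_table <- function(x) {
  x <- as.data.frame(x)
  missing_cols <- setdiff(COMPOUND_REQUIRED, names(x))
  if (length(missing_cols) > 0) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  }
  x$id <- as.character(x$id)

  reasons <- character(nrow(x))
  flag <- function(bad, why) {
    bad <- !is.na(bad) & bad
    reasons[bad] <<- ifelse(nzchar(reasons[bad]),
                            paste(reasons[bad], why, sep = "; "), why)
  }
  flag(!is.finite(x$log_s0), "log_s0 not finite")
  flag(x$mw <= 0, "mw must be > 0")
  for (cc in intersect(COMPOUND_COUNTS, names(x))) {
    v <- x[[cc]]
    flag(v < 0 | (is.finite(v) & abs(v - round(v)) > 1e-8),
         paste0(cc, " must be a non-negative integer"))
  }
  if ("sd" %in% names(x)) flag(x$sd < 0, "sd must be >= 0")
  if ("ionization" %in% names(x)) {
    flag(!is.na(x$ionization) & !(x$ionization %in% IONIZATION_CLASSES),
         "unknown ionization class")
  }
  for (d in intersect(c("A", "B"), names(x))) {
    flag(x[[d]] < 0, paste0("Abraham ", d, " must be >= 0"))
  }
  if ("V" %in% names(x)) flag(x$V <= 0, "Abraham V must be > 0")

  bad <- nzchar(reasons)
  rejected <- NULL
  if (any(bad)) {
    rejected <- data.frame(row = which(bad), id = x$id[bad],
                           reason = reasons[bad], stringsAsFactors = FALSE)
    warning(sprintf("rejected %d row(s): %s", nrow(rejected),
                    paste(sprintf("row %d (%s): %s", rejected$row,
                                  rejected$id, rejected$reason),
                          collapse = " | ")), call. = FALSE)
    x <- x[!bad, , drop = FALSE]
    rownames(x) <- NULL
  }
  x$size_class <- ifelse(x$mw >= 800, "big", "small")
  class(x) <- c("compound_table", "data.frame")
  attr(x, "rejected") <- rejected
  x
}

#' Read a compound table from CSV
#'
#' Reads a UTF-8, comma-separated, header-mandatory compound table and
#' validates it with [as_compound_table()]. Column order is irrelevant;
#' a `schema` mapping renames non-canonical column headers.
#'
#' @param path path to a CSV file.
#' @param schema optional named character vector mapping canonical field
#'   names to the column names used in the file, e.g.
#'   `c(log_s0 = "logS", mp = "melting_point")`.
#' @return a `compound_table` (possibly with zero rows).
#' @export
read_compound_table <- function(path, schema = NULL) {
  x <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character",
                fileEncoding = "UTF-8")
  if (!is.null(schema)) {
    for (canon in names(schema)) {
      j <- match(schema[[canon]], names(x))
      if (is.na(j)) stop("schema column not found in file: ", schema[[canon]])
      names(x)[j] <- canon
    }
  }
  missing_cols <- setdiff(COMPOUND_REQUIRED, names(x))
  if (length(missing_cols) > 0) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  }
  for (nc in intersect(COMPOUND_NUMERIC, names(x))) {
    raw <- x[[nc]]
    val <- suppressWarnings(as.numeric(raw))
    bad <- which(!is.na(raw) & nzchar(trimws(raw)) & is.na(val))
    if (length(bad) > 0) {
      stop(sprintf("non-numeric value '%s' in column '%s', row %d",
                   raw[bad[1]], nc, bad[1]))
    }
    x[[nc]] <- val
  }
  if (nrow(x) == 0) {
    x$size_class <- character(0)
    class(x) <- c("compound_table", "data.frame")
    return(x)
  }
  as_compound_table(x)
}

#' Write a compound table to CSV
#'
#' Inverse of [read_compound_table()]: a written table reloads to the same
#' records field-by-field. The derived `size_class` column is not written.
#'
#' @param x a `compound_table`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_compound_table <- function(x, path) {
  x <- as.data.frame(x)
  x$size_class <- NULL
  write.csv(x, path, row.names = FALSE, quote = TRUE, fileEncoding = "UTF-8",
            na = "")
  invisible(path)
}

#' Partition compounds into big and small molecules
#'
#' Big molecules are those with molecular weight >= 800 Da, the operational
#' beyond-Rule-of-5 boundary used throughout the package. The partition is
#' exhaustive and disjoint and preserves row order within each part.
#'
#' @param records a `compound_table` or data frame with an `mw` column.
#' @return list with elements `big` and `small`.
#' @export
big_small_split <- function(records) {
  stopifnot("mw" %in% names(records))
  big <- records[records$mw >= 800, , drop = FALSE]
  small <- records[records$mw < 800, , drop = FALSE]
  list(big = big, small = small)
}

#' Summarize the physicochemical profile of a compound set
#'
#' Per-compound means of log S0, clogP and molecular weight, plus H-bond
#' acceptor/donor count histograms — the descriptors used to characterize
#' how big molecules differ from small ones.
#'
#' @param records a `compound_table`; must contain at least one row.
#' @param breaks histogram bin specification passed to [graphics::hist()]
#'   semantics via [base::table()] bucketing; here counts are tabulated per
#'   integer value by default.
#' @return list with `n`, `mean_log_s0`, `mean_clogp`, `mean_mw`, and
#'   (when the columns exist) `nha_counts`, `nhd_counts` tables.
#' @export
summarize_properties <- function(records, breaks = NULL) {
  if (nrow(records) == 0) stop("cannot summarize an empty compound set")
  out <- list(
    n = nrow(records),
    mean_log_s0 = mean(records$log_s0),
    mean_clogp = mean(records$clogp),
    mean_mw = mean(records$mw)
  )
  for (cc in intersect(c("nha", "nhd"), names(records))) {
    v <- records[[cc]]
    tab <- if (is.null(breaks)) table(v) else table(cut(v, breaks))
    out[[paste0(cc, "_counts")]] <- tab
  }
  class(out) <- "property_summary"
  out
}

#' @export
print.property_summary <- function(x, ...) {
  cat(sprintf("Compound set summary (n = %d)\n", x$n))
  cat(sprintf("  mean log S0: %7.2f log molar\n", x$mean_log_s0))
  cat(sprintf("  mean clogP : %7.2f\n", x$mean_clogp))
  cat(sprintf("  mean M_W   : %7.0f Da\n", x$mean_mw))
  invisible(x)
}

#' Packaged 31-compound big-molecule reference set
#'
#' Physicochemical properties of 31 big (MW >= 800 Da) drug-like molecules:
#' observed intrinsic solubility (log molar, source-averaged) with its
#' estimated SD, melting point, clogP, H-bond acceptor/donor and
#' rotatable-bond counts, the five Abraham solvation descriptors, and the
#' calculated enthalpy of solution (kJ/mol). Ionization classes are
#' `"acid"` for the two iodinated contrast-agent diacids and `"neutral"`
#' otherwise (classes for the remaining compounds are not part of the
#' printed reference data).
#'
#' @return a `compound_table` with 31 rows.
#' @export
big31_properties <- function() {
  read_compound_table(system.file("extdata", "big31_properties.csv",
                                  package = "bigmolsol", mustWork = TRUE))
}

#' Reference model predictions for the 31 big molecules
#'
#' Observed log S0 together with the published per-compound predictions of
#' the classic GSE, the small-molecule-trained ABSOLV model, the random
#' forest model, and the tabulated (integer-rounded) SEBM ratio. The RFR
#' column is reference context only: it derives from a training database
#' that is not redistributable, so it cannot be recomputed here.
#'
#' @return data frame with columns `id`, `obs`, `gse`, `absolv`, `rfr`,
#'   `sebm` (31 rows).
#' @export
big31_predictions <- function() {
  read.csv(system.file("extdata", "big31_predictions.csv",
                       package = "bigmolsol", mustWork = TRUE),
           stringsAsFactors = FALSE)
}
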