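# Per-subject report records and the cohort table writer/reader.

subjectRecordColumns <- c(
  "id", "e_prime_septal", "e_prime_lateral", "E", "A", "E_over_A",
  "E_over_eprime", "pfr", "edv", "esv", "lv_ef", "lv_mass",
  "la_vol_min", "la_vol_max", "la_ef", "lge_pct", "lge_sqrt_pct",
  "pcwp", "lvedp", "bsa"
)

#' One-row per-subject record of derived diastolic parameters
#'
#' Units: e' in cm/sec; E and A in m/sec; PFR in mL/sec; volumes in mL
#' (indexed to BSA upstream when requested); LA-EF and LV-EF in percent;
#' LGE burden as percent and its square root; pressures in mmHg.
#' Missing measurements stay NA and are preserved as empty cells on write.
#'
#' @param id subject identifier.
#' @param ... any of the remaining record columns (see
#'   \code{subjectRecordColumns}); unsupplied ones are NA.
#' @return one-row data.frame with the canonical column order.
#' @export
subjectRecord <- function(id, ...) {
  vals <- list(...)
  unknown <- setdiff(names(vals), subjectRecordColumns)
  if (length(unknown))
    stop("unknown record fields: ", paste(unknown, collapse = ", "))
  rec <- as.list(rep(NA_real_, length(subjectRecordColumns)))
  names(rec) <- subjectRecordColumns
  rec$id <- as.character(id)
  for (nm in names(vals)) rec[[nm]] <- vals[[nm]]
  num <- rec[setdiff(subjectRecordColumns, "id")]
  bad <- vapply(num, function(v) is.finite(v) && v < 0, logical(1))
  if (any(bad))
    stop("negative physical quantity in record: ",
         paste(names(num)[bad], collapse = ", "))
  if (is.finite(rec$la_vol_min) && is.finite(rec$la_vol_max) &&
      rec$la_vol_min > rec$la_vol_max)
    stop("la_vol_min must not exceed la_vol_max")
  as.data.frame(rec, stringsAsFactors = FALSE)
}

#' Write subject records as a cohort CSV (with optional JSON mirror)
#'
#' Fixed column order; missing values are written as empty cells.
#'
#' @param records data.frame of stacked \code{\link{subjectRecord}} rows.
#' @param path output CSV path.
#' @param json also write a JSON mirror next to the CSV.
#' @return \code{path}, invisibly.
#' @export
writeReport <- function(records, path, json = FALSE) {
  if (!nrow(records)) stop("records must be non-empty")
  missingCols <- setdiff(subjectRecordColumns, names(records))
  for (nm in missingCols) records[[nm]] <- NA_real_
  records <- records[, subjectRecordColumns]
  ok <- tryCatch({
    utils::write.csv(records, path, row.names = FALSE, na = "")
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("I/O error: cannot write report to ", path)
  if (json)
    jsonlite::write_json(records, sub("\\.csv$", ".json", path),
                         auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' Read a cohort CSV written by \code{\link{writeReport}}
#'
#' @param path CSV path.
#' @return data.frame in the canonical column order, empty cells as NA.
#' @export
readReport <- function(path) {
  if (!file.exists(path)) stop("path does not exist: ", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(id = "character"))
  tab[, intersect(subjectRecordColumns, names(tab))]
}
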