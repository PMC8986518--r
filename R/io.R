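#' Read a monthly time-series CSV
#'
#' Reads `date,value` or `date,value1,value2` files (ISO dates, monthly
#' cadence). Gaps in the monthly sequence are an error naming the
#' offending row, never imputed.
#'
#' @param path CSV file path.
#' @return Tibble with a `date` column and the numeric series columns.
#' @export
read_monthly_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (ncol(df) < 2) abort("expected columns: date,value[,value2]")
  dates <- as.Date(df[[1]])
  if (anyNA(dates)) {
    bad <- which(is.na(dates))[1]
    abort(sprintf("unparseable date at row %d of %s", bad, basename(path)))
  }
  mo <- as.integer(format(dates, "%Y")) * 12L + as.integer(format(dates, "%m"))
  gaps <- which(diff(mo) != 1L)
  if (length(gaps) > 0)
    abort(sprintf("gap in monthly cadence after row %d (%s); gaps are not imputed",
                  gaps[1], format(dates[gaps[1]])))
  for (j in 2:ncol(df)) {
    if (anyNA(suppressWarnings(as.numeric(df[[j]]))))
      abort(sprintf("non-numeric or missing value in column '%s' of %s",
                    names(df)[j], basename(path)))
    df[[j]] <- as.numeric(df[[j]])
  }
  out <- as_tibble(df)
  out[[1]] <- dates
  names(out)[1] <- "date"
  out
}

#' Read a station-network CSV
#'
#' Expects the long layout `station_id,lat,lon,year,mean_temp` (the
#' layout of annual-mean station-temperature rectangles).
#'
#' @param path CSV file path.
#' @return Tibble with those five columns.
#' @export
read_station_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("station_id", "lat", "lon", "year", "mean_temp")
  if (!all(need %in% names(df)))
    abort(paste("expected columns:", paste(need, collapse = ",")))
  as_tibble(df[, need])
}

#' Write a spectrum (with optional surrogate bands) to CSV
#'
#' @param spectrum An `ecots_spectrum` or `ecots_cospectrum` tibble.
#' @param path Output CSV path.
#' @param bands Optional [surrogate_bands()] tibble to append as columns.
#' @return `path`, invisibly.
#' @export
write_spectrum_csv <- function(spectrum, path, bands = NULL) {
  out <- as.data.frame(spectrum)
  if (!is.null(bands)) {
    stopifnot(nrow(bands) == nrow(out))
    out <- cbind(out, as.data.frame(bands)[, setdiff(names(bands),
                                                     c("frequency", "period")),
                                           drop = FALSE])
  }
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
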