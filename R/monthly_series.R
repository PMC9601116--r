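# Monthly time series container and CSV ingestion.

#' Monthly time series with measurement precision
#'
#' @param year,month integer vectors (consecutive calendar months).
#' @param value numeric measurements; `NA` marks masked (missing) months.
#' @param precision the significant digit of the measurements (e.g. 0.01 for
#'   a CO2 record in ppm, 0.1 for temperatures in degrees C), `> 0`.
#' @param name optional series label.
#' @return An object of class `monthly_series`.
#' @export
monthly_series <- function(year, month, value, precision, name = "series") {
  stopifnot(length(year) == length(month), length(month) == length(value),
            is.numeric(precision), precision > 0)
  if (any(month < 1 | month > 12)) stop("month must be in 1..12")
  mi <- year * 12 + (month - 1)
  if (length(mi) > 1 && any(diff(mi) <= 0))
    stop("months must be strictly increasing")
  if (length(mi) > 1 && any(diff(mi) != 1))
    stop("non-monthly cadence: months must be consecutive")
  structure(list(year = as.integer(year), month = as.integer(month),
                 value = as.numeric(value), precision = precision,
                 name = name),
            class = "monthly_series")
}

#' @export
length.monthly_series <- function(x) length(x$value)

#' @export
print.monthly_series <- function(x, ...) {
  n <- length(x$value)
  cat(sprintf("Monthly series '%s': %d months (%d-%02d to %d-%02d), precision %g, %d missing\n",
              x$name, n, x$year[1], x$month[1], x$year[n], x$month[n],
              x$precision, sum(is.na(x$value))))
  invisible(x)
}

#' @export
as.data.frame.monthly_series <- function(x, row.names = NULL, optional = FALSE, ...) {
  data.frame(year = x$year, month = x$month, value = x$value)
}

#' Read a monthly series from CSV
#'
#' Understands two dialects: the NOAA monthly-mean CO2 layout (columns
#' `year`, `month`, and a value column, possibly preceded by `#` comment
#' lines, with negative fill codes for missing months) and a generic
#' two-column `date,value` layout with dates `YYYY-MM` or `YYYY-MM-DD`.
#'
#' @param path CSV file path.
#' @param column_spec list of options: `format` (`"auto"`, `"noaa"`,
#'   `"generic"`), `value_col` (name or index of the value column),
#'   `sentinel` (values at or below this are masked as missing; default
#'   `-99`), `precision`, `name`.
#' @return A [monthly_series()].
#' @export
read_monthly_csv <- function(path, column_spec = list()) {
  if (!file.exists(path)) stop("file not found: ", path)
  cs <- utils::modifyList(list(format = "auto", value_col = NULL,
                               sentinel = -99, precision = NULL,
                               name = basename(path)), column_spec)
  df <- tryCatch(
    utils::read.csv(path, comment.char = "#", strip.white = TRUE),
    error = function(e) stop("unparseable CSV '", path, "': ", conditionMessage(e)))
  names(df) <- tolower(names(df))
  fmt <- cs$format
  if (fmt == "auto")
    fmt <- if (all(c("year", "month") %in% names(df))) "noaa" else "generic"
  if (fmt == "noaa") {
    if (!all(c("year", "month") %in% names(df)))
      stop("NOAA layout requires 'year' and 'month' columns")
    vcol <- cs$value_col
    if (is.null(vcol)) {
      cand <- intersect(c("average", "value", "mean", "monthly_average"), names(df))
      vcol <- if (length(cand)) cand[1] else setdiff(names(df), c("year", "month"))[1]
    }
    year <- df$year; month <- df$month; value <- as.numeric(df[[vcol]])
  } else {
    if (ncol(df) < 2) stop("generic layout requires date and value columns")
    dates <- as.character(df[[1]])
    parts <- regmatches(dates, regexec("^(\\d{4})-(\\d{2})", dates))
    bad <- which(vapply(parts, length, 1L) != 3)
    if (length(bad))
      stop("unparseable date(s) at data row(s): ", paste(utils::head(bad, 5), collapse = ", "))
    year <- as.integer(vapply(parts, `[`, "", 2))
    month <- as.integer(vapply(parts, `[`, "", 3))
    vcol <- if (is.null(cs$value_col)) 2 else cs$value_col
    value <- as.numeric(df[[vcol]])
  }
  nonnum <- which(is.na(value) & !is.na(df[[vcol]]))
  if (length(nonnum))
    stop("non-numeric value(s) at data row(s): ", paste(utils::head(nonnum, 5), collapse = ", "))
  value[value <= cs$sentinel] <- NA            # fill codes masked, not dropped
  prec <- cs$precision
  if (is.null(prec)) {
    # infer from the finest decimal place present
    dec <- nchar(sub("^[^.]*\\.?", "", format(value[!is.na(value)], trim = TRUE)))
    prec <- 10^(-max(dec, 0))
  }
  monthly_series(year, month, value, precision = prec, name = cs$name)
}

#' Write a monthly series to a generic CSV
#'
#' Two columns, `date` (`YYYY-MM`) and `value`; missing months are written as
#' the sentinel `-99.99`.  Round-trips through [read_monthly_csv()].
#'
#' @param series a [monthly_series()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_monthly_csv <- function(series, path) {
  stopifnot(inherits(series, "monthly_series"))
  v <- series$value
  v[is.na(v)] <- -99.99
  utils::write.csv(data.frame(
    date = sprintf("%04d-%02d", series$year, series$month),
    value = v), path, row.names = FALSE)
  invisible(path)
}
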