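# Readers and writers for the two tabular dialects the pipeline consumes:
# the GBD results CSV (measure, location, sex, age, cause, metric, year,
# val, upper, lower) and World Bank-style indicator tables (tidy or wide).

.gbd_cols <- c("measure", "location", "sex", "age", "cause", "metric",
               "year", "val", "upper", "lower")

#' Read a GBD-results-dialect DALY CSV
#'
#' @param path CSV file with columns \code{measure, location, sex, age,
#'   cause, metric, year, val, upper, lower}.
#' @param metric Required metric value (default \code{"Number"}).
#' @return DALY table data frame.
#' @export
read_gbd_csv <- function(path, metric = "Number") {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                error = function(e)
                  stop("schema error: unreadable or empty file ", path,
                       call. = FALSE))
  if (!nrow(d)) stop("schema error: empty file ", path)
  miss <- setdiff(.gbd_cols, names(d))
  if (length(miss))
    stop("schema error: missing column(s) ", paste(miss, collapse = ", "))
  for (col in c("year", "val", "upper", "lower")) {
    v <- suppressWarnings(as.numeric(d[[col]]))
    bad <- which(is.na(v) & !is.na(d[[col]]))
    if (length(bad))
      stop(sprintf("malformed numeric in column '%s', row(s) %s", col,
                   paste(utils::head(bad, 5), collapse = ", ")))
    d[[col]] <- v
  }
  if (!all(d$metric == metric))
    stop("expected metric '", metric, "', found: ",
         paste(setdiff(unique(d$metric), metric), collapse = ", "))
  bad <- which(d$upper < d$lower)
  if (length(bad))
    stop("upper < lower in row(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  d[.gbd_cols]
}

#' Write a DALY table in the GBD results dialect
#'
#' @param dalys DALY table (see \code{\link{gen_daly_table}}).
#' @param path Output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_gbd_csv <- function(dalys, path) {
  miss <- setdiff(.gbd_cols, names(dalys))
  if (length(miss))
    stop("missing column(s) ", paste(miss, collapse = ", "))
  utils::write.csv(dalys[.gbd_cols], path, row.names = FALSE)
  invisible(path)
}

#' Read a World Bank-style indicator CSV
#'
#' Accepts either the tidy dialect (columns \code{country}, \code{year},
#' \code{value}, optionally \code{iso3}/\code{indicator}) or the wide
#' dialect (a \code{country} column plus one column per year, e.g.
#' \code{X1990} or \code{1990}). The dialect is auto-detected. Missing cells
#' stay missing (\code{NA}), never zero.
#'
#' @param path CSV path.
#' @param indicator Name recorded in the output's \code{indicator} column.
#' @return Tidy data frame (\code{country}, \code{year}, \code{indicator},
#'   \code{value}).
#' @export
read_worldbank_csv <- function(path, indicator = "value") {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  nm <- names(d)
  if (all(c("country", "year", "value") %in% nm)) {
    out <- data.frame(country = d$country, year = as.integer(d$year),
                      indicator = indicator,
                      value = as.numeric(d$value),
                      stringsAsFactors = FALSE)
  } else if ("country" %in% nm) {
    yr_cols <- grep("^X?[0-9]{4}$", nm, value = TRUE)
    if (!length(yr_cols))
      stop("schema error: neither tidy (country, year, value) nor wide ",
           "(country + year columns) dialect in ", path)
    years <- as.integer(sub("^X", "", yr_cols))
    out <- data.frame(
      country = rep(d$country, times = length(yr_cols)),
      year = rep(years, each = nrow(d)),
      indicator = indicator,
      value = as.numeric(unlist(d[yr_cols], use.names = FALSE)),
      stringsAsFactors = FALSE)
  } else stop("schema error: no 'country' column in ", path)
  bad <- which(!is.na(out$value) & !is.finite(out$value))
  if (length(bad))
    stop("non-numeric cell(s) at row(s) ",
         paste(utils::head(bad, 5), collapse = ", "))
  out[order(out$country, out$year), ]
}

#' Write a tidy country-year panel CSV
#'
#' @param panel Data frame with at least \code{country} and \code{year}.
#' @param path Output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_panel_csv <- function(panel, path) {
  stopifnot(all(c("country", "year") %in% names(panel)))
  utils::write.csv(panel, path, row.names = FALSE)
  invisible(path)
}
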