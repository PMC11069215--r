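# Cohort-file ingestion: schema declaration, reading delimited text with
# missing-value handling, and median/mode imputation.

#' Declare a cohort file schema
#'
#' @param covariates character vector of covariate column names.
#' @param kinds character vector of the same length, entries
#'   \code{"continuous"} or \code{"binary"}.
#' @param event,time names of the event-code and time columns.
#' @param n_events,horizon outcome dimensions E and T.
#' @param labels optional character vector of event labels (length E).
#' @return list of class \code{"cohort_schema"}.
#' @export
cohort_schema <- function(covariates, kinds = rep("continuous", length(covariates)),
                          event = "event", time = "time", n_events, horizon,
                          labels = NULL) {
  kinds <- match.arg(kinds, c("continuous", "binary"), several.ok = TRUE)
  if (length(kinds) == 1L) kinds <- rep(kinds, length(covariates))
  if (length(kinds) != length(covariates))
    stop_domain("kinds must match covariates in length")
  structure(list(covariates = covariates, kinds = kinds, event = event,
                 time = time, n_events = as.integer(n_events),
                 horizon = as.integer(horizon),
                 labels = labels %||% paste0("event", seq_len(n_events))),
            class = "cohort_schema")
}

#' Impute missing covariate values
#'
#' Continuous columns receive the median of their observed values; binary
#' columns the most frequent observed value (ties broken toward 0). The
#' number of imputed entries per column is reported via \code{message()}.
#'
#' @param table data.frame of cohort rows.
#' @param schema a [cohort_schema()].
#' @return the table with covariate missingness filled in.
#' @export
impute_missing <- function(table, schema) {
  for (j in seq_along(schema$covariates)) {
    nm <- schema$covariates[j]
    col <- table[[nm]]
    miss <- is.na(col)
    if (!any(miss)) next
    if (all(miss)) stop_domain("column '", nm, "' is entirely missing")
    fill <- if (schema$kinds[j] == "binary") {
      tab <- table(col[!miss])
      modes <- names(tab)[tab == max(tab)]
      as.numeric(if ("0" %in% modes) min(as.numeric(modes)) else modes[1])
    } else {
      median(col[!miss])
    }
    table[[nm]][miss] <- fill
    message(sprintf("imputed %d missing value(s) in '%s' with %g",
                    sum(miss), nm, fill))
  }
  table
}

#' Read a cohort file
#'
#' Reads a comma-separated cohort file (one row per patient, header row),
#' validates it against the schema, imputes missing covariate values with
#' [impute_missing()], and returns a typed dataset. Unknown extra columns
#' are ignored with a warning; missing declared columns and non-integer
#' event/time values are schema errors naming the column.
#'
#' @param path file path.
#' @param schema a [cohort_schema()].
#' @return a [competing_risks_dataset()], row order preserved.
#' @export
read_cohort <- function(path, schema) {
  df <- read.csv(path)
  need <- c(schema$covariates, schema$event, schema$time)
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop_domain("schema error: missing column(s) ",
                paste(sQuote(missing_cols), collapse = ", "))
  extra <- setdiff(names(df), need)
  if (length(extra))
    warning("ignoring unknown column(s) ", paste(sQuote(extra), collapse = ", "))
  for (nm in c(schema$event, schema$time)) {
    v <- df[[nm]]
    if (anyNA(v) || !is.numeric(v) || any(v != as.integer(v)))
      stop_domain("schema error: column '", nm, "' is not integer-coercible")
  }
  if (any(df[[schema$event]] > schema$n_events))
    stop_domain("schema error: column '", schema$event,
                "' contains codes above n_events = ", schema$n_events)
  df <- impute_missing(df, schema)
  competing_risks_dataset(as.matrix(df[schema$covariates]),
                          df[[schema$event]], df[[schema$time]],
                          schema$n_events, schema$horizon)
}
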