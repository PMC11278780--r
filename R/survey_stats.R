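# Infection-frequency arithmetic and survey roll-ups.

#' Infection frequency as a percentage
#'
#' \code{100 * n_infected / n_samples}, rounded half-up to two decimals.
#' The rounding is done in exact integer arithmetic
#' (\code{10000 * n_infected / n_samples} with a half-up carry on the
#' remainder), so results never depend on binary floating point.
#'
#' @param n_infected,n_samples non-negative integer vectors (recycled);
#'   \code{n_samples} must be positive.
#' @return Numeric vector of percentages with two-decimal resolution.
#' @export
#' @examples
#' infection_frequency(36, 44)  # 81.82
#' infection_frequency(1, 12)   # 8.33
infection_frequency <- function(n_infected, n_samples) {
  if (inherits(n_infected, "survey_records")) {
    rec <- n_infected
    n_samples <- rec$n_samples
    n_infected <- rec$n_infected
  }
  n <- max(length(n_infected), length(n_samples))
  n_infected <- rep_len(n_infected, n)
  n_samples <- rep_len(n_samples, n)
  if (any(n_samples <= 0))
    abort_validation("infection frequency undefined for n_samples == 0")
  if (any(n_infected < 0 | n_infected > n_samples))
    abort_validation("n_infected must lie in [0, n_samples]")
  num <- 10000 * as.numeric(n_infected)
  q <- num %/% n_samples
  r <- num %% n_samples
  hundredths <- q + as.numeric(2 * r >= n_samples)
  hundredths / 100
}

#' Aggregate a survey table
#'
#' Exact integer totals plus per-host and per-location roll-ups, each with
#' the recomputed infection frequency.  Aggregates are invariant to record
#' order (roll-ups are key-sorted).
#'
#' @param records a \code{survey_records} data frame
#'   (see \code{\link{read_survey}}).
#' @return A list of class \code{survey_summary}: \code{total_samples},
#'   \code{total_infected}, \code{total_strains}, \code{n_locations},
#'   \code{overall_frequency}, and data frames \code{by_host},
#'   \code{by_location} and \code{records} (the input with a
#'   \code{frequency} column, input order preserved).
#' @export
aggregate_survey <- function(records) {
  empty <- !NROW(records)
  rollup <- function(key) {
    if (empty)
      return(data.frame(key = character(), n_samples = integer(),
                        n_infected = integer(), n_strains = integer(),
                        frequency = numeric(),
                        stringsAsFactors = FALSE,
                        check.names = FALSE))
    agg <- stats::aggregate(
      records[c("n_samples", "n_infected", "n_strains")],
      by = stats::setNames(list(records[[key]]), key), FUN = sum)
    agg <- agg[order(agg[[key]]), , drop = FALSE]
    agg$frequency <- ifelse(agg$n_samples > 0,
                            infection_frequency(pmin(agg$n_infected,
                                                     agg$n_samples),
                                                pmax(agg$n_samples, 1)), NA)
    rownames(agg) <- NULL
    agg
  }
  recs <- if (empty) records else {
    r <- as.data.frame(records)
    r$frequency <- ifelse(r$n_samples > 0,
                          infection_frequency(r$n_infected,
                                              pmax(r$n_samples, 1)), NA)
    r
  }
  total_samples <- if (empty) 0L else sum(records$n_samples)
  total_infected <- if (empty) 0L else sum(records$n_infected)
  structure(list(
    total_samples = total_samples,
    total_infected = total_infected,
    total_strains = if (empty) 0L else sum(records$n_strains),
    n_locations = if (empty) 0L else length(unique(records$location)),
    overall_frequency = if (total_samples > 0)
      infection_frequency(total_infected, total_samples) else NA_real_,
    by_host = rollup("host"),
    by_location = rollup("location"),
    records = recs
  ), class = "survey_summary")
}

#' @export
print.survey_summary <- function(x, ...) {
  cat(sprintf(
    "survey_summary: %d samples, %d infected (%.2f%%), %d strain(s), %d location(s)\n",
    x$total_samples, x$total_infected,
    if (is.na(x$overall_frequency)) 0 else x$overall_frequency,
    x$total_strains, x$n_locations))
  if (nrow(x$by_host)) {
    cat("  by host:\n")
    print(x$by_host, row.names = FALSE)
  }
  invisible(x)
}

#' Write a survey summary
#'
#' Writes the per-record frequency table as TSV and the full summary
#' (totals plus roll-ups) as JSON.
#'
#' @param summary a \code{survey_summary}.
#' @param tsv_path,json_path output paths (either may be \code{NULL} to
#'   skip).
#' @return Invisibly, the paths written.
#' @export
write_survey_summary <- function(summary, tsv_path = NULL, json_path = NULL) {
  if (!is.null(tsv_path)) {
    con <- file(tsv_path, open = "wb")
    utils::write.table(summary$records, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, eol = "\n")
    close(con)
  }
  if (!is.null(json_path))
    jsonlite::write_json(unclass(summary), json_path, auto_unbox = TRUE,
                         pretty = TRUE, dataframe = "rows", na = "null")
  invisible(c(tsv_path, json_path))
}
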