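# Readers/writers for strain presence-absence tables and survey count
# tables.  Marker calls are tri-state: "present", "absent" or "unknown".

.CALL_LEVELS <- c("present", "absent", "unknown")

# Map a raw cell token to a tri-state call; NA when the token is illegal.
parse_call_token <- function(x) {
  x <- trimws(x)
  out <- rep(NA_character_, length(x))
  out[x %in% c("+", "1", "present")] <- "present"
  # hyphen-minus, U+2212 minus, U+2013 en-dash
  out[x %in% c("-", "\u2212", "\u2013", "0", "absent")] <- "absent"
  out[x %in% c("", "?", "NA", "na", "unknown") | is.na(x)] <- "unknown"
  out
}

call_to_token <- function(x)
  c(present = "+", absent = "-", unknown = "?")[x]

# Read a delimited file, sniffing tab vs comma from the header line.
read_delim_sniff <- function(path) {
  if (!file.exists(path))
    abort_validation(sprintf("file not found: %s", path))
  header <- readLines(path, n = 1L, encoding = "UTF-8")
  sep <- if (length(header) && grepl("\t", header)) "\t" else ","
  utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                    colClasses = "character", quote = "\"",
                    comment.char = "", fileEncoding = "UTF-8",
                    blank.lines.skip = TRUE)
}

#' Read strain marker profiles
#'
#' Reads a row-per-strain, column-per-marker table (TSV or CSV; the
#' delimiter is sniffed from the header).  The first column holds the strain
#' id; remaining column headers must resolve, after alias mapping (e.g.
#' \code{"idtO"} to \code{"idtQ"}, delta-R spellings to \code{"ppzA-dR"}),
#' to registered markers.  Cells are tri-state: \code{+}/\code{1}/
#' \code{present} mean present; \code{-} (hyphen or true minus)/\code{0}/
#' \code{absent} mean absent; empty, \code{?} or \code{NA} mean unknown.
#'
#' @param path input file.
#' @param registry marker registry data frame; defaults to
#'   \code{\link{marker_registry}()}.
#' @return An object of class \code{gene_profiles}: a character matrix of
#'   calls (rows = strains, columns = canonical marker ids) with attributes
#'   \code{host} and \code{location} (named vectors, possibly empty).
#' @export
read_profiles <- function(path, registry = marker_registry()) {
  tab <- read_delim_sniff(path)
  if (ncol(tab) < 1L)
    abort_validation(sprintf("%s: no columns", path))
  strain <- trimws(tab[[1L]])
  if (any(!nzchar(strain)))
    abort_validation(sprintf("%s: empty strain id in row(s) %s", path,
                             paste(which(!nzchar(strain)), collapse = ", ")))
  if (anyDuplicated(strain))
    abort_validation(sprintf("%s: duplicate strain id(s): %s", path,
                             paste(unique(strain[duplicated(strain)]),
                                   collapse = ", ")))
  extra <- intersect(tolower(names(tab)), c("host", "location"))
  marker_cols <- setdiff(seq_along(tab)[-1L],
                         which(tolower(names(tab)) %in% extra))
  raw_names <- names(tab)[marker_cols]
  canon <- resolve_marker_names(raw_names)
  bad <- raw_names[!(canon %in% registry$id)]
  if (length(bad))
    abort_validation(sprintf("%s: unresolvable marker column(s): %s", path,
                             paste(bad, collapse = ", ")))
  if (anyDuplicated(canon))
    abort_validation(sprintf("%s: duplicate marker column(s): %s", path,
                             paste(canon[duplicated(canon)], collapse = ", ")))
  calls <- matrix("unknown", nrow = nrow(tab), ncol = length(canon),
                  dimnames = list(strain, canon))
  for (j in seq_along(marker_cols)) {
    v <- parse_call_token(tab[[marker_cols[j]]])
    if (anyNA(v)) {
      i <- which(is.na(v))[1L]
      abort_validation(sprintf(
        "%s: illegal cell value '%s' at row %d (strain %s), column '%s'",
        path, tab[[marker_cols[j]]][i], i, strain[i], raw_names[j]))
    }
    calls[, j] <- v
  }
  unk <- which(calls == "unknown", arr.ind = TRUE)
  if (nrow(unk))
    message(sprintf("%d unknown call(s): %s", nrow(unk),
                    paste(utils::head(paste0(rownames(calls)[unk[, 1]], "/",
                                             colnames(calls)[unk[, 2]]), 10L),
                          collapse = ", ")))
  host <- location <- stats::setNames(character(0), character(0))
  hcol <- which(tolower(names(tab)) == "host")
  if (length(hcol)) host <- stats::setNames(tab[[hcol[1L]]], strain)
  lcol <- which(tolower(names(tab)) == "location")
  if (length(lcol)) location <- stats::setNames(tab[[lcol[1L]]], strain)
  structure(calls, class = "gene_profiles", host = host, location = location)
}

#' Write strain marker profiles
#'
#' Inverse of \code{\link{read_profiles}}: writes the tri-state matrix as a
#' TSV with \code{+}, \code{-} and \code{?} cells.  Reading the file back
#' reproduces the calls exactly.
#'
#' @param profiles a \code{gene_profiles} object.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_profiles <- function(profiles, path) {
  m <- unclass(profiles)
  tok <- matrix(call_to_token(m), nrow = nrow(m), dimnames = dimnames(m))
  df <- data.frame(strain = rownames(m), tok, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

# Extract one strain's calls as a named character vector.
profile_calls <- function(profiles, strain) {
  if (!strain %in% rownames(profiles))
    abort_validation(sprintf("unknown strain id: %s", strain))
  m <- unclass(profiles)
  stats::setNames(m[strain, ], colnames(m))
}

#' @export
print.gene_profiles <- function(x, ...) {
  cat(sprintf("gene_profiles: %d strain(s) x %d marker(s)\n",
              nrow(x), ncol(x)))
  tab <- table(factor(unclass(x), levels = .CALL_LEVELS))
  cat(sprintf("  calls: %d present, %d absent, %d unknown\n",
              tab["present"], tab["absent"], tab["unknown"]))
  invisible(x)
}

#' Read a field-survey count table
#'
#' Expects columns \code{location}, \code{host}, \code{n_samples},
#' \code{n_infected} and optionally \code{n_strains} (TSV or CSV).  Counts
#' must be non-negative integers with \code{n_infected <= n_samples}.
#'
#' @param path input file.
#' @return A data frame of class \code{survey_records}.
#' @export
read_survey <- function(path) {
  tab <- read_delim_sniff(path)
  names(tab) <- tolower(names(tab))
  need <- c("location", "host", "n_samples", "n_infected")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    abort_validation(sprintf("%s: missing column(s): %s", path,
                             paste(miss, collapse = ", ")))
  if (!"n_strains" %in% names(tab))
    tab[["n_strains"]] <- rep("0", nrow(tab))
  rec <- data.frame(location = trimws(tab$location),
                    host = trimws(tab$host),
                    n_samples = suppressWarnings(as.numeric(tab$n_samples)),
                    n_infected = suppressWarnings(as.numeric(tab$n_infected)),
                    n_strains = suppressWarnings(as.numeric(tab$n_strains)),
                    stringsAsFactors = FALSE)
  for (col in c("n_samples", "n_infected", "n_strains")) {
    v <- rec[[col]]
    bad <- is.na(v) | v < 0 | v != floor(v)
    if (any(bad))
      abort_validation(sprintf("%s: column %s must be non-negative integers (row %d)",
                               path, col, which(bad)[1L]))
    rec[[col]] <- as.integer(v)
  }
  over <- rec$n_infected > rec$n_samples
  if (any(over))
    abort_validation(sprintf(
      "%s: n_infected > n_samples in row %d (%s / %s)",
      path, which(over)[1L], rec$location[which(over)[1L]],
      rec$host[which(over)[1L]]))
  class(rec) <- c("survey_records", "data.frame")
  rec
}

#' Write chemotype results as a TSV report
#'
#' Column order is fixed (strain, mating type, ppzA allele, per-cluster
#' pattern codes, producible metabolites, type, safety category) and output
#' is byte-identical across reruns on identical input.
#'
#' @param results a \code{chemotype_results} object from
#'   \code{\link{run_pipeline}}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_results <- function(results, path) {
  if (!length(results))
    abort_validation("no results to write")
  df <- as.data.frame(results)
  con <- file(path, open = "wb")
  on.exit(close(con))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     eol = "\n", fileEncoding = "UTF-8")
  invisible(path)
}

#' Write chemotype results as JSON
#'
#' One object per strain mirroring the full \code{chemotype_result}
#' structure (producible and terminal sets, calls, pattern codes, type,
#' category, warnings).
#'
#' @inheritParams write_results
#' @return \code{path}, invisibly.
#' @export
write_results_json <- function(results, path) {
  if (!length(results))
    abort_validation("no results to write")
  x <- lapply(unclass(results), function(r) {
    r <- unclass(r)
    r$pattern_codes <- as.list(r$pattern_codes)
    r
  })
  jsonlite::write_json(x, path, auto_unbox = TRUE, pretty = TRUE,
                       null = "null")
  invisible(path)
}

#' Path to a bundled example data file
#'
#' The package ships a 20-strain marker-profile table and a six-row survey
#' table for a field study of Epichloe endophytes in Elymus grasses from
#' Northwest China, plus the default pathway-model files.
#'
#' @param file file name under \code{extdata}; with no argument, lists the
#'   available files.
#' @return A file path, or a vector of file names.
#' @export
#' @examples
#' chemotype_example()
#' read_profiles(chemotype_example("elymus_profiles.tsv"))
chemotype_example <- function(file = NULL) {
  if (is.null(file))
    return(list.files(system.file("extdata", package = "chemotypeR"),
                      recursive = TRUE))
  path <- system.file("extdata", file, package = "chemotypeR")
  if (!nzchar(path))
    abort_validation(sprintf("no bundled file '%s'", file))
  path
}
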