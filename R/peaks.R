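#' Residue spans
#'
#' A contiguous span of residue numbers, used to restrict per-residue
#' profiles to a region such as the transmembrane domain.
#'
#' @param start,end First and last residue numbers (inclusive).
#' @param label Text label for the span.
#' @return An object of class `residue_span`.
#' @examples
#' span_length(residue_span(679, 707))  # the integrin beta2 TMD: 29 residues
#' @export
residue_span <- function(start, end, label = "TMD") {
  if (!is_whole(start) || !is_whole(end)) abort("span bounds must be integers")
  if (start > end) abort("`start` must be <= `end`")
  structure(list(start = as.integer(start), end = as.integer(end),
                 label = label),
            class = "residue_span")
}

#' @export
print.residue_span <- function(x, ...) {
  cat(sprintf("<residue_span> %s: %d-%d (%d residues)\n",
              x$label, x$start, x$end, span_length(x)))
  invisible(x)
}

#' @describeIn residue_span Number of residues in a span (`end - start + 1`).
#' @param span A `residue_span`.
#' @export
span_length <- function(span) {
  if (!inherits(span, "residue_span")) abort("`span` must be a residue_span")
  span$end - span$start + 1L
}

in_span <- function(residue_id, span) {
  if (is.null(span)) return(rep(TRUE, length(residue_id)))
  n <- residue_number(residue_id)
  n >= span$start & n <= span$end
}

#' Read a per-residue NMR peak table
#'
#' Reads a TSV of amide peak positions and intensities for one sample
#' condition.  Lines starting with `#` before the header are parsed as
#' `# key: value` condition metadata and attached as the `"condition"`
#' attribute.  Duplicate residue ids are an error; rows with negative
#' intensity are dropped with a row-numbered warning.
#'
#' @param path Path to a TSV with columns `residue` (residue id such as
#'   `"K702"`), `h_shift` (ppm), `n_shift` (ppm), `intensity` (a.u. >= 0).
#' @return A tibble with those four columns and a `"condition"` attribute
#'   (named list, possibly empty).
#' @seealso [write_peak_table()], [csp()], [intensity_ratio()]
#' @export
read_peak_table <- function(path) {
  header_lines <- grep("^#", readLines(path, warn = FALSE), value = TRUE)
  condition <- parse_condition_block(header_lines)
  df <- readr::read_tsv(path, comment = "#",
                        col_types = readr::cols(
                          residue = readr::col_character(),
                          h_shift = readr::col_double(),
                          n_shift = readr::col_double(),
                          intensity = readr::col_double()),
                        progress = FALSE)
  check_columns(df, c("residue", "h_shift", "n_shift", "intensity"), "peak table")
  if (anyDuplicated(df$residue)) {
    abort(sprintf("duplicate residue id(s) in peak table: %s",
                  paste(unique(df$residue[duplicated(df$residue)]), collapse = ", ")))
  }
  bad <- which(!is.na(df$intensity) & df$intensity < 0)
  if (length(bad) > 0) {
    warn(paste0("dropped ", length(bad), " row(s) with negative intensity (row ",
                paste(bad, collapse = ", "), ")"))
    df <- df[-bad, ]
  }
  attr(df, "condition") <- condition
  df
}

parse_condition_block <- function(lines) {
  lines <- sub("^#\\s*", "", lines)
  lines <- lines[grepl(":", lines, fixed = TRUE)]
  if (length(lines) == 0) return(list())
  keys <- trimws(sub(":.*$", "", lines))
  vals <- trimws(sub("^[^:]*:", "", lines))
  as.list(setNames(vals, keys))
}

#' Write a per-residue NMR peak table
#'
#' @param x A peak table tibble (columns `residue`, `h_shift`, `n_shift`,
#'   `intensity`).
#' @param path Output TSV path.
#' @param condition Named list of condition metadata written as a `# key:
#'   value` header block; defaults to the table's `"condition"` attribute.
#' @return `x`, invisibly.
#' @export
write_peak_table <- function(x, path, condition = attr(x, "condition")) {
  check_data_frame(x, "x")
  check_columns(x, c("residue", "h_shift", "n_shift", "intensity"), "peak table")
  hdr <- character()
  if (length(condition) > 0) {
    hdr <- sprintf("# %s: %s", names(condition), unlist(condition))
  }
  tsv <- readr::format_tsv(x[, c("residue", "h_shift", "n_shift", "intensity")])
  writeLines(c(hdr, strsplit(tsv, "\n", fixed = TRUE)[[1]]), path)
  invisible(x)
}
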