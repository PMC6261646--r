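#' Read a table of annotated single-span membrane proteins
#'
#' Reads a tab-separated annotation table of single-span transmembrane
#' proteins.  Each row carries the full sequence, the 1-based inclusive
#' transmembrane-domain (TMD) span, the topology (which terminus is
#' intracellular) and a free-text compartment label.  Rows that violate the
#' record invariants (non-integer span, span outside the sequence, invalid
#' topology or amino-acid codes in the TMD) are dropped with a row-numbered
#' warning; a missing column is an error.
#'
#' @param path Path to a TSV file with header columns `protein_id`,
#'   `sequence`, `tmd_start`, `tmd_end`, `cytoplasmic_terminus`, `location`.
#'
#' @return A tibble with one validated record per row; `tmd_start` and
#'   `tmd_end` are integers and `cytoplasmic_terminus` is `"N"` or `"C"`.
#' @seealso [write_tmd_table()], [gen_tmd_dataset()], [survey_fractions()]
#' @export
read_tmd_table <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  check_columns(raw, c("protein_id", "sequence", "tmd_start", "tmd_end",
                       "cytoplasmic_terminus", "location"), "TMD table")
  validate_tmd_records(raw)
}

validate_tmd_records <- function(raw) {
  start_num <- suppressWarnings(as.numeric(raw$tmd_start))
  end_num <- suppressWarnings(as.numeric(raw$tmd_end))
  seq_up <- toupper(raw$sequence)
  n_seq <- nchar(seq_up)

  problems <- character()
  ok <- rep(TRUE, nrow(raw))
  flag <- function(bad, msg) {
    bad <- which(ok & bad)
    if (length(bad) > 0) {
      problems <<- c(problems, sprintf("row %d: %s", bad, msg))
      ok[bad] <<- FALSE
    }
  }

  flag(!is_whole(start_num) | !is_whole(end_num), "non-integer TMD span")
  flag(start_num < 1 | end_num < start_num, "need 1 <= tmd_start <= tmd_end")
  flag(end_num > n_seq, "tmd_end exceeds sequence length")
  flag(!raw$cytoplasmic_terminus %in% c("N", "C"),
       "cytoplasmic_terminus must be \"N\" or \"C\"")
  tmd <- substr(seq_up, pmax(1, round(start_num)), pmin(n_seq, round(end_num)))
  flag(!vapply(strsplit(tmd, ""), function(ch) all(ch %in% AA_CODES), logical(1)),
       "TMD contains invalid amino-acid codes")

  if (length(problems) > 0) {
    warn(paste0("dropped ", sum(!ok), " invalid record(s):\n  ",
                paste(problems, collapse = "\n  ")))
  }

  tibble(
    protein_id = raw$protein_id[ok],
    sequence = seq_up[ok],
    tmd_start = as.integer(round(start_num[ok])),
    tmd_end = as.integer(round(end_num[ok])),
    cytoplasmic_terminus = raw$cytoplasmic_terminus[ok],
    location = raw$location[ok]
  )
}

#' Write a table of annotated single-span membrane proteins
#'
#' @param records A tibble of TMD records as returned by [read_tmd_table()].
#' @param path Output TSV path.
#' @return `records`, invisibly.
#' @export
write_tmd_table <- function(records, path) {
  check_data_frame(records, "records")
  check_columns(records, c("protein_id", "sequence", "tmd_start", "tmd_end",
                           "cytoplasmic_terminus", "location"), "TMD table")
  readr::write_tsv(records[, c("protein_id", "sequence", "tmd_start", "tmd_end",
                               "cytoplasmic_terminus", "location")], path,
                   progress = FALSE)
  invisible(records)
}

#' Check that both ends of each transmembrane domain are hydrophobic
#'
#' Mirrors the manual curation step applied to predicted TMD spans: a span is
#' kept only when its first and last residues belong to a hydrophobic set.
#'
#' @param records A tibble of TMD records.
#' @param hydrophobic_set Character vector of 1-letter codes accepted as
#'   hydrophobic.  The default is the positive Kyte-Doolittle residues plus
#'   tryptophan: `r paste(HYDROPHOBIC_DEFAULT, collapse = ", ")`.
#' @return `records` with an added logical column `ends_hydrophobic`.
#' @export
validate_hydrophobic_ends <- function(records, hydrophobic_set = HYDROPHOBIC_DEFAULT) {
  check_data_frame(records, "records")
  first <- substr(records$sequence, records$tmd_start, records$tmd_start)
  last <- substr(records$sequence, records$tmd_end, records$tmd_end)
  dplyr::mutate(as_tibble(records),
                ends_hydrophobic = first %in% hydrophobic_set & last %in% hydrophobic_set)
}

basic_categories <- function() c("K_only", "R_only", "K_and_R", "none")

#' Classify transmembrane domains by their basic-residue content
#'
#' A TMD is classified by the presence of lysine and/or arginine anywhere in
#' its span: `K_only`, `R_only`, `K_and_R` or `none`.  Histidine is never
#' counted as basic.
#'
#' @inheritParams validate_hydrophobic_ends
#' @return `records` with an added factor column `basic_class`.
#' @export
classify_basic_content <- function(records) {
  check_data_frame(records, "records")
  tmd <- substr(records$sequence, records$tmd_start, records$tmd_end)
  has_k <- grepl("K", tmd, fixed = TRUE)
  has_r <- grepl("R", tmd, fixed = TRUE)
  cls <- dplyr::case_when(has_k & has_r ~ "K_and_R",
                          has_k ~ "K_only",
                          has_r ~ "R_only",
                          .default = "none")
  dplyr::mutate(as_tibble(records),
                basic_class = factor(cls, levels = basic_categories()))
}

#' Distance of an intramembrane residue from the TMD/CD border
#'
#' The TMD/CD border is the junction between the transmembrane domain and the
#' cytoplasmic domain; distance 1 is the border-most TMD residue.  For a
#' protein whose C-terminus is cytoplasmic the border sits at `tmd_end`, so
#' the distance is `tmd_end - position + 1`; with an intracellular N-terminus
#' it is `position - tmd_start + 1`.  All arguments are recycled.
#'
#' @param position 1-based position in the full sequence; must lie within the
#'   TMD span.
#' @param tmd_start,tmd_end 1-based inclusive TMD span.
#' @param cytoplasmic_terminus `"N"` or `"C"`: which terminus is intracellular.
#' @return Integer vector of border distances (>= 1).
#' @examples
#' border_distance(702, 679, 707, "C")  # the snorkeling Lys of integrin beta2
#' @export
border_distance <- function(position, tmd_start, tmd_end, cytoplasmic_terminus) {
  n <- max(length(position), length(tmd_start), length(tmd_end),
           length(cytoplasmic_terminus))
  position <- rep_len(position, n)
  tmd_start <- rep_len(tmd_start, n)
  tmd_end <- rep_len(tmd_end, n)
  cytoplasmic_terminus <- rep_len(cytoplasmic_terminus, n)
  if (!all(cytoplasmic_terminus %in% c("N", "C"))) {
    abort("`cytoplasmic_terminus` must be \"N\" or \"C\"")
  }
  if (any(position < tmd_start | position > tmd_end)) {
    abort("`position` must lie within the TMD span")
  }
  as.integer(ifelse(cytoplasmic_terminus == "C",
                    tmd_end - position + 1,
                    position - tmd_start + 1))
}

#' Locate every intramembrane basic residue
#'
#' @inheritParams validate_hydrophobic_ends
#' @return A tibble with one row per Lys/Arg found inside a TMD span:
#'   `protein_id`, `residue` (`"K"` or `"R"`), `position` (absolute, 1-based)
#'   and `border_distance`.
#' @export
tmd_basic_hits <- function(records) {
  check_data_frame(records, "records")
  empty <- tibble(protein_id = character(), residue = character(),
                  position = integer(), border_distance = integer())
  if (nrow(records) == 0) return(empty)
  out <- purrr::pmap_dfr(
    records[, c("protein_id", "sequence", "tmd_start", "tmd_end",
                "cytoplasmic_terminus")],
    function(protein_id, sequence, tmd_start, tmd_end, cytoplasmic_terminus) {
      tmd <- strsplit(substr(sequence, tmd_start, tmd_end), "")[[1]]
      idx <- which(tmd %in% c("K", "R"))
      if (length(idx) == 0) return(NULL)
      pos <- tmd_start + idx - 1L
      tibble(protein_id = protein_id, residue = tmd[idx], position = pos,
             border_distance = border_distance(pos, tmd_start, tmd_end,
                                               cytoplasmic_terminus))
    })
  if (nrow(out) == 0) empty else out
}

#' Survey basic-residue content across a protein dataset
#'
#' Computes the percentage of proteins whose TMD contains Lys only, Arg only,
#' both, or neither, together with the histogram of basic-residue distances
#' from the TMD/CD border.  The histogram is reported both per residue (a TMD
#' with several basic residues contributes each of them) and per protein
#' (distinct proteins contributing at each distance).
#'
#' @inheritParams validate_hydrophobic_ends
#' @return An object of class `tmd_survey`: a list with `fractions` (tibble
#'   of `category`, `n`, `percent`), `histogram` (tibble of `residue`,
#'   `border_distance`, `n_residues`, `n_proteins`) and `n_records`.
#' @export
survey_fractions <- function(records) {
  check_data_frame(records, "records")
  if (nrow(records) == 0) {
    abort("`records` must contain at least one protein")
  }
  cls <- classify_basic_content(records)
  counts <- table(cls$basic_class)
  fractions <- tibble(
    category = factor(names(counts), levels = basic_categories()),
    n = as.integer(counts),
    percent = 100 * as.integer(counts) / nrow(records)
  )
  hits <- tmd_basic_hits(records)
  histogram <- hits %>%
    dplyr::group_by(.data$residue, .data$border_distance) %>%
    dplyr::summarise(n_residues = dplyr::n(),
                     n_proteins = dplyr::n_distinct(.data$protein_id),
                     .groups = "drop")
  structure(list(fractions = fractions, histogram = histogram,
                 n_records = nrow(records)),
            class = "tmd_survey")
}

#' @export
print.tmd_survey <- function(x, ...) {
  cat("Intramembrane basic-residue survey over", x$n_records, "proteins\n")
  print(x$fractions)
  cat("Border-distance histogram (", sum(x$histogram$n_residues),
      " basic residues):\n", sep = "")
  print(x$histogram, n = 10)
  invisible(x)
}

#' @describeIn survey_fractions Category fractions as a tibble.
#' @param x A `tmd_survey` object.
#' @param ... Unused.
#' @export
tidy.tmd_survey <- function(x, ...) x$fractions

#' @describeIn survey_fractions One-row summary: record count, percent with
#'   any basic residue, modal border distance.
#' @export
glance.tmd_survey <- function(x, ...) {
  pct_basic <- sum(x$fractions$percent[x$fractions$category != "none"])
  mode_dist <- if (nrow(x$histogram) == 0) NA_integer_ else {
    by_dist <- x$histogram %>%
      dplyr::group_by(.data$border_distance) %>%
      dplyr::summarise(n = sum(.data$n_residues), .groups = "drop")
    by_dist$border_distance[which.max(by_dist$n)]
  }
  tibble(n_records = x$n_records, percent_basic = pct_basic,
         modal_border_distance = mode_dist)
}
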