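#' Donor-dequenching FRET efficiency
#'
#' Computes E = 1 - F_pre/F_post per cell from the mean donor emission
#' intensity before and after acceptor photobleaching.  Values outside
#' \[0, 1\] are physically out of range (e.g. focus drift or bleaching of the
#' donor itself) and are returned flagged rather than clipped, since
#' clipping would bias group means.
#'
#' @param measurements A data frame with strictly positive columns `f_pre`
#'   and `f_post` (donor intensities, a.u.), typically also `cell_id` and
#'   `group`.
#' @return `measurements` as a tibble with added columns `efficiency` and
#'   logical `out_of_range`.
#' @export
fret_efficiency <- function(measurements) {
  check_data_frame(measurements, "measurements")
  check_columns(measurements, c("f_pre", "f_post"), "FRET table")
  if (any(measurements$f_post <= 0) || any(measurements$f_pre <= 0)) {
    abort("donor intensities must be strictly positive")
  }
  out <- dplyr::mutate(as_tibble(measurements),
                       efficiency = 1 - .data$f_pre / .data$f_post,
                       out_of_range = .data$efficiency < 0 | .data$efficiency > 1)
  if (any(out$out_of_range)) {
    warn(sprintf("%d cell(s) with FRET efficiency outside [0, 1] (flagged, not clipped)",
                 sum(out$out_of_range)))
  }
  out
}

#' Quality-control filter on labeling level
#'
#' Keeps cells whose labeling level lies within a relative tolerance band
#' around the cohort median, mirroring the requirement that only cells with
#' comparable labeling enter the FRET quantitation.
#'
#' @param measurements A data frame with a `label_level` column (a.u.).
#' @param label_tolerance Relative half-width of the acceptance band: a cell
#'   is kept when `|label_level - median| <= label_tolerance * median`.
#' @return The kept rows as a tibble; rejected rows are in the `"rejected"`
#'   attribute.
#' @export
fret_qc_filter <- function(measurements, label_tolerance = 0.5) {
  check_data_frame(measurements, "measurements")
  check_columns(measurements, "label_level", "FRET table")
  if (label_tolerance < 0) abort("`label_tolerance` must be >= 0")
  med <- median(measurements$label_level)
  keep <- abs(measurements$label_level - med) <= label_tolerance * med
  out <- as_tibble(measurements)[keep, ]
  attr(out, "rejected") <- as_tibble(measurements)[!keep, ]
  out
}

#' Group summary and pairwise comparison of FRET efficiencies
#'
#' Per-group mean, SEM and n of the donor-dequenching efficiency, plus
#' pairwise two-sample t tests between groups (Welch by default).
#'
#' @param measurements A data frame with a `group` column and either an
#'   `efficiency` column or `f_pre`/`f_post` columns from which efficiencies
#'   are computed via [fret_efficiency()].
#' @param var_equal Use the classical pooled-variance t test instead of the
#'   Welch unequal-variance default.
#' @return An object of class `fret_summary`: a list with `groups` (tibble
#'   of `group`, `n`, `mean_e`, `sem`) and `comparisons` (tibble of
#'   `group1`, `group2`, `mean_diff`, `statistic`, `p.value`; empty with a
#'   single group).
#' @export
fret_group_summary <- function(measurements, var_equal = FALSE) {
  check_data_frame(measurements, "measurements")
  check_columns(measurements, "group", "FRET table")
  if (!"efficiency" %in% names(measurements)) {
    measurements <- suppressWarnings(fret_efficiency(measurements))
  }
  groups <- as_tibble(measurements) %>%
    dplyr::group_by(group = .data$group) %>%
    dplyr::summarise(n = dplyr::n(), mean_e = mean(.data$efficiency),
                     sem = sd(.data$efficiency) / sqrt(dplyr::n()),
                     .groups = "drop")
  if (any(groups$n < 2)) {
    abort(sprintf("every group needs n >= 2 (offending: %s)",
                  paste(groups$group[groups$n < 2], collapse = ", ")))
  }
  labs <- groups$group
  comparisons <- tibble(group1 = character(), group2 = character(),
                        mean_diff = double(), statistic = double(),
                        p.value = double())
  if (length(labs) >= 2) {
    pairs <- combn(as.character(labs), 2)
    comparisons <- purrr::map_dfr(seq_len(ncol(pairs)), function(j) {
      g1 <- pairs[1, j]; g2 <- pairs[2, j]
      e1 <- measurements$efficiency[measurements$group == g1]
      e2 <- measurements$efficiency[measurements$group == g2]
      ht <- t.test(e1, e2, var.equal = var_equal)
      tibble(group1 = g1, group2 = g2, mean_diff = mean(e1) - mean(e2),
             statistic = unname(ht$statistic), p.value = ht$p.value)
    })
  }
  structure(list(groups = groups, comparisons = comparisons,
                 var_equal = var_equal, n_cells = nrow(measurements)),
            class = "fret_summary")
}

#' @export
print.fret_summary <- function(x, ...) {
  cat("FRET efficiency summary (", x$n_cells, " cells, ",
      if (x$var_equal) "pooled" else "Welch", " t test)\n", sep = "")
  print(x$groups)
  if (nrow(x$comparisons) > 0) print(x$comparisons)
  invisible(x)
}

#' @describeIn fret_group_summary Per-group summary as a tibble.
#' @param x A `fret_summary` object.
#' @param ... Unused.
#' @export
tidy.fret_summary <- function(x, ...) x$groups

#' @describeIn fret_group_summary One-row overview: number of groups and
#'   cells, smallest pairwise p-value.
#' @export
glance.fret_summary <- function(x, ...) {
  tibble(n_groups = nrow(x$groups), n_cells = x$n_cells,
         min_p = if (nrow(x$comparisons) > 0) min(x$comparisons$p.value) else NA_real_)
}
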