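#' Weighted amide chemical shift perturbation
#'
#' Per-residue chemical shift perturbation between two conditions, using the
#' weighted 2-norm of the amide 1H and 15N shift changes:
#' \deqn{\Delta\delta = \sqrt{(\Delta\delta_{HN})^2 + (w\,\Delta\delta_{15N})^2}}
#' with 15N weight \eqn{w = 0.154} by default.
#'
#' Residues present in only one table are reported in the `"missing"`
#' attribute, never imputed.
#'
#' @param reference,perturbed Peak tables (see [read_peak_table()]).
#' @param weight Dimensionless 15N scaling factor.
#' @return A tibble of class `csp_profile` with columns `residue`,
#'   `delta_hn`, `delta_n` (signed shift differences, perturbed minus
#'   reference, ppm) and `csp` (ppm, >= 0); attributes `weight` and
#'   `missing`.
#' @export
csp <- function(reference, perturbed, weight = 0.154) {
  check_data_frame(reference, "reference")
  check_data_frame(perturbed, "perturbed")
  joined <- dplyr::inner_join(
    dplyr::select(as_tibble(reference), "residue", ref_h = "h_shift", ref_n = "n_shift"),
    dplyr::select(as_tibble(perturbed), "residue", per_h = "h_shift", per_n = "n_shift"),
    by = "residue")
  if (nrow(joined) == 0) abort("the two peak tables share no residues")
  out <- joined %>%
    dplyr::transmute(residue = .data$residue,
                     delta_hn = .data$per_h - .data$ref_h,
                     delta_n = .data$per_n - .data$ref_n,
                     csp = sqrt(.data$delta_hn^2 + (weight * .data$delta_n)^2))
  attr(out, "weight") <- weight
  attr(out, "missing") <- sort(setdiff(union(reference$residue, perturbed$residue),
                                       joined$residue))
  class(out) <- c("csp_profile", class(out))
  out
}

#' Per-residue peak intensity ratio between two conditions
#'
#' Computes I/I0 for every residue shared by a sample and a reference peak
#' table: the workhorse quantity for dimerization (dimer vs monomer),
#' paramagnetic attenuation (probe vs no probe) and titration analyses.
#' Residues absent from either table, or with a zero reference intensity,
#' are listed in the `"missing"` attribute.
#'
#' @param sample,reference Peak tables; `sample` supplies I, `reference` I0.
#' @param span Optional [residue_span()] restricting the profile (e.g. the
#'   TMD); `NULL` keeps all shared residues.
#' @return A tibble of class `ratio_profile` with columns `residue`,
#'   `intensity`, `intensity_ref` and `ratio`; attributes `missing`,
#'   `numerator` and `denominator` (condition labels when available).
#' @export
intensity_ratio <- function(sample, reference, span = NULL) {
  check_data_frame(sample, "sample")
  check_data_frame(reference, "reference")
  s <- as_tibble(sample)[in_span(sample$residue, span), ]
  r <- as_tibble(reference)[in_span(reference$residue, span), ]
  joined <- dplyr::inner_join(
    dplyr::select(s, "residue", intensity = "intensity"),
    dplyr::select(r, "residue", intensity_ref = "intensity"),
    by = "residue")
  if (nrow(joined) == 0) abort("no shared residues between sample and reference")
  zero <- !is.na(joined$intensity_ref) & joined$intensity_ref == 0
  if (any(zero)) {
    warn(sprintf("%d residue(s) with zero reference intensity moved to the missing list",
                 sum(zero)))
  }
  keep <- joined[!zero, ]
  out <- dplyr::mutate(keep, ratio = .data$intensity / .data$intensity_ref)
  attr(out, "missing") <- sort(c(setdiff(union(s$residue, r$residue), joined$residue),
                                 joined$residue[zero]))
  cond <- function(x) attr(x, "condition")$label %||% NA_character_
  attr(out, "numerator") <- cond(sample)
  attr(out, "denominator") <- cond(reference)
  class(out) <- c("ratio_profile", class(out))
  out
}

#' Paired comparison of two intensity-ratio profiles
#'
#' Classical paired t test over residue-matched I/I0 pairs, as used to
#' compare dimerization of a wild-type and a mutant construct across the
#' same TMD residues.  Residues missing from either profile are dropped and
#' counted.
#'
#' @param profile_a,profile_b `ratio_profile` objects (see
#'   [intensity_ratio()]).
#' @return A one-row tibble: `n_pairs`, `n_dropped`, `mean_diff` (mean of
#'   a - b), `statistic` (t), `p.value` (two-sided), `conf.low`, `conf.high`.
#' @export
dimerization_compare <- function(profile_a, profile_b) {
  check_data_frame(profile_a, "profile_a")
  check_data_frame(profile_b, "profile_b")
  joined <- dplyr::inner_join(
    dplyr::select(as_tibble(profile_a), "residue", a = "ratio"),
    dplyr::select(as_tibble(profile_b), "residue", b = "ratio"),
    by = "residue")
  n_dropped <- length(union(profile_a$residue, profile_b$residue)) - nrow(joined)
  if (nrow(joined) < 3) abort("need at least 3 residue pairs for a paired t test")
  d <- joined$a - joined$b
  if (sd(d) == 0) {
    # degenerate but well-defined: identical profiles are indistinguishable,
    # an exactly constant nonzero shift is detected with certainty
    return(tibble(n_pairs = nrow(joined), n_dropped = n_dropped,
                  mean_diff = mean(d),
                  statistic = if (mean(d) == 0) 0 else sign(mean(d)) * Inf,
                  p.value = if (mean(d) == 0) 1 else 0,
                  conf.low = mean(d), conf.high = mean(d)))
  }
  ht <- t.test(joined$a, joined$b, paired = TRUE)
  tibble(n_pairs = nrow(joined), n_dropped = n_dropped,
         mean_diff = unname(ht$estimate), statistic = unname(ht$statistic),
         p.value = ht$p.value,
         conf.low = ht$conf.int[1], conf.high = ht$conf.int[2])
}

series_ratio_to_reference <- function(series, what) {
  check_data_frame(series, what)
  check_columns(series, c("residue", "ca_ratio", "intensity"), what)
  ref <- series[series$ca_ratio == 0, c("residue", "intensity")]
  if (nrow(ref) == 0) {
    abort(sprintf("`%s` must contain the zero-Ca reference (ca_ratio == 0)", what))
  }
  names(ref)[2] <- "i0"
  out <- dplyr::inner_join(as_tibble(series)[series$ca_ratio != 0, ], ref,
                           by = "residue")
  out <- out[out$i0 > 0, ]
  dplyr::transmute(out, residue = .data$residue, ca_ratio = .data$ca_ratio,
                   r = .data$intensity / .data$i0)
}

#' Calcium double-ratio profile
#'
#' For each residue and Ca level, the titration intensity ratio in the dimer
#' sample divided by the same ratio in the monomer sample:
#' \deqn{R_D/R_M = \frac{(I_{Ca}/I_{0Ca})_{dimer}}{(I_{Ca}/I_{0Ca})_{monomer}}.}
#' Any attenuation applied identically to both samples at a given Ca level
#' (the nonspecific salt effect) cancels, so values above 1 isolate specific
#' destabilization of the dimer by Ca.
#'
#' @param dimer_series,monomer_series Long tibbles with columns `residue`,
#'   `ca_ratio` (molar Ca:phospholipid ratio; the zero-Ca reference rows have
#'   `ca_ratio == 0`) and `intensity`.  [gen_titration()] produces this
#'   layout.
#' @return A tibble of class `double_ratio_profile` with columns `residue`,
#'   `ca_ratio`, `r_dimer`, `r_monomer` and `double_ratio`, defined only
#'   where all four intensities exist with positive denominators; dropped
#'   residues are in the `"missing"` attribute.
#' @export
double_ratio <- function(dimer_series, monomer_series) {
  rd <- series_ratio_to_reference(dimer_series, "dimer_series")
  rm_ <- series_ratio_to_reference(monomer_series, "monomer_series")
  joined <- dplyr::inner_join(dplyr::rename(rd, r_dimer = "r"),
                              dplyr::rename(rm_, r_monomer = "r"),
                              by = c("residue", "ca_ratio"))
  joined <- joined[joined$r_monomer > 0, ]
  if (nrow(joined) == 0) abort("no residue/level pairs with all four intensities")
  out <- dplyr::mutate(joined, double_ratio = .data$r_dimer / .data$r_monomer)
  all_res <- union(dimer_series$residue, monomer_series$residue)
  attr(out, "missing") <- sort(setdiff(all_res, unique(out$residue)))
  class(out) <- c("double_ratio_profile", class(out))
  out
}

#' Summarise a double-ratio profile by Ca level
#'
#' Mean, SD and n of R_D/R_M across residues at each Ca level; the pooled
#' per-level view complementing the per-residue scatter.
#'
#' @param profile A `double_ratio_profile` (see [double_ratio()]).
#' @param span Optional [residue_span()] restricting the residues averaged.
#' @return A tibble with columns `ca_ratio`, `n`, `mean`, `sd`.
#' @export
double_ratio_summary <- function(profile, span = NULL) {
  check_data_frame(profile, "profile")
  x <- as_tibble(profile)[in_span(profile$residue, span), ]
  x %>%
    dplyr::group_by(.data$ca_ratio) %>%
    dplyr::summarise(n = dplyr::n(), mean = mean(.data$double_ratio),
                     sd = sd(.data$double_ratio), .groups = "drop")
}

#' Paramagnetic attenuation profile and depth classification
#'
#' I/I0 between samples with and without a lipid-embedded paramagnetic probe
#' (e.g. 16-doxyl stearic acid), classified per residue by how strongly the
#' probe attenuates the signal: `core` (ratio below the lower cutoff,
#' membrane-buried), `exposed` (above the upper cutoff, solvent-exposed) or
#' `interfacial` in between.
#'
#' @param with_probe,without_probe Peak tables; `with_probe` supplies I.
#' @param thresholds Ordered pair of ratio cutoffs `(low, high)`.  The
#'   defaults (0.4, 0.85) separate "dramatic" from "moderate" attenuation.
#' @inheritParams intensity_ratio
#' @return A `ratio_profile` tibble of class `pre_profile` with an added
#'   factor column `class` (`core` < `interfacial` < `exposed`).
#' @export
pre_profile <- function(with_probe, without_probe, thresholds = c(0.4, 0.85),
                        span = NULL) {
  if (length(thresholds) != 2 || !thresholds[1] < thresholds[2]) {
    abort("`thresholds` must be an increasing pair of ratio cutoffs")
  }
  out <- intensity_ratio(with_probe, without_probe, span = span)
  out <- dplyr::mutate(out, class = factor(
    dplyr::case_when(.data$ratio < thresholds[1] ~ "core",
                     .data$ratio > thresholds[2] ~ "exposed",
                     .default = "interfacial"),
    levels = c("core", "interfacial", "exposed")))
  attr(out, "thresholds") <- thresholds
  class(out) <- unique(c("pre_profile", class(out)))
  out
}
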