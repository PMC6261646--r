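test_that("peak tables round-trip with condition metadata; bad rows are handled", {
  t <- gen_titration(seed = 4)
  tab <- dplyr::filter(t$monomer, ca_ratio == 0)[, c("residue", "h_shift",
                                                     "n_shift", "intensity")]
  path <- withr::local_tempfile(fileext = ".tsv")
  write_peak_table(tab, path, condition = list(label = "monomer", lipid = "POPG"))
  back <- read_peak_table(path)
  expect_equal(as.data.frame(back), as.data.frame(tab), ignore_attr = TRUE)
  expect_equal(attr(back, "condition")$lipid, "POPG")
  expect_equal(nrow(back), 29)

  writeLines(c("residue\th_shift\tn_shift\tintensity",
               "K702\t8.1\t120\t1.0", "K702\t8.2\t121\t0.9"), path)
  expect_error(read_peak_table(path), "duplicate residue")
  writeLines(c("residue\th_shift\tn_shift\tintensity",
               "K702\t8.1\t120\t1.0", "W701\t8.2\t121\t-0.5"), path)
  expect_warning(ok <- read_peak_table(path), "negative intensity")
  expect_equal(ok$residue, "K702")
})

test_that("chemical shift perturbation matches the weighted 2-norm arithmetic", {
  ref <- make_peaks(c("K702", "W701", "I705"), h_shift = c(8.0, 8.2, 8.4),
                    n_shift = c(120, 118, 116))
  expect_equal(csp(ref, ref)$csp, c(0, 0, 0))

  per <- ref
  per$h_shift <- ref$h_shift + c(0.05, 0.03, -0.02)
  per$n_shift <- ref$n_shift + c(0, 0.20, -0.10)
  prof <- csp(ref, per)
  expect_equal(prof$csp[1], 0.05, tolerance = 1e-12)
  expect_equal(prof$csp, oracle_csp(c(0.05, 0.03, -0.02), c(0, 0.20, -0.10)),
               tolerance = 1e-12)
  # frozen value for (0.03, 0.20): sqrt(0.0009 + 0.0308^2)
  expect_equal(prof$csp[2], 0.04299581, tolerance = 1e-7)
})

test_that("CSP is symmetric in the sign of shift differences and zero iff both are", {
  withr::with_seed(31, {
    for (i in 1:25) {
      dh <- rnorm(1, 0, 0.1); dn <- rnorm(1, 0, 0.5); w <- runif(1, 0.1, 0.3)
      ref <- make_peaks("K702")
      plus <- make_peaks("K702", h_shift = 8 + dh, n_shift = 115 + dn)
      minus <- make_peaks("K702", h_shift = 8 - dh, n_shift = 115 - dn)
      # tolerance bounded below by rounding of the shift differences themselves
      expect_equal(csp(ref, plus, weight = w)$csp, csp(ref, minus, weight = w)$csp,
                   tolerance = 1e-8)
      expect_equal(csp(ref, plus, weight = w)$csp, oracle_csp(dh, dn, w),
                   tolerance = 1e-8)
    }
  })
  expect_error(csp(make_peaks("A1"), make_peaks("B2")), "share no residues")
})

test_that("span arithmetic is inclusive", {
  expect_identical(span_length(residue_span(679, 707)), 29L)
  expect_identical(span_length(residue_span(5, 5)), 1L)
  expect_identical(span_length(residue_span(1, 10)), 10L)
  expect_error(residue_span(10, 1), "<=")
})

test_that("intensity ratios are I/I0 with explicit missing accounting", {
  tab <- make_peaks(c("I679", "K702", "L707"), intensity = c(0.8, 0.6, 0.4))
  expect_equal(intensity_ratio(tab, tab)$ratio, c(1, 1, 1))

  samp <- make_peaks(c("I679", "K702"), intensity = c(0.4, 0.3))
  prof <- intensity_ratio(samp, tab)
  expect_equal(prof$ratio, c(0.5, 0.5))
  expect_equal(attr(prof, "missing"), "L707")

  zero <- make_peaks(c("I679", "K702"), intensity = c(0, 0.6))
  expect_warning(pz <- intensity_ratio(samp, zero), "zero reference")
  expect_equal(pz$residue, "K702")
  expect_true("I679" %in% attr(pz, "missing"))
  expect_error(intensity_ratio(make_peaks("A1"), make_peaks("B2")), "shared")
})

test_that("a span restricts the ratio profile to the TMD", {
  t <- gen_titration(seed = 9)
  mono <- dplyr::filter(t$monomer, ca_ratio == 0)
  extra <- dplyr::bind_rows(mono, make_peaks("G660", intensity = 1))
  prof <- intensity_ratio(extra, extra, span = residue_span(679, 707))
  expect_equal(nrow(prof), 29)
  expect_false("G660" %in% prof$residue)
})

test_that("uniform dimer attenuation is recovered as a uniform ratio", {
  t <- gen_titration(attenuation = 0.35, dimer_fraction = function(c) rep(1, length(c)),
                     ca_levels = 0, noise_sd = 0.02, seed = 21)
  prof <- intensity_ratio(
    dplyr::filter(t$dimer, ca_ratio == 0),
    dplyr::filter(t$monomer, ca_ratio == 0))
  expect_equal(mean(prof$ratio), 0.65, tolerance = 0.02)
  expect_true(all(abs(prof$ratio - 0.65) < 5 * 0.02 * sqrt(2)))
})

test_that("the paired dimerization test matches a from-scratch oracle", {
  t <- gen_titration(seed = 2)
  base <- intensity_ratio(dplyr::filter(t$dimer, ca_ratio == 0),
                          dplyr::filter(t$monomer, ca_ratio == 0))
  same <- dimerization_compare(base, base)
  expect_equal(same$statistic, 0)
  expect_equal(same$p.value, 1)

  shifted <- dplyr::mutate(base, ratio = ratio + 0.2 +
                             withr::with_seed(8, rnorm(nrow(base), 0, 0.01)))
  cmp <- dimerization_compare(shifted, base)
  orc <- oracle_paired_t(shifted$ratio, base$ratio)
  expect_equal(cmp$statistic, orc$statistic, tolerance = 1e-10)
  expect_equal(cmp$p.value, orc$p.value, tolerance = 1e-10)
  expect_lt(cmp$p.value, 0.001)
  expect_equal(cmp$n_pairs, 29L)

  # dropped residues are counted, pairs reported as actually matched
  sub <- base[1:20, ]
  cmp2 <- dimerization_compare(shifted, sub)
  expect_equal(cmp2$n_pairs, 20L)
  expect_equal(cmp2$n_dropped, 9L)
  expect_error(dimerization_compare(base[1:2, ], base[1:2, ]), "at least 3")
})

test_that("identically attenuated monomer and dimer give a unit double ratio", {
  t <- gen_titration(noise_sd = 0, dimer_fraction = function(c) rep(0.7, length(c)),
                     seed = 3)
  dr <- double_ratio(t$dimer, t$monomer)
  expect_equal(dr$double_ratio, rep(1, nrow(dr)), tolerance = 1e-12)
})

test_that("a specific dimer recovery factor passes through regardless of salt", {
  res <- paste0("L", 1:5)
  i0_d <- c(1, 2, 0.5, 1.5, 0.8)
  i0_m <- c(2, 1, 1, 1, 1)
  s <- c(1, 0.6, 0.3)        # arbitrary per-level salt factors
  lv <- c(0, 0.05, 0.1)
  dimer <- make_series(res, lv, outer(i0_d, s) * matrix(rep(c(1, 1.25, 1.25),
                                                            each = 5), 5))
  mono <- make_series(res, lv, outer(i0_m, s))
  dr <- double_ratio(dimer, mono)
  expect_equal(dr$double_ratio, rep(1.25, 10), tolerance = 1e-12)
})

test_that("double ratio is invariant to per-level factors applied to both samples", {
  t <- gen_titration(seed = 6)
  ref <- double_ratio(t$dimer, t$monomer)
  apply_factors <- function(series, fac, lv) {
    series$intensity <- series$intensity * fac[match(series$ca_ratio, lv)]
    series
  }
  lv <- t$params$ca_levels
  withr::with_seed(41, {
    for (i in 1:20) {
      fac <- runif(length(lv), 0.2, 2)
      pert <- double_ratio(apply_factors(t$dimer, fac, lv),
                           apply_factors(t$monomer, fac, lv))
      expect_equal(pert$double_ratio, ref$double_ratio, tolerance = 1e-12)
    }
    # power-of-two factors scale mantissas exactly: bitwise identity
    for (i in 1:20) {
      fac <- 2^sample(-4:4, length(lv), replace = TRUE)
      pert <- double_ratio(apply_factors(t$dimer, fac, lv),
                           apply_factors(t$monomer, fac, lv))
      expect_identical(pert$double_ratio, ref$double_ratio)
    }
  })
})

test_that("double ratio requires the zero-Ca reference and drops dead residues", {
  t <- gen_titration(seed = 12)
  no_ref <- dplyr::filter(t$dimer, ca_ratio > 0)
  expect_error(double_ratio(no_ref, t$monomer), "zero-Ca reference")
  # a residue with zero reference intensity in the monomer is excluded
  broken <- t$monomer
  broken$intensity[broken$residue == broken$residue[1] & broken$ca_ratio == 0] <- 0
  dr <- double_ratio(t$dimer, broken)
  expect_false(broken$residue[1] %in% dr$residue)
  expect_true(broken$residue[1] %in% attr(dr, "missing"))
})

test_that("noiseless titrations recover the generative destabilization exactly", {
  t <- gen_titration(noise_sd = 0, seed = 1)
  dr <- double_ratio(t$dimer, t$monomer)
  joined <- dplyr::inner_join(dr, t$truth, by = c("residue", "ca_ratio"))
  expect_equal(joined$double_ratio, joined$g, tolerance = 1e-12)
  top <- max(t$params$ca_levels)
  expect_equal(unique(round(joined$g[joined$ca_ratio == top], 10)), 1.15)
})

test_that("paramagnetic classification follows the ratio cutoffs and depth order", {
  tab <- make_peaks(paste0("A", 1:3), intensity = 1)
  half <- dplyr::mutate(tab, intensity = 0.5)
  prof <- pre_profile(half, tab, thresholds = c(0.3, 0.8))
  expect_true(all(prof$class == "interfacial"))
  same <- pre_profile(tab, tab)
  expect_true(all(same$ratio == 1) && all(same$class == "exposed"))
  expect_error(pre_profile(tab, tab, thresholds = c(0.9, 0.2)), "increasing")

  g <- gen_pre(noise_sd = 0, seed = 5)
  prof <- pre_profile(g$with_probe, g$without_probe)
  joined <- dplyr::inner_join(as_tibble(prof), g$truth, by = "residue")
  # noiseless ratios equal the attenuation model, so classes match the
  # thresholded truth and ordering matches depth ordering
  expect_equal(joined$ratio, joined$ratio_true, tolerance = 1e-12)
  # round away sub-ulp jitter so symmetric depths tie as they should
  expect_equal(rank(round(joined$ratio, 9)), rank(-joined$depth))
  truth_class <- cut(joined$ratio_true, c(-Inf, 0.4, 0.85, Inf),
                     labels = c("core", "interfacial", "exposed"))
  expect_equal(as.character(joined$class), as.character(truth_class))
})
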