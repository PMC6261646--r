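# Deterministic synthetic-data generators.  Every generator runs inside
# withr::with_seed(seed, ...) so identical arguments give identical output,
# and returns its ground truth next to the data.

# default border-distance distribution: concentrated near the TMD/CD border
default_border_probs <- function() {
  setNames(c(0.22, 0.18, 0.14, 0.11, 0.09, 0.08, 0.06, 0.05, 0.04, 0.03),
           as.character(1:10))
}

#' Generate an annotated single-span membrane protein dataset
#'
#' Synthesises TMD annotation records with basic residues planted at known
#' border distances, emulating a curated survey dataset.  Categories are
#' sampled with the given probabilities (remainder: no basic residue); each
#' planted residue's distance from the TMD/CD border is drawn from
#' `border_distance_probs`, resampling (and counting) draws that exceed the
#' TMD length.  The defaults give roughly 43% of proteins a basic residue,
#' consistent with surveys of yeast and human single-span proteins.
#'
#' @param n Number of proteins.
#' @param p_k_only,p_r_only,p_both Category probabilities (sum <= 1).
#' @param border_distance_probs Named numeric vector: probability of each
#'   border distance (names are the distances).
#' @param tmd_lengths Integer vector of TMD lengths to sample uniformly.
#' @param p_bad_ends Probability that a record gets a polar residue at one
#'   TMD end (for testing end-hydrophobicity screening).
#' @param seed Integer seed; identical inputs give identical output.
#' @return A list with `records` (a tibble accepted by the survey
#'   functions), `truth` (list of per-protein `proteins` and per-residue
#'   `hits` tibbles plus the resample count) and `params`.
#' @export
gen_tmd_dataset <- function(n, p_k_only = 0.25, p_r_only = 0.12, p_both = 0.06,
                            border_distance_probs = default_border_probs(),
                            tmd_lengths = 19:25, p_bad_ends = 0, seed = 1L) {
  stopifnot(n >= 1)
  p_none <- 1 - (p_k_only + p_r_only + p_both)
  if (p_none < 0) abort("category probabilities must sum to <= 1")
  dists <- as.integer(names(border_distance_probs))
  if (anyNA(dists) || any(dists < 1)) {
    abort("`border_distance_probs` must be named by positive integer distances")
  }
  withr::with_seed(seed, {
    category <- sample(basic_categories(), n, replace = TRUE,
                       prob = c(p_k_only, p_r_only, p_both, p_none))
    tmd_len <- sample(tmd_lengths, n, replace = TRUE)
    terminus <- sample(c("N", "C"), n, replace = TRUE)
    location <- sample(c("PM", "ER", "Golgi"), n, replace = TRUE,
                       prob = c(0.7, 0.2, 0.1))
    n_resampled <- 0L

    draw_distances <- function(k, len) {
      feasible <- sum(dists <= len)
      if (feasible == 0) abort("no border distance fits inside the TMD length")
      if (k > feasible) {
        # degenerate support: plant the extra residue at the nearest free slot
        d1 <- draw_distances(1, len)
        d2 <- if (d1 < len) d1 + 1L else d1 - 1L
        return(c(d1, d2))
      }
      # rejection-sample distances that fit inside the TMD, all distinct
      repeat {
        d <- dists[sample.int(length(dists), k, replace = FALSE,
                              prob = border_distance_probs)]
        if (all(d <= len)) return(d)
        n_resampled <<- n_resampled + 1L
      }
    }

    rec <- purrr::map(seq_len(n), function(i) {
      len <- tmd_len[i]
      tmd <- sample(HYDROPHOBIC_DEFAULT, len, replace = TRUE)
      plant <- switch(category[i],
                      K_only = "K", R_only = "R",
                      K_and_R = c("K", "R"), none = character())
      d <- if (length(plant) > 0) draw_distances(length(plant), len) else integer()
      # border distance 1 is the TMD residue adjacent to the cytoplasmic end
      idx <- if (terminus[i] == "C") len - d + 1L else d
      tmd[idx] <- plant
      if (runif(1) < p_bad_ends) {
        end_pos <- sample(c(1L, len), 1)
        if (!end_pos %in% idx) tmd[end_pos] <- sample(c("S", "T", "N", "Q", "G"), 1)
      }
      flank_n <- paste(sample(AA_CODES, sample(5:30, 1), replace = TRUE),
                       collapse = "")
      flank_c <- paste(sample(AA_CODES, sample(5:30, 1), replace = TRUE),
                       collapse = "")
      start <- nchar(flank_n) + 1L
      list(sequence = paste0(flank_n, paste(tmd, collapse = ""), flank_c),
           tmd_start = start, tmd_end = start + len - 1L,
           plant = plant, distance = d,
           ends_ok = tmd[1] %in% HYDROPHOBIC_DEFAULT &&
             tmd[len] %in% HYDROPHOBIC_DEFAULT)
    })

    records <- tibble(
      protein_id = sprintf("SYN%05d", seq_len(n)),
      sequence = purrr::map_chr(rec, "sequence"),
      tmd_start = purrr::map_int(rec, "tmd_start"),
      tmd_end = purrr::map_int(rec, "tmd_end"),
      cytoplasmic_terminus = terminus,
      location = location
    )
    proteins <- tibble(protein_id = records$protein_id,
                       category = factor(category, levels = basic_categories()),
                       ends_hydrophobic = purrr::map_lgl(rec, "ends_ok"))
    hits <- purrr::map_dfr(seq_len(n), function(i) {
      r <- rec[[i]]
      if (length(r$plant) == 0) return(NULL)
      idx <- if (terminus[i] == "C") tmd_len[i] - r$distance + 1L else r$distance
      tibble(protein_id = records$protein_id[i], residue = r$plant,
             position = r$tmd_start + idx - 1L,
             border_distance = as.integer(r$distance))
    })

    list(records = records,
         truth = list(proteins = proteins, hits = hits,
                      n_resampled = n_resampled),
         params = list(n = n, p_k_only = p_k_only, p_r_only = p_r_only,
                       p_both = p_both, p_bad_ends = p_bad_ends, seed = seed))
  })
}

# multiplicative intensity noise, truncated so intensities stay positive
intensity_noise <- function(n, sd) {
  if (sd == 0) return(rep(1, n))
  1 + pmax(rnorm(n, 0, sd), -0.9)
}

#' Generate a synthetic calcium titration of monomer and dimer samples
#'
#' Simulates per-residue peak intensities for a monomer and a dimer sample
#' across a Ca titration under the generative model
#' \deqn{I_{mono}(r, c) = I_0(r)\, s(c)\, (1+\epsilon), \qquad
#'       I_{dim}(r, c) = I_0(r)\, (1 - f_D(c)\, a_r)\, s(c)\, (1+\epsilon)}
#' where `s(c)` is the nonspecific salt attenuation common to both samples,
#' `f_D(c)` the dimer fraction and `a_r` the per-residue dimer attenuation
#' amplitude.  The specific destabilization recovered by the double ratio is
#' \deqn{g(r, c) = \frac{1 - f_D(c)\,a_r}{1 - f_D(0)\,a_r},}
#' recorded as ground truth.  The defaults (29 TMD residues, `a = 15/42`,
#' dimer fraction declining linearly from 0.8 to 0.5 across the level grid
#' 0.03-1/6) give g = 1.15 exactly at the top Ca level.
#'
#' @param span A [residue_span()] naming the residues simulated.
#' @param base_intensities Per-residue reference intensities `I_0`;
#'   defaults to Uniform(0.6, 1.4) draws.
#' @param attenuation Per-residue dimer attenuation amplitude(s) in \[0, 1\],
#'   recycled across the span.
#' @param dimer_fraction Function of the Ca level returning the dimer
#'   fraction in (0, 1\]; default declines linearly from 0.8 at level 0 to
#'   0.5 at the top level.
#' @param salt Function of the Ca level returning the nonspecific
#'   attenuation factor in (0, 1\].
#' @param noise_sd Standard deviation of the multiplicative intensity noise
#'   (truncated at -0.9).
#' @param ca_levels Molar Ca:phospholipid ratios; must include 0.
#' @param seed Integer seed.
#' @return A list with `monomer` and `dimer` (long tibbles with columns
#'   `residue`, `ca_ratio`, `h_shift`, `n_shift`, `intensity`, accepted by
#'   [double_ratio()]), `truth` (tibble of `residue`, `ca_ratio`, `g`) and
#'   `params`.
#' @export
gen_titration <- function(span = residue_span(679, 707),
                          base_intensities = NULL,
                          attenuation = 15 / 42,
                          dimer_fraction = NULL,
                          salt = function(c) exp(-4 * c),
                          noise_sd = 0.02,
                          ca_levels = c(0, 0.03, 0.06, 0.10, 0.14, 1 / 6),
                          seed = 1L) {
  if (!0 %in% ca_levels) abort("`ca_levels` must include the zero-Ca reference")
  n_res <- span_length(span)
  a <- rep_len(attenuation, n_res)
  if (any(a < 0 | a > 1)) abort("`attenuation` must lie in [0, 1]")
  if (is.null(dimer_fraction)) {
    top <- max(ca_levels)
    dimer_fraction <- if (top == 0) function(c) rep(0.8, length(c)) else
      function(c) 0.8 - 0.3 * c / top
  }
  withr::with_seed(seed, {
    residues <- paste0(sample(HYDROPHOBIC_DEFAULT, n_res, replace = TRUE),
                       seq(span$start, span$end))
    i0 <- base_intensities %||% runif(n_res, 0.6, 1.4)
    i0 <- rep_len(i0, n_res)
    h_shift <- runif(n_res, 7.5, 9.5)
    n_shift <- runif(n_res, 105, 130)

    fd <- vapply(ca_levels, function(c) dimer_fraction(c)[1], double(1))
    sc <- vapply(ca_levels, function(c) salt(c)[1], double(1))
    if (any(fd <= 0 | fd > 1) || any(sc <= 0 | sc > 1)) {
      abort("`dimer_fraction` and `salt` must map levels into (0, 1]")
    }

    grid <- tidyr::expand_grid(level = seq_along(ca_levels),
                               res = seq_len(n_res))
    mono <- tibble(residue = residues[grid$res], ca_ratio = ca_levels[grid$level],
                   h_shift = h_shift[grid$res], n_shift = n_shift[grid$res],
                   intensity = i0[grid$res] * sc[grid$level] *
                     intensity_noise(nrow(grid), noise_sd))
    dim_ <- tibble(residue = residues[grid$res], ca_ratio = ca_levels[grid$level],
                   h_shift = h_shift[grid$res], n_shift = n_shift[grid$res],
                   intensity = i0[grid$res] * (1 - fd[grid$level] * a[grid$res]) *
                     sc[grid$level] * intensity_noise(nrow(grid), noise_sd))
    fd0 <- fd[which(ca_levels == 0)[1]]
    truth <- tibble(residue = residues[grid$res],
                    ca_ratio = ca_levels[grid$level],
                    g = (1 - fd[grid$level] * a[grid$res]) / (1 - fd0 * a[grid$res]))
    list(monomer = mono, dimer = dim_, truth = truth,
         params = list(span = span, attenuation = a, noise_sd = noise_sd,
                       ca_levels = ca_levels, dimer_fraction = fd,
                       salt = sc, seed = seed))
  })
}

#' Generate a synthetic paramagnetic probe experiment
#'
#' Simulates peak tables with and without a membrane-embedded paramagnetic
#' probe.  Each residue has a membrane immersion depth (Angstrom); the
#' probe attenuates its signal by a monotone decreasing function of depth,
#' so the I/I0 ordering matches the depth ordering.  The default depth
#' profile is V-shaped across the span (deepest mid-TMD), the default
#' attenuation `exp(-depth/6)`.
#'
#' @inheritParams gen_titration
#' @param depths Per-residue membrane depths in Angstrom (>= 0); recycled.
#' @param attenuation_fn Monotone decreasing function mapping depth to the
#'   I/I0 attenuation ratio in (0, 1\].
#' @return A list with `with_probe` and `without_probe` peak tables, `truth`
#'   (tibble of `residue`, `depth`, `ratio_true`) and `params`.
#' @export
gen_pre <- function(span = residue_span(679, 707), depths = NULL,
                    attenuation_fn = function(d) exp(-d / 6),
                    noise_sd = 0.01, seed = 1L) {
  n_res <- span_length(span)
  if (is.null(depths)) {
    mid <- (n_res + 1) / 2
    depths <- pmax(0, 15 - 1.2 * abs(seq_len(n_res) - mid))
  }
  depths <- rep_len(depths, n_res)
  if (any(depths < 0)) abort("`depths` must be >= 0")
  ratio_true <- attenuation_fn(depths)
  if (any(ratio_true <= 0 | ratio_true > 1)) {
    abort("`attenuation_fn` must map depths into (0, 1]")
  }
  withr::with_seed(seed, {
    residues <- paste0(sample(HYDROPHOBIC_DEFAULT, n_res, replace = TRUE),
                       seq(span$start, span$end))
    i0 <- runif(n_res, 0.6, 1.4)
    h_shift <- runif(n_res, 7.5, 9.5)
    n_shift <- runif(n_res, 105, 130)
    without <- tibble(residue = residues, h_shift = h_shift, n_shift = n_shift,
                      intensity = i0 * intensity_noise(n_res, noise_sd))
    with_ <- tibble(residue = residues, h_shift = h_shift, n_shift = n_shift,
                    intensity = i0 * ratio_true * intensity_noise(n_res, noise_sd))
    list(with_probe = with_, without_probe = without,
         truth = tibble(residue = residues, depth = depths,
                        ratio_true = ratio_true),
         params = list(span = span, noise_sd = noise_sd, seed = seed))
  })
}

#' Generate a synthetic acceptor-photobleach FRET cohort
#'
#' Simulates per-cell donor intensities before and after acceptor
#' photobleaching for one or more groups with known true efficiencies:
#' `f_post` is drawn around `bleach_base`, and
#' `f_pre = f_post * (1 - E_true) * (1 + noise)`.  Optional labeling-level
#' outliers (10x the base level) are injected for QC-filter tests.
#'
#' @param groups A data frame with columns `group`, `e_true` (in \[0, 1)),
#'   `n` and `noise_sd`.
#' @param bleach_base Mean post-bleach donor intensity (a.u.).
#' @param label_base Mean labeling level (a.u.).
#' @param outlier_count Number of cells (across all groups) whose
#'   `label_level` is multiplied by `outlier_factor`.
#' @param outlier_factor Labeling multiplier for injected outliers.
#' @param seed Integer seed.
#' @return A list with `measurements` (tibble of `cell_id`, `group`,
#'   `f_pre`, `f_post`, `label_level`), `truth` (the `groups` input plus the
#'   outlier cell ids) and `params`.
#' @export
gen_fret <- function(groups, bleach_base = 1000, label_base = 500,
                     outlier_count = 0, outlier_factor = 10, seed = 1L) {
  check_data_frame(groups, "groups")
  check_columns(groups, c("group", "e_true", "n", "noise_sd"), "FRET groups")
  if (any(groups$e_true < 0 | groups$e_true >= 1)) {
    abort("`e_true` must lie in [0, 1)")
  }
  withr::with_seed(seed, {
    cells <- purrr::pmap_dfr(groups, function(group, e_true, n, noise_sd, ...) {
      f_post <- bleach_base * pmax(1 + rnorm(n, 0, 0.1), 0.1)
      f_pre <- f_post * (1 - e_true) * intensity_noise(n, noise_sd)
      tibble(group = group, f_pre = f_pre, f_post = f_post,
             label_level = label_base * pmax(1 + rnorm(n, 0, 0.1), 0.1))
    })
    cells$cell_id <- sprintf("cell%04d", seq_len(nrow(cells)))
    outliers <- character()
    if (outlier_count > 0) {
      idx <- sample(nrow(cells), outlier_count)
      cells$label_level[idx] <- cells$label_level[idx] * outlier_factor
      outliers <- cells$cell_id[idx]
    }
    list(measurements = cells[, c("cell_id", "group", "f_pre", "f_post",
                                  "label_level")],
         truth = list(groups = as_tibble(groups), outliers = outliers),
         params = list(bleach_base = bleach_base, label_base = label_base,
                       outlier_count = outlier_count, seed = seed))
  })
}

#' Generate synthetic lipid/protein trajectory frames
#'
#' Simulates labeled point clouds emulating membrane simulation snapshots:
#' one headgroup atom per lipid, with the enriched species (POPS) drawn in
#' the inner-leaflet z window from the ring-shaped density
#' \deqn{\rho(r) \propto 1 + A \exp\left(-\frac{(r - r_0)^2}{2\sigma^2}\right)}
#' around `center`, POPC uniform, and protein C-alpha atoms on ideal helix
#' axes with per-frame Gaussian jitter.
#'
#' @param n_frames Number of frames.
#' @param n_pops,n_popc Lipids per species per frame.
#' @param amplitude Enrichment amplitude `A` (0 for uniform POPS).
#' @param center xy center of the enrichment ring (Angstrom).
#' @param r0 Ring radius (Angstrom; 0 concentrates density at the center).
#' @param sigma Ring width (Angstrom).
#' @param region An [sdf_region()] bounding the lipid positions.
#' @param helix_axes Data frame of protein chains: columns `chain`, `x`, `y`
#'   (axis position, Angstrom).
#' @param n_residues C-alpha atoms per chain.
#' @param helix_radius Helix radius for the C-alpha spiral (Angstrom).
#' @param jitter_sd Per-frame Gaussian coordinate jitter (Angstrom).
#' @param seed Integer seed.
#' @return A list with `frames` (tibble accepted by [compute_sdf()]) and
#'   `truth`/`params` recording the generative settings.
#' @export
gen_lipid_frames <- function(n_frames = 50, n_pops = 40, n_popc = 80,
                             amplitude = 2, center = c(0, 0), r0 = 15,
                             sigma = 3, region = sdf_region(),
                             helix_axes = tibble(chain = c("alphaL", "beta2"),
                                                 x = c(-5, 5), y = c(0, 0)),
                             n_residues = 29, helix_radius = 2.3,
                             jitter_sd = 0.3, seed = 1L) {
  if (n_frames < 1) abort("`n_frames` must be >= 1")
  if (amplitude < 0) abort("`amplitude` must be >= 0")
  withr::with_seed(seed, {
    sample_pops_xy <- function(n) {
      # rejection sampling from the ring-enriched density
      out_x <- double(0); out_y <- double(0)
      while (length(out_x) < n) {
        m <- max(2 * (n - length(out_x)), 32)
        px <- runif(m, region$xlim[1], region$xlim[2])
        py <- runif(m, region$ylim[1], region$ylim[2])
        r <- sqrt((px - center[1])^2 + (py - center[2])^2)
        acc <- runif(m) < (1 + amplitude * exp(-(r - r0)^2 / (2 * sigma^2))) /
          (1 + amplitude)
        out_x <- c(out_x, px[acc]); out_y <- c(out_y, py[acc])
      }
      list(x = out_x[seq_len(n)], y = out_y[seq_len(n)])
    }

    theta <- seq_len(n_residues) * 100 * pi / 180  # ~3.6 residues/turn
    ca_z <- seq(-30, 12, length.out = n_residues)

    frames <- purrr::map_dfr(seq_len(n_frames), function(f) {
      ps <- sample_pops_xy(n_pops)
      pops <- tibble(frame = f, species = "POPS", chain = NA_character_,
                     resid = as.character(seq_len(n_pops)), atom = "P",
                     x = ps$x, y = ps$y,
                     z = runif(n_pops, region$zlim[1], region$zlim[2]))
      popc <- tibble(frame = f, species = "POPC", chain = NA_character_,
                     resid = as.character(seq_len(n_popc)), atom = "P",
                     x = runif(n_popc, region$xlim[1], region$xlim[2]),
                     y = runif(n_popc, region$ylim[1], region$ylim[2]),
                     z = runif(n_popc, region$zlim[1], region$zlim[2]))
      prot <- purrr::pmap_dfr(helix_axes, function(chain, x, y, ...) {
        tibble(frame = f, species = "protein", chain = chain,
               resid = as.character(seq_len(n_residues)), atom = "CA",
               x = x + helix_radius * cos(theta) + rnorm(n_residues, 0, jitter_sd),
               y = y + helix_radius * sin(theta) + rnorm(n_residues, 0, jitter_sd),
               z = ca_z + rnorm(n_residues, 0, jitter_sd))
      })
      dplyr::bind_rows(pops, popc, prot)
    })
    list(frames = frames,
         truth = list(amplitude = amplitude, center = center, r0 = r0,
                      sigma = sigma, helix_axes = as_tibble(helix_axes)),
         params = list(n_frames = n_frames, n_pops = n_pops, n_popc = n_popc,
                       jitter_sd = jitter_sd, seed = seed))
  })
}
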