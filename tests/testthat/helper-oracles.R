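# Independent from-scratch arithmetic oracles.  These deliberately avoid the
# package's code paths and stats::t.test so they can certify them.

oracle_csp <- function(d_hn, d_n, weight = 0.154) {
  sqrt(d_hn^2 + (weight * d_n)^2)
}

oracle_paired_t <- function(a, b) {
  d <- a - b
  n <- length(d)
  tstat <- mean(d) / (sd(d) / sqrt(n))
  list(statistic = tstat, p.value = 2 * pt(-abs(tstat), df = n - 1),
       mean_diff = mean(d), n = n)
}

oracle_welch_t <- function(x, y) {
  nx <- length(x); ny <- length(y)
  vx <- sd(x)^2; vy <- sd(y)^2
  se2 <- vx / nx + vy / ny
  tstat <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  list(statistic = tstat, p.value = 2 * pt(-abs(tstat), df = df), df = df)
}

# minimal in-memory peak table
make_peaks <- function(residue, h_shift = 8, n_shift = 115, intensity = 1) {
  tibble::tibble(residue = residue,
                 h_shift = rep_len(h_shift, length(residue)),
                 n_shift = rep_len(n_shift, length(residue)),
                 intensity = rep_len(intensity, length(residue)))
}

# long titration series from per-level intensity vectors (rows = residues)
make_series <- function(residues, levels, intensity_matrix) {
  purrr::map_dfr(seq_along(levels), function(j) {
    tibble::tibble(residue = residues, ca_ratio = levels[j],
                   intensity = intensity_matrix[, j])
  })
}
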