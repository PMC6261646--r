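#' Fit an Indo-1 ratiometric calcium calibration
#'
#' Fits a standard curve relating the Indo-1 F405/F485 emission ratio to
#' known free Ca concentrations.  The default model is the single-site
#' ratiometric (Grynkiewicz-style) form
#' \deqn{[Ca^{2+}]_{free} = K_d^{eff} \frac{R - R_{min}}{R_{max} - R}}
#' fitted by least squares on log-concentration residuals (standards span
#' decades, so log residuals weight them evenly).  A model-free log-linear
#' interpolation is available as a fallback.
#'
#' @param points A data frame of standards with columns `ratio`
#'   (dimensionless F405/F485) and `free_ca` (uM, >= 0).  At least three
#'   points, with ratio strictly increasing in free Ca.
#' @param model `"ratiometric"` or `"loglinear"`.
#' @return An object of class `indo_calibration` holding the standards, the
#'   fitted parameters (`r_min`, `r_max`, `kd` for the ratiometric model)
#'   and the log-space residuals.
#' @seealso [free_calcium()], [indo_ratio()]
#' @export
fit_indo_calibration <- function(points, model = c("ratiometric", "loglinear")) {
  model <- match.arg(model)
  check_data_frame(points, "points")
  check_columns(points, c("ratio", "free_ca"), "calibration standards")
  points <- dplyr::arrange(as_tibble(points), .data$free_ca)
  if (nrow(points) < 3) abort("need at least 3 calibration standards")
  if (any(points$free_ca < 0)) abort("`free_ca` must be >= 0")
  if (any(diff(points$ratio) <= 0)) {
    abort("standards must be strictly monotone: ratio must increase with free Ca")
  }

  params <- NULL
  residuals <- NULL
  if (model == "ratiometric") {
    fit_pts <- points[points$free_ca > 0, ]
    if (nrow(fit_pts) < 3) abort("need at least 3 standards with free_ca > 0")
    rng <- range(points$ratio)
    span <- diff(rng)
    start <- list(r_min = rng[1] - 0.05 * span,
                  r_max = rng[2] + 0.10 * span,
                  kd = median(fit_pts$free_ca))
    dat <- data.frame(log_ca = log(fit_pts$free_ca), ratio = fit_pts$ratio)
    eps <- 1e-8 * max(span, 1)
    fit <- minpack.lm::nlsLM(
      log_ca ~ log(kd) + log(ratio - r_min) - log(r_max - ratio),
      data = dat, start = start,
      lower = c(r_min = -Inf, r_max = max(fit_pts$ratio) + eps, kd = 1e-12),
      upper = c(r_min = min(fit_pts$ratio) - eps, r_max = Inf, kd = Inf),
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15,
                                           ptol = 1e-15))
    cf <- stats::coef(fit)
    params <- list(r_min = unname(cf["r_min"]), r_max = unname(cf["r_max"]),
                   kd = unname(cf["kd"]))
    residuals <- stats::residuals(fit)
  } else {
    pos <- points[points$free_ca > 0, ]
    if (nrow(pos) < 2) abort("log-linear interpolation needs >= 2 standards with free_ca > 0")
    residuals <- rep(0, nrow(pos))  # interpolation passes through the standards
  }

  structure(list(model = model, points = points, params = params,
                 residuals = residuals),
            class = "indo_calibration")
}

#' @export
print.indo_calibration <- function(x, ...) {
  cat("<indo_calibration> model:", x$model, "-", nrow(x$points), "standards\n")
  if (x$model == "ratiometric") {
    cat(sprintf("  r_min = %.4g, r_max = %.4g, Kd_eff = %.4g uM\n",
                x$params$r_min, x$params$r_max, x$params$kd))
  }
  invisible(x)
}

#' @describeIn fit_indo_calibration Fitted parameters as a tibble.
#' @param x An `indo_calibration` object.
#' @param ... Unused.
#' @export
tidy.indo_calibration <- function(x, ...) {
  if (x$model == "ratiometric") {
    tibble(term = c("r_min", "r_max", "kd"),
           estimate = c(x$params$r_min, x$params$r_max, x$params$kd))
  } else {
    tibble(term = character(), estimate = double())
  }
}

#' @describeIn fit_indo_calibration One-row fit overview.
#' @export
glance.indo_calibration <- function(x, ...) {
  tibble(model = x$model, n_points = nrow(x$points),
         rss_log = sum(x$residuals^2))
}

#' Convert a fluorescence ratio to free calcium
#'
#' Inverse-evaluates a fitted Indo-1 calibration.  In ratiometric mode a
#' ratio at or above `r_max` is a saturation error, and a ratio below
#' `r_min` is out of the admissible range; `r_min` itself maps to 0.
#'
#' @param ratio Numeric vector of F405/F485 ratios.
#' @param cal An `indo_calibration` (see [fit_indo_calibration()]).
#' @return Free Ca concentrations (uM).
#' @export
free_calcium <- function(ratio, cal) {
  if (!inherits(cal, "indo_calibration")) abort("`cal` must be an indo_calibration")
  if (cal$model == "ratiometric") {
    p <- cal$params
    if (any(ratio >= p$r_max)) abort("ratio at or above r_max: indicator saturated")
    if (any(ratio < p$r_min)) abort("ratio below fitted r_min")
    p$kd * (ratio - p$r_min) / (p$r_max - ratio)
  } else {
    pos <- cal$points[cal$points$free_ca > 0, ]
    if (any(ratio < min(pos$ratio)) || any(ratio > max(pos$ratio))) {
      abort("ratio outside the interpolation range of the standards")
    }
    exp(approx(pos$ratio, log(pos$free_ca), xout = ratio)$y)
  }
}

#' Forward-evaluate an Indo-1 calibration
#'
#' Predicts the F405/F485 ratio at given free Ca concentrations; the inverse
#' of [free_calcium()] over the admissible range.
#'
#' @param free_ca Free Ca concentrations (uM, >= 0).
#' @inheritParams free_calcium
#' @return Predicted fluorescence ratios.
#' @export
indo_ratio <- function(free_ca, cal) {
  if (!inherits(cal, "indo_calibration")) abort("`cal` must be an indo_calibration")
  if (any(free_ca < 0)) abort("`free_ca` must be >= 0")
  if (cal$model == "ratiometric") {
    p <- cal$params
    (p$r_min + p$r_max * free_ca / p$kd) / (1 + free_ca / p$kd)
  } else {
    pos <- cal$points[cal$points$free_ca > 0, ]
    if (any(free_ca < min(pos$free_ca)) || any(free_ca > max(pos$free_ca))) {
      abort("free_ca outside the interpolation range of the standards")
    }
    approx(log(pos$free_ca), pos$ratio, xout = log(free_ca))$y
  }
}

#' Bicelle q ratio
#'
#' The molar ratio of long-chain phospholipid to the short-chain detergent
#' lipid DHPC, which sets bicelle size (e.g. 72 mM phospholipid over 240 mM
#' DHPC gives q = 0.3).
#'
#' @param long_chain_mM Numeric vector (possibly named by species) of
#'   long-chain lipid concentrations in mM; summed.
#' @param dhpc_mM DHPC concentration in mM (> 0).
#' @return The dimensionless q ratio.
#' @examples
#' bicelle_q(c(POPG = 24, POPC = 48), 240)
#' @export
bicelle_q <- function(long_chain_mM, dhpc_mM) {
  if (any(long_chain_mM < 0)) abort("lipid concentrations must be >= 0")
  if (length(dhpc_mM) != 1 || dhpc_mM <= 0) abort("`dhpc_mM` must be a single value > 0")
  sum(long_chain_mM) / dhpc_mM
}

#' Mole percentages of a lipid mixture
#'
#' @param species_mM Named numeric vector of per-species concentrations
#'   (mM), or a data frame with columns `species` and `mM`.
#' @return A tibble with columns `species`, `mM` and `mole_percent`
#'   (summing to 100).
#' @examples
#' mole_percent(c(POPG = 24, POPC = 48))
#' @export
mole_percent <- function(species_mM) {
  if (is.data.frame(species_mM)) {
    check_columns(species_mM, c("species", "mM"), "lipid mixture")
    species <- species_mM$species
    conc <- species_mM$mM
  } else {
    species <- names(species_mM) %||% paste0("species", seq_along(species_mM))
    conc <- unname(species_mM)
  }
  if (any(conc < 0)) abort("concentrations must be >= 0")
  total <- sum(conc)
  if (total <= 0) abort("total concentration must be > 0")
  tibble(species = species, mM = conc, mole_percent = 100 * conc / total)
}

#' Total calcium at given Ca:phospholipid molar ratios
#'
#' Converts a titration grid of molar Ca:phospholipid ratios into absolute
#' total Ca concentrations (e.g. ratios 1/30 to 1/6 over 72 mM phospholipid
#' give 2.4 to 12 mM Ca, printed as the rounded ratios 0.03-0.17).
#'
#' @param ratios Numeric vector of Ca:phospholipid molar ratios (>= 0).
#' @param phospholipid_mM Total phospholipid concentration in mM (> 0).
#' @return A tibble with columns `ca_to_lipid` and `ca_mM`.
#' @export
titration_totals <- function(ratios, phospholipid_mM) {
  if (any(ratios < 0)) abort("`ratios` must be >= 0")
  if (length(phospholipid_mM) != 1 || phospholipid_mM <= 0) {
    abort("`phospholipid_mM` must be a single value > 0")
  }
  tibble(ca_to_lipid = ratios, ca_mM = ratios * phospholipid_mM)
}
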