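#' Axis-aligned analysis region for spatial distribution functions
#'
#' The default region is the inner-leaflet box
#' \[-40, 40\] x \[-40, 40\] x \[-40, 0\] Angstrom, with the membrane plane
#' in xy and the leaflet selected by the z window.
#'
#' @param xlim,ylim,zlim Numeric length-2 lower/upper bounds in Angstrom.
#' @return An object of class `sdf_region`.
#' @export
sdf_region <- function(xlim = c(-40, 40), ylim = c(-40, 40), zlim = c(-40, 0)) {
  for (lim in list(xlim, ylim, zlim)) {
    if (length(lim) != 2 || !all(is.finite(lim)) || lim[1] >= lim[2]) {
      abort("region limits must be finite length-2 vectors with lower < upper")
    }
  }
  structure(list(xlim = xlim, ylim = ylim, zlim = zlim), class = "sdf_region")
}

#' Voxel-based spatial distribution function of a lipid species
#'
#' Counts atoms of one species in each voxel of an axis-aligned region,
#' averaged over frames: the per-voxel mean count is a time-averaged 3-D
#' density whose peaks mark where the species resides with high probability.
#' Voxels are half-open `[lo, hi)` intervals on each axis, so an atom
#' sitting exactly on a voxel boundary is assigned to the higher voxel;
#' atoms outside the region are ignored (but still counted in the per-frame
#' species total used for normalization).
#'
#' @param frames A frame table (see [read_frames()]): columns `frame`,
#'   `species`, `x`, `y`, `z` at minimum.
#' @param species Species label to count (e.g. `"POPS"`).
#' @param region An [sdf_region()]; the voxel edge must divide each extent.
#' @param voxel_edge Voxel edge length in Angstrom.
#' @return An object of class `sdf_grid`: the 3-D array of per-voxel mean
#'   counts plus region/voxel metadata, the number of frames, and the mean
#'   per-frame species atom counts in total and in region.
#' @export
compute_sdf <- function(frames, species, region = sdf_region(), voxel_edge = 1) {
  check_data_frame(frames, "frames")
  check_columns(frames, c("frame", "species", "x", "y", "z"), "frame table")
  if (!inherits(region, "sdf_region")) abort("`region` must be an sdf_region")
  if (voxel_edge <= 0) abort("`voxel_edge` must be > 0")
  n_frames <- dplyr::n_distinct(frames$frame)
  if (n_frames == 0) abort("`frames` contains no frames")
  dims <- vapply(list(region$xlim, region$ylim, region$zlim),
                 function(lim) diff(lim) / voxel_edge, double(1))
  if (!all(is_whole(dims))) {
    abort("`voxel_edge` must divide the region extents exactly")
  }
  dims <- as.integer(round(dims))

  sel <- frames[frames$species == species, ]
  if (!all(is.finite(sel$x) & is.finite(sel$y) & is.finite(sel$z))) {
    abort("coordinates must be finite")
  }
  inx <- sel$x >= region$xlim[1] & sel$x < region$xlim[2]
  iny <- sel$y >= region$ylim[1] & sel$y < region$ylim[2]
  inz <- sel$z >= region$zlim[1] & sel$z < region$zlim[2]
  inside <- inx & iny & inz
  ix <- floor((sel$x[inside] - region$xlim[1]) / voxel_edge) + 1
  iy <- floor((sel$y[inside] - region$ylim[1]) / voxel_edge) + 1
  iz <- floor((sel$z[inside] - region$zlim[1]) / voxel_edge) + 1
  lin <- (iz - 1) * dims[1] * dims[2] + (iy - 1) * dims[1] + ix
  counts <- tabulate(lin, nbins = prod(dims))

  structure(list(
    counts = array(counts / n_frames, dim = dims),
    region = region, voxel_edge = voxel_edge, n_frames = n_frames,
    species = species,
    atoms_per_frame_total = nrow(sel) / n_frames,
    atoms_per_frame_in_region = sum(inside) / n_frames
  ), class = "sdf_grid")
}

#' @export
print.sdf_grid <- function(x, ...) {
  cat(sprintf("<sdf_grid> %s: %s voxels of %g A, %d frames\n",
              x$species, paste(dim(x$counts), collapse = " x "),
              x$voxel_edge, x$n_frames))
  cat(sprintf("  mean %s atoms/frame: %.2f total, %.2f in region\n",
              x$species, x$atoms_per_frame_total, x$atoms_per_frame_in_region))
  invisible(x)
}

#' Project a spatial distribution function onto the membrane plane
#'
#' Column-sums the voxel grid over z to give a 2-D xy map.  With
#' `normalize = TRUE` the map is divided by a per-frame atom-count
#' denominator so values become per-voxel-column occupancy probabilities
#' (magnitudes around 1e-4 for realistic lipid occupancy).  Because the
#' denominator of such published color scales is ambiguous, both
#' conventions are available: `"all_atoms"` (mean species atoms per frame,
#' so the map sums to the in-region fraction, at most 1) or `"in_region"`
#' (the map sums to exactly 1).
#'
#' @param grid An `sdf_grid` (see [compute_sdf()]).
#' @param normalize Divide by the chosen denominator.
#' @param denominator `"all_atoms"` or `"in_region"`; ignored unless
#'   `normalize = TRUE`.
#' @return An object of class `sdf_map`: the xy value matrix plus metadata.
#' @export
project_xy <- function(grid, normalize = FALSE,
                       denominator = c("all_atoms", "in_region")) {
  if (!inherits(grid, "sdf_grid")) abort("`grid` must be an sdf_grid")
  denominator <- match.arg(denominator)
  values <- apply(grid$counts, c(1, 2), sum)
  if (normalize) {
    denom <- switch(denominator,
                    all_atoms = grid$atoms_per_frame_total,
                    in_region = grid$atoms_per_frame_in_region)
    if (denom > 0) values <- values / denom
  }
  structure(list(values = values, xlim = grid$region$xlim,
                 ylim = grid$region$ylim, voxel_edge = grid$voxel_edge,
                 species = grid$species, normalized = normalize,
                 denominator = if (normalize) denominator else NA_character_),
            class = "sdf_map")
}

#' @export
print.sdf_map <- function(x, ...) {
  cat(sprintf("<sdf_map> %s: %d x %d cells of %g A%s\n", x$species,
              nrow(x$values), ncol(x$values), x$voxel_edge,
              if (x$normalized) paste0(", normalized by ", x$denominator) else ""))
  invisible(x)
}

map_cell_centers <- function(map) {
  xc <- map$xlim[1] + (seq_len(nrow(map$values)) - 0.5) * map$voxel_edge
  yc <- map$ylim[1] + (seq_len(ncol(map$values)) - 0.5) * map$voxel_edge
  list(x = xc, y = yc)
}

#' @export
as_tibble.sdf_map <- function(x, ...) {
  ctr <- map_cell_centers(x)
  tibble(x = rep(ctr$x, times = length(ctr$y)),
         y = rep(ctr$y, each = length(ctr$x)),
         density = as.vector(x$values))
}

#' Time-averaged xy positions of protein C-alpha atoms
#'
#' Per-residue mean xy position of the C-alpha atoms of one protein chain
#' across frames, used to overlay the protein footprint on an SDF
#' projection.
#'
#' @inheritParams compute_sdf
#' @param chain Chain label (e.g. `"beta2"`); must exist among the protein
#'   atoms.
#' @return A tibble with columns `resid`, `x`, `y` and `n_frames`.
#' @export
project_protein_ca <- function(frames, chain) {
  check_data_frame(frames, "frames")
  check_columns(frames, c("frame", "species", "chain", "resid", "atom",
                          "x", "y"), "frame table")
  ca <- frames[frames$species == "protein" & !is.na(frames$chain) &
                 frames$chain == chain & frames$atom == "CA", ]
  if (nrow(ca) == 0) abort(sprintf("no C-alpha atoms found for chain \"%s\"", chain))
  as_tibble(ca) %>%
    dplyr::group_by(resid = .data$resid) %>%
    dplyr::summarise(x = mean(.data$x), y = mean(.data$y),
                     n_frames = dplyr::n_distinct(.data$frame),
                     .groups = "drop")
}

#' Local enrichment score on an xy density map
#'
#' Mean density within a near radius of a center, divided by the mean
#' density in a far annulus: a dimensionless measure of how much a species
#' is enriched around a point (1 for a uniform distribution).
#'
#' @param map An `sdf_map` (see [project_xy()]).
#' @param center xy coordinates of the reference point (Angstrom).
#' @param r_near Radius of the near disc (Angstrom).
#' @param r_far_band Length-2 inner/outer radii of the far annulus; must not
#'   overlap the near disc.
#' @return The enrichment ratio (near mean / far mean).
#' @export
enrichment_score <- function(map, center = c(0, 0), r_near = 5,
                             r_far_band = c(20, 35)) {
  if (!inherits(map, "sdf_map")) abort("`map` must be an sdf_map")
  if (length(r_far_band) != 2 || r_far_band[1] >= r_far_band[2]) {
    abort("`r_far_band` must be an increasing pair of radii")
  }
  if (r_near <= 0 || r_near > r_far_band[1]) {
    abort("bands must not overlap: need 0 < r_near <= r_far_band[1]")
  }
  ctr <- map_cell_centers(map)
  d <- sqrt(outer(ctr$x - center[1], rep(1, length(ctr$y)))^2 +
              outer(rep(1, length(ctr$x)), ctr$y - center[2])^2)
  near <- map$values[d <= r_near]
  far <- map$values[d >= r_far_band[1] & d <= r_far_band[2]]
  if (length(near) == 0 || length(far) == 0) abort("empty near disc or far annulus")
  far_mean <- mean(far)
  if (far_mean == 0) abort("far annulus has zero density; enrichment undefined")
  mean(near) / far_mean
}

#' Radial profile of an xy density map
#'
#' Mean density as a function of distance from a center, binned at the
#' voxel resolution by default.  The radius of the profile's maximum
#' locates a ring-shaped enrichment.
#'
#' @inheritParams enrichment_score
#' @param bin_width Radial bin width (Angstrom).
#' @return A tibble with columns `r` (bin midpoint), `mean_density` and
#'   `n_cells`; empty bins are dropped.
#' @export
sdf_radial_profile <- function(map, center = c(0, 0), bin_width = NULL) {
  if (!inherits(map, "sdf_map")) abort("`map` must be an sdf_map")
  bin_width <- bin_width %||% map$voxel_edge
  ctr <- map_cell_centers(map)
  d <- sqrt(outer(ctr$x - center[1], rep(1, length(ctr$y)))^2 +
              outer(rep(1, length(ctr$x)), ctr$y - center[2])^2)
  bin <- floor(as.vector(d) / bin_width)
  tibble(bin = bin, density = as.vector(map$values)) %>%
    dplyr::group_by(bin = .data$bin) %>%
    dplyr::summarise(mean_density = mean(.data$density),
                     n_cells = dplyr::n(), .groups = "drop") %>%
    dplyr::transmute(r = (.data$bin + 0.5) * bin_width,
                     mean_density = .data$mean_density,
                     n_cells = .data$n_cells)
}
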