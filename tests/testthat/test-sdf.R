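test_that("frame tables round-trip through writer and reader", {
  g <- gen_lipid_frames(n_frames = 2, n_pops = 5, n_popc = 5, n_residues = 4,
                        seed = 1)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_frames(g$frames, path)
  back <- read_frames(path)
  expect_equal(as.data.frame(back), as.data.frame(g$frames))
  expect_equal(dplyr::n_distinct(back$frame), 2)
})

test_that("multi-model PDB files are parsed into frames with species labels", {
  skip_if_not_installed("bio3d")
  path <- withr::local_tempfile(fileext = ".pdb")
  atom_line <- function(serial, name, resn, chain, resno, x, y, z) {
    sprintf("ATOM  %5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
            serial, name, resn, chain, resno, x, y, z, 1, 0)
  }
  writeLines(c(
    "MODEL        1",
    atom_line(1, " CA ", "ALA", "A", 1, 0, 0, 0),
    atom_line(2, " P  ", "POS", "L", 2, 5, 5, -10),
    "ENDMDL",
    "MODEL        2",
    atom_line(1, " CA ", "ALA", "A", 1, 1, 0, 0),
    atom_line(2, " P  ", "POS", "L", 2, 6, 5, -10),
    "ENDMDL",
    "END"), path)
  fr <- read_frames(path)
  expect_equal(dplyr::n_distinct(fr$frame), 2)
  expect_setequal(unique(fr$species), c("protein", "POS"))
  expect_equal(fr$x[fr$species == "protein"], c(0, 1))
})

test_that("voxel counting follows the half-open binning convention", {
  one <- tibble::tibble(frame = 1L, species = "POPS", chain = NA, resid = "1",
                        atom = "P", x = 0.5, y = 0.5, z = -0.5)
  grid <- compute_sdf(one, "POPS")
  expect_equal(sum(grid$counts), 1)
  expect_equal(grid$counts[41, 41, 40], 1)  # voxel [0,1)x[0,1)x[-1,0)

  # an atom exactly on the boundary x = 1 belongs to the higher voxel [1,2)
  bnd <- dplyr::mutate(one, x = 1.0)
  grid <- compute_sdf(bnd, "POPS")
  expect_equal(grid$counts[42, 41, 40], 1)
  expect_error(compute_sdf(one[0, ], "POPS"), "no frames")
  expect_error(compute_sdf(one, "POPS", voxel_edge = 3), "divide")
})

test_that("total grid mass equals the mean in-region atom count per frame", {
  g <- gen_lipid_frames(n_frames = 15, n_pops = 30, n_popc = 50, seed = 9)
  grid <- compute_sdf(g$frames, "POPS")
  pops <- g$frames[g$frames$species == "POPS", ]
  in_region <- pops$x >= -40 & pops$x < 40 & pops$y >= -40 & pops$y < 40 &
    pops$z >= -40 & pops$z < 0
  expect_equal(sum(grid$counts), sum(in_region) / 15, tolerance = 1e-9)
})

test_that("the SDF is equivariant under integer-voxel translations", {
  g <- gen_lipid_frames(n_frames = 4, n_pops = 25, n_popc = 0, seed = 3)
  grid <- compute_sdf(g$frames, "POPS")
  shift <- c(3, -2, 1)
  moved <- dplyr::mutate(g$frames, x = x + shift[1], y = y + shift[2],
                         z = z + shift[3])
  region2 <- sdf_region(c(-40, 40) + shift[1], c(-40, 40) + shift[2],
                        c(-40, 0) + shift[3])
  expect_equal(compute_sdf(moved, "POPS", region = region2)$counts,
               grid$counts)
})

test_that("uniform occupancy stays inside a 5-sigma Poisson band per voxel", {
  n_frames <- 20
  n_atoms <- 4000
  withr::with_seed(55, {
    frames <- tibble::tibble(
      frame = rep(seq_len(n_frames), each = n_atoms),
      species = "POPC", chain = NA_character_, resid = "1", atom = "P",
      x = runif(n_frames * n_atoms, -40, 40),
      y = runif(n_frames * n_atoms, -40, 40),
      z = runif(n_frames * n_atoms, -40, 0))
  })
  grid <- compute_sdf(frames, "POPC", voxel_edge = 4)
  n_vox <- prod(dim(grid$counts))
  lambda <- n_atoms / n_vox            # expected mean count per voxel
  band <- 5 * sqrt(lambda / n_frames)  # sd of a frame-averaged Poisson count
  expect_true(all(abs(grid$counts - lambda) <= band))
})

test_that("xy projection preserves mass and normalizes to an occupancy fraction", {
  g <- gen_lipid_frames(n_frames = 6, n_pops = 20, n_popc = 10, seed = 13)
  grid <- compute_sdf(g$frames, "POPS")
  raw <- project_xy(grid)
  expect_equal(sum(raw$values), sum(grid$counts), tolerance = 1e-12)

  # all POPS are generated inside the region, so the map sums to exactly 1
  norm <- project_xy(grid, normalize = TRUE)
  expect_equal(sum(norm$values), 1, tolerance = 1e-12)

  # single occupied voxel projects to a single xy cell with its value
  one <- tibble::tibble(frame = 1L, species = "POPS", chain = NA, resid = "1",
                        atom = "P", x = 0.5, y = 0.5, z = -0.5)
  m1 <- project_xy(compute_sdf(one, "POPS"))
  expect_equal(sum(m1$values != 0), 1)
  expect_equal(m1$values[41, 41], 1)

  # with out-of-region atoms the all-atoms normalization sums below 1
  out <- dplyr::bind_rows(g$frames,
                          dplyr::mutate(g$frames[g$frames$species == "POPS", ][1:10, ],
                                        z = 10))
  grid2 <- compute_sdf(out, "POPS")
  expect_lt(sum(project_xy(grid2, normalize = TRUE)$values), 1)
  expect_equal(sum(project_xy(grid2, normalize = TRUE,
                              denominator = "in_region")$values), 1,
               tolerance = 1e-12)
})

test_that("protein C-alpha projection averages per residue over frames", {
  g <- gen_lipid_frames(n_frames = 8, n_pops = 5, n_popc = 5, jitter_sd = 0,
                        seed = 2)
  ca <- project_protein_ca(g$frames, "beta2")
  expect_equal(nrow(ca), 29)
  # no jitter: every frame is identical to frame 1
  f1 <- g$frames[g$frames$frame == 1 & g$frames$chain %in% "beta2" &
                   g$frames$atom == "CA", ]
  expect_equal(ca$x[match(f1$resid, ca$resid)], f1$x, tolerance = 1e-12)
  expect_error(project_protein_ca(g$frames, "gamma"), "no C-alpha")

  # centroid of a jittered helix stays on its axis
  g2 <- gen_lipid_frames(n_frames = 25, n_pops = 5, n_popc = 5, seed = 4)
  ca2 <- project_protein_ca(g2$frames, "alphaL")
  expect_lt(sqrt((mean(ca2$x) - (-5))^2 + mean(ca2$y)^2), 0.1)
})

test_that("enrichment scores separate ring-enriched from uniform lipid fields", {
  flat <- gen_lipid_frames(n_frames = 15, n_pops = 120, amplitude = 0, seed = 6)
  m0 <- project_xy(compute_sdf(flat$frames, "POPS", voxel_edge = 4))
  expect_equal(enrichment_score(m0, r_near = 8, r_far_band = c(20, 36)), 1,
               tolerance = 0.15)

  ring0 <- gen_lipid_frames(n_frames = 30, n_pops = 150, amplitude = 2, r0 = 0,
                            seed = 8)
  m <- project_xy(compute_sdf(ring0$frames, "POPS", voxel_edge = 4))
  expect_gt(enrichment_score(m, r_near = 4, r_far_band = c(20, 36)), 1.5)

  zero <- m0
  zero$values[] <- 0
  zero$values[10, 10] <- 1
  expect_error(enrichment_score(zero, r_near = 4, r_far_band = c(20, 36)),
               "zero density")
  expect_error(enrichment_score(m0, r_near = 25, r_far_band = c(20, 36)),
               "overlap")
  expect_error(enrichment_score(m0, r_near = 4, r_far_band = c(36, 20)),
               "increasing")
})

test_that("the radial profile peaks at the generative ring radius", {
  g <- gen_lipid_frames(n_frames = 300, n_pops = 200, n_popc = 0, r0 = 15,
                        seed = 10)
  m <- project_xy(compute_sdf(g$frames, "POPS"), normalize = TRUE)
  prof <- sdf_radial_profile(m)
  prof <- prof[prof$r <= 40, ]  # annuli fully inside the region
  peak <- prof$r[which.max(prof$mean_density)]
  expect_lt(abs(peak - 15), 1)
})
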