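# amino-acid 3-letter codes used to tag protein atoms on PDB import
AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
         "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
         "TYR", "VAL")

#' Read multi-frame labeled 3-D coordinates
#'
#' Reads trajectory snapshots either from a flat tab-separated table
#' (columns `frame`, `species`, `chain`, `resid`, `atom`, `x`, `y`, `z`;
#' `chain` and `resid` may be omitted) or from a multi-model PDB file
#' (`MODEL` records become frames; standard amino-acid residues are tagged
#' with species `"protein"`, other residue names such as `POPS` become the
#' species label).  Coordinates are in Angstrom.  Inconsistent atom counts
#' across frames raise a warning, not an error.
#'
#' @param path Input file path.
#' @param format `"auto"` (by extension), `"table"` or `"pdb"`.  PDB import
#'   requires the bio3d package.
#' @return A tibble with columns `frame`, `species`, `chain`, `resid`,
#'   `atom`, `x`, `y`, `z`.
#' @seealso [write_frames()], [compute_sdf()], [gen_lipid_frames()]
#' @export
read_frames <- function(path, format = c("auto", "table", "pdb")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.pdb$", path, ignore.case = TRUE)) "pdb" else "table"
  }
  frames <- if (format == "pdb") read_frames_pdb(path) else read_frames_table(path)
  per_frame <- table(frames$frame)
  if (length(unique(per_frame)) > 1) {
    warn("atom counts differ across frames; labeling may be inconsistent")
  }
  frames
}

read_frames_table <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    frame = readr::col_integer(), species = readr::col_character(),
    x = readr::col_double(), y = readr::col_double(),
    z = readr::col_double(), .default = readr::col_character()),
    progress = FALSE)
  check_columns(df, c("frame", "species", "atom", "x", "y", "z"), "frame table")
  if (!"chain" %in% names(df)) df$chain <- NA_character_
  if (!"resid" %in% names(df)) df$resid <- NA_character_
  if (!all(is.finite(df$x) & is.finite(df$y) & is.finite(df$z))) {
    abort("coordinates must be finite")
  }
  df[, c("frame", "species", "chain", "resid", "atom", "x", "y", "z")]
}

read_frames_pdb <- function(path) {
  if (!requireNamespace("bio3d", quietly = TRUE)) {
    abort("PDB import requires the bio3d package; use the flat-table format instead")
  }
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  atoms <- pdb$atom
  xyz <- pdb$xyz
  n_models <- nrow(xyz)
  n_atoms <- nrow(atoms)
  species <- ifelse(atoms$resid %in% AA3, "protein", atoms$resid)
  purrr::map_dfr(seq_len(n_models), function(m) {
    coords <- matrix(xyz[m, ], ncol = 3, byrow = TRUE)
    tibble(frame = m, species = species, chain = atoms$chain,
           resid = as.character(atoms$resno), atom = atoms$elety,
           x = coords[, 1], y = coords[, 2], z = coords[, 3])
  })
}

#' Write multi-frame labeled 3-D coordinates as a flat table
#'
#' @param frames A frame table (see [read_frames()]).
#' @param path Output TSV path.
#' @return `frames`, invisibly.
#' @export
write_frames <- function(frames, path) {
  check_data_frame(frames, "frames")
  check_columns(frames, c("frame", "species", "chain", "resid", "atom",
                          "x", "y", "z"), "frame table")
  readr::write_tsv(frames[, c("frame", "species", "chain", "resid", "atom",
                              "x", "y", "z")], path, progress = FALSE)
  invisible(frames)
}
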