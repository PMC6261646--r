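# shared internal helpers (not exported)

# canonical 1-letter amino-acid alphabet
AA_CODES <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
              "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# default hydrophobic set: positive Kyte-Doolittle residues plus Trp
HYDROPHOBIC_DEFAULT <- c("A", "C", "F", "I", "L", "M", "V", "W")

check_columns <- function(df, required, what) {
  miss <- setdiff(required, names(df))
  if (length(miss) > 0) {
    abort(sprintf("%s is missing required column(s): %s",
                  what, paste(miss, collapse = ", ")))
  }
  invisible(df)
}

check_data_frame <- function(x, arg = "x") {
  if (!is.data.frame(x)) {
    abort(sprintf("`%s` must be a data frame", arg))
  }
  invisible(x)
}

# residue ids are "<code><number>" (e.g. "K702"); extract the number
residue_number <- function(residue_id) {
  n <- suppressWarnings(as.integer(gsub("[^0-9]", "", residue_id)))
  if (anyNA(n)) {
    abort("residue ids must contain a residue number (e.g. \"K702\")")
  }
  n
}

is_whole <- function(x, tol = 1e-9) {
  is.finite(x) & abs(x - round(x)) < tol
}
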