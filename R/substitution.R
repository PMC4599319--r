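#' BLOSUM62 substitution matrix over the package alphabet
#'
#' Returns the standard BLOSUM62 matrix (from Biostrings) restricted and
#' extended to this package's amino-acid alphabet. The nonstandard letters
#' U (selenocysteine) and O (pyrrolysine) are not part of published
#' BLOSUM62; they are scored with the X (unknown residue) column, the usual
#' convention for residues outside the scoring model. Exact-match k-tuple
#' scorers never consult this matrix; it is used only by the
#' Needleman-Wunsch distance and the progressive aligner.
#'
#' @return A 25 x 25 integer matrix with row/column names [AA_ALPHABET]
#'   order (20 standard residues then B, Z, X, U, O).
#' @export
blosum62 <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  b <- e$BLOSUM62
  m <- matrix(0L, 25, 25, dimnames = list(AA_ALPHABET, AA_ALPHABET))
  base <- intersect(AA_ALPHABET, rownames(b))
  m[base, base] <- b[base, base]
  for (aa in c("U", "O")) {
    m[aa, base] <- b["X", base]
    m[base, aa] <- b[base, "X"]
    m[aa, c("U", "O")] <- b["X", "X"]
    m[c("U", "O"), aa] <- b["X", "X"]
  }
  m
}

#' Affine gap parameters
#'
#' A gap run of length g costs `open + (g - 1) * extend` score units.
#' Terminal gaps are penalized like internal ones unless `terminal_free`.
#'
#' @param open gap-opening penalty (>= 0 score units).
#' @param extend gap-extension penalty (>= 0, <= open).
#' @param terminal_free if `TRUE`, leading and trailing gap runs are free.
#' @return An object of class `gap_params`.
#' @export
gap_params <- function(open = 11, extend = 1, terminal_free = FALSE) {
  stopifnot(open >= extend, extend >= 0)
  structure(list(open = open, extend = extend,
                 terminal_free = isTRUE(terminal_free)),
            class = "gap_params")
}
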