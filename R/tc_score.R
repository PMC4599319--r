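#' Reference alignment with a core-column mask
#'
#' Wraps an alignment of reference sequences together with a logical mask
#' marking which columns are "core" (structurally reliable). TC scoring is
#' restricted to core columns by default.
#'
#' @param alignment an [msa_alignment()] over the reference ids.
#' @param core_mask logical vector, one entry per alignment column. If
#'   omitted, [default_core_mask()] is used.
#' @return An object of class `ref_alignment`.
#' @export
ref_alignment <- function(alignment, core_mask = NULL) {
  stopifnot(inherits(alignment, "msa_alignment"))
  if (is.null(core_mask)) core_mask <- default_core_mask(alignment)
  if (length(core_mask) != ncol(alignment$mat)) {
    stop("core mask length must equal column count")
  }
  structure(list(alignment = alignment, core_mask = as.logical(core_mask)),
            class = "ref_alignment")
}

#' Default core-column mask: gap-free reference columns
#'
#' Real benchmark masks come from structural annotation; for synthetic
#' references the natural stand-in is to call a column core iff no
#' reference row has a gap in it.
#'
#' @param ref an [msa_alignment()].
#' @return Logical vector of length `ncol(ref$mat)`.
#' @export
default_core_mask <- function(ref) {
  stopifnot(inherits(ref, "msa_alignment"))
  colSums(ref$mat == "-") == 0
}

#' Core-column TC score of a test alignment against a reference
#'
#' For each core column of the reference, collect its cells as (sequence
#' id, residue ordinal) pairs, skipping gaps. The column is correctly
#' aligned iff all those residues sit in one single column of the test
#' alignment. The TC score is the fraction of core columns correctly
#' aligned: 0.0 means no core column was reproduced, 1.0 means all were.
#' Only reference rows participate; other sequences in the test alignment
#' affect the score solely by displacing reference residues.
#'
#' @param test an [msa_alignment()] containing (at least) every reference
#'   id; ungapped test rows must equal the ungapped reference rows.
#' @param ref a [ref_alignment()] (or an [msa_alignment()], in which case
#'   the default mask is applied).
#' @param columns `"core"` (default) scores only masked columns; `"all"`
#'   scores every reference column.
#' @param count_singletons whether a core column whose only residue lies
#'   in a single reference row counts as correct vacuously (default
#'   `TRUE`); if `FALSE`, such columns are dropped from the denominator.
#' @return A `tc_result`: list with `correct_core`, `total_core` and `tc
#'   = correct_core / total_core`.
#' @export
tc_core_score <- function(test, ref, columns = c("core", "all"),
                          count_singletons = TRUE) {
  columns <- match.arg(columns)
  if (inherits(ref, "msa_alignment")) ref <- ref_alignment(ref)
  stopifnot(inherits(test, "msa_alignment"), inherits(ref, "ref_alignment"))
  rmat <- ref$alignment$mat
  rids <- ref$alignment$ids
  missing <- setdiff(rids, test$ids)
  if (length(missing) > 0) {
    stop("reference id(s) missing from test alignment: ",
         paste(missing, collapse = ", "))
  }
  # residue ordinal -> test column, per reference row
  test_col <- vector("list", length(rids))
  for (i in seq_along(rids)) {
    trow <- test$mat[match(rids[i], test$ids), ]
    rrow <- rmat[i, ]
    tres <- trow[trow != "-"]
    rres <- rrow[rrow != "-"]
    if (!identical(paste(tres, collapse = ""), paste(rres, collapse = ""))) {
      stop("ungapped residues differ between test and reference for id '",
           rids[i], "'")
    }
    test_col[[i]] <- which(trow != "-")
  }
  # reference residue ordinals per row, cumulative over columns
  ord <- (rmat != "-") * 1L
  if (ncol(ord) > 1) {
    for (j in 2:ncol(ord)) ord[, j] <- ord[, j] + ord[, j - 1L]
  }
  use <- if (columns == "core") which(ref$core_mask) else seq_len(ncol(rmat))
  correct <- 0L
  total <- 0L
  for (cc in use) {
    rows <- which(rmat[, cc] != "-")
    if (length(rows) == 0) next
    if (length(rows) == 1 && !count_singletons) next
    total <- total + 1L
    cols <- vapply(rows, function(i) test_col[[i]][ord[i, cc]], numeric(1))
    if (length(unique(cols)) == 1L) correct <- correct + 1L
  }
  structure(list(correct_core = correct, total_core = total,
                 tc = if (total >= 1) correct / total else NA_real_),
            class = "tc_result")
}

#' @export
print.tc_result <- function(x, ...) {
  cat(sprintf("TC (core) = %.4f  (%d / %d core columns correct)\n",
              x$tc, x$correct_core, x$total_core))
  invisible(x)
}

#' Read a 0/1 core-column mask from a side-car text file
#' @param path file with one 0/1 per column (whitespace/newline separated).
#' @return Logical vector.
#' @export
read_core_mask <- function(path) {
  v <- scan(path, what = integer(), quiet = TRUE)
  if (!all(v %in% c(0L, 1L))) stop("mask file must contain only 0 and 1")
  v == 1L
}

#' Write a core-column mask as 0/1 text
#' @param mask logical vector.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_core_mask <- function(mask, path) {
  writeLines(paste(as.integer(mask), collapse = " "), path)
  invisible(path)
}
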