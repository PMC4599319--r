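#' Gapped alignment blocks
#'
#' An `msa_alignment` stores rows as a character matrix (one row per
#' sequence, one column per alignment column, cells are residues or
#' `"-"`). Removing the gaps from each row reproduces the input residues
#' exactly, and no column is all-gap.
#'
#' @param ids character vector of row ids.
#' @param rows character vector of equal-length gapped strings, or a
#'   character matrix of single characters.
#' @return An object of class `msa_alignment` (fields `ids`, `mat`).
#' @export
msa_alignment <- function(ids, rows) {
  ids <- as.character(ids)
  if (is.matrix(rows)) {
    mat <- rows
  } else {
    if (length(unique(nchar(rows))) > 1) stop("rows must have equal length")
    mat <- matrix(unlist(strsplit(rows, "")), nrow = length(rows),
                  byrow = TRUE)
  }
  if (nrow(mat) != length(ids)) stop("ids and rows disagree")
  if (anyDuplicated(ids)) stop("duplicate row id")
  if (ncol(mat) > 0 && any(colSums(mat != "-") == 0)) {
    stop("all-gap column in alignment")
  }
  structure(list(ids = ids, mat = mat), class = "msa_alignment")
}

#' Alignment rows as gapped strings
#' @param a an [msa_alignment()].
#' @return Character vector named by id.
#' @export
alignment_rows <- function(a) {
  stopifnot(inherits(a, "msa_alignment"))
  stats::setNames(apply(a$mat, 1, paste, collapse = ""), a$ids)
}

#' @export
print.msa_alignment <- function(x, ...) {
  cat("msa_alignment:", nrow(x$mat), "rows x", ncol(x$mat), "columns\n")
  rows <- alignment_rows(x)
  n <- min(length(rows), 6L)
  for (i in seq_len(n)) {
    r <- rows[i]
    if (nchar(r) > 60) r <- paste0(substr(r, 1, 60), "...")
    cat(sprintf("  %-12s %s\n", x$ids[i], r))
  }
  if (length(rows) > n) cat("  ...\n")
  invisible(x)
}

#' Read an aligned FASTA file
#' @param path path to an aligned FASTA file (rows may contain `-`).
#' @return An [msa_alignment()].
#' @export
read_alignment <- function(path) {
  xs <- Biostrings::readBStringSet(path)
  if (length(xs) == 0) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(xs))
  rows <- toupper(gsub("[*[:space:]]", "", as.character(xs)))
  msa_alignment(ids, rows)
}

# Apply a DP path to an alignment's columns: path positions are 1-based
# column indices into `mat` (0 = new gap column).
apply_path <- function(mat, pos) {
  out <- matrix("-", nrow = nrow(mat), ncol = length(pos))
  nz <- pos > 0
  out[, nz] <- mat[, pos[nz], drop = FALSE]
  out
}

# Per-column residue counts (alphabet x columns), gaps excluded.
profile_counts <- function(mat) {
  n_col <- ncol(mat)
  cnt <- matrix(0, length(AA_ALPHABET), n_col,
                dimnames = list(AA_ALPHABET, NULL))
  ix <- match(mat, AA_ALPHABET)              # NA for gaps
  cols <- rep(seq_len(n_col), each = nrow(mat))
  keep <- !is.na(ix)
  if (any(keep)) {
    tab <- table(factor(ix[keep], levels = seq_along(AA_ALPHABET)),
                 factor(cols[keep], levels = seq_len(n_col)))
    cnt[] <- as.numeric(tab)
  }
  cnt
}

#' Optimal global pairwise alignment (Needleman-Wunsch / Gotoh)
#'
#' Affine-gap global alignment with a three-state DP and deterministic
#' traceback (tie preference: diagonal, then up, then left). Determinism
#' is part of the contract: any instability observed downstream can then
#' be attributed to the guide tree, never to the aligner.
#'
#' @param a,b residue strings (non-empty).
#' @param sub substitution matrix (default [blosum62()]).
#' @param gap a [gap_params()].
#' @param ids row ids for the result (default `"a"`, `"b"`).
#' @return An [msa_alignment()] with attribute `score`.
#' @export
pairwise_nw <- function(a, b, sub = blosum62(), gap = gap_params(),
                        ids = c("a", "b")) {
  stopifnot(nchar(a) >= 1, nchar(b) >= 1)
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  sc <- sub[ca, cb, drop = FALSE]
  res <- .gotoh_align(sc, gap$open, gap$extend, gap$terminal_free)
  mat <- rbind(ifelse(res$a_pos > 0, ca[pmax(res$a_pos, 1)], "-"),
               ifelse(res$b_pos > 0, cb[pmax(res$b_pos, 1)], "-"))
  out <- msa_alignment(ids, mat)
  out$score <- res$score
  out
}

#' Profile-profile alignment of two alignment blocks
#'
#' Global DP over alignment columns where the score of pairing column u of
#' A with column v of B is the average substitution score over all
#' `nrow(A) * nrow(B)` row pairs; pairs involving a gap contribute 0 to
#' the average. Existing gaps are never removed ("once a gap, always a
#' gap"); the DP only inserts whole gap columns into one block or the
#' other. Rows of A precede rows of B in the result.
#'
#' @param A,B [msa_alignment()] blocks with disjoint id sets.
#' @param sub substitution matrix.
#' @param gap a [gap_params()].
#' @return An [msa_alignment()] with attribute `score`.
#' @export
profile_profile_align <- function(A, B, sub = blosum62(), gap = gap_params()) {
  stopifnot(inherits(A, "msa_alignment"), inherits(B, "msa_alignment"))
  if (length(intersect(A$ids, B$ids)) > 0) stop("profiles share ids")
  pa <- profile_counts(A$mat)
  pb <- profile_counts(B$mat)
  sub <- sub[AA_ALPHABET, AA_ALPHABET]  # align to profile row order
  sc <- crossprod(pa, sub %*% pb) / (nrow(A$mat) * nrow(B$mat))
  res <- .gotoh_align(sc, gap$open, gap$extend, gap$terminal_free)
  mat <- rbind(apply_path(A$mat, res$a_pos), apply_path(B$mat, res$b_pos))
  out <- msa_alignment(c(A$ids, B$ids), mat)
  out$score <- res$score
  out
}

#' Progressive alignment along a guide tree
#'
#' Post-order traversal: leaves become single-row alignments; each
#' internal node merges its children with [profile_profile_align()]. At
#' every internal node the two children are ordered canonically (the child
#' containing the smallest leaf label first), so the result is a pure
#' function of the tree *topology*, the sequence contents and the
#' parameters — two guide trees with the same topology yield byte-identical
#' alignments regardless of input-file order. Any forward/reverse
#' difference in output is therefore attributable to the guide tree.
#'
#' @param s a [seq_set()]; ids must match the tree's leaves.
#' @param t a `guide_tree` over the same ids.
#' @param sub substitution matrix.
#' @param gap a [gap_params()].
#' @return An [msa_alignment()] whose rows follow the canonical leaf
#'   order of the tree.
#' @export
progressive_align <- function(s, t, sub = blosum62(), gap = gap_params()) {
  stopifnot(inherits(s, "seq_set"), inherits(t, "guide_tree"))
  leaves <- tree_leaves(t$root)
  if (!setequal(leaves, s$ids) || length(leaves) != length(s$ids)) {
    stop("tree leaves do not match sequence ids")
  }
  lookup <- stats::setNames(s$seqs, s$ids)
  rec <- function(node) {
    if (node$leaf) {
      aln <- msa_alignment(node$label,
                           matrix(strsplit(lookup[[node$label]], "")[[1]],
                                  nrow = 1))
      return(list(aln = aln, min_label = node$label))
    }
    r1 <- rec(node$children[[1]])
    r2 <- rec(node$children[[2]])
    # canonical child order: block holding the smallest leaf label first
    if (sort(c(r1$min_label, r2$min_label), method = "radix")[1L] ==
        r2$min_label) {
      tmp <- r1; r1 <- r2; r2 <- tmp
    }
    list(aln = profile_profile_align(r1$aln, r2$aln, sub = sub, gap = gap),
         min_label = r1$min_label)
  }
  rec(t$root)$aln
}
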