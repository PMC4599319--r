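#' Distance method specification
#'
#' Names one of the five pairwise distance measures implemented here and
#' carries its tuple length:
#' * `clustalo1` — 1-tuple (residue composition) score, scaled by the
#'   shorter sequence length (Clustal Omega's formula family);
#' * `muscle6` — 6-tuple score scaled by the number of 6-tuples in the
#'   shorter sequence (Muscle);
#' * `kalign_mm` — an approximate-string-matching stand-in for Kalign's
#'   Muth-Manber distance, scaled by the longer sequence length;
#' * `mafft6` — 6-tuple score with Mafft's two-stage normalization
#'   `D' = D / f(x, y)`;
#' * `nw` — Needleman-Wunsch fractional-identity distance, the "expensive
#'   accurate" contrast that does not rely on exact word matches.
#'
#' @param name one of `"clustalo1"`, `"muscle6"`, `"kalign_mm"`,
#'   `"mafft6"`, `"nw"`.
#' @param k tuple length; fixed at 1 for `clustalo1` and 6 for `muscle6` /
#'   `mafft6`, default 6 for `kalign_mm`, unused for `nw`.
#' @param params method-specific constants: for `kalign_mm`,
#'   `max_mismatch` (default 1); for `nw`, `sub` (substitution matrix) and
#'   `gap` (a [gap_params()]).
#' @return An object of class `method_spec`.
#' @export
method_spec <- function(name = c("clustalo1", "muscle6", "kalign_mm",
                                 "mafft6", "nw"),
                        k = NULL, params = list()) {
  name <- match.arg(name)
  k <- switch(name,
              clustalo1 = 1L,
              muscle6 = 6L,
              mafft6 = 6L,
              kalign_mm = if (is.null(k)) 6L else as.integer(k),
              nw = NA_integer_)
  if (name == "kalign_mm" && is.null(params$max_mismatch)) {
    params$max_mismatch <- 1L
  }
  structure(list(name = name, k = k, params = params), class = "method_spec")
}

#' Shared k-tuple count between two sequences
#'
#' Counts k-tuple matches in the order-independent multiset form: the sum
#' over distinct k-tuples w of `min(count_a(w), count_b(w))`. This is
#' symmetric in its arguments by construction and reproduces the self-score
#' `L - k + 1` (e.g. `L - 5` six-tuples in a length-L sequence). A scan
#' description that restarts at the next residue after each match can be
#' asymmetric depending on which sequence drives the scan; the multiset
#' form avoids that defect, and [symmetry_audit()] verifies it.
#'
#' @param a,b residue strings.
#' @param k tuple length (>= 1).
#' @return Integer score; 0 when either sequence is shorter than `k`.
#' @examples
#' tuple_count_score("ACADCGKTFSQSSHLVQHRRIH", "ACADCGKTFSQSSHLVQHRRIH", 1)
#' @export
tuple_count_score <- function(a, b, k) {
  stopifnot(k >= 1)
  ta <- seq_tuples(a, k)
  tb <- seq_tuples(b, k)
  if (length(ta) == 0 || length(tb) == 0) return(0L)
  ca <- table(ta)
  cb <- table(tb)
  shared <- intersect(names(ca), names(cb))
  if (length(shared) == 0) return(0L)
  as.integer(sum(pmin(as.integer(ca[shared]), as.integer(cb[shared]))))
}

# All overlapping k-tuples of a residue string (length L - k + 1, or
# character(0) if L < k).
seq_tuples <- function(x, k) {
  L <- nchar(x)
  if (L < k) return(character(0))
  substring(x, 1:(L - k + 1), k:L)
}

#' Clustal Omega-style 1-tuple distance
#'
#' `1 - S1 / min(La, Lb)` where S1 is the shared 1-tuple (residue
#' composition) count: the 1-tuple score scaled by the length of the
#' shorter of the two sequences. With equal-length sequences of length L
#' this can take at most L + 1 distinct values.
#'
#' @param a,b residue strings (non-empty).
#' @return Distance in \[0, 1\].
#' @export
clustalo_distance <- function(a, b) {
  la <- nchar(a); lb <- nchar(b)
  stopifnot(la >= 1, lb >= 1)
  1 - tuple_count_score(a, b, 1L) / min(la, lb)
}

#' Muscle-style 6-tuple distance
#'
#' `1 - S6 / (min(La, Lb) - 5)`: the 6-tuple score scaled by the number of
#' 6-tuples in the shorter sequence. Sequences shorter than 6 residues have
#' no 6-tuples; such degenerate pairs are assigned distance 1 with a
#' warning.
#'
#' @param a,b residue strings.
#' @return Distance in \[0, 1\].
#' @export
muscle_distance <- function(a, b) {
  mn <- min(nchar(a), nchar(b))
  if (mn < 6) {
    warning("sequence shorter than 6 residues: muscle6 distance set to 1")
    return(1)
  }
  1 - tuple_count_score(a, b, 6L) / (mn - 5)
}

#' Kalign-style approximate-matching distance (stand-in)
#'
#' Kalign derives its distances from Muth-Manber approximate string
#' matching. This package does not replicate those internals; it provides a
#' documented stand-in with the same character: the score is the number of
#' k-tuple positions of the shorter sequence that occur anywhere in the
#' longer sequence with at most `max_mismatch` substitutions (brute-force
#' search), the similarity is `score / (min(La, Lb) - k + 1)`, and the
#' resulting distance `1 - similarity` is rescaled by `min(La, Lb) /
#' max(La, Lb)` — i.e. scaling based on the length of the longer sequence —
#' then clipped to \[0, 1\].
#'
#' @param a,b residue strings.
#' @param k tuple length (default 6).
#' @param max_mismatch maximum substitutions per tuple match (default 1).
#' @return Distance in \[0, 1\].
#' @export
kalign_distance <- function(a, b, k = 6L, max_mismatch = 1L) {
  la <- nchar(a); lb <- nchar(b)
  if (min(la, lb) < k) {
    warning("sequence shorter than k residues: kalign_mm distance set to 1")
    return(1)
  }
  # canonical roles: by length, breaking equal lengths lexicographically —
  # otherwise equal-length pairs would score asymmetrically depending on
  # which sequence drives the scan
  if (la > lb || (la == lb && sort(c(a, b), method = "radix")[2L] == a)) {
    lng <- a; shr <- b
  } else {
    lng <- b; shr <- a
  }
  ts <- seq_tuples(shr, k)
  tl <- seq_tuples(lng, k)
  # tuple-vs-tuple Hamming distances via per-position character comparison
  ms <- matrix(unlist(strsplit(ts, "")), nrow = k)
  ml <- matrix(unlist(strsplit(tl, "")), nrow = k)
  score <- 0L
  for (i in seq_along(ts)) {
    mism <- colSums(ml != ms[, i])
    if (any(mism <= max_mismatch)) score <- score + 1L
  }
  d <- (1 - score / length(ts)) * (min(la, lb) / max(la, lb))
  min(max(d, 0), 1)
}

#' Mafft's length-scaling factor f(x, y)
#'
#' `f(x, y) = y/x * 0.1 + 10000 / (x + 10000) + 0.01`, where x and y are
#' the lengths of the longer and shorter sequence respectively. The raw
#' distance D can be near zero when comparing very short and very long
#' sequences even if they are unrelated; dividing by f compensates for
#' that. Because both lengths enter, equal-length datasets with c distinct
#' lengths admit up to c^2 distinct factors.
#'
#' @param x length of the longer sequence (x >= y >= 1).
#' @param y length of the shorter sequence.
#' @return The scaling factor (> 0).
#' @examples
#' mafft_scale_factor(100, 100)
#' @export
mafft_scale_factor <- function(x, y) {
  stopifnot(x >= y, y >= 1)
  y / x * 0.1 + 10000 / (x + 10000) + 0.01
}

#' Mafft-style two-stage 6-tuple distance
#'
#' `D = 1 - S6 / min(Sii, Sjj)` with self-scores `Sii = La - 5` and
#' `Sjj = Lb - 5`, then `D' = D / f(x, y)` with [mafft_scale_factor()].
#' Degenerate pairs (shorter than 6 residues) are treated as D = 1 with a
#' warning.
#'
#' @param a,b residue strings.
#' @return An object of class `pair_score` with fields `s_ij`, `s_ii`,
#'   `s_jj`, `x`, `y`, `d_ij`, `f_xy` and `d_prime`; `d_prime` is the
#'   matrix entry.
#' @export
mafft_distance <- function(a, b) {
  la <- nchar(a); lb <- nchar(b)
  x <- max(la, lb); y <- min(la, lb)
  f <- mafft_scale_factor(x, y)
  if (y < 6) {
    warning("sequence shorter than 6 residues: mafft6 D set to 1")
    s_ij <- 0L; d <- 1
  } else {
    s_ij <- tuple_count_score(a, b, 6L)
    d <- 1 - s_ij / min(la - 5, lb - 5)
  }
  structure(list(s_ij = s_ij, s_ii = la - 5L, s_jj = lb - 5L,
                 x = x, y = y, d_ij = d, f_xy = f, d_prime = d / f),
            class = "pair_score")
}

#' Needleman-Wunsch fractional-identity distance
#'
#' Aligns the pair globally (affine gaps, deterministic traceback) and
#' returns `1 - identities / min(La, Lb)`, where identities counts
#' identical aligned residue pairs in the optimal alignment found. This is
#' the slow, information-rich alternative to k-tuple scores: it sees
#' positional context, so unrelated pairs rarely tie.
#'
#' @param a,b residue strings (non-empty).
#' @param sub substitution matrix (default [blosum62()]).
#' @param gap a [gap_params()] (default open 11, extend 1).
#' @return Distance in \[0, 1\].
#' @export
nw_distance <- function(a, b, sub = blosum62(), gap = gap_params()) {
  # align the pair in a canonical order: with co-optimal alignments, the
  # deterministic traceback could otherwise report different identity
  # counts for (a, b) and (b, a)
  p <- sort(c(a, b), method = "radix")
  aln <- pairwise_nw(p[1L], p[2L], sub = sub, gap = gap)
  ident <- sum(aln$mat[1, ] == aln$mat[2, ] & aln$mat[1, ] != "-")
  1 - ident / min(nchar(a), nchar(b))
}

new_dist_matrix <- function(labels, values, method = NULL) {
  structure(list(labels = labels, values = values, method = method),
            class = "dist_matrix")
}

#' @export
print.dist_matrix <- function(x, ...) {
  cat("dist_matrix:", length(x$labels), "x", length(x$labels),
      if (!is.null(x$method)) paste0("(", x$method$name, ")") else "", "\n")
  invisible(x)
}

# Fast pairwise k-tuple score matrix S[i, j] = sum_w min(count_i(w),
# count_j(w)) for all pairs at once. Counts are expanded by multiplicity
# level (a tuple seen c times contributes indicator rows for levels
# 1..c), turning the elementwise min into a single sparse cross-product.
tuple_score_matrix <- function(seqs, k) {
  tuples <- lapply(seqs, seq_tuples, k = k)
  all_t <- unique(unlist(tuples))
  n <- length(seqs)
  if (length(all_t) == 0) return(matrix(0L, n, n))
  ii <- vector("list", n); jj <- vector("list", n)
  for (s in seq_len(n)) {
    tb <- table(match(tuples[[s]], all_t))
    idx <- as.integer(names(tb))
    cnt <- as.integer(tb)
    # level expansion: tuple t with count c -> rows (t, 1) .. (t, c)
    ii[[s]] <- rep(idx, cnt) + length(all_t) * (sequence(cnt) - 1L)
    jj[[s]] <- rep.int(s, sum(cnt))
  }
  ii <- unlist(ii); jj <- unlist(jj)
  B <- Matrix::sparseMatrix(i = ii, j = jj, x = 1, dims = c(max(ii), n))
  as.matrix(Matrix::crossprod(B))
}

#' Build the full pairwise distance matrix for a sequence set
#'
#' Computes all n(n-1)/2 pairs once under the chosen method; the matrix is
#' symmetric by construction with a zero diagonal. The k-tuple methods use
#' a vectorized shared-tuple computation that is exactly equivalent to
#' calling the pair functions (the equivalence is tested); `kalign_mm` and
#' `nw` loop over pairs.
#'
#' @param s a [seq_set()].
#' @param m a [method_spec()].
#' @return A `dist_matrix` (fields `labels`, `values`, `method`).
#' @export
build_distance_matrix <- function(s, m = method_spec("clustalo1")) {
  stopifnot(inherits(s, "seq_set"), inherits(m, "method_spec"))
  n <- length(s)
  if (n < 2) stop("need at least 2 sequences")
  L <- nchar(s$seqs)
  minL <- outer(L, L, pmin)
  vals <- switch(
    m$name,
    clustalo1 = 1 - tuple_score_matrix(s$seqs, 1L) / minL,
    muscle6 = {
      if (any(L < 6)) warning("sequences shorter than 6 residues: distance 1")
      v <- 1 - tuple_score_matrix(s$seqs, 6L) / pmax(minL - 5, 1)
      v[minL < 6] <- 1
      v
    },
    mafft6 = {
      if (any(L < 6)) warning("sequences shorter than 6 residues: D = 1")
      d <- 1 - tuple_score_matrix(s$seqs, 6L) / pmax(minL - 5, 1)
      d[minL < 6] <- 1
      maxL <- outer(L, L, pmax)
      f <- minL / maxL * 0.1 + 10000 / (maxL + 10000) + 0.01
      d / f
    },
    kalign_mm = pair_loop_matrix(s$seqs, function(a, b) {
      kalign_distance(a, b, k = m$k, max_mismatch = m$params$max_mismatch)
    }),
    nw = {
      sub <- if (!is.null(m$params$sub)) m$params$sub else blosum62()
      gap <- if (!is.null(m$params$gap)) m$params$gap else gap_params()
      pair_loop_matrix(s$seqs, function(a, b) nw_distance(a, b, sub, gap))
    })
  vals <- as.matrix(vals)
  # symmetrize exactly from the upper triangle and zero the diagonal
  vals[lower.tri(vals)] <- t(vals)[lower.tri(vals)]
  diag(vals) <- 0
  dimnames(vals) <- list(s$ids, s$ids)
  new_dist_matrix(s$ids, vals, m)
}

pair_loop_matrix <- function(seqs, fun) {
  n <- length(seqs)
  v <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      v[i, j] <- v[j, i] <- fun(seqs[[i]], seqs[[j]])
    }
  }
  v
}

#' Audit the symmetry of a distance method
#'
#' Computes every pair in both argument orders independently through the
#' pair-level functions and returns the maximum absolute discrepancy
#' `|d(a, b) - d(b, a)|`. All methods in this package are symmetric by
#' construction, so the audit returns 0; it exists because real aligner
#' implementations are not always symmetric, and an asymmetric distance is
#' another route to input-order-dependent guide trees.
#'
#' @param s a [seq_set()].
#' @param m a [method_spec()].
#' @return Maximum absolute discrepancy over all ordered pairs (numeric).
#' @export
symmetry_audit <- function(s, m = method_spec("clustalo1")) {
  stopifnot(inherits(s, "seq_set"), inherits(m, "method_spec"))
  n <- length(s)
  if (n < 2) stop("need at least 2 sequences")
  f <- switch(m$name,
              clustalo1 = clustalo_distance,
              muscle6 = function(a, b) suppressWarnings(muscle_distance(a, b)),
              kalign_mm = function(a, b) {
                suppressWarnings(
                  kalign_distance(a, b, k = m$k,
                                  max_mismatch = m$params$max_mismatch))
              },
              mafft6 = function(a, b) suppressWarnings(mafft_distance(a, b)$d_prime),
              nw = function(a, b) {
                sub <- if (!is.null(m$params$sub)) m$params$sub else blosum62()
                gap <- if (!is.null(m$params$gap)) m$params$gap else gap_params()
                nw_distance(a, b, sub, gap)
              })
  worst <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      worst <- max(worst, abs(f(s$seqs[i], s$seqs[j]) - f(s$seqs[j], s$seqs[i])))
    }
  }
  worst
}
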