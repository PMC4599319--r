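#' Census of tied distance values in a matrix
#'
#' Rounds the off-diagonal upper-triangle values to `decimals` places and
#' counts how many distinct values remain. Word-based distances can take
#' only a bounded number of values, so as n grows the n(n-1)/2 pairs must
#' increasingly collide — these ties are what make the downstream guide
#' tree depend on input order. The default precision of 25 decimals mirrors
#' the precision used when distance matrices are written to disk, so ties
#' counted here are ties in the file as well; it is configurable because
#' binary representation can split mathematically tied values.
#'
#' @param m a `dist_matrix`.
#' @param decimals rounding precision used for equality (default 25).
#' @return A `tie_report`: list with `n_pairs`, `n_unique`,
#'   `duplicate_fraction`, `multiplicity_histogram` (named count vector,
#'   names are the distinct values) and `rounding_decimals`.
#' @export
count_unique_distances <- function(m, decimals = 25) {
  stopifnot(inherits(m, "dist_matrix"))
  n <- length(m$labels)
  if (n < 2) stop("need at least 2 sequences")
  v <- round(m$values[upper.tri(m$values)], decimals)
  tab <- table(v)
  structure(list(n_pairs = length(v),
                 n_unique = length(tab),
                 duplicate_fraction = (length(v) - length(tab)) / length(v),
                 multiplicity_histogram = tab,
                 rounding_decimals = decimals),
            class = "tie_report")
}

#' @export
print.tie_report <- function(x, ...) {
  cat(sprintf("tie_report: %d pairs, %d unique values (%.1f%% duplicated)\n",
              x$n_pairs, x$n_unique, 100 * x$duplicate_fraction))
  invisible(x)
}

#' Closed-form maximum number of unique distances for a sequence set
#'
#' The number of distinct values a word-based distance can take is driven
#' by two dataset features: the longest sequence length and the number of
#' distinct sequence lengths. For the linear family (Clustal Omega, Kalign,
#' Muscle — one length enters the scaling),
#' `MaxUniqueDists = MaxSeqLength * Count(SeqLengths)`; for Mafft, where
#' both lengths enter the scaling factor,
#' `MaxUniqueDists = MaxSeqLength * Count(SeqLengths)^2`. These deliberately
#' ignore the minor per-method adjustments (the +1 for zero matches, the
#' k-tuple end effect) and are conservative upper bounds. The derived
#' `max_seqs` is the largest sequence count whose n(n-1)/2 pairs can still
#' all receive distinct values.
#'
#' @param s a [seq_set()].
#' @param family `"linear"` (Clustal Omega / Kalign / Muscle) or `"mafft"`.
#' @return A `theoretical_maxima`: list with `max_seq_length`, `n_lengths`,
#'   `max_unique_dists`, `max_seqs` and `method_family`.
#' @export
theoretical_max_unique <- function(s, family = c("linear", "mafft")) {
  stopifnot(inherits(s, "seq_set"), length(s) >= 1)
  family <- match.arg(family)
  L <- nchar(s$seqs)
  max_len <- max(L)
  n_len <- length(unique(L))
  m <- if (family == "linear") max_len * n_len else max_len * n_len^2
  structure(list(max_seq_length = max_len,
                 n_lengths = n_len,
                 max_unique_dists = m,
                 max_seqs = max_stable_sequences(m),
                 method_family = family),
            class = "theoretical_maxima")
}

#' @export
print.theoretical_maxima <- function(x, ...) {
  cat(sprintf(paste0("theoretical_maxima (%s): max length %d, %d distinct",
                     " lengths\n  max unique distances %d -> at most %d",
                     " sequences before forced ties\n"),
              x$method_family, x$max_seq_length, x$n_lengths,
              x$max_unique_dists, x$max_seqs))
  invisible(x)
}

#' Maximum number of sequences alignable before ties are forced
#'
#' N sequences produce N(N-1)/2 pairwise distances; once that exceeds the
#' number of values the distance can take, ties are unavoidable. Solving
#' `MaxSeqs(MaxSeqs - 1)/2 = MaxUniqueDists` gives the largest integer N
#' with `N(N-1)/2 <= M`, i.e. `floor((1 + sqrt(1 + 8 M)) / 2)`.
#'
#' @param max_unique_dists M, the available number of distinct values
#'   (>= 1).
#' @return The integer MaxSeqs.
#' @examples
#' max_stable_sequences(499500)  # 1000 * 999 / 2, exactly
#' @export
max_stable_sequences <- function(max_unique_dists) {
  m <- max_unique_dists
  if (length(m) != 1 || is.na(m) || m < 1) stop("max_unique_dists must be >= 1")
  n <- floor((1 + sqrt(1 + 8 * m)) / 2)
  # guard against floating-point edge cases around perfect squares
  while (n * (n - 1) / 2 > m) n <- n - 1
  while ((n + 1) * n / 2 <= m) n <- n + 1
  as.integer(n)
}

#' Mean unique-distance count as a function of sample size
#'
#' For each requested size, draws `reps` random subsets of the set (without
#' replacement, seeded), builds the distance matrix under method `m`, and
#' records the number of unique distance values. The resulting curve
#' levels off with growing sample size — the plateau whose height is
#' bounded by [theoretical_max_unique()] — while the number of pairs grows
#' quadratically.
#'
#' @param s a [seq_set()].
#' @param sample_sizes integer vector of subset sizes (each <= length(s)).
#' @param reps replicates per size (>= 1).
#' @param m a [method_spec()].
#' @param seed integer seed; the whole table is a deterministic function
#'   of it.
#' @param decimals tie-rounding precision (see [count_unique_distances()]).
#' @return A data.frame with columns `size`, `n_pairs`, `mean_unique`,
#'   `sd_unique`.
#' @export
unique_distance_curve <- function(s, sample_sizes, reps, m = method_spec("clustalo1"),
                                  seed = 1L, decimals = 25) {
  stopifnot(inherits(s, "seq_set"), reps >= 1)
  if (any(sample_sizes > length(s))) {
    stop("sample size exceeds number of sequences (", length(s), ")")
  }
  if (any(sample_sizes < 2)) stop("sample sizes must be >= 2")
  with_seed(seed, {
    rows <- lapply(sample_sizes, function(sz) {
      u <- vapply(seq_len(reps), function(r) {
        sub <- subset_set(s, sample.int(length(s), sz))
        dm <- suppressWarnings(build_distance_matrix(sub, m))
        count_unique_distances(dm, decimals)$n_unique
      }, numeric(1))
      data.frame(size = sz, n_pairs = sz * (sz - 1) / 2,
                 mean_unique = mean(u),
                 sd_unique = if (reps > 1) sd(u) else NA_real_)
    })
    do.call(rbind, rows)
  })
}
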