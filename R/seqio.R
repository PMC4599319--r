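#' Ordered, named protein sequence sets
#'
#' A `seq_set` is an ordered collection of named protein sequences. The
#' order is semantically meaningful: progressive alignment pipelines are
#' sensitive to it, and that sensitivity is the phenomenon this package
#' studies. Residues are uppercase letters from the 20 standard amino acids
#' plus the ambiguity/nonstandard letters B, Z, X, U and O.
#'
#' @param ids character vector of unique sequence identifiers.
#' @param seqs character vector of residue strings (same length as `ids`).
#' @param desc optional character vector of free-text descriptions.
#' @param provenance free-text note on how this ordering arose
#'   (e.g. `"input"`, `"shuffled seed=7"`, `"reversed"`).
#' @return An object of class `seq_set` with fields `ids`, `seqs`, `desc`
#'   and `provenance`.
#' @examples
#' s <- seq_set(c("a", "b"), c("ACDEFG", "ACDEFH"))
#' length(s)
#' @export
seq_set <- function(ids, seqs, desc = NULL, provenance = "input") {
  ids <- as.character(ids)
  seqs <- toupper(as.character(seqs))
  if (length(ids) != length(seqs)) {
    stop("`ids` and `seqs` must have the same length")
  }
  if (anyDuplicated(ids)) {
    dup <- ids[duplicated(ids)][1L]
    stop("duplicate sequence id: '", dup, "'")
  }
  if (any(!nzchar(seqs))) {
    stop("empty residue string for id '", ids[which(!nzchar(seqs))[1L]], "'")
  }
  bad <- setdiff(unique(strsplit(paste(seqs, collapse = ""), "")[[1L]]),
                 AA_ALPHABET)
  if (length(bad) > 0) {
    stop("invalid residue character(s): ", paste(bad, collapse = ", "))
  }
  if (is.null(desc)) desc <- rep("", length(ids))
  structure(list(ids = ids, seqs = seqs, desc = as.character(desc),
                 provenance = provenance),
            class = "seq_set")
}

#' @export
length.seq_set <- function(x) length(x$ids)

#' @export
print.seq_set <- function(x, ...) {
  cat("seq_set with", length(x), "sequences (order:", x$provenance, ")\n")
  n <- min(length(x), 5L)
  for (i in seq_len(n)) {
    s <- x$seqs[i]
    if (nchar(s) > 50) s <- paste0(substr(s, 1, 50), "...")
    cat(sprintf("  %s  [%d aa]  %s\n", x$ids[i], nchar(x$seqs[i]), s))
  }
  if (length(x) > n) cat("  ...\n")
  invisible(x)
}

#' Sequence lengths of a set
#' @param s a [seq_set()].
#' @return Integer vector of residue counts, named by id.
#' @export
seq_lengths <- function(s) {
  stopifnot(inherits(s, "seq_set"))
  stats::setNames(nchar(s$seqs), s$ids)
}

#' Read unaligned protein sequences from a FASTA file
#'
#' Records are returned in file order. Residues are uppercased; `*` and
#' whitespace characters inside the sequence are stripped. Ids are taken as
#' the header text up to the first whitespace, the remainder becoming the
#' description.
#'
#' @param path path to a FASTA file.
#' @return A [seq_set()] in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  xs <- Biostrings::readBStringSet(path)
  if (length(xs) == 0) stop("empty FASTA file: ", path)
  headers <- names(xs)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  if (anyDuplicated(ids)) {
    stop("duplicate sequence id in ", path, ": '", ids[duplicated(ids)][1L], "'")
  }
  seqs <- toupper(gsub("[*[:space:]]", "", as.character(xs)))
  seq_set(ids, seqs, desc, provenance = "input")
}

#' Write a sequence set (or alignment rows) to FASTA
#'
#' @param x a [seq_set()] or [msa_alignment()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path) {
  if (inherits(x, "msa_alignment")) {
    ids <- x$ids
    seqs <- alignment_rows(x)
    desc <- rep("", length(ids))
  } else {
    stopifnot(inherits(x, "seq_set"))
    ids <- x$ids
    seqs <- x$seqs
    desc <- x$desc
  }
  headers <- ifelse(nzchar(desc), paste(ids, desc), ids)
  xs <- Biostrings::BStringSet(stats::setNames(seqs, headers))
  Biostrings::writeXStringSet(xs, path)
  invisible(path)
}

#' Remove duplicate sequences from a set
#'
#' Two records are duplicates when their residue strings are identical
#' (case-insensitive); ids are ignored, mirroring the situation in large
#' Pfam-derived families where identical proteins carry different labels.
#' One record is kept per distinct residue string (the lexicographically
#' smallest id among the duplicates) and the output is sorted in ascending
#' order of the residue strings themselves, not of the ids. Duplicate
#' sequences in the input necessarily produce tied pairwise distances, so
#' deduplication separates that trivial source of ties from ties caused by
#' the distance formulas.
#'
#' @param s a [seq_set()].
#' @return A list with elements `set` (the deduplicated, residue-sorted
#'   [seq_set()]) and `stats` (list with `total`, `unique` and `pct_dup`
#'   where `pct_dup = 100 * (total - unique) / total`).
#' @examples
#' s <- seq_set(c("x", "y", "z"), c("ACD", "ACD", "WWW"))
#' dedup_sequences(s)$stats
#' @export
dedup_sequences <- function(s) {
  stopifnot(inherits(s, "seq_set"))
  total <- length(s)
  # keeper per residue string = lexicographically smallest id
  keep <- vapply(split(seq_len(total), s$seqs), function(ix) {
    ix[order(s$ids[ix])][1L]
  }, integer(1))
  keep <- keep[order(names(keep), method = "radix")]  # sort by residue string
  set <- seq_set(s$ids[keep], s$seqs[keep], s$desc[keep],
                 provenance = paste0(s$provenance, "; dedup (residue-sorted)"))
  uniq <- length(keep)
  list(set = set,
       stats = list(total = total, unique = uniq,
                    pct_dup = 100 * (total - uniq) / total))
}

#' Reverse the order of a sequence set
#'
#' Exact order reversal; records are otherwise untouched. Reversing twice
#' reproduces the original set.
#'
#' @param s a [seq_set()].
#' @return The reversed [seq_set()].
#' @export
reverse_order <- function(s) {
  stopifnot(inherits(s, "seq_set"))
  ix <- rev(seq_len(length(s)))
  prov <- if (endsWith(s$provenance, "; reversed")) {
    sub("; reversed$", "", s$provenance)
  } else {
    paste0(s$provenance, "; reversed")
  }
  structure(list(ids = s$ids[ix], seqs = s$seqs[ix], desc = s$desc[ix],
                 provenance = prov),
            class = "seq_set")
}

#' Shuffle a sequence set with a recorded seed
#'
#' The permutation is a deterministic function of `seed`; the caller's RNG
#' stream is left untouched.
#'
#' @param s a [seq_set()].
#' @param seed integer seed.
#' @return The shuffled [seq_set()], provenance noting the seed.
#' @export
shuffle_order <- function(s, seed) {
  stopifnot(inherits(s, "seq_set"))
  ix <- with_seed(seed, sample.int(length(s)))
  structure(list(ids = s$ids[ix], seqs = s$seqs[ix], desc = s$desc[ix],
                 provenance = sprintf("%s; shuffled seed=%d",
                                      s$provenance, as.integer(seed))),
            class = "seq_set")
}

#' Take a subset of a sequence set by index
#' @param s a [seq_set()].
#' @param ix integer indices (order respected).
#' @return The sub-[seq_set()].
#' @export
subset_set <- function(s, ix) {
  stopifnot(inherits(s, "seq_set"))
  structure(list(ids = s$ids[ix], seqs = s$seqs[ix], desc = s$desc[ix],
                 provenance = paste0(s$provenance, "; subset")),
            class = "seq_set")
}

#' Write a distance matrix in PHYLIP square format with 25-decimal values
#'
#' The first line holds the sequence count; each following row holds the
#' label and then all n distances printed to 25 decimal places, so that
#' values that tie do so in the file exactly as in memory. Labels are
#' written in full (up to 64 characters) rather than the classic 10-column
#' PHYLIP truncation, which would collide typical Pfam-style ids.
#'
#' @param m a `dist_matrix` as returned by [build_distance_matrix()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_distance_matrix <- function(m, path) {
  stopifnot(inherits(m, "dist_matrix"))
  n <- length(m$labels)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%d", n), con)
  labs <- substr(m$labels, 1, 64)
  for (i in seq_len(n)) {
    writeLines(paste(c(labs[i], sprintf("%.25f", m$values[i, ])),
                     collapse = " "), con)
  }
  invisible(path)
}

#' Read a PHYLIP square distance matrix written by [write_distance_matrix()]
#'
#' @param path input file path.
#' @param method optional [method_spec()] to attach as provenance.
#' @return A `dist_matrix`.
#' @export
read_distance_matrix <- function(path, method = NULL) {
  lines <- readLines(path)
  if (length(lines) < 2) stop("not a PHYLIP distance matrix: ", path)
  n <- as.integer(trimws(lines[1L]))
  if (is.na(n) || length(lines) < n + 1L) {
    stop("malformed PHYLIP distance matrix: ", path)
  }
  labels <- character(n)
  values <- matrix(0, n, n)
  for (i in seq_len(n)) {
    parts <- strsplit(trimws(lines[i + 1L]), "[[:space:]]+")[[1L]]
    if (length(parts) != n + 1L) {
      stop("row ", i, " has ", length(parts) - 1L, " values, expected ", n)
    }
    labels[i] <- parts[1L]
    values[i, ] <- as.numeric(parts[-1L])
  }
  dimnames(values) <- list(labels, labels)
  new_dist_matrix(labels, values, method)
}
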