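# Independent brute-force oracles used to validate the package's
# implementations on small inputs. These deliberately avoid the code paths
# they check.

# --- shared k-tuple count as a maximum bipartite matching ------------------
# Enumerate all position pairs (i, j) whose k-tuples are equal and compute a
# maximum matching between a-positions and b-positions with an augmenting-
# path search.
oracle_tuple_count <- function(a, b, k) {
  ta <- oracle_tuples(a, k)
  tb <- oracle_tuples(b, k)
  if (length(ta) == 0 || length(tb) == 0) return(0L)
  adj <- lapply(seq_along(ta), function(i) which(tb == ta[i]))
  match_b <- rep(0L, length(tb))
  try_augment <- function(i, seen) {
    for (j in adj[[i]]) {
      if (!seen[j]) {
        seen[j] <- TRUE
        if (match_b[j] == 0L || Recall(match_b[j], seen)) {
          match_b[j] <<- i
          return(TRUE)
        }
      }
    }
    FALSE
  }
  total <- 0L
  for (i in seq_along(ta)) {
    if (try_augment(i, rep(FALSE, length(tb)))) total <- total + 1L
  }
  total
}

oracle_tuples <- function(x, k) {
  L <- nchar(x)
  if (L < k) return(character(0))
  vapply(1:(L - k + 1), function(i) substr(x, i, i + k - 1), character(1))
}

# --- exhaustive global alignment enumeration -------------------------------
# Enumerate every global alignment of an n x m column-score problem under
# affine gaps (gap run of length g costs open + (g-1)*extend, terminal gaps
# penalized). Returns the optimal score and the set of identity counts
# realized by optimal alignments (identity matrix optional).
oracle_enum_align <- function(colscore, open, extend, ident = NULL) {
  n <- nrow(colscore)
  m <- ncol(colscore)
  acc <- new.env()
  acc$best <- -Inf
  acc$idents <- integer(0)
  rec <- function(i, j, last, score, nid) {
    if (i == n && j == m) {
      if (score > acc$best + 1e-9) {
        acc$best <- score
        acc$idents <- nid
      } else if (abs(score - acc$best) <= 1e-9) {
        acc$idents <- unique(c(acc$idents, nid))
      }
      return(invisible())
    }
    if (i < n && j < m) {
      rec(i + 1, j + 1, "d", score + colscore[i + 1, j + 1],
          nid + if (!is.null(ident)) ident[i + 1, j + 1] else 0L)
    }
    if (i < n) {
      rec(i + 1, j, "u", score - if (last == "u") extend else open, nid)
    }
    if (j < m) {
      rec(i, j + 1, "l", score - if (last == "l") extend else open, nid)
    }
  }
  rec(0L, 0L, "s", 0, 0L)
  list(score = acc$best, idents = acc$idents)
}

# Substitution-score and identity matrices for a residue pair.
oracle_pair_matrices <- function(a, b, sub) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  list(score = sub[ca, cb, drop = FALSE],
       ident = outer(ca, cb, "==") * 1L)
}

# Column-vs-column profile score computed by explicit double loop (average
# over all row pairs, gap-involving pairs contribute 0).
oracle_profile_colscore <- function(A, B, sub) {
  sc <- matrix(0, ncol(A$mat), ncol(B$mat))
  for (u in seq_len(ncol(A$mat))) {
    for (v in seq_len(ncol(B$mat))) {
      tot <- 0
      for (p in seq_len(nrow(A$mat))) {
        for (q in seq_len(nrow(B$mat))) {
          x <- A$mat[p, u]; y <- B$mat[q, v]
          if (x != "-" && y != "-") tot <- tot + sub[x, y]
        }
      }
      sc[u, v] <- tot / (nrow(A$mat) * nrow(B$mat))
    }
  }
  sc
}

# --- TC score by direct column scanning ------------------------------------
oracle_tc <- function(test, ref_aln, mask) {
  rmat <- ref_aln$mat
  total <- 0L
  correct <- 0L
  for (cc in which(mask)) {
    rows <- which(rmat[, cc] != "-")
    if (length(rows) == 0) next
    total <- total + 1L
    # cells: id -> residue ordinal in that reference row
    cells <- lapply(rows, function(i) {
      list(id = ref_aln$ids[i], ord = sum(rmat[i, 1:cc] != "-"))
    })
    hit <- FALSE
    for (tc_col in seq_len(ncol(test$mat))) {
      all_there <- TRUE
      for (cell in cells) {
        trow <- test$mat[match(cell$id, test$ids), ]
        if (trow[tc_col] == "-" ||
            sum(trow[1:tc_col] != "-") != cell$ord) {
          all_there <- FALSE
          break
        }
      }
      if (all_there) { hit <- TRUE; break }
    }
    if (hit) correct <- correct + 1L
  }
  list(correct = correct, total = total,
       tc = if (total > 0) correct / total else NA_real_)
}

# --- misc helpers -----------------------------------------------------------
random_seqs <- function(n, len, seed = 1) {
  withr::with_seed(seed, {
    vapply(seq_len(n), function(i) {
      paste(sample(c("A","R","N","D","C","Q","E","G","H","I","L","K","M",
                     "F","P","S","T","W","Y","V"), len, replace = TRUE),
            collapse = "")
    }, character(1))
  })
}

random_seq_set <- function(n, len, seed = 1, prefix = "s") {
  seq_set(sprintf("%s%02d", prefix, seq_len(n)), random_seqs(n, len, seed))
}

# Collect internal-node merge heights of a guide tree (unsorted).
tree_heights <- function(t) {
  rec <- function(node) {
    if (node$leaf) return(numeric(0))
    c(node$height, rec(node$children[[1]]), rec(node$children[[2]]))
  }
  rec(t$root)
}

quiet_upgma <- function(...) {
  withCallingHandlers(upgma(...),
                      warning = function(w) invokeRestart("muffleWarning"))
}
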