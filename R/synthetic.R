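#' Simulate a protein family with a known true alignment
#'
#' Generates a family of related protein sequences by evolving a root
#' sequence down a random binary tree, recording every indel so the true
#' column homology is exact by construction. This is the desk-scale
#' stand-in for a curated benchmark family: a set of moderately similar
#' sequences of controllable size, divergence, length diversity and
#' exact-duplicate fraction, with an embedded reference subset whose true
#' alignment and core-column mask are known.
#'
#' The generative model, chosen for transparency rather than biological
#' realism:
#' * topology — successive random pair joins over `n` lineages
#'   (coalescent-style); every edge is one "branch" of evolution;
#' * root — `root_length` residues drawn iid uniform over the 20 standard
#'   amino acids;
#' * substitutions — along each branch every site mutates independently
#'   with probability `subst_rate`, uniformly to one of the 19 other
#'   residues;
#' * indels — along each branch each site independently hosts an indel
#'   event with probability `indel_rate`; the event deletes or inserts
#'   (50/50) a run of geometric length with mean `mean_indel_len`.
#'   `indel_rate = 0` therefore forces all sequences to the same length
#'   and a gap-free truth alignment — the regime that maximizes distance
#'   ties;
#' * duplicates — after leaf generation, the last
#'   `floor(duplicate_fraction * n)` leaves are overwritten with exact
#'   copies of randomly chosen earlier leaves, keeping their own ids
#'   (identical residues under different labels, as found in large
#'   curated families);
#' * reference — the first `n_refs` leaves form the reference subset; its
#'   rows of the truth alignment (all-gap columns dropped) plus the
#'   gap-free-column mask form the embedded reference alignment.
#'
#' @param n number of sequences (>= 2).
#' @param root_length root sequence length in residues.
#' @param subst_rate per-site substitution probability per branch, in
#'   \[0, 1\].
#' @param indel_rate per-site indel probability per branch, in \[0, 1\].
#' @param mean_indel_len mean indel run length in residues (>= 1).
#' @param duplicate_fraction fraction of records that are exact copies,
#'   in \[0, 1).
#' @param n_refs reference subset size (<= n).
#' @param seed integer seed; the family is a deterministic function of the
#'   full configuration.
#' @return A `synthetic_family`: list with `sequences` (a [seq_set()]),
#'   `truth` (an [msa_alignment()] of all n rows), `reference` (a
#'   [ref_alignment()] over the first `n_refs` rows) and `provenance`
#'   (the configuration).
#' @examples
#' fam <- simulate_family(n = 10, root_length = 40, subst_rate = 0.1,
#'                        n_refs = 3, seed = 1)
#' fam$sequences
#' @export
simulate_family <- function(n, root_length, subst_rate,
                            indel_rate = 0, mean_indel_len = 3,
                            duplicate_fraction = 0, n_refs = min(5L, n),
                            seed = 1L) {
  stopifnot(n >= 2, root_length >= 1,
            subst_rate >= 0, subst_rate <= 1,
            indel_rate >= 0, indel_rate <= 1,
            mean_indel_len >= 1,
            duplicate_fraction >= 0, duplicate_fraction < 1,
            n_refs >= 1, n_refs <= n)
  cfg <- list(n = as.integer(n), root_length = as.integer(root_length),
              subst_rate = subst_rate, indel_rate = indel_rate,
              mean_indel_len = mean_indel_len,
              duplicate_fraction = duplicate_fraction,
              n_refs = as.integer(n_refs), seed = as.integer(seed))
  aa20 <- AA_ALPHABET[1:20]
  with_seed(seed, {
    # --- topology: successive random pair joins -------------------------
    # nodes 1..n are leaves; joins create nodes n+1 .. 2n-1 (root last)
    parent <- integer(2 * n - 1)
    active <- seq_len(n)
    nxt <- n + 1L
    while (length(active) > 1) {
      pair <- sample(length(active), 2L)
      parent[active[pair]] <- nxt
      active <- c(active[-pair], nxt)
      nxt <- nxt + 1L
    }
    root_id <- 2L * n - 1L
    children <- split(seq_len(root_id - 1L), parent[seq_len(root_id - 1L)])

    # --- evolve down the tree ------------------------------------------
    # a node's state: integer vector of global column ids + residue vector
    col_count <- root_length
    # global column order as a list of id vectors we can splice into
    col_order <- seq_len(root_length)
    root_state <- list(cols = seq_len(root_length),
                       res = sample(aa20, root_length, replace = TRUE))
    states <- vector("list", root_id)
    states[[root_id]] <- root_state
    evolve <- function(st) {
      res <- st$res; cols <- st$cols
      L <- length(res)
      # substitutions
      mut <- which(stats::runif(L) < subst_rate)
      for (i in mut) {
        res[i] <- sample(setdiff(aa20, res[i]), 1L)
      }
      # indels, right-to-left so positions stay valid while editing
      if (indel_rate > 0 && L > 0) {
        ev <- which(stats::runif(L) < indel_rate)
        for (i in rev(ev)) {
          g <- stats::rgeom(1L, 1 / mean_indel_len) + 1L
          if (stats::runif(1) < 0.5) {
            # deletion of up to g residues starting at i (keep >= 1 residue)
            last <- min(i + g - 1L, length(res))
            if (last - i + 1L < length(res)) {
              res <- res[-(i:last)]
              cols <- cols[-(i:last)]
            }
          } else {
            # insertion of g fresh residues after position i
            newids <- col_count + seq_len(g)
            col_count <<- col_count + g
            at <- match(cols[i], col_order)
            col_order <<- append(col_order, newids, after = at)
            res <- append(res, sample(aa20, g, replace = TRUE), after = i)
            cols <- append(cols, newids, after = i)
          }
        }
      }
      list(cols = cols, res = res)
    }
    # breadth-first from the root so parents are evolved before children
    queue <- root_id
    while (length(queue)) {
      p <- queue[1]; queue <- queue[-1]
      for (ch in children[[as.character(p)]]) {
        states[[ch]] <- evolve(states[[p]])
        if (ch > n) queue <- c(queue, ch)
      }
    }

    # --- duplicates -----------------------------------------------------
    n_dup <- floor(duplicate_fraction * n)
    if (n_dup > 0) {
      src <- sample(n - n_dup, n_dup, replace = TRUE)
      for (k in seq_len(n_dup)) {
        states[[n - n_dup + k]] <- states[[src[k]]]
      }
    }

    # --- assemble truth alignment over the global column order ----------
    ids <- sprintf("seq%0*d", max(3L, nchar(n)), seq_len(n))
    used <- sort(unique(unlist(lapply(states[1:n], `[[`, "cols"))))
    colpos <- integer(col_count)
    colpos[col_order[col_order %in% used]] <- seq_along(used)
    mat <- matrix("-", nrow = n, ncol = length(used))
    for (i in seq_len(n)) {
      mat[i, colpos[states[[i]]$cols]] <- states[[i]]$res
    }
    truth <- msa_alignment(ids, mat)
    seqs <- seq_set(ids, vapply(states[1:n],
                                function(st) paste(st$res, collapse = ""),
                                character(1)),
                    provenance = sprintf("simulated seed=%d", cfg$seed))

    # --- reference subset ----------------------------------------------
    rmat <- mat[seq_len(n_refs), , drop = FALSE]
    rmat <- rmat[, colSums(rmat != "-") > 0, drop = FALSE]
    reference <- ref_alignment(msa_alignment(ids[seq_len(n_refs)], rmat))

    structure(list(sequences = seqs, truth = truth, reference = reference,
                   provenance = cfg),
              class = "synthetic_family")
  })
}

#' @export
print.synthetic_family <- function(x, ...) {
  p <- x$provenance
  cat(sprintf(paste0("synthetic_family: n=%d, root_length=%d, subst=%g, ",
                     "indel=%g, dup=%g, n_refs=%d, seed=%d\n"),
              p$n, p$root_length, p$subst_rate, p$indel_rate,
              p$duplicate_fraction, p$n_refs, p$seed))
  invisible(x)
}

#' Length profile of a sequence set
#'
#' The two dataset features that bound the number of distinct word-based
#' distances: the longest sequence length and the number of distinct
#' lengths.
#'
#' @param s a [seq_set()].
#' @return List with `max_seq_length`, `n_lengths` and `histogram`
#'   (a table of length -> count).
#' @export
length_profile <- function(s) {
  stopifnot(inherits(s, "seq_set"), length(s) >= 1)
  L <- nchar(s$seqs)
  list(max_seq_length = max(L),
       n_lengths = length(unique(L)),
       histogram = table(L))
}
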