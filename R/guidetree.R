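# Tree nodes are plain nested lists:
#   leaf:     list(leaf = TRUE, label = <id>, height = 0)
#   internal: list(leaf = FALSE, children = list(a, b), height = h, step = s)
# A guide_tree wraps the root with the leaf count.

new_guide_tree <- function(root, n_leaves) {
  structure(list(root = root, n_leaves = n_leaves), class = "guide_tree")
}

#' @export
print.guide_tree <- function(x, ...) {
  cat("guide_tree with", x$n_leaves, "leaves\n ", to_newick(x), "\n")
  invisible(x)
}

#' UPGMA guide tree with explicit tie detection
#'
#' Standard UPGMA (arithmetic-average linkage): repeatedly merge the pair
#' of clusters at minimum distance, updating distances as size-weighted
#' averages, with merge height half the merge distance. At every step the
#' global minimum is found and *all* cluster pairs within `tol` of it form
#' the tie set. When that set has more than one pair, the choice among
#' them is arbitrary in principle — this is exactly where input-order
#' dependence enters a progressive aligner — so the event is recorded and
#' a warning of potential instability is issued. The pair actually merged
#' is chosen by `policy`:
#' * `input_order_first` — first tied pair in row-major order over the
#'   current cluster order (clusters keep the position of their first
#'   member, so this models "first pair wins" code);
#' * `input_order_last` — last tied pair in row-major order;
#' * `lexicographic` — the pair whose sorted member-label tuples compare
#'   smallest; this makes the tree invariant to input order even in the
#'   presence of ties (the lexicographic-ordering mitigation);
#' * `random` — a seeded draw among the tied pairs.
#'
#' @param m a symmetric `dist_matrix`.
#' @param policy tie-breaking policy (see above).
#' @param seed integer seed, used only by the `random` policy.
#' @param tol tie tolerance in distance units; pairs within `tol` of the
#'   step minimum count as tied. Default 0 (exact equality of the stored
#'   doubles, which at the 25-decimal output precision is the same thing).
#' @return A list with `tree` (a `guide_tree`) and `tie_events` (list of
#'   `tie_event` records: `step`, `tied_pairs`, `chosen`, `policy`).
#' @examples
#' s <- seq_set(c("a", "b", "c"), c("AAAAAA", "AAAAAC", "CCCCCC"))
#' upgma(build_distance_matrix(s, method_spec("clustalo1")))
#' @export
upgma <- function(m, policy = c("input_order_first", "input_order_last",
                                "lexicographic", "random"),
                  seed = 1L, tol = 0) {
  stopifnot(inherits(m, "dist_matrix"))
  policy <- match.arg(policy)
  d <- m$values
  n <- length(m$labels)
  if (n < 2) stop("need at least 2 sequences")
  if (!isTRUE(all.equal(d, t(d), tolerance = 0))) {
    stop("distance matrix is not symmetric")
  }
  run <- function() {
    clusters <- lapply(seq_len(n), function(i) {
      list(node = list(leaf = TRUE, label = m$labels[i], height = 0),
           size = 1L,
           members = m$labels[i],
           key = m$labels[i])
    })
    D <- d
    events <- list()
    for (step in seq_len(n - 1)) {
      nc <- length(clusters)
      Dq <- D
      Dq[lower.tri(Dq, diag = TRUE)] <- Inf
      dmin <- min(Dq)
      tied <- which(Dq <= dmin + tol, arr.ind = TRUE)
      # row-major order over the current cluster arrangement
      tied <- tied[order(tied[, 1], tied[, 2]), , drop = FALSE]
      pick <- switch(policy,
        input_order_first = 1L,
        input_order_last = nrow(tied),
        lexicographic = {
          keys <- apply(tied, 1, function(p) {
            ks <- sort(c(clusters[[p[1]]]$key, clusters[[p[2]]]$key),
                       method = "radix")
            paste(ks, collapse = "\r")
          })
          order(keys, method = "radix")[1L]
        },
        random = sample.int(nrow(tied), 1L))
      i <- tied[pick, 1]; j <- tied[pick, 2]
      if (nrow(tied) > 1) {
        pair_ids <- apply(tied, 1, function(p) {
          paste(sort(c(clusters[[p[1]]]$key, clusters[[p[2]]]$key)),
                collapse = " | ")
        })
        events[[length(events) + 1L]] <- structure(
          list(step = step, tied_pairs = unname(pair_ids),
               chosen = unname(pair_ids[pick]), policy = policy),
          class = "tie_event")
        warning(sprintf(paste0("potential instability: %d tied minimum ",
                               "distance pairs at merge step %d"),
                        nrow(tied), step),
                call. = FALSE)
      }
      h <- D[i, j] / 2
      ci <- clusters[[i]]; cj <- clusters[[j]]
      merged <- list(
        node = list(leaf = FALSE, children = list(ci$node, cj$node),
                    height = h, step = step),
        size = ci$size + cj$size,
        members = c(ci$members, cj$members),
        key = sort(c(ci$key, cj$key), method = "radix")[1L])
      # average-linkage update; merged cluster takes position i, j removed
      if (nc > 2) {
        others <- setdiff(seq_len(nc), c(i, j))
        newd <- (ci$size * D[i, others] + cj$size * D[j, others]) /
          (ci$size + cj$size)
        D[i, others] <- newd
        D[others, i] <- newd
      }
      D <- D[-j, -j, drop = FALSE]
      clusters[[i]] <- merged
      clusters[[j]] <- NULL
    }
    list(tree = new_guide_tree(clusters[[1]]$node, n), tie_events = events)
  }
  if (policy == "random") with_seed(seed, run()) else run()
}

#' Chained (caterpillar) guide tree over the input order
#'
#' A fully unbalanced tree `((((s1, s2), s3), s4) ...)`: sequences join the
#' growing profile one at a time in input order. Chained guide trees can
#' improve alignment accuracy at scale, but by construction they carry a
#' maximal dependence on input-file order (reversing the input mirrors the
#' caterpillar). Merge heights are set to the step index so the
#' non-decreasing-heights invariant holds.
#'
#' @param s a [seq_set()].
#' @return A `guide_tree`.
#' @export
chained_tree <- function(s) {
  stopifnot(inherits(s, "seq_set"))
  n <- length(s)
  if (n < 2) stop("need at least 2 sequences")
  node <- list(leaf = TRUE, label = s$ids[1], height = 0)
  for (i in 2:n) {
    node <- list(leaf = FALSE,
                 children = list(node,
                                 list(leaf = TRUE, label = s$ids[i], height = 0)),
                 height = i - 1, step = i - 1L)
  }
  new_guide_tree(node, n)
}

newick_label <- function(x) {
  if (grepl("[\\s()\\[\\]',:;]", x, perl = TRUE)) {
    paste0("'", gsub("'", "''", x), "'")
  } else {
    x
  }
}

#' Serialize a guide tree to Newick
#'
#' Branch lengths are differences of merge heights (leaves sit at height
#' 0). Labels containing whitespace or Newick metacharacters are quoted.
#'
#' @param t a `guide_tree`.
#' @return A single Newick string terminated by `;`.
#' @export
to_newick <- function(t) {
  stopifnot(inherits(t, "guide_tree"))
  rec <- function(node, parent_h) {
    bl <- parent_h - node$height
    if (node$leaf) {
      sprintf("%s:%.10g", newick_label(node$label), bl)
    } else {
      sprintf("(%s,%s):%.10g",
              rec(node$children[[1]], node$height),
              rec(node$children[[2]], node$height),
              bl)
    }
  }
  node <- t$root
  if (node$leaf) return(sprintf("%s;", newick_label(node$label)))
  sprintf("(%s,%s);",
          rec(node$children[[1]], node$height),
          rec(node$children[[2]], node$height))
}

#' Parse a rooted binary Newick tree into a guide tree
#'
#' Thin wrapper over `ape::read.tree`. The tree must be rooted and binary.
#' Node heights are reconstructed from branch lengths (leaves at height 0);
#' trees without branch lengths get unit-depth heights.
#'
#' @param text Newick string, or `file` to read from.
#' @param file optional path to a Newick file.
#' @return A `guide_tree`.
#' @export
from_newick <- function(text = NULL, file = NULL) {
  phy <- if (!is.null(file)) ape::read.tree(file) else ape::read.tree(text = text)
  if (is.null(phy)) stop("could not parse Newick input")
  if (!ape::is.binary(phy) || !ape::is.rooted(phy)) {
    stop("guide trees must be rooted and binary")
  }
  # undo Newick single-quoting, which ape preserves verbatim
  quoted <- grepl("^'.*'$", phy$tip.label)
  phy$tip.label[quoted] <- gsub("''", "'",
                                substr(phy$tip.label[quoted], 2,
                                       nchar(phy$tip.label[quoted]) - 1L))
  n <- length(phy$tip.label)
  # node depths from the root, then heights = max depth - depth
  el <- if (is.null(phy$edge.length)) rep(1, nrow(phy$edge)) else phy$edge.length
  depth <- numeric(n + phy$Nnode)
  root <- n + 1L
  ord <- order(phy$edge[, 1])  # parents before children via BFS instead
  # simple BFS from root
  kids <- split(seq_len(nrow(phy$edge)), phy$edge[, 1])
  queue <- root
  while (length(queue)) {
    p <- queue[1]; queue <- queue[-1]
    for (e in kids[[as.character(p)]]) {
      ch <- phy$edge[e, 2]
      depth[ch] <- depth[p] + el[e]
      if (ch > n) queue <- c(queue, ch)
    }
  }
  maxd <- max(depth[seq_len(n)])
  build <- function(v, step_env) {
    if (v <= n) {
      list(leaf = TRUE, label = phy$tip.label[v], height = 0)
    } else {
      es <- kids[[as.character(v)]]
      ch <- lapply(phy$edge[es, 2], build, step_env = step_env)
      step_env$s <- step_env$s + 1L
      list(leaf = FALSE, children = ch, height = maxd - depth[v],
           step = step_env$s)
    }
  }
  env <- new.env(); env$s <- 0L
  new_guide_tree(build(root, env), n)
}

tree_leaves <- function(node) {
  if (node$leaf) return(node$label)
  c(tree_leaves(node$children[[1]]), tree_leaves(node$children[[2]]))
}

canonical_form <- function(node) {
  if (node$leaf) return(node$label)
  ks <- sort(c(canonical_form(node$children[[1]]),
               canonical_form(node$children[[2]])), method = "radix")
  paste0("(", ks[1], ",", ks[2], ")")
}

#' Test whether two guide trees share the same topology
#'
#' Compares canonical forms in which the children of every internal node
#' are sorted by their smallest descendant label; merge heights and child
#' order are ignored.
#'
#' @param t1,t2 `guide_tree` objects over the same leaf-label set.
#' @return `TRUE` or `FALSE`.
#' @export
same_topology <- function(t1, t2) {
  stopifnot(inherits(t1, "guide_tree"), inherits(t2, "guide_tree"))
  l1 <- sort(tree_leaves(t1$root))
  l2 <- sort(tree_leaves(t2$root))
  if (!identical(l1, l2)) stop("trees have different leaf sets")
  identical(canonical_form(t1$root), canonical_form(t2$root))
}
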