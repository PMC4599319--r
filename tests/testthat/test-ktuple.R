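zf <- "ACADCGKTFSQSSHLVQHRRIH"  # the 22-residue zinc-finger sequence

test_that("tuple_count_score matches hand counts and degenerate rules", {
  expect_identical(tuple_count_score(zf, zf, 1), 22L)
  expect_identical(tuple_count_score(zf, zf, 6), 17L)  # (22 - 5) six-tuples
  expect_identical(tuple_count_score("AAAA", "CCCC", 1), 0L)
  expect_identical(tuple_count_score("ACD", "ACDEF", 6), 0L)  # min length < k
})

test_that("tuple_count_score equals the bipartite position-matching oracle", {
  for (seed in 1:6) {
    a <- random_seqs(1, 8 + 3 * seed, seed = seed)
    b <- random_seqs(1, 30 - 2 * seed, seed = seed + 100)
    for (k in c(1L, 2L, 3L, 6L)) {
      expect_identical(tuple_count_score(a, b, k),
                       as.integer(oracle_tuple_count(a, b, k)),
                       info = sprintf("seed=%d k=%d", seed, k))
    }
  }
  # repeated-tuple cases where multiset minima matter
  expect_identical(tuple_count_score("AAAA", "AA", 2),
                   as.integer(oracle_tuple_count("AAAA", "AA", 2)))
  expect_identical(tuple_count_score("ABABAB", "BABA", 2),
                   as.integer(oracle_tuple_count("ABABAB", "BABA", 2)))
})

test_that("clustalo_distance applies shorter-length scaling", {
  expect_equal(clustalo_distance(zf, zf), 0)
  expect_equal(clustalo_distance("AAA", "CCC"), 1)
  expect_equal(clustalo_distance("AAC", "AAA"), 1 - 2 / 3)
})

test_that("muscle_distance applies shorter-6-tuple-count scaling", {
  expect_equal(muscle_distance(zf, zf), 0)
  expect_equal(muscle_distance("AAAAAAAAAA", "CCCCCCCCCC"), 1)
  # b = first 7 residues of a (all 6-tuples distinct): both of b's 6-tuples
  # occur in a, so the scaled distance is 1 - 2/2 = 0
  a <- "ACDEFGHIKLMN"
  b <- substr(a, 1, 7)
  expect_equal(muscle_distance(a, b), 0)
  expect_warning(d <- muscle_distance("ACD", "ACD"), "shorter")
  expect_equal(d, 1)
})

test_that("kalign stand-in distance behaves at its anchors and matches a direct recount", {
  expect_equal(kalign_distance("ACDEFGHIKL", "ACDEFGHIKL"), 0)
  expect_equal(kalign_distance("AAAAAAAAAA", "CCCCCCCCCC"), 1)
  # independent recount: loop over all tuple pairs, count shorter-sequence
  # tuples with any <=1-mismatch hit in the longer
  for (seed in c(3, 8)) {
    a <- random_seqs(1, 50, seed = seed)
    b <- random_seqs(1, 50, seed = seed + 50)
    # equal lengths: the scan runs over the lexicographically smaller
    # sequence's tuples (the canonical orientation)
    shr <- sort(c(a, b), method = "radix")[1L]
    lng <- setdiff(c(a, b), shr)
    ta <- oracle_tuples(lng, 6); tb <- oracle_tuples(shr, 6)
    hits <- 0
    for (i in seq_along(tb)) {
      ok <- FALSE
      for (j in seq_along(ta)) {
        mm <- sum(strsplit(tb[i], "")[[1]] != strsplit(ta[j], "")[[1]])
        if (mm <= 1) { ok <- TRUE; break }
      }
      if (ok) hits <- hits + 1
    }
    expected <- (1 - hits / length(tb)) * (50 / 50)
    expect_equal(kalign_distance(a, b), min(max(expected, 0), 1))
  }
})

test_that("mafft scale factor and two-stage distance match hand evaluation", {
  expect_equal(mafft_scale_factor(100, 100), 0.1 + 10000 / 10100 + 0.01,
               tolerance = 1e-12)
  expect_equal(mafft_scale_factor(200, 100), 0.05 + 10000 / 10200 + 0.01,
               tolerance = 1e-12)
  # monotone limit: x grows with y fixed -> f approaches 0.01
  f_vals <- vapply(c(1e3, 1e5, 1e7, 1e9), function(x) mafft_scale_factor(x, 50),
                   numeric(1))
  expect_true(all(diff(f_vals) < 0))
  expect_lt(f_vals[4], 0.0101)

  for (len in c(6, 22, 100)) {
    a <- random_seqs(1, len, seed = len)
    ps <- mafft_distance(a, a)
    expect_equal(ps$d_ij, 0)
    expect_equal(ps$d_prime, 0)
    expect_identical(ps$s_ii, as.integer(len - 5))
  }
  a <- paste(rep("A", 100), collapse = "")
  b <- paste(rep("C", 100), collapse = "")
  ps <- mafft_distance(a, b)
  expect_equal(ps$d_ij, 1)
  expect_equal(ps$d_prime, 1 / mafft_scale_factor(100, 100), tolerance = 1e-12)
})

test_that("nw_distance anchors and exhaustive-enumeration agreement", {
  expect_equal(nw_distance("ACDEFGHIK", "ACDEFGHIK"), 0)
  expect_equal(nw_distance("AAAA", "CCCC"), 1)
  sub <- blosum62()
  g <- gap_params()
  for (seed in 1:4) {
    la <- c(4L, 6L, 7L, 8L)[seed]; lb <- c(5L, 8L, 6L, 8L)[seed]
    a <- random_seqs(1, la, seed = seed * 11)
    b <- random_seqs(1, lb, seed = seed * 11 + 1)
    om <- oracle_pair_matrices(a, b, sub)
    oracle <- oracle_enum_align(om$score, g$open, g$extend, om$ident)
    aln <- pairwise_nw(a, b, sub = sub, gap = g)
    expect_equal(aln$score, oracle$score, tolerance = 1e-9)
    ident <- sum(aln$mat[1, ] == aln$mat[2, ] & aln$mat[1, ] != "-")
    expect_true(ident %in% oracle$idents)
    expect_equal(nw_distance(a, b, sub, g), 1 - ident / min(la, lb))
  }
})

test_that("every distance method is symmetric with zero self-distance on random pairs", {
  set <- random_seq_set(6, 40, seed = 21)
  pairs <- utils::combn(6, 2)
  fns <- list(clustalo = clustalo_distance,
              muscle = muscle_distance,
              kalign = kalign_distance,
              mafft = function(a, b) mafft_distance(a, b)$d_prime,
              nw = nw_distance)
  for (nm in names(fns)) {
    f <- fns[[nm]]
    for (p in seq_len(ncol(pairs))) {
      a <- set$seqs[pairs[1, p]]; b <- set$seqs[pairs[2, p]]
      expect_identical(f(a, b), f(b, a), info = nm)
      if (nm != "mafft") expect_gte(f(a, b), 0)
      if (nm != "mafft") expect_lte(f(a, b), 1)
    }
    expect_equal(f(set$seqs[1], set$seqs[1]), 0, info = nm)
  }
})

test_that("build_distance_matrix agrees with the pair functions and is exactly symmetric", {
  s <- random_seq_set(7, 35, seed = 31)
  pairfn <- list(clustalo1 = clustalo_distance,
                 muscle6 = muscle_distance,
                 kalign_mm = kalign_distance,
                 mafft6 = function(a, b) mafft_distance(a, b)$d_prime,
                 nw = nw_distance)
  for (meth in names(pairfn)) {
    dm <- build_distance_matrix(s, method_spec(meth))
    expect_identical(dm$values, t(dm$values))
    expect_true(all(diag(dm$values) == 0))
    for (i in 1:6) for (j in (i + 1):7) {
      expect_equal(dm$values[i, j], pairfn[[meth]](s$seqs[i], s$seqs[j]),
                   tolerance = 1e-12, info = meth)
    }
  }
  expect_error(build_distance_matrix(subset_set(s, 1),
                                     method_spec("clustalo1")))
})

test_that("same-length sets respect the distinct-value ceilings L+1 and L-4", {
  L <- 30
  s <- random_seq_set(50, L, seed = 41)
  d1 <- build_distance_matrix(s, method_spec("clustalo1"))
  expect_lte(length(unique(c(d1$values))), L + 1 + 1)  # +1 for the 0 diagonal
  expect_lte(count_unique_distances(d1)$n_unique, L + 1)
  d6 <- build_distance_matrix(s, method_spec("muscle6"))
  expect_lte(count_unique_distances(d6)$n_unique, L - 4)
  dm <- build_distance_matrix(s, method_spec("mafft6"))
  expect_lte(count_unique_distances(dm)$n_unique, L - 4)  # f constant here
})

test_that("symmetry_audit returns exactly zero for every method", {
  s <- random_seq_set(6, 25, seed = 51)
  for (meth in c("clustalo1", "muscle6", "kalign_mm", "mafft6", "nw")) {
    expect_identical(symmetry_audit(s, method_spec(meth)), 0, info = meth)
  }
  s2 <- random_seq_set(2, 20, seed = 52)
  expect_identical(symmetry_audit(s2, method_spec("clustalo1")), 0)
})
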