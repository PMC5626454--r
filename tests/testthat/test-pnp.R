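prof_of <- function(g) predicate_profiles(g)

test_that("share patterns follow the set-intersection definitions", {
  g <- kg(c("x", "x"), c("a", "b"), c("y", "z"))
  pr <- prof_of(g)
  hits <- detect_share(pr$a, pr$b)
  expect_equal(vapply(hits, `[[`, "", "pattern"), "SUBJECT_SHARE")
  expect_equal(hits[[1]]$evidence, "x")

  g2 <- kg(c("x", "w", "x", "w"), c("a", "a", "b", "b"), c("y", "z", "y", "z"))
  pr2 <- prof_of(g2)
  pats <- vapply(detect_share(pr2$a, pr2$b), `[[`, "", "pattern")
  expect_setequal(pats, c("SUBJECT_OBJECT_SHARE", "SUBJECT_SHARE",
                          "OBJECT_SHARE"))
  expect_error(detect_share(pr2$a, pr2$a), class = "predtopics_usage_error")
})

test_that("connection patterns: path, cycle (cycle implies path), key errors", {
  g <- kg(c("x", "y"), c("a", "b"), c("y", "z"))
  pats <- vapply(detect_connection(g, "a", "b"), `[[`, "", "pattern")
  expect_equal(pats, "PATH_CONNECTIVITY")

  g2 <- kg(c("x", "y"), c("a", "b"), c("y", "x"))
  pats2 <- vapply(detect_connection(g2, "a", "b"), `[[`, "", "pattern")
  expect_setequal(pats2, c("CYCLE_CONNECTIVITY", "PATH_CONNECTIVITY"))
  ## symmetric in the argument order
  pats3 <- vapply(detect_connection(g2, "b", "a"), `[[`, "", "pattern")
  expect_setequal(pats3, pats2)
  expect_error(detect_connection(g2, "a", "missing"),
               class = "predtopics_key_error")
})

test_that("share and connection detection match exhaustive oracles on random graphs", {
  for (seed in 1:25) {
    g <- random_kg(sample(20:120, 1), sample(4:12, 1),
                   n_concepts = sample(6:25, 1), seed = seed)
    preds <- predicates(g)
    pr <- prof_of(g)
    pairs <- utils::combn(preds, 2)
    for (j in seq_len(ncol(pairs))) {
      a <- pairs[1, j]; b <- pairs[2, j]
      expect_setequal(vapply(detect_share(pr[[a]], pr[[b]]), `[[`, "",
                             "pattern"),
                      oracle_share(g, a, b))
      expect_setequal(vapply(detect_connection(g, a, b), `[[`, "", "pattern"),
                      oracle_connection(g, a, b))
    }
  }
})

test_that("pairwise similarity reproduces hand-computed cases", {
  ## identical profiles -> w_so * 1
  g <- kg(c("x", "x"), c("a", "b"), c("y", "y"))
  pr <- prof_of(g)
  expect_equal(pnp_similarity(g, pr$a, pr$b), 1.0)

  ## disjoint, unconnected -> 0
  g2 <- kg(c("x", "u"), c("a", "b"), c("y", "v"))
  pr2 <- prof_of(g2)
  expect_equal(pnp_similarity(g2, pr2$a, pr2$b), 0)

  ## subject Jaccard 1/3, no object overlap, no connection -> 0.8 * (1/3)
  g3 <- kg(c("x", "y", "y", "z"), c("a", "a", "b", "b"),
           c("o1", "o2", "o3", "o4"))
  pr3 <- prof_of(g3)
  expect_equal(pnp_similarity(g3, pr3$a, pr3$b), 0.8 * (1 / 3))

  ## connection-only pair scores the path weight
  g4 <- kg(c("x", "y"), c("a", "b"), c("y", "z"))
  pr4 <- prof_of(g4)
  expect_equal(pnp_similarity(g4, pr4$a, pr4$b), 0.5)
  expect_equal(pnp_similarity(g4, pr4$a, pr4$b,
                              pnp_config(w_path = 0.25)), 0.25)
})

test_that("similarity matrix has unit diagonal, symmetry, [0,1] range, and matches the per-pair oracle", {
  g <- kg(c("x", "x"), c("a", "b"), c("y", "y"))
  m <- similarity_matrix(g)
  expect_equal(unclass(m), matrix(1, 2, 2, dimnames = list(c("a", "b"),
                                                           c("a", "b"))),
               ignore_attr = TRUE)
  expect_error(similarity_matrix(kg("x", "a", "y")),
               class = "predtopics_usage_error")

  for (seed in 1:10) {
    g2 <- random_kg(sample(40:150, 1), 15, n_concepts = 20, seed = 200 + seed)
    m2 <- unclass(similarity_matrix(g2))
    expect_true(isSymmetric(m2))
    expect_equal(unname(diag(m2)), rep(1, nrow(m2)))
    expect_true(all(m2 >= 0 & m2 <= 1))
    preds <- rownames(m2)
    idx <- utils::combn(seq_along(preds), 2)
    pick <- idx[, sample(ncol(idx), 12)]
    for (j in seq_len(ncol(pick))) {
      a <- preds[pick[1, j]]; b <- preds[pick[2, j]]
      expect_equal(m2[a, b], oracle_similarity(g2, a, b))
    }
  }
})

test_that("adding a shared subject never decreases similarity", {
  base <- data.frame(s = c("x1", "x2", "u1", "u2"),
                     p = c("a", "a", "b", "b"),
                     o = c("y1", "y2", "v1", "v2"))
  g0 <- kg(base$s, base$p, base$o)
  pr0 <- prof_of(g0)
  s0 <- pnp_similarity(g0, pr0$a, pr0$b)
  ## grow the shared subject set one concept at a time
  shared <- sprintf("sh%d", 1:4)
  prev <- s0
  for (k in seq_along(shared)) {
    add <- data.frame(s = rep(shared[1:k], 2),
                      p = rep(c("a", "b"), each = k),
                      o = c(sprintf("ya%d", 1:k), sprintf("yb%d", 1:k)))
    gk <- kg(c(base$s, add$s), c(base$p, add$p), c(base$o, add$o))
    prk <- prof_of(gk)
    sk <- pnp_similarity(gk, prk$a, prk$b)
    expect_gte(sk, prev - 1e-12)
    prev <- sk
  }
})

test_that("a five-predicate toy graph exhibits a pattern on every pair", {
  ## a hub subject joins all five predicates; p1/p2 and p4/p5 overlap more
  g <- kg(subject = c("s0", "sA", "s0", "sA", "s0", "s0", "sB", "s0", "sB"),
          predicate = c("p1", "p1", "p2", "p2", "p3", "p4", "p4", "p5", "p5"),
          object = c("b1", "b2", "c1", "c2", "d1", "e1", "e2", "f1", "f2"))
  pr <- prof_of(g)
  m <- unclass(similarity_matrix(g))
  combos <- utils::combn(sprintf("p%d", 1:5), 2)
  for (j in seq_len(ncol(combos))) {
    ab <- combos[, j]
    share <- detect_share(pr[[ab[1]]], pr[[ab[2]]])
    conn <- detect_connection(g, ab[1], ab[2])
    expect_gt(length(share) + length(conn), 0)
  }
  ## strongly overlapping subject sets outscore single-hub overlap
  expect_gt(m["p1", "p2"], m["p1", "p4"])
  expect_equal(m["p1", "p2"], 0.8 * 1)
  expect_equal(m["p1", "p4"], 0.8 * (1 / 3))
})

test_that("similarity matrices round-trip through TSV and CSV", {
  g <- random_kg(60, 6, seed = 5)
  m <- similarity_matrix(g)
  for (fmt in c("tsv", "csv")) {
    f <- withr::local_tempfile(fileext = paste0(".", fmt))
    write_similarity(m, f, fmt)
    back <- read_similarity(f, fmt)
    expect_equal(unclass(back), unclass(m), tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
})
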