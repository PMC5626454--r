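## The worked three-predicate cluster: uci (highest degree) with
## sim(uci, held) = 0.6 and sim(uci, transferred) = 0.5.
worked_cluster <- function() {
  g <- kg(subject = c("patient", "patient", "patient", "nurse"),
          predicate = c("uci", "uci", "held", "transferred"),
          object = c("catheter", "drain", "catheter", "ward"),
          domain = c("ILEUS", "ILEUS", "BLEED", "ABSCESS"))
  m <- matrix(0, 3, 3, dimnames = list(c("uci", "held", "transferred"),
                                       c("uci", "held", "transferred")))
  diag(m) <- 1
  m["uci", "held"] <- m["held", "uci"] <- 0.6
  m["uci", "transferred"] <- m["transferred", "uci"] <- 0.5
  m["held", "transferred"] <- m["transferred", "held"] <- 0.2
  list(g = g, m = structure(m, class = c("similarity_matrix", "matrix")))
}

test_that("cluster graphs keep exactly the nonzero-similarity edges", {
  w <- worked_cluster()
  cg <- cluster_graph(c("uci", "held", "transferred"), w$m, w$g)
  expect_equal(nrow(cg$edges), 3L)
  expect_equal(unname(cg$degrees), c(2, 1, 1))

  cg1 <- cluster_graph("uci", w$m, w$g)
  expect_equal(length(cg1$nodes), 1L)
  expect_equal(nrow(cg1$edges), 0L)

  ## triangle when all pairs are similar
  m3 <- matrix(0.7, 3, 3); diag(m3) <- 1
  dimnames(m3) <- list(c("a", "b", "c"), c("a", "b", "c"))
  g3 <- kg(c("x", "y", "z"), c("a", "b", "c"), c("u", "v", "w"))
  expect_equal(nrow(cluster_graph(c("a", "b", "c"), m3, g3)$edges), 3L)

  ## random leaf: edges equal the nonzero-entry scan of the submatrix
  g4 <- random_kg(120, 10, seed = 6)
  m4 <- similarity_matrix(g4)
  leaf <- predicates(g4)[1:6]
  cg4 <- cluster_graph(leaf, m4, g4)
  idx <- utils::combn(leaf, 2)
  nz <- sum(unclass(m4)[cbind(idx[1, ], idx[2, ])] > 0)
  expect_equal(nrow(cg4$edges), nz)
  expect_error(cluster_graph(character(0), m4, g4),
               class = "predtopics_usage_error")
  expect_error(cluster_graph("nope", m4, g4), class = "predtopics_key_error")
})

test_that("the worked crawl visits uci, held, transferred and thresholds to {uci, held}", {
  w <- worked_cluster()
  cg <- cluster_graph(c("uci", "held", "transferred"), w$m, w$g)
  qg <- crawl(cg, t = 0)
  expect_equal(qg$visited_order, c("uci", "held", "transferred"))
  expect_setequal(qg$kept_nodes, c("uci", "held", "transferred"))

  qg6 <- crawl(cg, t = 0.6)
  expect_setequal(qg6$kept_nodes, c("uci", "held"))
  expect_error(crawl(cg, t = 1.5), class = "predtopics_usage_error")
})

test_that("crawling is deterministic, anti-monotone in t, and covers the component at t = 0", {
  set.seed(14)
  for (rep_i in 1:8) {
    nodes <- sprintf("n%d", 1:6)
    idx <- utils::combn(nodes, 2)
    keep <- stats::runif(ncol(idx)) < 0.6
    edges <- data.frame(a = idx[1, keep], b = idx[2, keep],
                        similarity = round(stats::runif(sum(keep)), 2),
                        stringsAsFactors = FALSE)
    degrees <- stats::setNames(sample(1:10, 6), nodes)
    cg <- structure(list(nodes = nodes, edges = edges, degrees = degrees),
                    class = "cluster_graph")
    t0 <- crawl(cg, 0)
    expect_identical(t0$visited_order, crawl(cg, 0)$visited_order)
    ## step-by-step hand simulation oracle
    orc <- oracle_crawl(nodes, edges, degrees, 0)
    expect_identical(t0$visited_order, orc$order)
    prev <- NULL
    for (t in c(0, 0.3, 0.6, 0.9)) {
      kept <- crawl(cg, t)$kept_nodes
      orc_t <- oracle_crawl(nodes, edges, degrees, t)
      expect_setequal(kept, orc_t$kept)
      if (!is.null(prev)) expect_true(all(kept %in% prev))
      prev <- kept
    }
    ## component coverage at t = 0
    start <- t0$visited_order[1]
    reach <- start
    repeat {
      nxt <- unique(c(edges$b[edges$a %in% reach],
                      edges$a[edges$b %in% reach]))
      nxt <- setdiff(nxt, reach)
      if (!length(nxt)) break
      reach <- c(reach, nxt)
    }
    expect_setequal(t0$visited_order, reach)
  }
})

test_that("single-predicate query graphs emit one pattern with fresh variables", {
  g <- kg("patient", "uci", "catheter")
  qg <- structure(list(visited_order = "uci",
                       traversed = data.frame(),
                       kept_edges = data.frame(a = character(0),
                                               b = character(0),
                                               similarity = numeric(0)),
                       kept_nodes = "uci", threshold = 0),
                  class = "query_graph")
  q <- generate_sparql(qg, g)
  expect_match(q$text, "SELECT DISTINCT \\?v0 \\?v1")
  expect_match(q$text, "\\?v0 <urn:pt:uci> \\?v1 \\.")
  expect_equal(nrow(match_query(q, g)), 1L)
})

test_that("path-connected predicates share the chaining variable", {
  g <- kg(c("x", "y"), c("a", "b"), c("y", "z"))
  m <- similarity_matrix(g)
  cg <- cluster_graph(c("a", "b"), m, g)
  q <- generate_sparql(crawl(cg, 0), g)
  expect_equal(nrow(q$triple_patterns), 2L)
  vars <- unique(c(q$triple_patterns$s, q$triple_patterns$o))
  expect_length(vars, 3L)
  pa <- q$triple_patterns[q$triple_patterns$predicate == "a", ]
  pb <- q$triple_patterns[q$triple_patterns$predicate == "b", ]
  expect_equal(pa$o, pb$s)
  sol <- match_query(q, g)
  expect_equal(nrow(sol), 1L)
  expect_equal(sol[[pa$s]], "x")
  expect_equal(sol[[pb$o]], "z")
})

test_that("share-unified queries stay satisfiable on their source graph", {
  gen <- synth_kg(synth_spec(seed = 4))
  g <- gen$graph
  m <- similarity_matrix(g)
  fit <- suppressWarnings(hfcm(m, g, alpha = ceiling(n_triples(g) / 4),
                               seed = 4))
  for (leaf in fit$leaves) {
    qg <- crawl(cluster_graph(leaf, m, g), t = 0)
    for (strict in c(FALSE, TRUE)) {
      q <- generate_sparql(qg, g, strict = strict)
      expect_gte(nrow(match_query(q, g, limit = 1L)), 1L)
    }
  }
})

test_that("queries serialise as .rq text and parse under a SPARQL 1.1 grammar", {
  g <- kg(c("x", "y"), c("a", "b"), c("y", "z"))
  q <- generate_sparql(crawl(cluster_graph(c("a", "b"),
                                           similarity_matrix(g), g), 0), g)
  f <- withr::local_tempfile(fileext = ".rq")
  write_query(q, f)
  expect_identical(paste(readLines(f), collapse = "\n"),
                   sub("\n$", "", q$text))
  parse_check <- system2("python", c("-c", shQuote(paste0(
    "import sys; from rdflib.plugins.sparql import prepareQuery; ",
    "prepareQuery(open(sys.argv[1]).read())")), f),
    stdout = TRUE, stderr = TRUE)
  expect_equal(attr(parse_check, "status") %||% 0L, 0L)
})
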