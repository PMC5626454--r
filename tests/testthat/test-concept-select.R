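## the worked counts are internally inconsistent (n_co > n_o), so building
## them warns but still scores
worked_counts <- suppressWarnings(cooccurrence(
  data.frame(concept = "uci", domain = "ILEUS",
             n_c = 600, n_o = 400, n_co = 500), N = 1980))

test_that("association score equals the closed-form smoothed PMI", {
  ## hand evaluation of log2(((500 + 0.01) * 1980) / (600 * 400))
  expect_equal(concept_inequality(worked_counts, "uci", "ILEUS"),
               log2((500.01 * 1980) / (600 * 400)))
  expect_equal(concept_inequality(worked_counts, "uci", "ILEUS"),
               2.044424, tolerance = 1e-5)
})

test_that("independent concept and domain score about zero", {
  cc <- cooccurrence(data.frame(concept = "c", domain = "o",
                                n_c = 20, n_o = 50, n_co = 10), N = 100)
  expect_lt(abs(concept_inequality(cc, "c", "o")), 0.002)
})

test_that("score is strictly increasing in the joint count and signed by independence", {
  mk <- function(nco) cooccurrence(
    data.frame(concept = "c", domain = "o", n_c = 30, n_o = 40, n_co = nco),
    N = 200)
  sc <- vapply(0:30, function(n) concept_inequality(mk(n), "c", "o"), 0)
  expect_true(all(diff(sc) > 0))
  ## sign flips exactly where (n_co + eps)/N crosses (n_c/N)(n_o/N)
  indep <- 30 * 40 / 200
  expect_true(all((sc > 0) == ((0:30 + 0.01) > indep)))
})

test_that("eps = 0 yields -Inf for zero joint counts, which rank last", {
  cc <- cooccurrence(data.frame(concept = c("a", "b"), domain = "o",
                                n_c = c(10, 10), n_o = 50, n_co = c(0, 5)),
                     N = 100)
  expect_identical(concept_inequality(cc, "a", "o", eps = 0), -Inf)
  r <- rank_concepts(cc, "o", k = 2, eps = 0)
  expect_equal(r$ranked$concept, c("b", "a"))
})

test_that("scoring errors are classed: missing pair, zero marginals, bad eps", {
  expect_error(concept_inequality(worked_counts, "uci", "BLEED"),
               class = "predtopics_key_error")
  cc <- cooccurrence(data.frame(concept = "c", domain = "o",
                                n_c = 0, n_o = 10, n_co = 0), N = 100)
  expect_error(concept_inequality(cc, "c", "o"),
               class = "predtopics_domain_error")
  expect_error(concept_inequality(worked_counts, "uci", "ILEUS", eps = -1),
               class = "predtopics_usage_error")
  expect_warning(cooccurrence(data.frame(concept = "c", domain = "o",
                                         n_c = 5, n_o = 10, n_co = 7), N = 100),
                 "inconsistent")
  expect_error(cooccurrence(data.frame(concept = "c", domain = "o",
                                       n_c = 5, n_o = 10, n_co = -1), N = 100),
               class = "predtopics_validation_error")
})

test_that("ranking keeps the top k, breaks ties lexicographically, matches a full sort", {
  cc <- cooccurrence(data.frame(concept = c("a", "b", "c"), domain = "o",
                                n_c = c(10, 10, 10), n_o = 50,
                                n_co = c(9, 6, 3)), N = 100)
  expect_equal(rank_concepts(cc, "o", k = 2)$ranked$concept, c("a", "b"))

  tie <- cooccurrence(data.frame(concept = c("zeta", "beta"), domain = "o",
                                 n_c = 10, n_o = 50, n_co = 5), N = 100)
  expect_equal(rank_concepts(tie, "o", k = 2)$ranked$concept,
               c("beta", "zeta"))

  set.seed(31)
  n <- 100
  big <- cooccurrence(data.frame(
    concept = sprintf("c%03d", seq_len(n)), domain = "o",
    n_c = sample(5:80, n, TRUE), n_o = 90,
    n_co = sample(0:5, n, TRUE)), N = 500)
  r <- rank_concepts(big, "o", k = 60)
  sc <- concept_inequality(big, big$entries$concept, "o")
  full <- big$entries$concept[order(-sc, big$entries$concept,
                                    method = "radix")]
  expect_equal(r$ranked$concept, full[1:60])
  ## prefix property: smaller k is a prefix of larger k
  expect_equal(rank_concepts(big, "o", k = 10)$ranked$concept, full[1:10])
})

test_that("a domain with no concepts warns and yields an empty ranking", {
  expect_warning(r <- rank_concepts(worked_counts, "NONE", k = 5),
                 "no concepts")
  expect_equal(nrow(r$ranked), 0L)
})

test_that("triple filtering keeps OR-matches per domain and equals a membership oracle", {
  g <- kg(c("uci", "x", "y"), c("p", "p", "q"), c("z", "catheter", "w"),
          domain = c("A", "A", "B"))
  ra <- structure(list(domain = "A",
                       ranked = data.frame(rank = 1:2,
                                           concept = c("uci", "catheter"),
                                           score = c(2, 1)), k = 2),
                  class = "concept_ranking")
  rb <- structure(list(domain = "B",
                       ranked = data.frame(rank = 1L, concept = "none",
                                           score = 0), k = 1),
                  class = "concept_ranking")
  out <- filter_triples(g, list(ra, rb))
  ## subject match and object match retained; neither-term triple dropped
  expect_equal(n_triples(out), 2L)
  expect_setequal(out$triples$subject, c("uci", "x"))
  expect_error(filter_triples(g, list(ra)),
               class = "predtopics_configuration_error")

  ## 500-triple random graph vs exhaustive membership test
  g2 <- random_kg(500, 10, n_concepts = 30, seed = 77, n_domains = 3)
  cons <- sprintf("c%02d", 1:30)
  rks <- lapply(domains(g2), function(d) {
    set.seed(match(d, domains(g2)))
    structure(list(domain = d,
                   ranked = data.frame(rank = 1:8,
                                       concept = sample(cons, 8),
                                       score = 8:1), k = 8),
              class = "concept_ranking")
  })
  out2 <- filter_triples(g2, rks)
  tops <- stats::setNames(lapply(rks, function(r) r$ranked$concept),
                          vapply(rks, `[[`, "", "domain"))
  keep <- mapply(function(s, o, d) s %in% tops[[d]] || o %in% tops[[d]],
                 g2$triples$subject, g2$triples$object, g2$triples$domain)
  expect_equal(n_triples(out2), sum(keep))
})

test_that("co-occurrence TSV round-trips with its total-count header", {
  f <- withr::local_tempfile(fileext = ".tsv")
  write_cooccurrence(worked_counts, f)
  back <- suppressWarnings(read_cooccurrence(f))
  expect_equal(back$N, 1980)
  expect_equal(back$entries, worked_counts$entries)
  expect_equal(suppressWarnings(read_cooccurrence(f, total_n = 2000))$N, 2000)
  f2 <- withr::local_tempfile(fileext = ".tsv")
  r <- rank_concepts(worked_counts, "ILEUS", k = 1)
  write_ranking(r, f2)
  expect_equal(utils::read.delim(f2)$concept, "uci")
})
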