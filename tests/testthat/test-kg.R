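test_that("N-Triples parsing preserves statements, handles empties and duplicates", {
  f <- withr::local_tempfile(fileext = ".nt")
  writeLines(c("<urn:a> <urn:p> <urn:b> .",
               "<urn:c> <urn:p> <urn:b> .",
               "<urn:a> <urn:q> \"a literal\" ."), f)
  g <- read_kg(f, "ntriples")
  expect_equal(n_triples(g), 3L)
  expect_setequal(predicates(g), c("urn:p", "urn:q"))
  expect_true(g$triples$object_literal[3])

  writeLines(character(0), f)
  expect_equal(n_triples(read_kg(f, "ntriples")), 0L)

  writeLines(rep("<urn:a> <urn:p> <urn:b> .", 2), f)
  expect_warning(g2 <- read_kg(f, "ntriples"), "duplicate")
  expect_equal(n_triples(g2), 1L)
  expect_equal(attr(g2, "duplicates"), 1L)
})

test_that("parse errors name the offending line; bad inputs raise usage errors", {
  f <- withr::local_tempfile(fileext = ".nt")
  writeLines(c("<urn:a> <urn:p> <urn:b> .", "not a triple"), f)
  expect_error(read_kg(f, "ntriples"), "line 2",
               class = "predtopics_parse_error")
  expect_error(read_kg(file.path(tempdir(), "nope.nt")),
               class = "predtopics_io_error")
  expect_error(read_kg(f, "json"))
})

test_that("Turtle subset and the TSV dialect parse to the same triples", {
  ttl <- withr::local_tempfile(fileext = ".ttl")
  writeLines(c("@prefix ex: <http://ex.org/> .",
               "ex:a ex:p ex:b , ex:c ;",
               "     ex:q \"lit\" .",
               "<http://ex.org/d> a ex:Thing ."), ttl)
  g <- read_kg(ttl, "turtle")
  expect_equal(n_triples(g), 4L)
  expect_true("http://ex.org/a" %in% g$triples$subject)
  expect_true(any(g$triples$predicate ==
                    "http://www.w3.org/1999/02/22-rdf-syntax-ns#type"))

  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("subject\tpredicate\tobject\tdomain",
               "patient\tuci\tcatheter\tILEUS",
               "patient\theld\tdrip\tBLEED"), tsv)
  g2 <- read_kg(tsv)
  expect_equal(n_triples(g2), 2L)
  expect_equal(domains(g2), c("BLEED", "ILEUS"))
  g3 <- read_kg(tsv, domain = "X")
  expect_equal(domains(g3), "X")
})

test_that("RDF/XML descriptions with resources, literals and types are read", {
  f <- withr::local_tempfile(fileext = ".rdf")
  writeLines(c(
    '<?xml version="1.0"?>',
    '<rdf:RDF xmlns:rdf="http://www.w3.org/1999/02/22-rdf-syntax-ns#"',
    '         xmlns:ex="http://ex.org/">',
    '  <rdf:Description rdf:about="http://ex.org/a">',
    '    <ex:p rdf:resource="http://ex.org/b"/>',
    '    <ex:q>forty-two</ex:q>',
    '  </rdf:Description>',
    '  <ex:Thing rdf:about="http://ex.org/c"/>',
    '</rdf:RDF>'), f)
  g <- read_kg(f, "rdfxml")
  expect_equal(n_triples(g), 3L)
  expect_true(any(g$triples$object == "forty-two" & g$triples$object_literal))
  expect_true(any(g$triples$predicate ==
                    "http://www.w3.org/1999/02/22-rdf-syntax-ns#type"))
})

test_that("write/read round trip is the identity on the triple set", {
  g <- random_kg(60, 8, seed = 42)
  f <- withr::local_tempfile(fileext = ".nt")
  write_kg(g, f, "ntriples")
  expect_kg_equal(read_kg(f, domain = NULL), kg(g$triples$subject,
                                                g$triples$predicate,
                                                g$triples$object))
  ## domain tags survive the TSV dialect
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_kg(g, f2, "tsv")
  expect_kg_equal(read_kg(f2), g)
})

test_that("merge_kg unions triples and is commutative, associative, idempotent", {
  a <- kg(c("x", "y"), c("p", "p"), c("1", "2"), domain = "D1")
  b <- kg(c("u", "v"), c("q", "q"), c("3", "4"), domain = "D2")
  m <- merge_kg(a, b)
  expect_equal(n_triples(m), 4L)
  expect_equal(domains(m), c("D1", "D2"))
  expect_kg_equal(merge_kg(a, a), a)
  expect_kg_equal(merge_kg(a, b), merge_kg(b, a))
  c3 <- random_kg(20, 4, seed = 9)
  expect_kg_equal(merge_kg(merge_kg(a, b), c3), merge_kg(a, merge_kg(b, c3)))
  expect_error(merge_kg(), class = "predtopics_usage_error")
})

test_that("merging six domain graphs matches the brute-force set union", {
  sizes <- c(220, 142, 32, 624, 132, 60)
  gs <- lapply(seq_along(sizes), function(i) {
    g <- random_kg(sizes[i], 12, n_concepts = 40, seed = 100 + i,
                   n_domains = 1)
    g$triples$domain <- sprintf("D%d", i)
    g
  })
  m <- merge_kg(gs)
  keys <- unlist(lapply(gs, function(g)
    paste(g$triples$subject, g$triples$predicate, g$triples$object,
          g$triples$domain, sep = "\r")))
  expect_equal(n_triples(m), length(unique(keys)))
  expect_equal(length(domains(m)), 6L)
})

test_that("predicate profiles equal an exhaustive per-predicate scan", {
  g <- kg(c("a", "c"), c("p", "p"), c("b", "b"))
  pr <- predicate_profiles(g)
  expect_setequal(pr$p$subjects, c("a", "c"))
  expect_equal(pr$p$objects, "b")
  expect_equal(pr$p$degree, 2L)

  g2 <- random_kg(200, 15, seed = 7)
  pr2 <- predicate_profiles(g2)
  orc <- oracle_profiles(g2)
  expect_setequal(names(pr2), names(orc))
  for (p in names(orc)) {
    expect_setequal(pr2[[p]]$subjects, orc[[p]]$subjects)
    expect_setequal(pr2[[p]]$objects, orc[[p]]$objects)
    expect_equal(pr2[[p]]$degree, orc[[p]]$degree)
  }
  ## degrees always partition the triple count
  expect_equal(sum(vapply(pr2, `[[`, 0, "degree")), n_triples(g2))
  expect_error(predicate_profiles(kg(character(0), character(0), character(0))),
               class = "predtopics_usage_error")
})

test_that("GraphML and DOT exports carry the graph's node and edge counts", {
  g <- kg(c("a", "b", "a"), c("p", "q", "q"), c("b", "c", "c"))
  f <- withr::local_tempfile(fileext = ".graphml")
  export_graph(g, f, "graphml")
  doc <- xml2::read_xml(f)
  expect_length(xml2::xml_find_all(doc, "//*[local-name()='node']"), 3L)
  expect_length(xml2::xml_find_all(doc, "//*[local-name()='edge']"), 3L)

  fd <- withr::local_tempfile(fileext = ".dot")
  export_graph(g, fd, "dot")
  lines <- readLines(fd)
  expect_length(grep("label=.*\\];$", grep("--|->", lines, value = TRUE)), 3L)
  expect_error(export_graph(g, f, "png"))
  cg <- cluster_graph("p", similarity_matrix(g), g)
  export_graph(cg, f, "graphml")
  expect_length(xml2::xml_find_all(xml2::read_xml(f),
                                   "//*[local-name()='node']"), 1L)
})
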