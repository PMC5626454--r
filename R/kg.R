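## Knowledge-graph container and RDF input/output.
##
## Triples are stored as plain character strings after IRI normalisation:
## full IRIs keep their text, while bare lexicon labels (the normal case for
## clinical-triple data, e.g. {patient, uci, catheter}) stay as labels and are
## serialised under the reserved "urn:pt:" base so that a write/read cycle is
## an identity on the triple set.

.pt_base <- "urn:pt:"
.rdf_type <- "http://www.w3.org/1999/02/22-rdf-syntax-ns#type"

#' Construct a knowledge graph from term vectors
#'
#' A knowledge graph is an insertion-ordered set of subject-predicate-object
#' triples, each optionally tagged with the domain (source graph) it came
#' from. Duplicate triples (identical in all four fields) are collapsed with a
#' warning; the number dropped is kept in the `"duplicates"` attribute.
#'
#' @param subject,predicate,object character vectors of equal length; IRIs or
#'   bare labels. Empty strings are rejected.
#' @param domain optional domain tag, recycled to the triple count; `NA` means
#'   untagged.
#' @param object_literal logical, recycled; marks objects that are RDF
#'   literals rather than resources (only affects serialisation).
#' @return an object of class `kg`.
#' @examples
#' g <- kg(c("a", "c"), c("p", "p"), c("b", "b"), domain = "D1")
#' n_triples(g)
#' @export
kg <- function(subject, predicate, object, domain = NA_character_,
               object_literal = FALSE) {
  n <- length(subject)
  if (length(predicate) != n || length(object) != n)
    pt_stop("usage", "subject, predicate and object must have equal length")
  subject <- as.character(subject)
  predicate <- as.character(predicate)
  object <- as.character(object)
  domain <- rep_len(as.character(domain), max(n, 1L))[seq_len(n)]
  object_literal <- rep_len(as.logical(object_literal), max(n, 1L))[seq_len(n)]
  if (n > 0 && (any(!nzchar(subject)) || any(!nzchar(predicate)) ||
                any(!nzchar(object))))
    pt_stop("validation", "subject, predicate and object must be non-empty")
  tr <- data.frame(subject = subject, predicate = predicate, object = object,
                   domain = domain, object_literal = object_literal,
                   stringsAsFactors = FALSE)
  key <- paste(tr$subject, tr$predicate, tr$object, tr$domain, sep = "\r")
  dup <- duplicated(key)
  ndup <- sum(dup)
  if (ndup > 0) {
    pt_warn("collapsed %d duplicate triple(s)", ndup)
    tr <- tr[!dup, , drop = FALSE]
    rownames(tr) <- NULL
  }
  structure(list(triples = tr), duplicates = ndup, class = "kg")
}

#' @export
print.kg <- function(x, ...) {
  cat(sprintf("<kg> %d triple(s), %d predicate(s), %d domain(s)\n",
              n_triples(x), length(predicates(x)), length(domains(x))))
  if (n_triples(x) > 0) {
    show <- utils::head(x$triples[, c("subject", "predicate", "object",
                                      "domain")], 6L)
    print(show, row.names = FALSE)
    if (n_triples(x) > 6) cat(sprintf("... and %d more\n", n_triples(x) - 6L))
  }
  invisible(x)
}

#' @export
summary.kg <- function(object, ...) {
  pr <- predicate_profiles(object)
  deg <- vapply(pr, function(p) p$degree, numeric(1))
  out <- list(n_triples = n_triples(object),
              n_subjects = length(unique(object$triples$subject)),
              n_predicates = length(pr),
              n_objects = length(unique(object$triples$object)),
              domains = domains(object),
              degree_summary = summary(deg))
  class(out) <- "summary.kg"
  out
}

#' @export
print.summary.kg <- function(x, ...) {
  cat(sprintf("Knowledge graph: %d triples | %d subjects | %d predicates | %d objects\n",
              x$n_triples, x$n_subjects, x$n_predicates, x$n_objects))
  if (length(x$domains))
    cat("Domains:", paste(x$domains, collapse = ", "), "\n")
  cat("Predicate degree distribution:\n")
  print(x$degree_summary)
  invisible(x)
}

#' Basic accessors for `kg` objects
#'
#' @param x a `kg`.
#' @return `n_triples()` the triple count; `predicates()` the distinct
#'   predicate labels in first-appearance order; `domains()` the non-missing
#'   domain tags present.
#' @export
n_triples <- function(x) nrow(x$triples)

#' @rdname n_triples
#' @export
predicates <- function(x) unique(x$triples$predicate)

#' @rdname n_triples
#' @export
domains <- function(x) {
  d <- unique(x$triples$domain)
  lex_sort(d[!is.na(d)])
}

triple_key <- function(x)
  paste(x$triples$subject, x$triples$predicate, x$triples$object,
        x$triples$domain, sep = "\r")

#' Test two knowledge graphs for triple-set equality
#'
#' Order-insensitive comparison of the (subject, predicate, object, domain)
#' sets.
#' @param a,b `kg` objects.
#' @export
kg_equal <- function(a, b) setequal(triple_key(a), triple_key(b))

## ---------------------------------------------------------------- parsing --

normalize_iri <- function(iri) {
  ifelse(startsWith(iri, .pt_base),
         vapply(substring(iri, nchar(.pt_base) + 1L), utils::URLdecode, "",
                USE.NAMES = FALSE),
         iri)
}

label_to_iri <- function(term) {
  has_scheme <- grepl("^[A-Za-z][A-Za-z0-9+.-]*:", term) | startsWith(term, "_:")
  enc <- vapply(term, function(t) utils::URLencode(t, reserved = TRUE), "",
                USE.NAMES = FALSE)
  ifelse(has_scheme, term, paste0(.pt_base, enc))
}

unescape_literal <- function(x) {
  x <- gsub("\\\\t", "\t", x)
  x <- gsub("\\\\n", "\n", x)
  x <- gsub("\\\\r", "\r", x)
  x <- gsub("\\\\\"", "\"", x)
  gsub("\\\\\\\\", "\\\\", x)
}

escape_literal <- function(x) {
  x <- gsub("\\\\", "\\\\\\\\", x)
  x <- gsub("\"", "\\\\\"", x)
  x <- gsub("\n", "\\\\n", x)
  x <- gsub("\r", "\\\\r", x)
  gsub("\t", "\\\\t", x)
}

## Parse one RDF term token as found by the tokenizer / N-Triples regex.
parse_term <- function(tok, prefixes = NULL, base = NULL, line = NA) {
  if (startsWith(tok, "<")) {
    iri <- substr(tok, 2L, nchar(tok) - 1L)
    if (!is.null(base) && !grepl("^[A-Za-z][A-Za-z0-9+.-]*:", iri))
      iri <- paste0(base, iri)
    list(value = normalize_iri(iri), literal = FALSE)
  } else if (startsWith(tok, "\"")) {
    lex <- sub("^\"((?:[^\"\\\\]|\\\\.)*)\".*$", "\\1", tok, perl = TRUE)
    list(value = unescape_literal(lex), literal = TRUE)
  } else if (startsWith(tok, "_:")) {
    list(value = tok, literal = FALSE)
  } else if (tok == "a") {
    list(value = .rdf_type, literal = FALSE)
  } else if (grepl("^[A-Za-z_][A-Za-z0-9_.-]*:", tok) || startsWith(tok, ":")) {
    px <- sub(":.*$", "", tok)
    local <- sub("^[^:]*:", "", tok)
    if (is.null(prefixes) || is.na(prefixes[px]))
      pt_stop("parse", "undeclared prefix '%s:' (line %s)", px, line)
    list(value = normalize_iri(paste0(prefixes[[px]], local)), literal = FALSE)
  } else if (grepl("^[+-]?[0-9]", tok) || tok %in% c("true", "false")) {
    list(value = tok, literal = TRUE)
  } else {
    pt_stop("parse", "cannot parse RDF term '%s' (line %s)", tok, line)
  }
}

.nt_line_re <- paste0(
  "^\\s*(<[^>]*>|_:[A-Za-z0-9]+)\\s+(<[^>]*>)\\s+",
  "(<[^>]*>|_:[A-Za-z0-9]+|\"(?:[^\"\\\\]|\\\\.)*\"",
  "(?:\\^\\^<[^>]*>|@[A-Za-z]+(?:-[A-Za-z0-9]+)*)?)\\s*\\.\\s*$")

parse_ntriples <- function(lines) {
  keep <- which(nzchar(trimws(lines)) & !grepl("^\\s*#", lines))
  s <- p <- o <- character(length(keep))
  lit <- logical(length(keep))
  for (i in seq_along(keep)) {
    ln <- lines[keep[i]]
    m <- regmatches(ln, regexec(.nt_line_re, ln, perl = TRUE))[[1]]
    if (length(m) == 0)
      pt_stop("parse", "malformed N-Triples statement at line %d: %s",
              keep[i], trimws(ln))
    s[i] <- parse_term(m[2], line = keep[i])$value
    p[i] <- parse_term(m[3], line = keep[i])$value
    ot <- parse_term(m[4], line = keep[i])
    o[i] <- ot$value
    lit[i] <- ot$literal
  }
  list(subject = s, predicate = p, object = o, literal = lit)
}

.ttl_token_re <- paste0(
  "<[^>]*>",
  "|\"(?:[^\"\\\\]|\\\\.)*\"(?:\\^\\^(?:<[^>]*>|[A-Za-z_][\\w.-]*:[\\w.-]*)|@[A-Za-z-]+)?",
  "|#[^\\n]*",
  "|@[A-Za-z]+",
  "|[A-Za-z_][\\w.-]*:[\\w.-]*|:[\\w.-]*",
  "|[+-]?[0-9][\\w.+-]*",
  "|[A-Za-z][\\w-]*",
  "|[;,.]|\\S")

## Turtle subset: @prefix/PREFIX, @base/BASE, predicate-object lists with ';'
## and ',', IRIs, prefixed names, 'a', plain/typed/language string literals and
## numeric/boolean literals.  No blank-node property lists or collections.
parse_turtle <- function(text) {
  toks <- regmatches(text, gregexpr(.ttl_token_re, text, perl = TRUE))[[1]]
  toks <- toks[!startsWith(toks, "#")]
  prefixes <- c(rdf = "http://www.w3.org/1999/02/22-rdf-syntax-ns#")
  base <- NULL
  s <- p <- o <- character(0)
  lit <- logical(0)
  i <- 1L
  nt <- length(toks)
  take <- function() {
    if (i > nt) pt_stop("parse", "unexpected end of Turtle input")
    tk <- toks[i]; i <<- i + 1L; tk
  }
  while (i <= nt) {
    tk <- take()
    low <- tolower(tk)
    if (low %in% c("@prefix", "prefix")) {
      pname <- take(); iri_tok <- take()
      if (!startsWith(iri_tok, "<"))
        pt_stop("parse", "expected IRI after prefix declaration, got '%s'", iri_tok)
      px <- sub(":$", "", pname)
      prefixes[px] <- substr(iri_tok, 2L, nchar(iri_tok) - 1L)
      if (i <= nt && toks[i] == ".") i <- i + 1L
      next
    }
    if (low %in% c("@base", "base")) {
      iri_tok <- take()
      base <- substr(iri_tok, 2L, nchar(iri_tok) - 1L)
      if (i <= nt && toks[i] == ".") i <- i + 1L
      next
    }
    subj <- parse_term(tk, prefixes, base)
    repeat {
      pred <- parse_term(take(), prefixes, base)
      repeat {
        obj <- parse_term(take(), prefixes, base)
        s <- c(s, subj$value); p <- c(p, pred$value)
        o <- c(o, obj$value); lit <- c(lit, obj$literal)
        sep <- take()
        if (sep == ",") next
        if (sep %in% c(";", ".")) break
        pt_stop("parse", "expected ',', ';' or '.' in Turtle input, got '%s'", sep)
      }
      if (sep == ".") break
      ## a ';' may be dangling before '.'
      if (i <= nt && toks[i] == ".") { i <- i + 1L; break }
    }
  }
  list(subject = s, predicate = p, object = o, literal = lit)
}

parse_rdfxml <- function(path) {
  doc <- xml2::read_xml(path)
  ns <- xml2::xml_ns(doc)
  expand <- function(node) {
    nm <- xml2::xml_name(node, ns)
    if (grepl(":", nm, fixed = TRUE)) {
      px <- sub(":.*$", "", nm)
      paste0(ns[[px]], sub("^[^:]*:", "", nm))
    } else nm
  }
  rdfns <- "http://www.w3.org/1999/02/22-rdf-syntax-ns#"
  s <- p <- o <- character(0); lit <- logical(0)
  for (desc in xml2::xml_children(doc)) {
    subj <- xml2::xml_attr(desc, "about")
    if (is.na(subj)) {
      nid <- xml2::xml_attr(desc, "nodeID")
      subj <- if (!is.na(nid)) paste0("_:", nid) else {
        id <- xml2::xml_attr(desc, "ID")
        if (!is.na(id)) paste0("#", id) else
          pt_stop("parse", "rdf:Description without rdf:about/nodeID/ID")
      }
    }
    subj <- normalize_iri(subj)
    tname <- expand(desc)
    if (tname != paste0(rdfns, "Description")) {
      s <- c(s, subj); p <- c(p, .rdf_type); o <- c(o, tname)
      lit <- c(lit, FALSE)
    }
    for (prop in xml2::xml_children(desc)) {
      pred <- expand(prop)
      res <- xml2::xml_attr(prop, "resource")
      if (!is.na(res)) {
        s <- c(s, subj); p <- c(p, pred)
        o <- c(o, normalize_iri(res)); lit <- c(lit, FALSE)
      } else {
        s <- c(s, subj); p <- c(p, pred)
        o <- c(o, xml2::xml_text(prop)); lit <- c(lit, TRUE)
      }
    }
  }
  list(subject = s, predicate = normalize_iri(p), object = o, literal = lit)
}

parse_kg_tsv <- function(lines) {
  keep <- nzchar(trimws(lines)) & !grepl("^\\s*#", lines)
  lines <- lines[keep]
  if (length(lines) == 0)
    return(list(subject = character(0), predicate = character(0),
                object = character(0), literal = logical(0),
                domain = character(0)))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3 | nf > 4))
    pt_stop("parse", "TSV triples need 3 or 4 tab-separated columns (line %d)",
            which(nf < 3 | nf > 4)[1])
  first <- tolower(trimws(fields[[1]]))
  if (identical(first[1:3], c("subject", "predicate", "object")))
    fields <- fields[-1]
  s <- vapply(fields, `[`, "", 1L)
  p <- vapply(fields, `[`, "", 2L)
  o <- vapply(fields, `[`, "", 3L)
  d <- vapply(fields, function(f) if (length(f) >= 4) f[4] else NA_character_, "")
  list(subject = s, predicate = p, object = o,
       literal = rep(FALSE, length(s)), domain = d)
}

#' Read a knowledge graph from a file
#'
#' Supported serialisations: N-Triples, a Turtle subset (prefix declarations,
#' `;`/`,` predicate-object lists, IRIs, prefixed names, literals; no blank
#' node property lists or collections), basic RDF/XML, and a 4-column TSV
#' dialect `subject, predicate, object, domain` convenient for fixtures.
#' IRIs under the internal `urn:pt:` base are decoded back to bare labels so
#' that label graphs round-trip through N-Triples.
#'
#' @param path file to read.
#' @param format one of `"ntriples"`, `"turtle"`, `"rdfxml"`, `"tsv"`; the
#'   default guesses from the file extension (`.nt`, `.ttl`, `.rdf`/`.xml`,
#'   `.tsv`).
#' @param domain optional domain tag applied to every triple in the file (for
#'   TSV input it overrides the file's domain column when given).
#' @return a [kg()] object.
#' @export
read_kg <- function(path, format = NULL, domain = NULL) {
  if (!file.exists(path)) pt_stop("io", "cannot read '%s': no such file", path)
  if (is.null(format)) {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, nt = "ntriples", ntriples = "ntriples",
                     ttl = "turtle", turtle = "turtle",
                     rdf = "rdfxml", xml = "rdfxml", owl = "rdfxml",
                     tsv = "tsv",
                     pt_stop("usage", "cannot guess RDF format from '.%s'", ext))
  }
  format <- match.arg(format, c("ntriples", "turtle", "rdfxml", "tsv"))
  tr <- switch(format,
    ntriples = parse_ntriples(readLines(path, warn = FALSE)),
    turtle = parse_turtle(paste(readLines(path, warn = FALSE), collapse = "\n")),
    rdfxml = parse_rdfxml(path),
    tsv = parse_kg_tsv(readLines(path, warn = FALSE)))
  dom <- if (!is.null(domain)) domain else tr$domain %||% NA_character_
  kg(tr$subject, tr$predicate, tr$object, domain = dom,
     object_literal = tr$literal)
}

## --------------------------------------------------------------- writing --

term_to_nt <- function(term, literal = FALSE) {
  literal <- rep_len(literal, length(term))
  ifelse(literal,
         paste0("\"", escape_literal(term), "\""),
         ifelse(startsWith(term, "_:"),
                term,
                paste0("<", label_to_iri(term), ">")))
}

#' Write a knowledge graph to disk
#'
#' @param x a `kg`.
#' @param path output file.
#' @param format `"ntriples"` or `"tsv"`. N-Triples output encodes bare labels
#'   under the `urn:pt:` base; [read_kg()] reverses this.
#' @return `path`, invisibly.
#' @export
write_kg <- function(x, path, format = c("ntriples", "tsv")) {
  format <- match.arg(format)
  tr <- x$triples
  if (format == "ntriples") {
    lines <- paste(term_to_nt(tr$subject), term_to_nt(tr$predicate),
                   term_to_nt(tr$object, tr$object_literal), ".")
  } else {
    lines <- c("subject\tpredicate\tobject\tdomain",
               paste(tr$subject, tr$predicate, tr$object,
                     ifelse(is.na(tr$domain), "", tr$domain), sep = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Merge knowledge graphs
#'
#' Set union of the inputs' triples, preserving domain tags; the same
#' (subject, predicate, object) occurring under two domains is kept once per
#' domain. Commutative and associative up to triple-set equality.
#'
#' @param ... `kg` objects, or a single list of them.
#' @return a `kg`.
#' @export
merge_kg <- function(...) {
  gs <- list(...)
  if (length(gs) == 1 && !inherits(gs[[1]], "kg")) gs <- gs[[1]]
  if (length(gs) == 0) pt_stop("usage", "merge_kg() needs at least one graph")
  ok <- vapply(gs, inherits, TRUE, what = "kg")
  if (!all(ok)) pt_stop("usage", "all inputs to merge_kg() must be kg objects")
  tr <- do.call(rbind, lapply(gs, `[[`, "triples"))
  suppressWarnings(kg(tr$subject, tr$predicate, tr$object, tr$domain,
                      tr$object_literal))
}

## -------------------------------------------------------------- profiles --

#' Per-predicate profiles
#'
#' For each distinct predicate, collects the exact subject and object sets
#' observed, the degree (number of triples using the predicate: its edge count
#' in the RDF multigraph, split as out-side = distinct subjects and in-side =
#' distinct objects when a split is needed) and the domain tags of its
#' triples. The profiles are the unit of comparison for all neighbouring
#' patterns.
#'
#' @param x a non-empty `kg`.
#' @return a named list of `predicate_profile` objects, one per predicate, in
#'   first-appearance order. The sum of their degrees equals [n_triples()].
#' @export
predicate_profiles <- function(x) {
  if (!inherits(x, "kg")) pt_stop("usage", "x must be a kg")
  if (n_triples(x) == 0) pt_stop("usage", "cannot profile an empty graph")
  tr <- x$triples
  idx <- split(seq_len(nrow(tr)), factor(tr$predicate, levels = predicates(x)))
  out <- lapply(names(idx), function(p) {
    rows <- idx[[p]]
    dom <- unique(tr$domain[rows])
    structure(list(predicate = p,
                   subjects = unique(tr$subject[rows]),
                   objects = unique(tr$object[rows]),
                   degree = length(rows),
                   out_side = length(unique(tr$subject[rows])),
                   in_side = length(unique(tr$object[rows])),
                   domains = lex_sort(dom[!is.na(dom)])),
              class = "predicate_profile")
  })
  names(out) <- names(idx)
  out
}

#' @export
print.predicate_profile <- function(x, ...) {
  cat(sprintf("<predicate_profile> %s: degree %d, |S|=%d, |O|=%d%s\n",
              x$predicate, x$degree, length(x$subjects), length(x$objects),
              if (length(x$domains))
                paste0(" [", paste(x$domains, collapse = ","), "]") else ""))
  invisible(x)
}

## ---------------------------------------------------------------- export --

#' Export a graph for external visualisation
#'
#' Writes GraphML or DOT. For a `kg` the nodes are the concepts and each
#' triple becomes a predicate-labelled edge; for a [cluster_graph()] the nodes
#' are predicates and the edges carry similarity weights.
#'
#' @param x a `kg` or `cluster_graph`.
#' @param path output file.
#' @param format `"graphml"` or `"dot"`.
#' @return `path`, invisibly.
#' @export
export_graph <- function(x, path, format = c("graphml", "dot")) {
  format <- match.arg(format)
  UseMethod("export_graph")
}

graph_export_write <- function(nodes, edges, path, format, directed) {
  if (length(nodes) == 0) pt_stop("usage", "cannot export an empty graph")
  nid <- stats::setNames(sprintf("n%d", seq_along(nodes) - 1L), nodes)
  if (format == "graphml") {
    lines <- c(
      "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
      "<graphml xmlns=\"http://graphml.graphdrawing.org/xmlns\">",
      "  <key id=\"label\" for=\"node\" attr.name=\"label\" attr.type=\"string\"/>",
      "  <key id=\"elabel\" for=\"edge\" attr.name=\"label\" attr.type=\"string\"/>",
      "  <key id=\"weight\" for=\"edge\" attr.name=\"weight\" attr.type=\"double\"/>",
      sprintf("  <graph id=\"G\" edgedefault=\"%s\">",
              if (directed) "directed" else "undirected"),
      sprintf("    <node id=\"%s\"><data key=\"label\">%s</data></node>",
              nid, xml_escape(nodes)))
    if (nrow(edges) > 0)
      lines <- c(lines, sprintf(
        "    <edge source=\"%s\" target=\"%s\"><data key=\"elabel\">%s</data><data key=\"weight\">%s</data></edge>",
        nid[edges$from], nid[edges$to], xml_escape(edges$label),
        format(edges$weight, digits = 10)))
    lines <- c(lines, "  </graph>", "</graphml>")
  } else {
    q <- function(s) paste0("\"", gsub("\"", "\\\\\"", s), "\"")
    arrow <- if (directed) " -> " else " -- "
    lines <- c(sprintf("%s G {", if (directed) "digraph" else "graph"),
               sprintf("  %s [label=%s];", q(nid[nodes]), q(nodes)))
    if (nrow(edges) > 0)
      lines <- c(lines, sprintf("  %s%s%s [label=%s, weight=%s];",
                                q(nid[edges$from]), arrow, q(nid[edges$to]),
                                q(edges$label),
                                format(edges$weight, digits = 10)))
    lines <- c(lines, "}")
  }
  writeLines(lines, path)
  invisible(path)
}

#' @export
export_graph.kg <- function(x, path, format = c("graphml", "dot")) {
  format <- match.arg(format)
  if (n_triples(x) == 0) pt_stop("usage", "cannot export an empty graph")
  tr <- x$triples
  nodes <- unique(c(tr$subject, tr$object))
  edges <- data.frame(from = tr$subject, to = tr$object, label = tr$predicate,
                      weight = 1, stringsAsFactors = FALSE)
  graph_export_write(nodes, edges, path, format, directed = TRUE)
}
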