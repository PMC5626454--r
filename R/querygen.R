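## Cluster-graph crawling and SPARQL query generation.
##
## Each leaf topic induces a similarity-weighted graph over its predicates.
## The crawler starts from the highest-degree predicate and expands
## neighbourhoods in descending similarity order; edges at or above the
## threshold t survive into the query graph, whose predicates are turned into
## one triple pattern each, with variables unified along the detected
## neighbouring patterns so that share/connection structure becomes joins.

#' Build the similarity graph of one cluster
#'
#' Nodes are the leaf's predicates; an undirected edge joins every pair with
#' nonzero similarity, weighted by the similarity matrix entry. Node degrees
#' (triple counts) drive the crawl start.
#'
#' @param leaf an `hfcm` leaf node, or a character vector of predicates.
#' @param sim the [similarity_matrix()] of the full graph.
#' @param graph the source `kg`.
#' @return an object of class `cluster_graph` with fields `nodes`, `edges`
#'   (data frame `a`, `b`, `similarity`) and `degrees`.
#' @export
cluster_graph <- function(leaf, sim, graph) {
  preds <- if (is.character(leaf)) leaf else leaf$predicates
  if (length(preds) == 0) pt_stop("usage", "empty cluster")
  if (!all(preds %in% rownames(sim)))
    pt_stop("key", "cluster predicates missing from similarity matrix")
  deg <- table(graph$triples$predicate)[preds]
  if (anyNA(deg)) pt_stop("key", "cluster predicates missing from graph")
  edges <- data.frame(a = character(0), b = character(0),
                      similarity = numeric(0), stringsAsFactors = FALSE)
  if (length(preds) > 1) {
    idx <- utils::combn(preds, 2)
    w <- unclass(sim)[cbind(idx[1, ], idx[2, ])]
    keep <- w > 0
    edges <- data.frame(a = idx[1, keep], b = idx[2, keep],
                        similarity = w[keep], stringsAsFactors = FALSE)
  }
  structure(list(nodes = preds, edges = edges,
                 degrees = stats::setNames(as.numeric(deg), preds)),
            class = "cluster_graph")
}

#' @export
print.cluster_graph <- function(x, ...) {
  cat(sprintf("<cluster_graph> %d node(s), %d edge(s)\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' @export
export_graph.cluster_graph <- function(x, path, format = c("graphml", "dot")) {
  format <- match.arg(format)
  edges <- data.frame(from = x$edges$a, to = x$edges$b,
                      label = rep("", nrow(x$edges)),
                      weight = x$edges$similarity, stringsAsFactors = FALSE)
  graph_export_write(x$nodes, edges, path, format, directed = FALSE)
}

#' Crawl a cluster graph into a query graph
#'
#' The crawl starts at the predicate with the highest degree (ties broken
#' lexicographically) and repeatedly visits all unvisited neighbours of the
#' current node in descending similarity order (ties lexicographic). The next
#' current node is the just-visited neighbour of highest similarity that
#' still has unvisited neighbours, falling back to the earliest-visited node
#' with unvisited neighbours; the crawl stops when the start's connected
#' component is exhausted. Traversed edges with similarity at or above `t`
#' are kept, and the kept nodes are those incident to a kept edge (the start
#' node is always kept), so raising `t` never enlarges the query graph.
#'
#' @param cg a [cluster_graph()].
#' @param t similarity threshold in \[0, 1\] (default 0).
#' @return an object of class `query_graph` with `visited_order`,
#'   `traversed` (all crawl edges), `kept_edges`, `kept_nodes` and
#'   `threshold`.
#' @export
crawl <- function(cg, t = 0) {
  if (!inherits(cg, "cluster_graph")) pt_stop("usage", "cg must be a cluster_graph")
  if (!is_scalar_number(t) || t < 0 || t > 1)
    pt_stop("usage", "threshold t must lie in [0, 1]")
  nodes <- cg$nodes
  adj <- lapply(stats::setNames(nodes, nodes), function(n) {
    e <- cg$edges
    sel <- e$a == n | e$b == n
    nb <- ifelse(e$a[sel] == n, e$b[sel], e$a[sel])
    stats::setNames(e$similarity[sel], nb)[lex_order(-e$similarity[sel], nb)]
  })
  deg <- cg$degrees
  start <- nodes[lex_order(-deg, nodes)][1]
  visited <- start
  traversed <- data.frame(a = character(0), b = character(0),
                          similarity = numeric(0), stringsAsFactors = FALSE)
  has_unvisited <- function(n) any(!(names(adj[[n]]) %in% visited))
  current <- start
  repeat {
    nb <- adj[[current]]
    new <- nb[!(names(nb) %in% visited)]
    if (length(new)) {
      visited <- c(visited, names(new))
      traversed <- rbind(traversed, data.frame(
        a = current, b = names(new), similarity = unname(new),
        stringsAsFactors = FALSE))
    }
    nxt <- NULL
    for (cand in names(new))       # just-visited, already in descending sim
      if (has_unvisited(cand)) { nxt <- cand; break }
    if (is.null(nxt))
      for (cand in visited)        # earliest-visited fallback
        if (has_unvisited(cand)) { nxt <- cand; break }
    if (is.null(nxt)) break
    current <- nxt
  }
  kept <- traversed[traversed$similarity >= t, , drop = FALSE]
  kept_nodes <- unique(c(start, kept$a, kept$b))
  structure(list(visited_order = visited, traversed = traversed,
                 kept_edges = kept, kept_nodes = kept_nodes, threshold = t),
            class = "query_graph")
}

#' @export
print.query_graph <- function(x, ...) {
  cat(sprintf("<query_graph> t=%g: visit order %s; kept {%s}\n", x$threshold,
              paste(x$visited_order, collapse = " -> "),
              paste(x$kept_nodes, collapse = ", ")))
  invisible(x)
}

## Minimal union-find over slot names.
uf_new <- function(slots) {
  e <- new.env(parent = emptyenv())
  e$parent <- stats::setNames(slots, slots)
  e
}
uf_find <- function(uf, x) {
  while (uf$parent[[x]] != x) {
    uf$parent[[x]] <- uf$parent[[uf$parent[[x]]]]
    x <- uf$parent[[x]]
  }
  x
}
uf_union <- function(uf, a, b) {
  ra <- uf_find(uf, a); rb <- uf_find(uf, b)
  if (ra != rb) uf$parent[[rb]] <- ra
  invisible(NULL)
}

#' Generate a SPARQL query from a query graph
#'
#' Every kept predicate contributes one triple pattern `?s <p> ?o`. Subject
#' and object variables are unified along the neighbouring patterns of the
#' kept edges: a subject share merges the two subject variables, an object
#' share the two object variables, and path connectivity chains the upstream
#' object variable into the downstream subject variable (share patterns take
#' precedence over path chaining on the same edge). A candidate merge is kept
#' only when the joined query still has a solution on the source graph, so
#' every emitted query is satisfiable by construction. With `strict = TRUE`,
#' unification instead considers any two variable slots whose observed
#' concept sets intersect, across all kept pairs - instance-level equality
#' rather than pattern structure. The emitted query is a plain conjunctive
#' `SELECT DISTINCT`.
#'
#' @param qg a [crawl()] result with at least one kept node.
#' @param graph the source `kg`.
#' @param strict use concept-label-equality unification.
#' @return an object of class `sparql_query`: `text`, `variables` (slot ->
#'   variable map), `triple_patterns` (data frame `s`, `predicate`, `o`) and
#'   `predicates`.
#' @export
generate_sparql <- function(qg, graph, strict = FALSE) {
  preds <- qg$kept_nodes
  if (length(preds) == 0) pt_stop("usage", "query graph has no kept nodes")
  prof <- predicate_profiles(graph)
  if (!all(preds %in% names(prof)))
    pt_stop("key", "kept predicates missing from graph")
  slots <- c(rbind(paste0("s|", preds), paste0("o|", preds)))
  uf <- uf_new(slots)
  ## Candidate variable merges, in evidence order. Each one is applied only
  ## if the joined query still has at least one solution on the source graph,
  ## so the emitted query is satisfiable by construction.
  cand <- list()
  add_cand <- function(role_a, a, role_b, b)
    cand[[length(cand) + 1L]] <<- c(paste0(role_a, "|", a),
                                    paste0(role_b, "|", b))
  if (strict) {
    pairs <- if (length(preds) > 1) utils::combn(preds, 2) else
      matrix(character(0), 2, 0)
    for (j in seq_len(ncol(pairs))) {
      a <- pairs[1, j]; b <- pairs[2, j]
      if (length(intersect(prof[[a]]$subjects, prof[[b]]$subjects)))
        add_cand("s", a, "s", b)
      if (length(intersect(prof[[a]]$objects, prof[[b]]$objects)))
        add_cand("o", a, "o", b)
      if (length(intersect(prof[[a]]$objects, prof[[b]]$subjects)))
        add_cand("o", a, "s", b)
      if (length(intersect(prof[[b]]$objects, prof[[a]]$subjects)))
        add_cand("o", b, "s", a)
    }
  } else {
    for (j in seq_len(nrow(qg$kept_edges))) {
      a <- qg$kept_edges$a[j]; b <- qg$kept_edges$b[j]
      if (!(a %in% preds) || !(b %in% preds)) next
      share <- detect_share(prof[[a]], prof[[b]])
      if (length(share)) {
        for (h in share) {
          if (h$pattern == "SUBJECT_SHARE") add_cand("s", a, "s", b)
          if (h$pattern == "OBJECT_SHARE") add_cand("o", a, "o", b)
        }
      } else {
        conn <- detect_connection(graph, a, b)
        for (h in conn) {
          if (h$pattern != "PATH_CONNECTIVITY") next
          if (length(intersect(prof[[a]]$objects, prof[[b]]$subjects)))
            add_cand("o", a, "s", b)
          if (length(intersect(prof[[b]]$objects, prof[[a]]$subjects)))
            add_cand("o", b, "s", a)
        }
      }
    }
  }
  patterns_of <- function() {
    data.frame(s = vapply(paste0("s|", preds), function(x) uf_find(uf, x), ""),
               predicate = preds,
               o = vapply(paste0("o|", preds), function(x) uf_find(uf, x), ""),
               stringsAsFactors = FALSE, row.names = NULL)
  }
  for (cd in cand) {
    if (uf_find(uf, cd[1]) == uf_find(uf, cd[2])) next
    snapshot <- uf$parent
    uf_union(uf, cd[1], cd[2])
    if (nrow(match_patterns(patterns_of(), graph$triples, limit = 1L)) == 0)
      uf$parent <- snapshot
  }
  roots <- vapply(slots, function(s) uf_find(uf, s), "")
  var_of <- stats::setNames(character(length(slots)), slots)
  counter <- 0L
  for (s in slots) {
    r <- roots[[s]]
    if (var_of[[r]] == "") {
      var_of[[r]] <- sprintf("?v%d", counter)
      counter <- counter + 1L
    }
    var_of[[s]] <- var_of[[r]]
  }
  patterns <- data.frame(
    s = var_of[paste0("s|", preds)],
    predicate = preds,
    o = var_of[paste0("o|", preds)],
    stringsAsFactors = FALSE, row.names = NULL)
  vars <- unique(c(patterns$s, patterns$o))
  text <- paste0(
    "SELECT DISTINCT ", paste(vars, collapse = " "), "\nWHERE {\n",
    paste(sprintf("  %s <%s> %s .", patterns$s,
                  label_to_iri(patterns$predicate), patterns$o),
          collapse = "\n"),
    "\n}\n")
  structure(list(text = text, variables = var_of[slots],
                 triple_patterns = patterns, predicates = preds),
            class = "sparql_query")
}

#' @export
print.sparql_query <- function(x, ...) {
  cat(x$text)
  invisible(x)
}

#' Write a SPARQL query to a .rq file
#'
#' @param q a [generate_sparql()] result.
#' @param path output file.
#' @export
write_query <- function(q, path) {
  writeLines(q$text, path, sep = "")
  invisible(path)
}

#' Match a generated query against a knowledge graph
#'
#' A brute-force conjunctive pattern matcher: backtracks over the query's
#' triple patterns, binding variables to concepts, and returns all solutions.
#' It serves to check that generated queries are satisfiable on their source
#' graph; it is not a SPARQL engine.
#'
#' @param q a [generate_sparql()] result.
#' @param graph a `kg`.
#' @param limit stop after this many solutions (default 100).
#' @return a data frame of variable bindings, one row per solution (0 rows
#'   when unsatisfiable).
#' @export
match_query <- function(q, graph, limit = 100L) {
  match_patterns(q$triple_patterns, graph$triples, limit = limit)
}

## Backtracking join over a patterns table (columns s, predicate, o, where s
## and o are variable names). Patterns are processed most-constrained-first.
match_patterns <- function(pat, tr, limit = 100L) {
  sols <- list()
  done <- FALSE
  recurse <- function(remaining, binding) {
    if (done) return()
    if (nrow(remaining) == 0) {
      sols[[length(sols) + 1L]] <<- binding
      if (length(sols) >= limit) done <<- TRUE
      return()
    }
    ## pick the pattern with the most bound variables first
    bound <- (remaining$s %in% names(binding)) +
      (remaining$o %in% names(binding))
    i <- which.max(bound)
    cand <- tr[tr$predicate == remaining$predicate[i], , drop = FALSE]
    sv <- remaining$s[i]; ov <- remaining$o[i]
    if (!is.null(binding[[sv]]))
      cand <- cand[cand$subject == binding[[sv]], , drop = FALSE]
    if (!is.null(binding[[ov]]))
      cand <- cand[cand$object == binding[[ov]], , drop = FALSE]
    if (sv == ov)
      cand <- cand[cand$subject == cand$object, , drop = FALSE]
    rest <- remaining[-i, , drop = FALSE]
    seen <- character(0)
    for (r in seq_len(nrow(cand))) {
      key <- paste(cand$subject[r], cand$object[r], sep = "\r")
      if (key %in% seen) next
      seen <- c(seen, key)
      b2 <- binding
      b2[[sv]] <- cand$subject[r]
      b2[[ov]] <- cand$object[r]
      recurse(rest, b2)
      if (done) return()
    }
  }
  recurse(pat, list())
  vars <- unique(c(pat$s, pat$o))
  if (length(sols) == 0) {
    empty <- as.data.frame(matrix(character(0), 0, length(vars)),
                           stringsAsFactors = FALSE)
    names(empty) <- vars
    return(empty)
  }
  out <- as.data.frame(matrix(unlist(lapply(sols, function(b)
    unname(unlist(b[vars])))), ncol = length(vars), byrow = TRUE),
    stringsAsFactors = FALSE)
  names(out) <- vars
  unique(out)
}
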