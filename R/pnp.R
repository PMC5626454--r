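## Predicate neighbouring patterns (PNP) and the predicate similarity matrix.
##
## Two predicates are compared through their profiles P1<S1,O1>, P2<S2,O2>:
##  * share patterns    - overlapping subject sets and/or object sets;
##  * connection patterns - a concept that is object of one and subject of the
##    other (path), possibly closing back into a two-triple cycle.
## The similarity combines weighted Jaccard overlap for share patterns with a
## fixed weight for connection patterns and takes the stronger of the two, so
## it is symmetric, bounded in [0, 1], and 1 for identical profiles.

.pattern_types <- c("SUBJECT_OBJECT_SHARE", "SUBJECT_SHARE", "OBJECT_SHARE",
                    "PATH_CONNECTIVITY", "CYCLE_CONNECTIVITY")

#' Pattern weights for predicate similarity
#'
#' Weights (all in \[0, 1\]) applied to each neighbouring pattern when scoring
#' a predicate pair. Share patterns scale Jaccard overlaps; connection
#' patterns contribute a fixed weight. The defaults order the evidence
#' strength as subject+object share > single share > cycle > path.
#'
#' @param w_so weight of the joint subject-and-object share term (default 1).
#' @param w_s,w_o weights of subject-only / object-only share (default 0.8).
#' @param w_cycle,w_path weights of cycle / path connectivity (defaults 0.6,
#'   0.5).
#' @return an object of class `pnp_config`.
#' @export
pnp_config <- function(w_so = 1.0, w_s = 0.8, w_o = 0.8,
                       w_cycle = 0.6, w_path = 0.5) {
  w <- c(w_so = w_so, w_s = w_s, w_o = w_o, w_cycle = w_cycle, w_path = w_path)
  if (any(!is.finite(w)) || any(w < 0) || any(w > 1))
    pt_stop("usage", "all pattern weights must lie in [0, 1]")
  structure(as.list(w), class = "pnp_config")
}

pattern_hit <- function(a, b, pattern, evidence) {
  structure(list(predicate_a = a, predicate_b = b,
                 pattern = match.arg(pattern, .pattern_types),
                 evidence = evidence),
            class = "pattern_hit")
}

#' @export
print.pattern_hit <- function(x, ...) {
  cat(sprintf("<pattern_hit> %s: (%s, %s) via {%s}\n", x$pattern,
              x$predicate_a, x$predicate_b,
              paste(utils::head(x$evidence, 5L), collapse = ", ")))
  invisible(x)
}

#' Detect share patterns between two predicate profiles
#'
#' Reports `SUBJECT_SHARE` when the subject sets intersect, `OBJECT_SHARE`
#' when the object sets intersect, and additionally `SUBJECT_OBJECT_SHARE`
#' when both do; the shared concepts are attached as evidence.
#'
#' @param profile_a,profile_b distinct [predicate_profiles()] entries.
#' @return a list of `pattern_hit` objects (possibly empty).
#' @export
detect_share <- function(profile_a, profile_b) {
  if (identical(profile_a$predicate, profile_b$predicate))
    pt_stop("usage", "share patterns are defined between distinct predicates")
  si <- intersect(profile_a$subjects, profile_b$subjects)
  oi <- intersect(profile_a$objects, profile_b$objects)
  hits <- list()
  if (length(si) && length(oi))
    hits <- c(hits, list(pattern_hit(profile_a$predicate, profile_b$predicate,
                                     "SUBJECT_OBJECT_SHARE", union(si, oi))))
  if (length(si))
    hits <- c(hits, list(pattern_hit(profile_a$predicate, profile_b$predicate,
                                     "SUBJECT_SHARE", si)))
  if (length(oi))
    hits <- c(hits, list(pattern_hit(profile_a$predicate, profile_b$predicate,
                                     "OBJECT_SHARE", oi)))
  hits
}

#' Detect connection patterns between two predicates in a graph
#'
#' `PATH_CONNECTIVITY` holds when some object of one predicate equals some
#' subject of the other (either direction); `CYCLE_CONNECTIVITY` when two
#' concepts x, y close a loop - triples (x, a, y) and (y, b, x) exist (or with
#' the roles of a and b swapped). A cycle always implies the path pattern,
#' which is reported alongside it.
#'
#' @param graph a `kg` containing both predicates.
#' @param a,b distinct predicate labels.
#' @return a list of `pattern_hit` objects (possibly empty).
#' @export
detect_connection <- function(graph, a, b) {
  if (identical(a, b))
    pt_stop("usage", "connection patterns are defined between distinct predicates")
  tr <- graph$triples
  ia <- tr$predicate == a
  ib <- tr$predicate == b
  if (!any(ia)) pt_stop("key", "predicate '%s' not present in graph", a)
  if (!any(ib)) pt_stop("key", "predicate '%s' not present in graph", b)
  link <- union(intersect(tr$object[ia], tr$subject[ib]),
                intersect(tr$object[ib], tr$subject[ia]))
  pa <- paste(tr$subject[ia], tr$object[ia], sep = "\r")
  rb <- paste(tr$object[ib], tr$subject[ib], sep = "\r")
  cyc <- intersect(pa, rb)
  hits <- list()
  if (length(cyc)) {
    ev <- unique(unlist(strsplit(cyc, "\r", fixed = TRUE)))
    hits <- c(hits, list(pattern_hit(a, b, "CYCLE_CONNECTIVITY", ev)))
  }
  if (length(link))
    hits <- c(hits, list(pattern_hit(a, b, "PATH_CONNECTIVITY", link)))
  hits
}

jaccard <- function(x, y) {
  u <- length(union(x, y))
  if (u == 0) 0 else length(intersect(x, y)) / u
}

#' Similarity between two predicates
#'
#' The share score is `w_so * (J(S) + J(O)) / 2` when both the subject and the
#' object sets overlap, `w_s * J(S)` or `w_o * J(O)` for a single share, and 0
#' otherwise, with `J` the Jaccard index. The connection score is `w_cycle`
#' for a cycle, `w_path` for a path, 0 otherwise. The similarity is the
#' maximum of the two, so share evidence dominates whenever its overlap is
#' substantial.
#'
#' @param graph a `kg` containing both predicates.
#' @param profile_a,profile_b their [predicate_profiles()] entries.
#' @param config a [pnp_config()].
#' @return a number in \[0, 1\].
#' @export
pnp_similarity <- function(graph, profile_a, profile_b, config = pnp_config()) {
  js <- jaccard(profile_a$subjects, profile_b$subjects)
  jo <- jaccard(profile_a$objects, profile_b$objects)
  s_share <- if (js > 0 && jo > 0) config$w_so * (js + jo) / 2
             else if (js > 0) config$w_s * js
             else if (jo > 0) config$w_o * jo
             else 0
  conn <- detect_connection(graph, profile_a$predicate, profile_b$predicate)
  pats <- vapply(conn, `[[`, "", "pattern")
  s_conn <- if ("CYCLE_CONNECTIVITY" %in% pats) config$w_cycle
            else if ("PATH_CONNECTIVITY" %in% pats) config$w_path
            else 0
  max(s_share, s_conn)
}

#' Build the symmetric predicate similarity matrix
#'
#' Computes [pnp_similarity()] for every predicate pair of the graph. The
#' result has unit diagonal, is symmetric by construction, and all entries lie
#' in \[0, 1\]; it is the input of the hierarchical clustering step.
#'
#' @param graph a `kg` with at least two predicates.
#' @param config a [pnp_config()].
#' @return a `similarity_matrix`: a square numeric matrix with predicate
#'   labels as dimnames and the configuration attached as an attribute.
#' @export
similarity_matrix <- function(graph, config = pnp_config()) {
  prof <- predicate_profiles(graph)
  preds <- names(prof)
  n <- length(preds)
  if (n < 2) pt_stop("usage", "similarity_matrix() needs at least 2 predicates")
  tr <- graph$triples
  rows <- split(seq_len(nrow(tr)), factor(tr$predicate, levels = preds))
  pairs <- lapply(rows, function(ix) paste(tr$subject[ix], tr$object[ix], sep = "\r"))
  rpairs <- lapply(rows, function(ix) paste(tr$object[ix], tr$subject[ix], sep = "\r"))
  m <- diag(1, n)
  dimnames(m) <- list(preds, preds)
  for (i in seq_len(n - 1L)) {
    pi <- prof[[i]]
    for (j in seq.int(i + 1L, n)) {
      pj <- prof[[j]]
      js <- jaccard(pi$subjects, pj$subjects)
      jo <- jaccard(pi$objects, pj$objects)
      s_share <- if (js > 0 && jo > 0) config$w_so * (js + jo) / 2
                 else if (js > 0) config$w_s * js
                 else if (jo > 0) config$w_o * jo
                 else 0
      s_conn <- 0
      if (any(pairs[[i]] %in% rpairs[[j]])) s_conn <- config$w_cycle
      else if (any(pi$objects %in% pj$subjects) ||
               any(pj$objects %in% pi$subjects)) s_conn <- config$w_path
      m[i, j] <- m[j, i] <- max(s_share, s_conn)
    }
  }
  structure(m, config = config, class = c("similarity_matrix", "matrix"))
}

#' @export
print.similarity_matrix <- function(x, ...) {
  cat(sprintf("<similarity_matrix> %d x %d predicates; off-diagonal range [%.3f, %.3f]\n",
              nrow(x), ncol(x), min(x[upper.tri(x)]), max(x[upper.tri(x)])))
  invisible(x)
}

#' Read/write a similarity matrix
#'
#' TSV layout: a header row and first column carry the predicate labels; CSV
#' layout is the same with commas.
#'
#' @param x a `similarity_matrix`.
#' @param path file path.
#' @param format `"tsv"` or `"csv"`.
#' @export
write_similarity <- function(x, path, format = c("tsv", "csv")) {
  format <- match.arg(format)
  sep <- if (format == "tsv") "\t" else ","
  utils::write.table(as.data.frame(unclass(x)), path, sep = sep, quote = FALSE,
                     row.names = TRUE, col.names = NA)
  invisible(path)
}

#' @rdname write_similarity
#' @export
read_similarity <- function(path, format = c("tsv", "csv")) {
  format <- match.arg(format)
  sep <- if (format == "tsv") "\t" else ","
  tab <- utils::read.table(path, sep = sep, header = TRUE, row.names = 1,
                           check.names = FALSE)
  m <- as.matrix(tab)
  structure(m, class = c("similarity_matrix", "matrix"))
}
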