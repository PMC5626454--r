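## Concept-domain association scoring and triple filtering.
##
## The association score is smoothed base-2 pointwise mutual information
## between a concept c and a domain o over N observed cases:
##
##     score(c, o) = log2( ((N_co + eps) * N) / (N_c * N_o) ),  eps = 0.01
##
## Positive scores mean c occurs in o's cases more often than independence
## predicts. Concepts are ranked per domain and only triples mentioning a
## top-K concept of their own domain are retained downstream.

#' Concept-domain co-occurrence counts
#'
#' @param entries a data frame with columns `concept`, `domain`, `n_c` (cases
#'   containing the concept), `n_o` (cases of the domain) and `n_co` (cases
#'   containing the concept within the domain).
#' @param N total number of observed cases.
#' @return an object of class `cooccurrence`.
#' @export
cooccurrence <- function(entries, N) {
  need <- c("concept", "domain", "n_c", "n_o", "n_co")
  if (!all(need %in% names(entries)))
    pt_stop("usage", "entries must have columns %s", paste(need, collapse = ", "))
  entries <- as.data.frame(entries)[need]
  if (!is_scalar_number(N) || N <= 0)
    pt_stop("validation", "N must be a single positive number")
  bad <- entries$n_co < 0 | pmax(entries$n_c, entries$n_o) > N
  if (any(bad))
    pt_stop("validation",
            "count invariant 0 <= n_co and n_c, n_o <= N violated in row %d",
            which(bad)[1])
  ## joint counts exceeding a marginal are tolerated with a warning: published
  ## co-occurrence tables are sometimes internally inconsistent, and the score
  ## is still well defined
  over <- entries$n_co > pmin(entries$n_c, entries$n_o)
  if (any(over))
    pt_warn("n_co exceeds min(n_c, n_o) in %d row(s); counts look inconsistent",
            sum(over))
  structure(list(N = N, entries = entries), class = "cooccurrence")
}

#' @export
print.cooccurrence <- function(x, ...) {
  cat(sprintf("<cooccurrence> N=%g, %d (concept, domain) entries over %d domain(s)\n",
              x$N, nrow(x$entries), length(unique(x$entries$domain))))
  invisible(x)
}

#' Read co-occurrence counts from TSV
#'
#' Expects header columns `concept`, `domain`, `n_c`, `n_o`, `n_co`. The total
#' case count `N` is taken from a `# N: <count>` comment line in the file, or
#' from `total_n`, which takes precedence.
#'
#' @param path TSV file.
#' @param total_n optional total case count overriding the file's `# N:` line.
#' @return a [cooccurrence()] object.
#' @export
read_cooccurrence <- function(path, total_n = NULL) {
  if (!file.exists(path)) pt_stop("io", "cannot read '%s': no such file", path)
  lines <- readLines(path, warn = FALSE)
  nline <- grep("^#\\s*N\\s*[:=]", lines, value = TRUE)
  N <- total_n %||% if (length(nline))
    as.numeric(sub("^#\\s*N\\s*[:=]\\s*", "", nline[1])) else
    pt_stop("usage", "'%s' has no '# N:' line and total_n was not given", path)
  tab <- utils::read.delim(text = lines[!grepl("^#", lines)],
                           stringsAsFactors = FALSE)
  cooccurrence(tab, N)
}

#' @rdname read_cooccurrence
#' @param x a `cooccurrence`.
#' @export
write_cooccurrence <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# N: %g", x$N), con)
  utils::write.table(x$entries, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Concept-domain association score (smoothed pointwise mutual information)
#'
#' Computes `log2(((n_co + eps) * N) / (n_c * n_o))` for each requested
#' (concept, domain) pair. The additive smoothing constant keeps the score
#' finite when a concept never co-occurs with a domain; with `eps = 0` such
#' pairs return `-Inf`, which sorts last in rankings. The score is zero (up to
#' smoothing) under independence and strictly increasing in `n_co`.
#'
#' @param counts a [cooccurrence()] object.
#' @param concept,domain character vectors (recycled to equal length) naming
#'   the pairs to score; every pair must be present in `counts`.
#' @param eps additive smoothing on `n_co` (default 0.01).
#' @return a numeric vector of scores.
#' @examples
#' cc <- cooccurrence(data.frame(concept = "uci", domain = "D1",
#'                               n_c = 600, n_o = 400, n_co = 500), N = 1980)
#' concept_inequality(cc, "uci", "D1")
#' @export
concept_inequality <- function(counts, concept, domain, eps = 0.01) {
  if (!inherits(counts, "cooccurrence"))
    pt_stop("usage", "counts must be a cooccurrence object")
  if (!is_scalar_number(eps) || eps < 0)
    pt_stop("usage", "eps must be a single non-negative number")
  n <- max(length(concept), length(domain))
  concept <- rep_len(as.character(concept), n)
  domain <- rep_len(as.character(domain), n)
  key <- paste(counts$entries$concept, counts$entries$domain, sep = "\r")
  ix <- match(paste(concept, domain, sep = "\r"), key)
  if (anyNA(ix))
    pt_stop("key", "no counts for (%s, %s)",
            concept[is.na(ix)][1], domain[is.na(ix)][1])
  e <- counts$entries[ix, , drop = FALSE]
  if (any(e$n_c <= 0) || any(e$n_o <= 0))
    pt_stop("domain", "n_c and n_o must be positive to score (%s, %s)",
            concept[e$n_c <= 0 | e$n_o <= 0][1],
            domain[e$n_c <= 0 | e$n_o <= 0][1])
  log2(((e$n_co + eps) * counts$N) / (e$n_c * e$n_o))
}

#' Rank a domain's concepts by association score
#'
#' Sorts every concept observed for `domain` by [concept_inequality()]
#' (descending; ties broken lexicographically by concept label) and keeps the
#' top `k`.
#'
#' @inheritParams concept_inequality
#' @param domain a single domain tag.
#' @param k selection size (default 60).
#' @return an object of class `concept_ranking` with fields `domain`, `ranked`
#'   (data frame `rank`, `concept`, `score`) and `k`. A domain with no
#'   observed concepts yields an empty ranking with a warning.
#' @export
rank_concepts <- function(counts, domain, k = 60, eps = 0.01) {
  if (!is_scalar_number(k) || k < 1)
    pt_stop("usage", "k must be a positive integer")
  k <- as.integer(k)
  sel <- counts$entries$domain == domain
  if (!any(sel)) {
    pt_warn("no concepts observed for domain '%s'; empty ranking", domain)
    ranked <- data.frame(rank = integer(0), concept = character(0),
                         score = numeric(0))
    return(structure(list(domain = domain, ranked = ranked, k = k),
                     class = "concept_ranking"))
  }
  concepts <- counts$entries$concept[sel]
  scores <- concept_inequality(counts, concepts, domain, eps = eps)
  ord <- lex_order(-scores, concepts)
  keep <- utils::head(ord, k)
  ranked <- data.frame(rank = seq_along(keep), concept = concepts[keep],
                       score = scores[keep], stringsAsFactors = FALSE)
  structure(list(domain = domain, ranked = ranked, k = k),
            class = "concept_ranking")
}

#' @export
print.concept_ranking <- function(x, ...) {
  cat(sprintf("<concept_ranking> domain %s: top %d of k=%d\n",
              x$domain, nrow(x$ranked), x$k))
  print(utils::head(x$ranked, 10L), row.names = FALSE)
  invisible(x)
}

#' Write a concept ranking as TSV (rank, concept, score)
#'
#' @param x a `concept_ranking`.
#' @param path output file.
#' @export
write_ranking <- function(x, path) {
  utils::write.table(x$ranked, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Filter a graph to triples mentioning top-ranked concepts
#'
#' A triple is retained when its subject or its object is among the top-k
#' concepts of the triple's own domain.
#'
#' @param graph a `kg` whose triples all carry domain tags.
#' @param rankings a list of [rank_concepts()] results covering every domain
#'   tag present in `graph`.
#' @return the filtered `kg`.
#' @export
filter_triples <- function(graph, rankings) {
  if (inherits(rankings, "concept_ranking")) rankings <- list(rankings)
  rdom <- vapply(rankings, `[[`, "", "domain")
  tr <- graph$triples
  if (anyNA(tr$domain))
    pt_stop("validation", "filter_triples() needs every triple domain-tagged")
  missing <- setdiff(unique(tr$domain), rdom)
  if (length(missing))
    pt_stop("configuration", "no concept ranking for domain(s): %s",
            paste(missing, collapse = ", "))
  tops <- lapply(rankings, function(r) r$ranked$concept)
  names(tops) <- rdom
  keep <- mapply(function(s, o, d) s %in% tops[[d]] || o %in% tops[[d]],
                 tr$subject, tr$object, tr$domain, USE.NAMES = FALSE)
  suppressWarnings(kg(tr$subject[keep], tr$predicate[keep], tr$object[keep],
                      tr$domain[keep], tr$object_literal[keep]))
}
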