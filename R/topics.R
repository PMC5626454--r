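## Topic signatures and gold-standard validation.
##
## A leaf cluster (topic) is summarised by the domains it spans, its top-5
## predicates by degree, and up to 2 predicates unique to it; topic
## composition is then checked against pairwise correlations of a binary
## subject-by-domain gold-standard indicator table.

#' Topic signatures of an HFCM clustering
#'
#' For every leaf of the hierarchy, builds a signature: covered domains (the
#' union over member predicates), predicate count, the top 5 predicates by
#' degree (ties broken lexicographically), and the top 2 predicates that
#' appear in no other leaf ("unique" predicates; some topics have none).
#'
#' @param fit an [hfcm()] object.
#' @param graph the `kg` the clustering was computed from.
#' @return a list of `topic_signature` objects.
#' @export
topic_signatures <- function(fit, graph) {
  if (!inherits(fit, "hfcm")) pt_stop("usage", "fit must be an hfcm object")
  prof <- predicate_profiles(graph)
  leaf_preds <- lapply(fit$leaves, `[[`, "predicates")
  tally <- table(unlist(leaf_preds))
  lapply(seq_along(fit$leaves), function(i) {
    preds <- leaf_preds[[i]]
    deg <- vapply(prof[preds], `[[`, numeric(1), "degree")
    ord <- lex_order(-deg, preds)
    top <- utils::head(ord, 5L)
    uniq_mask <- tally[preds] == 1L
    uniq_ord <- ord[uniq_mask[ord]]
    uni <- utils::head(uniq_ord, 2L)
    structure(list(
      topic = fit$leaves[[i]]$id,
      domains = lex_sort(unique(unlist(lapply(prof[preds], `[[`, "domains")))),
      n_predicates = length(preds),
      top_predicates = data.frame(predicate = preds[top],
                                  degree = unname(deg[top]),
                                  stringsAsFactors = FALSE),
      unique_predicates = data.frame(predicate = preds[uni],
                                     degree = unname(deg[uni]),
                                     stringsAsFactors = FALSE),
      total_degree = sum(deg)),
      class = "topic_signature")
  })
}

#' @export
print.topic_signature <- function(x, ...) {
  cat(sprintf("<topic_signature> %s: %d predicates over {%s}\n", x$topic,
              x$n_predicates, paste(x$domains, collapse = ", ")))
  cat("  top:", paste(sprintf("%s(%g)", x$top_predicates$predicate,
                              x$top_predicates$degree), collapse = ", "), "\n")
  if (nrow(x$unique_predicates))
    cat("  unique:", paste(x$unique_predicates$predicate, collapse = ", "), "\n")
  invisible(x)
}

#' Write topic signatures
#'
#' JSON (one object per topic) or a human-readable text report.
#'
#' @param signatures result of [topic_signatures()].
#' @param path output file.
#' @param format `"json"` or `"text"`.
#' @export
write_signatures <- function(signatures, path, format = c("json", "text")) {
  format <- match.arg(format)
  if (format == "json") {
    jsonlite::write_json(lapply(signatures, unclass), path,
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         dataframe = "rows")
  } else {
    con <- file(path, "w"); on.exit(close(con))
    for (s in signatures) {
      writeLines(sprintf("Topic %s (%d predicates; domains: %s)", s$topic,
                         s$n_predicates, paste(s$domains, collapse = ", ")), con)
      writeLines(sprintf("  top: %s",
                         paste(sprintf("%s(%g)", s$top_predicates$predicate,
                                       s$top_predicates$degree),
                               collapse = ", ")), con)
      writeLines(sprintf("  unique: %s",
                         if (nrow(s$unique_predicates))
                           paste(s$unique_predicates$predicate, collapse = ", ")
                         else "none"), con)
    }
  }
  invisible(path)
}

#' Read a binary subject-by-domain indicator table
#'
#' CSV with subjects as rows (first column or rownames) and domains as
#' columns; entries must be 0/1.
#'
#' @param path CSV file.
#' @param domain_map optional named character vector renaming / merging the
#'   file's domain columns onto analysis domains (e.g. mapping a LEAK column
#'   onto ABSCESS); columns mapped to the same name are combined with
#'   logical OR.
#' @return a binary integer matrix.
#' @export
read_indicators <- function(path, domain_map = NULL) {
  tab <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  m <- as.matrix(tab)
  if (!all(m %in% c(0, 1)))
    pt_stop("validation", "indicator table entries must be 0/1")
  storage.mode(m) <- "integer"
  if (!is.null(domain_map)) {
    unknown <- setdiff(colnames(m), names(domain_map))
    if (length(unknown))
      pt_stop("validation", "domain_map does not cover column(s): %s",
              paste(unknown, collapse = ", "))
    tgt <- domain_map[colnames(m)]
    m <- vapply(unique(tgt), function(d)
      as.integer(rowSums(m[, tgt == d, drop = FALSE]) > 0),
      integer(nrow(m)))
  }
  m
}

#' Pairwise correlation of binary domain indicators
#'
#' Pearson correlation between the binary columns (equal to the phi
#' coefficient). Constant columns get zero correlation with a warning. Each
#' domain's three strongest off-diagonal partners are reported, mirroring the
#' way a gold-standard complication table is read.
#'
#' @param indicators a binary subject-by-domain matrix (>= 2 subjects and
#'   domains, entries 0/1).
#' @return an object of class `correlation_report` with fields `labels`,
#'   `matrix` (symmetric, unit diagonal) and `top3` (named list of character
#'   vectors).
#' @export
gold_correlation <- function(indicators) {
  m <- as.matrix(indicators)
  if (nrow(m) < 2 || ncol(m) < 2)
    pt_stop("usage", "need at least 2 subjects and 2 domains")
  if (!all(m %in% c(0, 1)))
    pt_stop("validation", "indicator entries must be 0/1")
  const <- apply(m, 2, function(col) stats::var(col) == 0)
  if (any(const))
    pt_warn("constant indicator column(s) %s: correlations set to 0",
            paste(colnames(m)[const], collapse = ", "))
  cm <- suppressWarnings(stats::cor(m))
  cm[is.na(cm)] <- 0
  diag(cm) <- 1
  labels <- colnames(m)
  top3 <- lapply(seq_along(labels), function(i) {
    v <- cm[i, -i]
    nm <- labels[-i]
    nm[lex_order(-v, nm)][seq_len(min(3L, length(nm)))]
  })
  names(top3) <- labels
  structure(list(labels = labels, matrix = cm, top3 = top3),
            class = "correlation_report")
}

#' @export
print.correlation_report <- function(x, ...) {
  cat(sprintf("<correlation_report> %d domains\n", length(x$labels)))
  print(round(x$matrix, 3))
  for (d in x$labels)
    cat(sprintf("  %s ~ %s\n", d, paste(x$top3[[d]], collapse = ", ")))
  invisible(x)
}

#' Check topic composition against gold-standard correlations
#'
#' A topic is "supported" when every pair of domains it covers is a top-3
#' correlation partner pair in the report (in either direction). Topics
#' covering a single domain are supported vacuously. This is a reporting aid
#' that operationalises reading the correlation matrix against the topics,
#' not a statistical test.
#'
#' @param signatures result of [topic_signatures()].
#' @param report result of [gold_correlation()]; must cover every domain the
#'   signatures mention.
#' @return a data frame with columns `topic` and `supported`.
#' @export
concordance_check <- function(signatures, report) {
  sdom <- unique(unlist(lapply(signatures, `[[`, "domains")))
  missing <- setdiff(sdom, report$labels)
  if (length(missing))
    pt_stop("validation", "domains absent from correlation report: %s",
            paste(missing, collapse = ", "))
  supported <- vapply(signatures, function(s) {
    d <- s$domains
    if (length(d) < 2) return(TRUE)
    pr <- utils::combn(d, 2)
    all(apply(pr, 2, function(p)
      p[2] %in% report$top3[[p[1]]] || p[1] %in% report$top3[[p[2]]]))
  }, logical(1))
  data.frame(topic = vapply(signatures, `[[`, "", "topic"),
             supported = supported, stringsAsFactors = FALSE)
}
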