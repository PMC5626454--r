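## Hierarchical fuzzy c-means over the predicate similarity matrix.
##
## Each node of the hierarchy holds a predicate set; it is split by fuzzy
## c-means at the silhouette-optimal k and the children are recursed into,
## until a node's triple load fits the capacity threshold alpha, no candidate
## split clears the silhouette threshold delta, or a split fails to separate
## the items. Hardened (argmax) assignments make the leaves a true partition
## of the predicates; the fuzzy memberships are kept on every internal node
## so bridging ("fuzzy") predicates remain visible.

#' Silhouette-optimal number of clusters
#'
#' Fits fuzzy c-means for each k in `2..k_max` on the profile rows of the
#' similarity submatrix, hardens the memberships, and scores each candidate
#' with the mean silhouette width. The k with the largest silhouette wins
#' (ties to the smallest k); if even the best silhouette falls below `delta`,
#' `k = 1` is returned, meaning "do not split".
#'
#' @param sim a [similarity_matrix()].
#' @param subset predicate labels to restrict to (default: all).
#' @param delta minimum acceptable silhouette width (default 0.4).
#' @param k_max largest k scanned; default `min(10, n - 1)`.
#' @param m,tol,max_iter,restarts,seed passed to [fcm()].
#' @return a list with `k`, `silhouette` (NA when no valid split exists),
#'   `fit` (the winning [fcm()] object, NULL for k = 1), `labels` (hard
#'   assignment for the winning k) and `scan` (a data frame of k vs
#'   silhouette over the candidates).
#' @export
optimal_k <- function(sim, subset = NULL, delta = 0.4, k_max = NULL,
                      m = 2, tol = 1e-6, max_iter = 300, restarts = 5,
                      seed = 1) {
  subset <- subset %||% rownames(sim)
  n <- length(subset)
  empty_scan <- data.frame(k = integer(0), silhouette = numeric(0))
  if (n < 2)
    return(list(k = 1L, silhouette = NA_real_, fit = NULL,
                labels = rep(1L, n), scan = empty_scan))
  x <- unclass(sim)[subset, subset, drop = FALSE]
  k_max <- min(k_max %||% 10L, n - 1L)
  if (k_max < 2)
    return(list(k = 1L, silhouette = NA_real_, fit = NULL,
                labels = rep(1L, n), scan = empty_scan))
  fits <- vector("list", k_max)
  sil <- rep(NA_real_, k_max)
  for (k in 2:k_max) {
    fit <- fcm(x, k, m = m, tol = tol, max_iter = max_iter,
               restarts = restarts, seed = derive_seed(seed, 7L, k))
    lab <- harden(fit)
    if (length(unique(lab)) < 2) next  # degenerate: all mass in one cluster
    fits[[k]] <- fit
    sil[k] <- silhouette_width(x, lab)
  }
  scan <- data.frame(k = 2:k_max, silhouette = sil[2:k_max])
  if (all(is.na(sil)) || max(sil, na.rm = TRUE) < delta)
    return(list(k = 1L, silhouette = suppressWarnings(max(sil, na.rm = TRUE)),
                fit = NULL, labels = rep(1L, n), scan = scan))
  kbest <- which.max(sil)  # first maximum -> smallest k on ties
  list(k = as.integer(kbest), silhouette = sil[kbest], fit = fits[[kbest]],
       labels = harden(fits[[kbest]]), scan = scan)
}

#' Hierarchical fuzzy c-means clustering of predicates
#'
#' Recursively partitions the predicates of a similarity matrix into a
#' topic hierarchy. At every node [optimal_k()] selects the split; a node
#' becomes a leaf when (a) the triples carried by its predicates number at
#' most `alpha` (capacity rule), (b) no split reaches silhouette `delta`, or
#' (c) a split leaves all items together. Every predicate ends up in exactly
#' one leaf.
#'
#' @param sim a [similarity_matrix()] over the graph's predicates.
#' @param graph the `kg` the matrix came from; supplies per-predicate triple
#'   counts. May be `NULL`, in which case every predicate counts as one
#'   triple.
#' @param delta silhouette acceptance threshold in \[0, 1\] (default 0.4).
#' @param alpha capacity threshold in triples; default one third of the total
#'   triple count (rounded up).
#' @param beta membership threshold for reporting fuzzy predicates (default
#'   0.3).
#' @param k_max,m,tol,max_iter,restarts passed to [optimal_k()]/[fcm()].
#' @param seed integer seed; the whole tree is reproducible from it.
#' @return an object of class `hfcm` with components `tree` (nested nodes:
#'   `id`, `level`, `predicates`, `n_triples`, `k`, `silhouette`,
#'   `stop_rule`, `membership`, `fuzzy`, `children`), `leaves` (flat list),
#'   `assignment` (data frame `predicate`, `topic`), plus the call and
#'   parameters. Methods: `print`, `summary`, `plot`.
#' @examples
#' g <- synth_kg(synth_spec(seed = 7))
#' sm <- similarity_matrix(g$graph)
#' fit <- hfcm(sm, g$graph, seed = 7)
#' fit
#' @export
hfcm <- function(sim, graph = NULL, delta = 0.4, alpha = NULL, beta = 0.3,
                 k_max = NULL, m = 2, tol = 1e-6, max_iter = 300,
                 restarts = 5, seed = 1) {
  if (!is.matrix(sim)) pt_stop("usage", "sim must be a similarity matrix")
  if (!is_scalar_number(delta) || delta < 0 || delta > 1)
    pt_stop("usage", "delta must lie in [0, 1]")
  preds <- rownames(sim)
  tcount <- if (is.null(graph)) {
    stats::setNames(rep(1, length(preds)), preds)
  } else {
    tab <- table(graph$triples$predicate)
    stats::setNames(as.numeric(tab[preds]), preds)
  }
  if (anyNA(tcount))
    pt_stop("usage", "similarity matrix predicates missing from graph")
  total <- sum(tcount)
  alpha <- alpha %||% ceiling(total / 3)
  if (!is_scalar_number(alpha) || alpha < 1)
    pt_stop("usage", "alpha must be >= 1")

  counter <- new.env(parent = emptyenv())
  build <- function(subset, level, path) {
    node <- list(id = paste0("C", level, ".", path), level = level,
                 predicates = subset, n_triples = sum(tcount[subset]),
                 k = 1L, silhouette = NA_real_, stop_rule = NULL,
                 membership = NULL, fuzzy = list(), children = list())
    if (node$n_triples <= alpha) {
      node$stop_rule <- "capacity"
      return(node)
    }
    if (length(subset) < 2) {
      node$stop_rule <- "singleton"
      return(node)
    }
    opt <- optimal_k(sim, subset, delta = delta, k_max = k_max, m = m,
                     tol = tol, max_iter = max_iter, restarts = restarts,
                     seed = derive_seed(seed, level, length(subset)))
    if (opt$k == 1L) {
      node$stop_rule <- "silhouette"
      node$silhouette <- opt$silhouette
      return(node)
    }
    groups <- split(subset, opt$labels)
    if (length(groups) < 2 || any(lengths(groups) == length(subset))) {
      node$stop_rule <- "no_change"
      return(node)
    }
    node$k <- opt$k
    node$silhouette <- opt$silhouette
    node$membership <- opt$fit$U
    node$fuzzy <- fuzzy_predicates(opt$fit, beta = beta)
    node$children <- lapply(seq_along(groups), function(j)
      build(groups[[j]], level + 1L, paste0(path, ".", j)))
    node
  }
  tree <- build(preds, 0L, "1")

  leaves <- list()
  walk <- function(node) {
    if (length(node$children) == 0) leaves[[length(leaves) + 1L]] <<- node
    else for (ch in node$children) walk(ch)
  }
  walk(tree)
  assignment <- data.frame(
    predicate = unlist(lapply(leaves, `[[`, "predicates")),
    topic = rep(vapply(leaves, `[[`, "", "id"),
                vapply(leaves, function(l) length(l$predicates), 0L)),
    stringsAsFactors = FALSE)
  structure(list(tree = tree, leaves = leaves, assignment = assignment,
                 params = list(delta = delta, alpha = alpha, beta = beta,
                               k_max = k_max, m = m, tol = tol,
                               max_iter = max_iter, restarts = restarts,
                               seed = seed),
                 call = match.call()),
            class = "hfcm")
}

#' @export
print.hfcm <- function(x, ...) {
  cat(sprintf("<hfcm> %d predicates in %d leaf topic(s), alpha=%g, delta=%g\n",
              nrow(x$assignment), length(x$leaves), x$params$alpha,
              x$params$delta))
  show <- function(node, indent) {
    tag <- if (length(node$children)) {
      sprintf("split k=%d, sw=%.3f", node$k, node$silhouette)
    } else sprintf("leaf [%s]", node$stop_rule)
    cat(sprintf("%s%s: %d predicate(s), %g triple(s) - %s\n",
                strrep("  ", indent), node$id, length(node$predicates),
                node$n_triples, tag))
    for (ch in node$children) show(ch, indent + 1L)
  }
  show(x$tree, 0L)
  invisible(x)
}

#' @export
summary.hfcm <- function(object, ...) {
  sw <- vapply(object$leaves, function(l) l$silhouette %||% NA_real_,
               numeric(1))
  out <- list(n_leaves = length(object$leaves),
              leaf_sizes = vapply(object$leaves,
                                  function(l) length(l$predicates), 0L),
              stop_rules = table(vapply(object$leaves, `[[`, "", "stop_rule")),
              split_silhouettes = internal_silhouettes(object),
              params = object$params)
  class(out) <- "summary.hfcm"
  out
}

#' Silhouette widths of the accepted splits
#'
#' @param fit an [hfcm()] object.
#' @return a named numeric vector: for every internal node, the silhouette
#'   width of the split that produced its children.
#' @export
internal_silhouettes <- function(fit) {
  out <- c()
  walk <- function(node) {
    if (length(node$children)) {
      out[node$id] <<- node$silhouette
      for (ch in node$children) walk(ch)
    }
  }
  walk(fit$tree)
  out
}

#' @export
print.summary.hfcm <- function(x, ...) {
  cat(sprintf("HFCM hierarchy: %d leaves (sizes %s)\n", x$n_leaves,
              paste(x$leaf_sizes, collapse = ", ")))
  cat("Leaf stop rules:\n"); print(x$stop_rules)
  if (length(x$split_silhouettes)) {
    cat("Accepted split silhouettes:\n")
    print(round(x$split_silhouettes, 3))
  }
  invisible(x)
}

#' @export
plot.hfcm <- function(x, ...) {
  depth <- function(node) if (!length(node$children)) 1L else
    1L + max(vapply(node$children, depth, 0L))
  d <- depth(x$tree)
  nl <- length(x$leaves)
  graphics::plot(NULL, xlim = c(0.5, nl + 0.5), ylim = c(0, d),
                 xlab = "", ylab = "level", axes = FALSE, ...)
  graphics::axis(2, at = 0:(d - 1))
  nxt <- new.env(parent = emptyenv()); nxt$x <- 0
  layout <- function(node, level) {
    if (!length(node$children)) {
      nxt$x <- nxt$x + 1
      xpos <- nxt$x
      graphics::text(xpos, d - level - 1, cex = 0.7, srt = 90, adj = c(1, 0.5),
                     labels = sprintf("%s (%d)", node$id,
                                      length(node$predicates)))
      return(xpos)
    }
    xs <- vapply(node$children, layout, 0, level = level + 1)
    xpos <- mean(xs)
    for (xi in xs)
      graphics::segments(xpos, d - level, xi, d - level - 1)
    graphics::text(xpos, d - level, pos = 3, cex = 0.7,
                   labels = sprintf("k=%d sw=%.2f", node$k, node$silhouette))
    xpos
  }
  layout(x$tree, 0L)
  invisible(x)
}

#' Serialize an HFCM hierarchy
#'
#' `write_tree()` emits the full hierarchy (levels, members, silhouettes,
#' stop rules, fuzzy predicates) as JSON; `write_assignment()` the flat
#' leaf assignment as TSV.
#'
#' @param fit an [hfcm()] object.
#' @param path output file.
#' @export
write_tree <- function(fit, path) {
  strip <- function(node) {
    list(id = node$id, level = node$level, predicates = node$predicates,
         n_triples = node$n_triples, k = node$k,
         silhouette = node$silhouette, stop_rule = node$stop_rule,
         fuzzy = lapply(node$fuzzy, function(f)
           list(predicate = f$predicate, clusters = f$clusters)),
         children = lapply(node$children, strip))
  }
  jsonlite::write_json(strip(fit$tree), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_tree
#' @export
write_assignment <- function(fit, path) {
  utils::write.table(fit$assignment, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
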