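## Seeded synthetic multi-domain knowledge graphs with planted predicate
## clusters, plus matching co-occurrence counts and gold-standard indicator
## tables. The generator emulates the statistical structure the clustering
## assumes: predicates of the same (leaf) topic draw their subjects and
## objects from a shared concept pool, topics of the same super-topic share a
## weaker super-level pool, selected cross-topic predicate pairs chain
## object-to-subject through bridge concepts, and a small fraction of noise
## triples links random predicates to concepts of other super-topics.

#' Specification of a synthetic knowledge graph
#'
#' @param n_domains number of domain tags.
#' @param predicates_per_domain integer vector (length `n_domains`) of
#'   predicate counts per domain; defaults to an even split of the planted
#'   total.
#' @param planted a list of integer vectors: one vector per super-cluster,
#'   whose entries are the leaf-cluster sizes. The leaves partition the
#'   predicate set.
#' @param concepts_per_cluster size of each leaf's subject pool and object
#'   pool (>= 2).
#' @param super_concepts size of each super-cluster's shared pools.
#' @param p_share probability a triple draws its object from the leaf pool
#'   (objects carry the leaf/topic identity); the rest of the object mass
#'   goes to the super-cluster pool (up to 0.25) and to fresh private
#'   concepts. With `p_share = 1` every object comes from the leaf pool, so
#'   all within-cluster pairs share objects.
#' @param p_share_super probability a triple draws its subject from the
#'   super-cluster pool (subjects bind a super-cluster together); a small
#'   remainder (up to 0.10) comes from the leaf pool and the rest is fresh.
#' @param p_conn probability that a cross-leaf predicate pair within the same
#'   super-cluster is chained through a bridge concept (inducing a path
#'   connection pattern).
#' @param triples_per_predicate mean triple count per predicate (Poisson
#'   jittered, floor 2).
#' @param noise_rate rate of spurious cross-super-cluster paths: noise
#'   triples re-use one predicate's private object as another super's
#'   subject, blurring fine partition structure at the whole-graph level
#'   while leaving within-super geometry intact.
#' @param n_patients rows of the gold-standard indicator table.
#' @param alpha recommended clustering capacity threshold for this graph
#'   (triples per topic); `NULL` defers to the [hfcm()] default.
#' @param seed mandatory integer seed; identical seeds give byte-identical
#'   outputs.
#' @return an object of class `synth_spec`.
#' @export
synth_spec <- function(n_domains = 3,
                       predicates_per_domain = NULL,
                       planted = list(c(5, 5), c(5, 5)),
                       concepts_per_cluster = 4,
                       super_concepts = 3,
                       p_share = 0.70,
                       p_share_super = 0.90,
                       p_conn = 0.05,
                       triples_per_predicate = 14,
                       noise_rate = 0.03,
                       n_patients = 400,
                       alpha = NULL,
                       seed) {
  if (missing(seed)) pt_stop("usage", "synth_spec() requires a seed")
  total <- sum(unlist(planted))
  predicates_per_domain <- predicates_per_domain %||% {
    base <- rep(total %/% n_domains, n_domains)
    base + c(rep(1, total %% n_domains), rep(0, n_domains - total %% n_domains))
  }
  if (sum(predicates_per_domain) != total)
    pt_stop("validation",
            "predicates_per_domain (%d) must sum to the planted total (%d)",
            sum(predicates_per_domain), total)
  probs <- c(p_share, p_share_super, p_conn, noise_rate)
  if (any(probs < 0) || any(probs > 1))
    pt_stop("validation", "probabilities must lie in [0, 1]")

  if (concepts_per_cluster < 2)
    pt_stop("validation", "concepts_per_cluster must be >= 2")
  structure(list(n_domains = n_domains,
                 predicates_per_domain = as.integer(predicates_per_domain),
                 planted = lapply(planted, as.integer),
                 concepts_per_cluster = as.integer(concepts_per_cluster),
                 super_concepts = as.integer(super_concepts),
                 p_share = p_share, p_share_super = p_share_super,
                 p_conn = p_conn,
                 triples_per_predicate = triples_per_predicate,
                 noise_rate = noise_rate,
                 n_patients = as.integer(n_patients),
                 alpha = alpha,
                 seed = as.integer(seed)),
            class = "synth_spec")
}

#' @export
print.synth_spec <- function(x, ...) {
  cat(sprintf("<synth_spec> %d domains, %d predicates in %d supers / %d leaves, seed %d\n",
              x$n_domains, sum(unlist(x$planted)), length(x$planted),
              length(unlist(x$planted)), x$seed))
  invisible(x)
}

#' Cohort-scale synthetic fixture
#'
#' A canned [synth_spec()] at the scale of a six-domain clinical cohort: 83
#' predicates over 6 domains, about 1210 triples, with a planted two-level
#' hierarchy of 3 super-clusters splitting into 8 leaf topics (3, 3 and 2).
#' The per-predicate draw count is set so that, after duplicate collapse on
#' the small concept pools, the unique-triple total centres on 1210. The
#' fixture records its own clustering capacity `alpha` of one sixth of that
#' total, a per-topic machine capacity under which the intermediate clusters
#' must split further while topic-scale clusters fit.
#'
#' @param seed integer seed (default 1).
#' @return a `synth_spec`.
#' @export
cohort_fixture <- function(seed = 1) {
  synth_spec(n_domains = 6,
             predicates_per_domain = c(13, 13, 10, 21, 12, 14),
             planted = list(c(11, 10, 10), c(11, 10, 10), c(11, 10)),
             concepts_per_cluster = 4,
             super_concepts = 3,
             p_share = 0.70,
             p_share_super = 0.90,
             p_conn = 0.02,
             triples_per_predicate = 17,
             noise_rate = 0.06,
             n_patients = 1505,
             alpha = ceiling(1210 / 6),
             seed = seed)
}

#' Generate a synthetic knowledge graph with planted structure
#'
#' Produces a domain-tagged graph whose predicates fall into known leaf and
#' super clusters, the matching ground truth, a concept-domain co-occurrence
#' table, and a binary patient-by-domain indicator table drawn from a
#' Gaussian copula whose target correlation follows the planted domain/topic
#' overlap. All four outputs are deterministic functions of the spec's seed.
#'
#' @param spec a [synth_spec()].
#' @return a list with components `graph` (a `kg`), `truth` (predicate
#'   assignment to leaf/super plus the planted share and connection pairs),
#'   `counts` (a [cooccurrence()]), `indicators` (binary matrix) and `spec`.
#' @export
synth_kg <- function(spec) {
  if (!inherits(spec, "synth_spec")) pt_stop("usage", "spec must be a synth_spec")
  set.seed(derive_seed(spec$seed, 555L))
  n_sup <- length(spec$planted)
  leaf_sizes <- unlist(spec$planted)
  n_leaf <- length(leaf_sizes)
  leaf_super <- rep(seq_len(n_sup), lengths(spec$planted))
  total <- sum(leaf_sizes)
  doms <- sprintf("D%d", seq_len(spec$n_domains))

  ## interleave domains across the predicate order so topics span domains
  dom_vec <- rep(doms, spec$predicates_per_domain)
  dom_vec <- dom_vec[order(stats::ave(seq_along(dom_vec), dom_vec,
                                      FUN = seq_along), dom_vec)]
  pred_leaf <- rep(seq_len(n_leaf), leaf_sizes)
  pred_name <- sprintf("%s_p%02d", tolower(dom_vec), seq_len(total))
  pred_super <- leaf_super[pred_leaf]

  pool <- function(role, kind, id, size)
    sprintf("%s_%s%d_%02d", role, kind, id, seq_len(size))
  SL <- lapply(seq_len(n_leaf), pool, role = "cs", kind = "l",
               size = spec$concepts_per_cluster)
  OL <- lapply(seq_len(n_leaf), pool, role = "co", kind = "l",
               size = spec$concepts_per_cluster)
  SU <- lapply(seq_len(n_sup), pool, role = "cs", kind = "u",
               size = spec$super_concepts)
  OU <- lapply(seq_len(n_sup), pool, role = "co", kind = "u",
               size = spec$super_concepts)
  fresh_n <- 0L
  fresh <- function(k) {
    out <- sprintf("x_%05d", fresh_n + seq_len(k))
    fresh_n <<- fresh_n + k
    out
  }
  ## Term sources are asymmetric: subjects draw mainly from the super-cluster
  ## pool (with weight p_share_super), objects mainly from the leaf pool
  ## (with weight p_share). Subject overlap therefore binds a super-cluster
  ## together while object overlap carries the leaf (topic) identity, so the
  ## two levels of the planted hierarchy are controlled independently.
  ## Leaf-pool object draws cover the whole pool before repeating, keeping
  ## within-topic overlap tight.
  covering <- function(pool, n) {
    if (n >= length(pool)) rep(sample(pool), length.out = n) else
      sample(pool, n, replace = TRUE)
  }
  draw_term <- function(k, p_leaf, p_super, leaf_pool, super_pool,
                        cover = c("none", "leaf", "super", "both")) {
    cover <- match.arg(cover)
    u <- stats::runif(k)
    out <- character(k)
    from_leaf <- u < p_leaf
    from_super <- !from_leaf & u < p_leaf + p_super
    nl <- sum(from_leaf); ns <- sum(from_super)
    out[from_leaf] <- if (cover %in% c("leaf", "both")) covering(leaf_pool, nl) else
      sample(leaf_pool, nl, replace = TRUE)
    out[from_super] <- if (cover %in% c("super", "both")) covering(super_pool, ns) else
      sample(super_pool, ns, replace = TRUE)
    out[!from_leaf & !from_super] <- fresh(k - nl - ns)
    out
  }

  s <- p <- o <- d <- character(0)
  for (i in seq_len(total)) {
    l <- pred_leaf[i]; u <- pred_super[i]
    k <- max(2L, stats::rpois(1, spec$triples_per_predicate))
    s <- c(s, draw_term(k, min(0.10, 1 - spec$p_share_super),
                        spec$p_share_super, SL[[l]], SU[[u]],
                        cover = "super"))
    o <- c(o, draw_term(k, spec$p_share, min(0.25, 1 - spec$p_share),
                        OL[[l]], OU[[u]], cover = "both"))
    p <- c(p, rep(pred_name[i], k))
    d <- c(d, rep(dom_vec[i], k))
  }

  ## cross-leaf chaining within each super-cluster
  conn_pairs <- data.frame(a = character(0), b = character(0),
                           stringsAsFactors = FALSE)
  if (spec$p_conn > 0 && total > 1) {
    idx <- utils::combn(seq_len(total), 2)
    cross <- pred_leaf[idx[1, ]] != pred_leaf[idx[2, ]] &
      pred_super[idx[1, ]] == pred_super[idx[2, ]]
    cand <- idx[, cross, drop = FALSE]
    pick <- stats::runif(ncol(cand)) < spec$p_conn
    for (j in which(pick)) {
      a <- cand[1, j]; b <- cand[2, j]
      y <- fresh(1L)
      s <- c(s, sample(SL[[pred_leaf[a]]], 1L), y)
      p <- c(p, pred_name[a], pred_name[b])
      o <- c(o, y, sample(OL[[pred_leaf[b]]], 1L))
      d <- c(d, dom_vec[a], dom_vec[b])
      conn_pairs <- rbind(conn_pairs,
                          data.frame(a = pred_name[a], b = pred_name[b],
                                     stringsAsFactors = FALSE))
    }
  }

  ## noise: spurious cross-super paths. A private (fresh) object y of a
  ## random predicate a becomes the subject of one new triple (y, b, z) on a
  ## predicate b of a different super-cluster, with z drawn from b's own
  ## leaf pool. Each unit creates exactly one predicate-to-predicate path
  ## across super-clusters while barely perturbing either profile, blurring
  ## fine partition structure at the whole-graph level but vanishing when
  ## clustering recurses inside a super-cluster.
  n_noise <- round(spec$noise_rate * length(s))
  if (n_noise > 0 && n_sup > 1) {
    for (j in seq_len(n_noise)) {
      a <- sample(seq_len(total), 1L)
      b <- sample(which(pred_super != pred_super[a]), 1L)
      own <- o[p == pred_name[a] & grepl("^x_", o)]
      y <- if (length(own)) sample(own, 1L) else {
        yy <- fresh(1L)
        s <- c(s, fresh(1L)); p <- c(p, pred_name[a])
        o <- c(o, yy); d <- c(d, dom_vec[a])
        yy
      }
      s <- c(s, y)
      p <- c(p, pred_name[b])
      o <- c(o, sample(OL[[pred_leaf[b]]], 1L))
      d <- c(d, dom_vec[b])
    }
  }
  graph <- suppressWarnings(kg(s, p, o, domain = d))

  ## ground truth
  share_idx <- utils::combn(seq_len(total), 2)
  same_leaf <- pred_leaf[share_idx[1, ]] == pred_leaf[share_idx[2, ]]
  truth <- list(
    assignment = data.frame(predicate = pred_name, domain = dom_vec,
                            leaf = pred_leaf, super = pred_super,
                            stringsAsFactors = FALSE),
    share_pairs = data.frame(a = pred_name[share_idx[1, same_leaf]],
                             b = pred_name[share_idx[2, same_leaf]],
                             stringsAsFactors = FALSE),
    connection_pairs = conn_pairs)

  ## gold-standard indicators: probit-threshold Gaussian copula whose target
  ## correlation mirrors how strongly two domains share planted topics
  M <- matrix(0, spec$n_domains, n_leaf, dimnames = list(doms, NULL))
  for (i in seq_len(total)) M[dom_vec[i], pred_leaf[i]] <-
    M[dom_vec[i], pred_leaf[i]] + 1
  A <- M %*% t(M)
  R <- stats::cov2cor(A + diag(0.5, spec$n_domains))
  L <- chol(R)
  Z <- matrix(stats::rnorm(spec$n_patients * spec$n_domains),
              spec$n_patients) %*% L
  prev <- 0.2
  ind <- (Z > stats::qnorm(1 - prev)) + 0L
  dimnames(ind) <- list(sprintf("case_%04d", seq_len(spec$n_patients)), doms)

  ## concept-domain co-occurrence counts consistent with the planted topics
  concepts <- unlist(c(SL, OL, SU, OU))
  leaf_of_concept <- c(rep(seq_len(n_leaf), each = spec$concepts_per_cluster),
                       rep(seq_len(n_leaf), each = spec$concepts_per_cluster),
                       rep(NA, 2L * n_sup * spec$super_concepts))
  aff <- M / pmax(1, matrix(rowSums(M), spec$n_domains, n_leaf))
  pmat <- matrix(0.05, spec$n_patients, length(concepts))
  for (ci in seq_along(concepts)) {
    l <- leaf_of_concept[ci]
    if (is.na(l)) next
    bump <- ind %*% aff[, l]  # per-case: sum of its domains' affinity to l
    pmat[, ci] <- pmin(0.9, 0.05 + 0.6 * bump)
  }
  X <- (matrix(stats::runif(length(pmat)), nrow(pmat)) < pmat) + 0L
  n_c <- colSums(X)
  keep <- n_c > 0
  Nco <- t(X[, keep, drop = FALSE]) %*% ind
  entries <- data.frame(
    concept = rep(concepts[keep], spec$n_domains),
    domain = rep(doms, each = sum(keep)),
    n_c = rep(n_c[keep], spec$n_domains),
    n_o = rep(colSums(ind), each = sum(keep)),
    n_co = as.vector(Nco),
    stringsAsFactors = FALSE)
  counts <- cooccurrence(entries, spec$n_patients)

  list(graph = graph, truth = truth, counts = counts, indicators = ind,
       spec = spec)
}

#' Write all outputs of a synthetic generation run
#'
#' Emits the graph as N-Triples and TSV, the co-occurrence counts as TSV, the
#' indicator table as CSV, the ground truth as JSON, and a manifest recording
#' the spec (including the seed) and the file paths.
#'
#' @param x result of [synth_kg()].
#' @param dir output directory (created if needed).
#' @return the manifest path, invisibly.
#' @export
write_synth <- function(x, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(ntriples = file.path(dir, "graph.nt"),
                tsv = file.path(dir, "graph.tsv"),
                counts = file.path(dir, "counts.tsv"),
                indicators = file.path(dir, "indicators.csv"),
                truth = file.path(dir, "truth.json"),
                manifest = file.path(dir, "manifest.json"))
  write_kg(x$graph, paths$ntriples, "ntriples")
  write_kg(x$graph, paths$tsv, "tsv")
  write_cooccurrence(x$counts, paths$counts)
  utils::write.csv(as.data.frame(x$indicators), paths$indicators)
  jsonlite::write_json(x$truth, paths$truth, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  jsonlite::write_json(list(spec = unclass(x$spec), files = paths,
                            n_triples = n_triples(x$graph)),
                       paths$manifest, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(paths$manifest)
}
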