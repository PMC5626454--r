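## End-to-end pipeline: ingest -> (optional) concept filter -> similarity ->
## hierarchical clustering -> topic signatures -> query generation, with every
## artifact written next to a manifest that records the resolved
## configuration, so a rerun from the manifest reproduces the run byte for
## byte.

#' Run the full topic-discovery and query-generation pipeline
#'
#' @param inputs either a `kg`, a [synth_spec()] (the graph is generated), or
#'   a character vector of file paths read with [read_kg()].
#' @param formats,input_domains optional per-file format and domain tag
#'   vectors, recycled along `inputs` when it is a path vector.
#' @param counts optional [cooccurrence()] object or TSV path; when given,
#'   triples are filtered to the `top_k` concepts of each domain before
#'   clustering.
#' @param top_k concepts kept per domain (default 60).
#' @param config a [pnp_config()].
#' @param delta,alpha,beta,k_max,m,restarts clustering controls, see
#'   [hfcm()]; `alpha = NULL` uses the input spec's recommended capacity when
#'   present, else the [hfcm()] default.
#' @param threshold_t crawl similarity threshold in \[0, 1\] (default 0).
#' @param strict_queries use instance-level variable unification, see
#'   [generate_sparql()].
#' @param seed integer seed driving every stochastic step.
#' @param out_dir output directory; created if needed.
#' @return invisibly, a list with the in-memory results (`graph`, `sim`,
#'   `fit`, `signatures`, `queries`) and `artifacts` (paths written).
#' @export
run_pipeline <- function(inputs, formats = NULL, input_domains = NULL,
                         counts = NULL, top_k = 60,
                         config = pnp_config(),
                         delta = 0.4, alpha = NULL, beta = 0.3, k_max = NULL,
                         m = 2, restarts = 5,
                         threshold_t = 0, strict_queries = FALSE,
                         seed = 1, out_dir) {
  if (missing(out_dir)) pt_stop("usage", "out_dir is required")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  graph <- if (inherits(inputs, "kg")) {
    inputs
  } else if (inherits(inputs, "synth_spec")) {
    if (is.null(alpha)) alpha <- inputs$alpha
    synth_kg(inputs)$graph
  } else if (is.character(inputs)) {
    fmts <- if (is.null(formats)) vector("list", length(inputs)) else
      as.list(rep_len(formats, length(inputs)))
    doms <- if (is.null(input_domains)) vector("list", length(inputs)) else
      as.list(rep_len(input_domains, length(inputs)))
    merge_kg(lapply(seq_along(inputs), function(i)
      read_kg(inputs[i], format = fmts[[i]], domain = doms[[i]])))
  } else {
    pt_stop("usage", "inputs must be a kg, a synth_spec or file paths")
  }

  if (!is.null(counts)) {
    if (is.character(counts)) counts <- read_cooccurrence(counts)
    rankings <- lapply(domains(graph), function(d)
      rank_concepts(counts, d, k = top_k))
    graph <- filter_triples(graph, rankings)
  }

  sim <- similarity_matrix(graph, config)
  fit <- hfcm(sim, graph, delta = delta, alpha = alpha, beta = beta,
              k_max = k_max, m = m, restarts = restarts, seed = seed)
  signatures <- topic_signatures(fit, graph)

  queries <- lapply(fit$leaves, function(leaf) {
    cg <- cluster_graph(leaf, sim, graph)
    qg <- crawl(cg, t = threshold_t)
    generate_sparql(qg, graph, strict = strict_queries)
  })
  names(queries) <- vapply(fit$leaves, `[[`, "", "id")

  artifacts <- list(
    graph = file.path(out_dir, "graph.nt"),
    matrix = file.path(out_dir, "similarity.tsv"),
    tree = file.path(out_dir, "tree.json"),
    assignment = file.path(out_dir, "assignment.tsv"),
    signatures = file.path(out_dir, "signatures.json"),
    manifest = file.path(out_dir, "manifest.json"))
  write_kg(graph, artifacts$graph, "ntriples")
  write_similarity(sim, artifacts$matrix, "tsv")
  write_tree(fit, artifacts$tree)
  write_assignment(fit, artifacts$assignment)
  write_signatures(signatures, artifacts$signatures, "json")
  qdir <- file.path(out_dir, "queries")
  dir.create(qdir, showWarnings = FALSE)
  for (id in names(queries)) {
    qp <- file.path(qdir, paste0(gsub("[^A-Za-z0-9_.-]", "_", id), ".rq"))
    write_query(queries[[id]], qp)
    artifacts[[paste0("query_", id)]] <- qp
  }
  resolved <- list(top_k = top_k, config = unclass(config), delta = delta,
                   alpha = fit$params$alpha, beta = beta, k_max = k_max,
                   m = m, restarts = restarts, threshold_t = threshold_t,
                   strict_queries = strict_queries, seed = seed,
                   package_version = as.character(utils::packageVersion("predtopics")),
                   r_version = as.character(getRversion()))
  jsonlite::write_json(list(config = resolved,
                            artifacts = lapply(artifacts, identity)),
                       artifacts$manifest, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(list(graph = graph, sim = sim, fit = fit,
                 signatures = signatures, queries = queries,
                 artifacts = artifacts))
}
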