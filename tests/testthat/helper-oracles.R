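## Independent oracles and random-instance generators used across the suite.
## Each oracle is a direct, brute-force restatement of the property it checks
## and never calls the implementation path it is compared against.

## A random labelled graph, independent of the package's synthetic generator.
random_kg <- function(n_triples, n_predicates, n_concepts = 12, seed = 1,
                      n_domains = 2) {
  set.seed(seed)
  preds <- sprintf("p%02d", seq_len(n_predicates))
  cons <- sprintf("c%02d", seq_len(n_concepts))
  doms <- sprintf("D%d", seq_len(n_domains))
  suppressWarnings(kg(sample(cons, n_triples, TRUE),
                      sample(preds, n_triples, TRUE),
                      sample(cons, n_triples, TRUE),
                      domain = sample(doms, n_triples, TRUE)))
}

## Exhaustive per-predicate scan of a triple table.
oracle_profiles <- function(g) {
  tr <- g$triples
  out <- list()
  for (p in unique(tr$predicate)) {
    rows <- tr[tr$predicate == p, ]
    out[[p]] <- list(subjects = sort(unique(rows$subject)),
                     objects = sort(unique(rows$object)),
                     degree = nrow(rows))
  }
  out
}

## Set-intersection share oracle: returns the pattern names.
oracle_share <- function(g, a, b) {
  tr <- g$triples
  sa <- tr$subject[tr$predicate == a]; sb <- tr$subject[tr$predicate == b]
  oa <- tr$object[tr$predicate == a];  ob <- tr$object[tr$predicate == b]
  s <- length(intersect(sa, sb)) > 0
  o <- length(intersect(oa, ob)) > 0
  as.character(c(if (s && o) "SUBJECT_OBJECT_SHARE", if (s) "SUBJECT_SHARE",
                 if (o) "OBJECT_SHARE"))
}

## Two-hop enumeration connection oracle.
oracle_connection <- function(g, a, b) {
  tr <- g$triples
  ta <- tr[tr$predicate == a, ]; tb <- tr[tr$predicate == b, ]
  path <- FALSE; cycle <- FALSE
  for (i in seq_len(nrow(ta))) for (j in seq_len(nrow(tb))) {
    if (ta$object[i] == tb$subject[j] || tb$object[j] == ta$subject[i])
      path <- TRUE
    if (ta$object[i] == tb$subject[j] && tb$object[j] == ta$subject[i])
      cycle <- TRUE
  }
  as.character(c(if (cycle) "CYCLE_CONNECTIVITY",
                 if (path) "PATH_CONNECTIVITY"))
}

## Direct evaluation of the pairwise similarity definition.
oracle_similarity <- function(g, a, b, cfg = pnp_config()) {
  jac <- function(x, y) {
    u <- length(union(x, y)); if (u == 0) 0 else length(intersect(x, y)) / u
  }
  tr <- g$triples
  sa <- unique(tr$subject[tr$predicate == a])
  sb <- unique(tr$subject[tr$predicate == b])
  oa <- unique(tr$object[tr$predicate == a])
  ob <- unique(tr$object[tr$predicate == b])
  js <- jac(sa, sb); jo <- jac(oa, ob)
  share <- if (js > 0 && jo > 0) cfg$w_so * (js + jo) / 2
           else if (js > 0) cfg$w_s * js else if (jo > 0) cfg$w_o * jo else 0
  pat <- oracle_connection(g, a, b)
  conn <- if ("CYCLE_CONNECTIVITY" %in% pat) cfg$w_cycle
          else if ("PATH_CONNECTIVITY" %in% pat) cfg$w_path else 0
  max(share, conn)
}

## Textbook fuzzy c-means run independently from a given initial membership
## matrix (plain loops, no shared code with the package implementation).
oracle_fcm <- function(x, U0, m = 2, tol = 1e-6, max_iter = 300) {
  n <- nrow(x); k <- ncol(U0); U <- U0
  obj <- NA_real_
  for (it in seq_len(max_iter)) {
    V <- matrix(0, k, ncol(x))
    for (j in seq_len(k)) {
      w <- U[, j]^m
      V[j, ] <- colSums(x * w) / sum(w)
    }
    d2 <- matrix(0, n, k)
    for (i in seq_len(n)) for (j in seq_len(k))
      d2[i, j] <- sum((x[i, ] - V[j, ])^2)
    Un <- matrix(0, n, k)
    for (i in seq_len(n)) {
      z <- which(d2[i, ] <= .Machine$double.eps)
      if (length(z)) Un[i, z] <- 1 / length(z)
      else {
        r <- d2[i, ]^(-1 / (m - 1))
        Un[i, ] <- r / sum(r)
      }
    }
    obj <- sum(Un^m * d2)
    if (max(abs(Un - U)) < tol) { U <- Un; break }
    U <- Un
  }
  list(U = U, objective = obj)
}

## Per-item silhouette from first principles.
oracle_silhouette <- function(x, labels) {
  n <- nrow(x)
  d <- as.matrix(stats::dist(x))
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    if (sum(own) == 1) { s[i] <- 0; next }
    a <- mean(d[i, own & seq_len(n) != i])
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(cl) mean(d[i, labels == cl]), 0))
    s[i] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }
  mean(s)
}

## Step-by-step crawl simulation following the narrative rules directly.
oracle_crawl <- function(nodes, edges, degrees, t) {
  nbrs <- function(n) {
    sel <- edges$a == n | edges$b == n
    nb <- ifelse(edges$a[sel] == n, edges$b[sel], edges$a[sel])
    w <- edges$similarity[sel]
    ord <- order(-w, nb, method = "radix")
    list(names = nb[ord], sims = w[ord])
  }
  start <- nodes[order(-degrees[nodes], nodes, method = "radix")][1]
  visited <- start
  kept <- character(0)
  current <- start
  repeat {
    nb <- nbrs(current)
    new <- !(nb$names %in% visited)
    newly <- nb$names[new]
    for (idx in which(new)) {
      visited <- c(visited, nb$names[idx])
      if (nb$sims[idx] >= t)
        kept <- union(kept, c(current, nb$names[idx]))
    }
    nxt <- NULL
    for (cand in newly)
      if (any(!(nbrs(cand)$names %in% visited))) { nxt <- cand; break }
    if (is.null(nxt))
      for (cand in visited)
        if (any(!(nbrs(cand)$names %in% visited))) { nxt <- cand; break }
    if (is.null(nxt)) break
    current <- nxt
  }
  list(order = visited, kept = union(start, kept))
}

expect_kg_equal <- function(a, b) expect_true(kg_equal(a, b))
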