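## Fuzzy c-means (Bezdek alternating optimisation) and silhouette width.
##
## Items are the rows of the similarity (sub)matrix: each predicate is
## represented by its vector of similarities to every predicate of the node
## being split, and both the clustering and the silhouette use Euclidean
## distance between these profile rows.

#' Fuzzy c-means clustering
#'
#' Standard fuzzy c-means: memberships and centroids are updated alternately,
#'
#'   v_j = sum_i u_ij^m x_i / sum_i u_ij^m,
#'   u_ij = 1 / sum_l (d_ij / d_il)^(2/(m-1)),
#'
#' minimising the objective `J = sum_ij u_ij^m d_ij^2`, which is
#' non-increasing across iterations within a run. Several random
#' initialisations are run and the one with the best final objective is
#' returned; with a fixed `seed` the result is reproducible.
#'
#' @param x numeric matrix, one row per item.
#' @param k number of clusters (1 <= k <= nrow(x)).
#' @param m fuzzifier, > 1 (default 2); values near 1 approach hard k-means.
#' @param tol convergence threshold on the maximum membership change.
#' @param max_iter iteration cap per run.
#' @param restarts independent random initialisations (default 5).
#' @param seed integer seed for the initialisations.
#' @return an object of class `fcm`: memberships `U` (rows sum to 1),
#'   `centroids`, final `objective`, the per-iteration `objective_trace` of
#'   the winning run, its initial membership matrix `init_U`, `iterations`,
#'   and a `converged` flag (a run stopped by `max_iter` is returned with a
#'   warning).
#' @examples
#' set.seed(1)
#' x <- rbind(matrix(rnorm(20, 0), 5), matrix(rnorm(20, 4), 5))
#' fit <- fcm(x, k = 2, seed = 1)
#' round(fit$U, 2)
#' @export
fcm <- function(x, k, m = 2, tol = 1e-6, max_iter = 300, restarts = 5,
                seed = 1) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (!is_scalar_number(k) || k < 1) pt_stop("usage", "k must be >= 1")
  k <- as.integer(k)
  if (k > n) pt_stop("usage", "k = %d exceeds the number of items (%d)", k, n)
  if (!is_scalar_number(m) || m <= 1) pt_stop("usage", "fuzzifier m must be > 1")
  if (k == 1L) {
    U <- matrix(1, n, 1, dimnames = list(rownames(x), NULL))
    v <- matrix(colMeans(x), 1)
    obj <- sum(sweep(x, 2, v[1, ])^2)
    return(structure(list(U = U, centroids = v, objective = obj,
                          objective_trace = obj, init_U = U, iterations = 0L,
                          converged = TRUE, k = 1L, m = m, restart = 1L),
                     class = "fcm"))
  }
  best <- NULL
  for (r in seq_len(restarts)) {
    set.seed(derive_seed(seed, 101L, r))
    U0 <- matrix(stats::runif(n * k), n, k)
    U0 <- U0 / rowSums(U0)
    run <- fcm_run(x, U0, m, tol, max_iter)
    if (is.null(best) || run$objective < best$objective) {
      best <- run
      best$init_U <- U0
      best$restart <- r
    }
  }
  if (!best$converged)
    pt_warn("fcm did not converge within %d iterations (k = %d)", max_iter, k)
  rownames(best$U) <- rownames(x)
  best$k <- k
  best$m <- m
  class(best) <- "fcm"
  best
}

## One alternating-optimisation run from a given initial membership matrix.
fcm_run <- function(x, U, m, tol, max_iter) {
  n <- nrow(x); k <- ncol(U)
  xsq <- rowSums(x^2)
  trace <- numeric(0)
  converged <- FALSE
  iter <- 0L
  V <- NULL
  repeat {
    iter <- iter + 1L
    Um <- U^m
    V <- crossprod(Um, x) / colSums(Um)
    d2 <- outer(xsq, rowSums(V^2), "+") - 2 * x %*% t(V)
    d2[d2 < 0] <- 0
    Unew <- fcm_memberships(d2, m)
    trace[iter] <- sum(Unew^m * d2)
    delta <- max(abs(Unew - U))
    U <- Unew
    if (delta < tol) { converged <- TRUE; break }
    if (iter >= max_iter) break
  }
  list(U = U, centroids = V, objective = trace[iter],
       objective_trace = trace, iterations = iter, converged = converged)
}

## Membership update; items at zero distance from one or more centroids get
## all their mass split across those centroids.
fcm_memberships <- function(d2, m) {
  n <- nrow(d2); k <- ncol(d2)
  U <- matrix(0, n, k)
  zero <- d2 <= .Machine$double.eps
  has_zero <- rowSums(zero) > 0
  if (any(has_zero))
    U[has_zero, ] <- zero[has_zero, , drop = FALSE] /
      rowSums(zero[has_zero, , drop = FALSE])
  if (any(!has_zero)) {
    d <- d2[!has_zero, , drop = FALSE]^(-1 / (m - 1))
    U[!has_zero, ] <- d / rowSums(d)
  }
  U
}

#' @export
print.fcm <- function(x, ...) {
  cat(sprintf("<fcm> k=%d, m=%g: objective %.6g after %d iteration(s)%s\n",
              x$k, x$m, x$objective, x$iterations,
              if (x$converged) "" else " (not converged)"))
  invisible(x)
}

#' Harden a fuzzy membership matrix
#'
#' Assigns every item to its cluster of maximum membership; ties go to the
#' lowest cluster index, making the hard view deterministic.
#'
#' @param U a membership matrix or an [fcm()] fit.
#' @return an integer vector of cluster labels.
#' @export
harden <- function(U) {
  if (inherits(U, "fcm")) U <- U$U
  max.col(U, ties.method = "first")
}

#' Fuzzy predicates of a membership matrix
#'
#' Predicates whose membership reaches `beta` in two or more clusters bridge
#' topics (e.g. a predicate shared by two complication domains).
#'
#' @param U a membership matrix with item rownames, or an [fcm()] fit.
#' @param beta membership threshold in (0, 0.5].
#' @return a list of `list(predicate, clusters)` entries, one per fuzzy
#'   predicate (possibly empty).
#' @export
fuzzy_predicates <- function(U, beta = 0.3) {
  if (inherits(U, "fcm")) U <- U$U
  if (!is_scalar_number(beta) || beta <= 0 || beta > 0.5)
    pt_stop("usage", "beta must lie in (0, 0.5]")
  items <- rownames(U) %||% as.character(seq_len(nrow(U)))
  out <- list()
  for (i in seq_len(nrow(U))) {
    cl <- which(U[i, ] >= beta)
    if (length(cl) >= 2)
      out[[length(out) + 1L]] <- list(predicate = items[i], clusters = cl)
  }
  out
}

#' Mean silhouette width of a hard clustering
#'
#' For each item, `a` is its mean Euclidean distance to the other members of
#' its cluster and `b` the smallest mean distance to any other cluster; the
#' silhouette is `(b - a) / max(a, b)`, with items alone in their cluster
#' contributing 0. The mean over items is returned.
#'
#' @param x numeric matrix of item profiles (rows).
#' @param labels integer cluster labels; at least two non-empty clusters.
#' @return a number in \[-1, 1\].
#' @export
silhouette_width <- function(x, labels) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (length(labels) != n)
    pt_stop("usage", "labels must have one entry per row of x")
  cl <- unique(labels)
  if (length(cl) < 2)
    pt_stop("usage", "silhouette width needs at least two non-empty clusters")
  d <- as.matrix(stats::dist(x))
  sizes <- table(factor(labels, levels = cl))
  s <- numeric(n)
  ## mean distance from every item to every cluster, in one matrix product
  G <- outer(labels, cl, "==") + 0
  sums <- d %*% G
  for (i in seq_len(n)) {
    own <- match(labels[i], cl)
    if (sizes[own] == 1L) { s[i] <- 0; next }
    a <- sums[i, own] / (sizes[own] - 1L)
    b <- min(sums[i, -own] / sizes[-own])
    s[i] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }
  mean(s)
}
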