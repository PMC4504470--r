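## Consensus partition from a co-assignment matrix: k-medoids (PAM) on the
## dissimilarity correlate D = 1 - P, with the cluster count chosen by the
## optimum average silhouette width.

#' k-medoids (PAM) clustering of a dissimilarity matrix
#'
#' Small instances (at most `exact_limit` candidate medoid subsets) are solved
#' exactly by enumeration, so the objective `sum_i D(i, medoid(i))` is the
#' global optimum whenever `choose(n, k)` is small — single-swap local search
#' can stall in local optima even at n = 8, which would break the exhaustive
#' consistency this clustering step is relied on for. Larger instances use the
#' classic deterministic BUILD initialization followed by SWAP steps until no
#' swap improves the objective. All ties break to the lowest index, so the
#' result is a pure function of `D` and `k`.
#'
#' @param D Symmetric non-negative dissimilarity matrix with zero diagonal.
#' @param k Number of clusters, `1 <= k <= n`.
#' @param exact_limit Enumerate all medoid subsets when their count is at most
#'   this (default 2000).
#' @return List: `medoids` (sorted indices), `clustering` (integer vector,
#'   cluster `j` is the cluster of `medoids[j]`), `objective`.
#' @export
pam_cluster <- function(D, k, exact_limit = 2000) {
  D <- as.matrix(D)
  n <- nrow(D)
  if (k > n) stopf("k = %d exceeds the number of points (%d)", k, n)
  if (k < 1L) stopf("k must be at least 1")
  check_dissimilarity(D)
  if (choose(n, k) <= exact_limit) {
    best <- NULL
    for (ms in utils::combn(n, k, simplify = FALSE)) {
      o <- sum(apply(D[, ms, drop = FALSE], 1L, min))
      if (is.null(best) || o < best$obj - 1e-12) best <- list(med = ms, obj = o)
    }
    cl <- apply(D[, best$med, drop = FALSE], 1L, which.min)
    return(list(medoids = best$med, clustering = as.integer(cl),
                objective = best$obj))
  }
  # BUILD: first medoid minimizes total dissimilarity; each later medoid
  # maximizes the decrease of the objective.
  med <- which.min(colSums(D))  # which.min takes the lowest index on ties
  dn <- D[, med]                # distance to nearest chosen medoid
  while (length(med) < k) {
    gain <- colSums(pmax(outer(dn, rep(1, n)) - D, 0))
    gain[med] <- -Inf
    nxt <- which.max(gain)
    med <- c(med, nxt)
    dn <- pmin(dn, D[, nxt])
  }
  objective <- function(ms) sum(apply(D[, ms, drop = FALSE], 1L, min))
  obj <- objective(med)
  # SWAP: best-improvement steps, objective strictly decreases
  repeat {
    best <- NULL
    for (mi in seq_along(med)) {
      for (h in setdiff(seq_len(n), med)) {
        cand <- med; cand[mi] <- h
        o <- objective(cand)
        if (o < obj - 1e-12 && (is.null(best) || o < best$obj - 1e-12)) {
          best <- list(med = cand, obj = o)
        }
      }
    }
    if (is.null(best)) break
    stopifnot(best$obj <= obj)  # objective is non-increasing across swaps
    med <- best$med; obj <- best$obj
  }
  med <- sort(unname(med))
  cl <- apply(D[, med, drop = FALSE], 1L, which.min)
  list(medoids = med, clustering = as.integer(cl), objective = objective(med))
}

check_dissimilarity <- function(D) {
  if (!isSymmetric(unname(D), tol = 1e-8)) stopf("dissimilarity matrix must be symmetric")
  if (any(diag(D) != 0)) stopf("dissimilarity matrix must have a zero diagonal")
  if (any(D < 0)) stopf("dissimilarities must be non-negative")
  invisible(TRUE)
}

#' Silhouette widths of a partition
#'
#' `s(i) = (b_i - a_i) / max(a_i, b_i)` with `a_i` the mean dissimilarity of
#' `i` to its own cluster (self excluded) and `b_i` the smallest mean
#' dissimilarity to another cluster. Singleton clusters take `s(i) = 0` by
#' convention; a single-cluster partition is an error.
#'
#' @param D Symmetric dissimilarity matrix.
#' @param clustering Integer cluster labels over the rows of `D`.
#' @return List: `s` (per-point widths) and `avg` (their mean).
#' @export
silhouette_width <- function(D, clustering) {
  D <- as.matrix(D)
  n <- nrow(D)
  stopifnot(length(clustering) == n)
  cl <- as.integer(factor(clustering))
  if (max(cl) < 2L) stopf("silhouette is undefined for a single cluster")
  sizes <- tabulate(cl)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- cl == cl[i]
    if (sizes[cl[i]] == 1L) { s[i] <- 0; next }
    a <- sum(D[i, own]) / (sizes[cl[i]] - 1L)
    b <- min(vapply(seq_len(max(cl))[-cl[i]],
                    function(g) mean(D[i, cl == g]), numeric(1L)))
    s[i] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }
  list(s = s, avg = mean(s))
}

#' Consensus partition of a co-assignment matrix
#'
#' Converts the co-assignment probabilities to dissimilarities `D = 1 - P`,
#' clusters with [pam_cluster()] for every `k` in `k_range`, and selects the
#' `k` with the highest average silhouette width (ties to the smallest `k`).
#' When every pairwise co-assignment probability is at least 0.5 the
#' degenerate single-cluster solution is also flagged.
#'
#' @param P Co-assignment matrix (symmetric, unit diagonal, values in
#'   `[0, 1]`).
#' @param k_max Largest cluster count evaluated (default
#'   `min(30, n - 1)`).
#' @param k_range Cluster counts to evaluate (default `2:k_max`).
#' @return List of class `cd_consensus`: `k`, `partition` (named integer
#'   vector), `medoids`, `profile` (k vs average silhouette width),
#'   `silhouette` (per-tip widths at the chosen k), `order` (tip order for
#'   heatmap display, consensus blocks contiguous), `k1_degenerate`.
#' @export
consensus_partition <- function(P, k_max = min(30L, nrow(P) - 1L),
                                k_range = 2:k_max) {
  P <- as.matrix(P)
  n <- nrow(P)
  if (n < 3L) stopf("need at least 3 tips for a consensus partition")
  if (!isSymmetric(unname(P), tol = 1e-8)) stopf("co-assignment matrix must be symmetric")
  if (any(P < 0 | P > 1)) stopf("co-assignment probabilities must lie in [0, 1]")
  if (any(abs(diag(P) - 1) > 1e-8)) stopf("co-assignment diagonal must be 1")
  k_range <- sort(unique(as.integer(k_range)))
  if (min(k_range) < 2L || max(k_range) > n - 1L) {
    stopf("k_range must lie within [2, n - 1]")
  }
  D <- 1 - P
  diag(D) <- 0
  prof <- data.frame(k = k_range, avg_silhouette = NA_real_)
  fits <- vector("list", length(k_range))
  for (i in seq_along(k_range)) {
    fits[[i]] <- pam_cluster(D, k_range[i])
    # ties in D can collapse the assignment below k distinct clusters
    if (length(unique(fits[[i]]$clustering)) >= 2L) {
      prof$avg_silhouette[i] <- silhouette_width(D, fits[[i]]$clustering)$avg
    }
  }
  tips <- rownames(P) %||% as.character(seq_len(n))
  k1 <- min(P) >= 0.5
  if (all(is.na(prof$avg_silhouette))) {
    if (!k1) stopf("no cluster structure found in the co-assignment matrix")
    # fully co-assigned tips: the degenerate single-cluster solution
    return(structure(list(k = 1L, partition = setNames(rep(1L, n), tips),
                          medoids = tips[which.min(colSums(D))],
                          profile = prof, silhouette = rep(NA_real_, n),
                          order = seq_len(n), k1_degenerate = TRUE),
                     class = "cd_consensus"))
  }
  sil <- ifelse(is.na(prof$avg_silhouette), -Inf, prof$avg_silhouette)
  best_i <- which.max(sil)  # ties -> smallest k (sorted order)
  best <- fits[[best_i]]
  part <- setNames(best$clustering, tips)
  ord <- order(best$clustering, seq_len(n))
  structure(list(k = k_range[best_i], partition = part,
                 medoids = tips[best$medoids], profile = prof,
                 silhouette = silhouette_width(D, best$clustering)$s,
                 order = ord,
                 k1_degenerate = k1),
            class = "cd_consensus")
}

#' @export
print.cd_consensus <- function(x, ...) {
  avg <- suppressWarnings(max(x$profile$avg_silhouette, na.rm = TRUE))
  cat(sprintf("Consensus partition: k = %d%s%s\n", x$k,
              if (is.finite(avg)) sprintf(" (avg silhouette %.3f)", avg) else "",
              if (x$k1_degenerate) " [k = 1 plausible: all P >= 0.5]" else ""))
  invisible(x)
}
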