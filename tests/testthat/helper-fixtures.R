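# Shared fixtures and independent oracle implementations. Oracles are kept
# deliberately naive (double loops, exhaustive enumeration) and separate from
# the package's code paths.

balanced4 <- function() ape::read.tree(text = "((a:1,b:1):9,(c:1,d:1):9);")

# 6-tip ultrametric tree with hand-checkable node heights:
# root 10; clade (c,d,e,f) at 5; (c,d) crown 2; (a,b) and (e,f) crowns 1.
tree6 <- function() {
  ape::read.tree(text = "((a:1,b:1):9,((c:2,d:2):3,(e:1,f:1):4):5);")
}

rand_coassign <- function(n, seed) {
  withr::with_seed(seed, {
    R <- matrix(runif(n * n), n)
    P <- (R + t(R)) / 2
    diag(P) <- 1
    dimnames(P) <- list(paste0("t", 1:n), paste0("t", 1:n))
    P
  })
}

# independent silhouette (plain formula, no vectorization tricks)
naive_silhouette <- function(D, cl) {
  n <- nrow(D)
  s <- numeric(n)
  for (i in 1:n) {
    mine <- which(cl == cl[i])
    if (length(mine) == 1L) { s[i] <- 0; next }
    a <- mean(D[i, setdiff(mine, i)])
    b <- Inf
    for (g in setdiff(unique(cl), cl[i])) {
      b <- min(b, mean(D[i, cl == g]))
    }
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

# exhaustive k-medoids: best objective over all medoid subsets (combn order
# breaks ties), nearest-medoid assignment with lowest-index ties
brute_pam <- function(D, k) {
  n <- nrow(D)
  subsets <- utils::combn(n, k, simplify = FALSE)
  best <- NULL
  for (ms in subsets) {
    o <- sum(apply(D[, ms, drop = FALSE], 1, min))
    if (is.null(best) || o < best$objective - 1e-12) {
      best <- list(medoids = ms, objective = o,
                   clustering = apply(D[, ms, drop = FALSE], 1, which.min))
    }
  }
  best
}

# exhaustive consensus: silhouette-optimal k over exhaustively solved PAM fits
brute_consensus_k <- function(P, k_range) {
  D <- 1 - P; diag(D) <- 0
  sil <- vapply(k_range, function(k) {
    naive_silhouette(D, brute_pam(D, k)$clustering)
  }, numeric(1))
  k_range[which.max(sil)]
}

# naive ANOSIM R: rank all pairs, average within/between by explicit loops
naive_anosim_R <- function(D, groups) {
  n <- nrow(D)
  pairs <- utils::combn(n, 2)
  dv <- apply(pairs, 2, function(ij) D[ij[1], ij[2]])
  rk <- rank(dv)
  wi <- apply(pairs, 2, function(ij) groups[ij[1]] == groups[ij[2]])
  M <- ncol(pairs)
  (mean(rk[!wi]) - mean(rk[wi])) / (M / 2)
}

expect_same_partition <- function(p1, p2) {
  p1 <- p1[names(p2)]
  expect_true(all(outer(unname(p1), unname(p1), "==") ==
                  outer(unname(p2), unname(p2), "==")))
}
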