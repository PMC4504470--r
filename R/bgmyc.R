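## Multitree GMYC sampling: a Metropolis-Hastings walk over the
## single-threshold delimitation index and the four rate/exponent parameters,
## run on a random subset of posterior trees, summarised as pairwise
## co-assignment probabilities.

# Per-tree cache: interval rows and tip partition for every candidate cut.
gmyc_candidate_cache <- function(tree) {
  prep <- gmyc_prep(tree)
  cand <- sort(gmyc_threshold_candidates(prep), decreasing = TRUE)
  list(prep = prep,
       thresholds = cand,
       rows = lapply(cand, function(t) build_rows(prep, cut_antichain(prep, t))),
       partitions = lapply(cand, function(t) crown_partition(prep, cut_antichain(prep, t))))
}

# MH chain over (threshold index, log lambda_div, p_div, log lambda_coal,
# p_coal). Priors: uniform threshold index, uniform log-rates on [-10, 10],
# uniform exponents on [0, 3]. One component is updated per iteration
# (Metropolis-within-Gibbs): +/-1 on the index, Gaussian sd 0.3 on log-rates,
# Gaussian sd 0.15 on exponents; out-of-prior proposals are rejected
# (reconstruction; the source method's proposal scheme is unpublished).
sample_partitions_tree <- function(cache, chain_length, burnin, thin) {
  n_cand <- length(cache$rows)
  ll_of <- function(ci, th) -as.numeric(gmyc_negll(th, cache$rows[[ci]]))
  # initialize at a mid-profile candidate's fit, then the best index for it
  st <- fit_rows(cache$rows[[max(1L, n_cand %/% 2L)]], n_starts = 1L)
  th <- pmin(pmax(c(log(st$params[["lambda_div"]]), st$params[["p_div"]],
                    log(st$params[["lambda_coal"]]), st$params[["p_coal"]]),
                  c(-9.5, 0.05, -9.5, 0.05)), c(9.5, 2.95, 9.5, 2.95))
  ci <- which.max(vapply(seq_len(n_cand), ll_of, numeric(1L), th = th))
  ll <- ll_of(ci, th)
  lower <- c(-10, 0, -10, 0); upper <- c(10, 3, 10, 3)
  sds <- c(0.3, 0.15, 0.3, 0.15)
  keep <- retained_indices(chain_length - burnin, 0, thin) + burnin
  out <- matrix(NA_integer_, length(keep), cache$prep$ntip)
  acc <- 0L; kk <- 0L
  for (s in seq_len(chain_length)) {
    comp <- sample.int(5L, 1L)
    if (comp == 5L) {  # threshold index
      ci2 <- ci + sample(c(-1L, 1L), 1L)
      if (ci2 >= 1L && ci2 <= n_cand) {
        ll2 <- ll_of(ci2, th)
        if (is.finite(ll2) && log(runif(1L)) < ll2 - ll) {
          ci <- ci2; ll <- ll2; acc <- acc + 1L
        }
      }
    } else {
      th2 <- th
      th2[comp] <- th2[comp] + rnorm(1L, 0, sds[comp])
      if (th2[comp] >= lower[comp] && th2[comp] <= upper[comp]) {
        ll2 <- ll_of(ci, th2)
        if (is.finite(ll2) && log(runif(1L)) < ll2 - ll) {
          th <- th2; ll <- ll2; acc <- acc + 1L
        }
      }
    }
    if (kk < length(keep) && s == keep[kk + 1L]) {
      kk <- kk + 1L
      out[kk, ] <- cache$partitions[[ci]]
    }
  }
  list(partitions = out, acceptance = acc / chain_length)
}

#' Sample GMYC delimitations across a posterior tree set
#'
#' Draws `n_trees` trees uniformly at random from the sample and runs, on each,
#' a Metropolis-Hastings sampler over the single-threshold GMYC posterior
#' (threshold index plus the four rate/exponent parameters under weakly
#' informative uniform priors). Retained delimitations from all trees are
#' concatenated. The study-scale defaults are a 50000-step chain with burn-in
#' 40000 and thinning 100, i.e. 100 retained delimitations per tree.
#'
#' @param trees A [tree_sample()] object.
#' @param n_trees Number of trees to draw (default: all).
#' @param chain_length,burnin,thin MH chain settings (defaults 50000, 40000,
#'   100).
#' @param seed Integer seed; identical inputs and seed give identical output.
#' @return A `cd_partitionsample`: integer matrix `partitions` (samples x
#'   tips, entity labels per row), `tips`, `tree_index`, `acceptance`.
#' @export
sample_partitions <- function(trees, n_trees = length(trees),
                              chain_length = 50000L, burnin = 40000L,
                              thin = 100L, seed = NULL) {
  stopifnot(inherits(trees, "cd_treesample"))
  if (n_trees > length(trees)) stopf("n_trees exceeds the tree sample size")
  if (chain_length <= burnin) stopf("chain_length must exceed burnin")
  per_tree <- length(retained_indices(chain_length - burnin, 0, thin))
  if (per_tree == 0L) stopf("no samples retained; reduce thinning")
  with_seed(seed, {
    idx <- sample.int(length(trees), n_trees)
    tips <- sort(trees$trees[[1L]]$tip.label)
    parts <- vector("list", n_trees)
    accs <- numeric(n_trees)
    for (i in seq_along(idx)) {
      cache <- gmyc_candidate_cache(trees$trees[[idx[i]]])
      run <- sample_partitions_tree(cache, chain_length, burnin, thin)
      # align tip order across trees
      ord <- match(tips, cache$prep$tips)
      parts[[i]] <- run$partitions[, ord, drop = FALSE]
      accs[i] <- run$acceptance
    }
    if (mean(accs) < 0.05 || mean(accs) > 0.8) {
      warnf(paste("MH acceptance rate %.2f outside [0.05, 0.8];",
                  "consider retuning proposal scales"), mean(accs))
    }
    structure(list(partitions = do.call(rbind, parts), tips = tips,
                   tree_index = rep(idx, each = per_tree),
                   acceptance = accs),
              class = "cd_partitionsample")
  })
}

#' @export
print.cd_partitionsample <- function(x, ...) {
  cat(sprintf("Partition sample: %d delimitations x %d tips (%d trees)\n",
              nrow(x$partitions), length(x$tips), length(unique(x$tree_index))))
  invisible(x)
}

#' Pairwise co-assignment probability matrix
#'
#' `P[i, j]` is the fraction of sampled delimitations that place tips `i` and
#' `j` in the same entity; `P` is symmetric with unit diagonal.
#'
#' @param samples A `cd_partitionsample` (or a plain integer matrix of
#'   partitions, samples in rows).
#' @param tips Optional tip labels when `samples` is a bare matrix.
#' @return Symmetric numeric matrix with tips as dimnames.
#' @export
coassignment_matrix <- function(samples, tips = NULL) {
  m <- if (inherits(samples, "cd_partitionsample")) samples$partitions else samples
  if (is.null(tips)) {
    tips <- if (inherits(samples, "cd_partitionsample")) samples$tips
            else colnames(m)
  }
  if (is.null(dim(m)) || nrow(m) == 0L) stopf("empty partition sample")
  n <- ncol(m)
  P <- matrix(0, n, n)
  for (s in seq_len(nrow(m))) {
    lab <- m[s, ]
    P <- P + (outer(lab, lab, "=="))
  }
  P <- P / nrow(m)
  dimnames(P) <- list(tips, tips)
  P
}
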