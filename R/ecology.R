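## Locality-level composition statistics: dissimilarities, ANOSIM, SIMPER,
## BIO-ENV/BVSTEP environmental matching and between-matrix rank correlation.

#' Dissimilarity matrix between localities
#'
#' Sorensen (`1 - 2a/(2a + b + c)`, presence/absence), Bray-Curtis (counts)
#' or Euclidean (environmental rows). The Sorensen and Bray-Curtis routes go
#' through `vegan::vegdist`; an all-zero row is an error under Sorensen.
#'
#' @param m Community matrix or (normalized) environmental table, localities
#'   in rows.
#' @param metric `"sorensen"`, `"braycurtis"` or `"euclidean"`.
#' @return Symmetric dissimilarity matrix with a `metric` attribute.
#' @export
dissimilarity <- function(m, metric = c("sorensen", "braycurtis", "euclidean")) {
  metric <- match.arg(metric)
  m <- as.matrix(m)
  d <- switch(metric,
    sorensen = {
      if (any(rowSums(m) == 0)) {
        stopf("all-zero locality row(s) not allowed under sorensen: %s",
              paste(rownames(m)[rowSums(m) == 0], collapse = ", "))
      }
      vegan::vegdist(m > 0, method = "bray", binary = TRUE)
    },
    braycurtis = vegan::vegdist(m, method = "bray"),
    euclidean = dist(m))
  out <- as.matrix(d)
  dimnames(out) <- list(rownames(m), rownames(m))
  attr(out, "metric") <- metric
  out
}

# ranks of the M = n(n-1)/2 pairwise dissimilarities (mean ranks for ties)
# and the ANOSIM R statistic for given group labels
anosim_r <- function(rk, within, M) {
  rb <- mean(rk[!within]); rw <- mean(rk[within])
  (rb - rw) / (M / 2)
}

#' Analysis of similarities (ANOSIM)
#'
#' Rank-based test contrasting between-group and within-group dissimilarities:
#' `R = (mean between-rank - mean within-rank) / (M/2)` with
#' `M = n(n-1)/2`. The global p-value comes from seeded label permutations,
#' `p = (#{R_perm >= R_obs} + 1) / (n_perm + 1)`; when the number of distinct
#' label assignments is small (`<= exact_limit`) all assignments are
#' enumerated instead and `p = #{R_perm >= R_obs} / N` over the full set
#' (the observed assignment included). Pairwise tests are run for every group
#' pair; pairs involving a single-member group are reported as not computable.
#'
#' @param D Dissimilarity matrix.
#' @param groups Group labels, one per locality (named or in row order).
#' @param n_perm Number of permutations (default 10000).
#' @param seed Integer seed for the permutations.
#' @param exact_limit Enumerate all assignments when their count is at most
#'   this (default 0: never).
#' @param pairwise Also compute pairwise tests (default `TRUE`).
#' @return List of class `cd_anosim`: `R`, `p`, `M`, `n_perm`, `exact`,
#'   `pairwise` (upper triangle R, lower triangle significance stars),
#'   `pairwise_R`, `pairwise_p`.
#' @export
anosim <- function(D, groups, n_perm = 10000L, seed = NULL,
                   exact_limit = 0L, pairwise = TRUE) {
  D <- as.matrix(D)
  n <- nrow(D)
  groups <- as.character(if (!is.null(names(groups)) && !is.null(rownames(D)))
    groups[rownames(D)] else groups)
  stopifnot(length(groups) == n)
  sizes <- table(groups)
  if (sum(sizes >= 2L) < 2L) {
    stopf("global ANOSIM needs at least 2 groups with at least 2 members")
  }
  res <- anosim_one(D, groups, n_perm, seed, exact_limit)
  pw_R <- pw_p <- NULL
  if (pairwise && length(sizes) >= 2L) {
    gs <- names(sizes)
    pw_R <- pw_p <- matrix(NA_real_, length(gs), length(gs),
                           dimnames = list(gs, gs))
    for (a in seq_along(gs)) for (b in seq_along(gs)) if (a < b) {
      sel <- groups %in% c(gs[a], gs[b])
      if (min(table(groups[sel])) < 2L) next  # size-1 group: "-" in the tables
      sub <- anosim_one(D[sel, sel, drop = FALSE], groups[sel],
                        n_perm, seed, exact_limit)
      pw_R[a, b] <- sub$R
      pw_p[b, a] <- sub$p
    }
  }
  structure(list(R = res$R, p = res$p, M = res$M, n_perm = res$n_perm,
                 exact = res$exact, pairwise_R = pw_R, pairwise_p = pw_p),
            class = "cd_anosim")
}

anosim_one <- function(D, groups, n_perm, seed, exact_limit) {
  n <- nrow(D)
  M <- n * (n - 1) / 2
  lower <- lower.tri(D)
  rk <- rank(D[lower])
  same <- outer(groups, groups, "==")[lower]
  R_obs <- anosim_r(rk, same, M)
  counts <- table(groups)
  n_assign <- exp(lgamma(n + 1) - sum(lgamma(counts + 1)))
  if (n_assign <= exact_limit) {
    perms <- distinct_assignments(groups)
    R_perm <- vapply(perms, function(g) {
      anosim_r(rk, outer(g, g, "==")[lower], M)
    }, numeric(1L))
    p <- sum(R_perm >= R_obs - 1e-12) / length(R_perm)
    return(list(R = R_obs, p = p, M = M, n_perm = length(R_perm), exact = TRUE))
  }
  exceed <- with_seed(seed, {
    sum(vapply(seq_len(n_perm), function(i) {
      g <- sample(groups)
      anosim_r(rk, outer(g, g, "==")[lower], M) >= R_obs - 1e-12
    }, logical(1L)))
  })
  list(R = R_obs, p = (exceed + 1) / (n_perm + 1), M = M, n_perm = n_perm,
       exact = FALSE)
}

# all distinct assignments of the multiset of group labels to positions
distinct_assignments <- function(groups) {
  n <- length(groups)
  lv <- unique(groups)
  out <- list()
  rec <- function(pos, remaining, current) {
    if (!length(pos)) { out[[length(out) + 1L]] <<- current; return(invisible()) }
    for (g in lv) {
      if (remaining[g] > 0L) {
        remaining[g] <- remaining[g] - 1L
        current[pos[1L]] <- g
        rec(pos[-1L], remaining, current)
        remaining[g] <- remaining[g] + 1L
      }
    }
  }
  counts <- table(groups)
  remaining <- setNames(as.integer(counts), names(counts))
  rec(seq_len(n), remaining, character(n))
  out
}

#' @export
print.cd_anosim <- function(x, ...) {
  cat(sprintf("ANOSIM: global R = %.3f, p = %.4g %s (%s, M = %d)\n",
              x$R, x$p, signif_stars(x$p),
              if (x$exact) "exact enumeration" else
                sprintf("%d permutations", x$n_perm), x$M))
  invisible(x)
}

#' SIMPER decomposition of between-group dissimilarity
#'
#' For every between-group sample pair `(i, j)` the Bray-Curtis contribution
#' of unit `k` is `|x_ik - x_jk| / sum_s (x_is + x_js)`; contributions are
#' averaged over pairs and expressed as percentages of the average between-
#' group dissimilarity (summing to 100).
#'
#' @param m Community matrix (localities x units).
#' @param groups Group labels over the rows of `m`.
#' @param pair The two groups to contrast (default: the first two levels).
#' @return Data frame of class `cd_simper`, units sorted by contribution:
#'   `unit`, `average`, `percent`, `cumulative`. Zero average between-group
#'   dissimilarity yields an empty table with a warning.
#' @export
simper <- function(m, groups, pair = NULL) {
  m <- as.matrix(m)
  groups <- as.character(if (!is.null(names(groups)) && !is.null(rownames(m)))
    groups[rownames(m)] else groups)
  stopifnot(length(groups) == nrow(m))
  if (is.null(pair)) pair <- unique(groups)[1:2]
  ia <- which(groups == pair[1L]); ib <- which(groups == pair[2L])
  if (!length(ia) || !length(ib)) stopf("empty group in SIMPER pair")
  contrib <- matrix(0, length(ia) * length(ib), ncol(m))
  r <- 0L
  for (i in ia) for (j in ib) {
    r <- r + 1L
    tot <- sum(m[i, ] + m[j, ])
    if (tot > 0) contrib[r, ] <- abs(m[i, ] - m[j, ]) / tot
  }
  avg <- colMeans(contrib)
  if (sum(avg) == 0) {
    warnf("zero between-group dissimilarity; empty SIMPER table")
    return(structure(data.frame(unit = character(0), average = numeric(0),
                                percent = numeric(0), cumulative = numeric(0)),
                     class = c("cd_simper", "data.frame")))
  }
  pct <- 100 * avg / sum(avg)
  ord <- order(pct, decreasing = TRUE)
  structure(data.frame(unit = colnames(m)[ord] %||% as.character(ord),
                       average = avg[ord], percent = pct[ord],
                       cumulative = cumsum(pct[ord]),
                       row.names = NULL, stringsAsFactors = FALSE),
            class = c("cd_simper", "data.frame"))
}

# Spearman rank correlation between the lower triangles of two matrices
triangle_rho <- function(D1, D2) {
  lt <- lower.tri(D1)
  cor(D1[lt], D2[lt], method = "spearman")
}

#' Rank correlation between two dissimilarity matrices
#'
#' Spearman correlation over corresponding off-diagonal entries, with a
#' permutation p-value obtained by relabelling the localities of the second
#' matrix.
#'
#' @param D1,D2 Dissimilarity matrices over the same localities.
#' @param n_perm Number of permutations (default 10000).
#' @param seed Integer seed.
#' @return List: `rho`, `p`, `n_perm`.
#' @export
matrix_correlation <- function(D1, D2, n_perm = 10000L, seed = NULL) {
  D1 <- as.matrix(D1); D2 <- as.matrix(D2)
  if (!is.null(rownames(D1)) && !is.null(rownames(D2))) {
    if (!setequal(rownames(D1), rownames(D2))) {
      stopf("locality sets differ between matrices")
    }
    D2 <- D2[rownames(D1), rownames(D1)]
  }
  if (!all(dim(D1) == dim(D2))) stopf("matrices have different dimensions")
  rho <- triangle_rho(D1, D2)
  n <- nrow(D1)
  exceed <- with_seed(seed, {
    sum(vapply(seq_len(n_perm), function(i) {
      pp <- sample.int(n)
      triangle_rho(D1, D2[pp, pp]) >= rho - 1e-12
    }, logical(1L)))
  })
  list(rho = rho, p = (exceed + 1) / (n_perm + 1), n_perm = n_perm)
}

#' Collinearity pre-filter for environmental variables
#'
#' Implements the literal exclusion rule: drop one variable of a pair whose
#' Euclidean distance (over localities) exceeds the cutoff. Because z-scored
#' columns are almost always farther apart than 0.8, the `"correlation"` mode
#' (drop one of a pair with `|r| > cutoff`) is provided as the conventional
#' alternative; the earlier column in table order is kept.
#'
#' @param env Normalized environmental table.
#' @param cutoff Threshold (default 0.80).
#' @param mode `"distance"` (literal) or `"correlation"`.
#' @return `env` restricted to the retained columns, with a `dropped`
#'   attribute.
#' @export
filter_collinear <- function(env, cutoff = 0.80,
                             mode = c("distance", "correlation")) {
  mode <- match.arg(mode)
  keep <- names(env)
  dropped <- character(0)
  i <- 1L
  while (i < length(keep)) {
    j <- i + 1L
    while (j <= length(keep)) {
      a <- env[[keep[i]]]; b <- env[[keep[j]]]
      bad <- if (mode == "distance") sqrt(sum((a - b)^2)) > cutoff
             else abs(cor(a, b)) > cutoff
      if (bad) {
        dropped <- c(dropped, keep[j])
        keep <- keep[-j]
      } else j <- j + 1L
    }
    i <- i + 1L
  }
  out <- env[, keep, drop = FALSE]
  attr(out, "dropped") <- dropped
  out
}

# best single BVSTEP run from a given starting subset
bvstep_search <- function(D_bio, env, start, rho_stop, delta_stop) {
  lt <- lower.tri(D_bio)
  dvec <- D_bio[lt]
  rho_of <- function(vars) {
    if (!length(vars)) return(-Inf)
    cor(dvec, dist_vec(env[, vars, drop = FALSE]), method = "spearman")
  }
  cur <- start
  rho <- rho_of(cur)
  repeat {
    if (rho > rho_stop) break
    best <- list(vars = cur, rho = rho)
    # backward drops
    if (length(cur) > 1L) {
      for (v in cur) {
        r <- rho_of(setdiff(cur, v))
        if (r > best$rho) best <- list(vars = setdiff(cur, v), rho = r)
      }
    }
    # forward adds
    for (v in setdiff(names(env), cur)) {
      r <- rho_of(c(cur, v))
      if (r > best$rho) best <- list(vars = c(cur, v), rho = r)
    }
    if (best$rho - rho < delta_stop) break
    cur <- best$vars; rho <- best$rho
  }
  list(vars = sort(cur), rho = rho)
}

dist_vec <- function(m) as.numeric(dist(as.matrix(m)))

#' BIO-ENV/BVSTEP search for the best environmental variable subset
#'
#' After the collinearity pre-filter, repeats from `n_restarts` random start
#' subsets a stepwise search that alternates backward-drop and forward-add
#' moves maximizing the Spearman correlation between the Euclidean distance of
#' the environmental subset and the biotic dissimilarity matrix, stopping when
#' `rho > rho_stop` or the improvement falls below `delta_stop`. Models are
#' tallied across restarts; the significance of the best (most frequent)
#' model's rho is assessed by permuting the locality labels of the biotic
#' matrix and re-running the search.
#'
#' @param D_bio Biotic dissimilarity matrix (e.g. Sorensen on OTU
#'   presence/absence).
#' @param env Normalized environmental table over the same localities.
#' @param n_restarts Number of random-start searches (default 50).
#' @param rho_stop,delta_stop Stopping criteria (defaults 0.95 and 0.001).
#' @param collin_cut,collin_mode Collinearity filter settings (see
#'   [filter_collinear()]).
#' @param n_perm Permutations for the significance of the best model
#'   (default 99; 0 skips the test).
#' @param seed Integer seed.
#' @return List of class `cd_bioenv`: `best` (variables, rho), `models`
#'   (data frame of distinct models with rho and restart frequency), `p`,
#'   `dropped` (variables removed by the pre-filter).
#' @export
bioenv_bvstep <- function(D_bio, env, n_restarts = 50L, rho_stop = 0.95,
                          delta_stop = 0.001, collin_cut = 0.80,
                          collin_mode = "correlation", n_perm = 99L,
                          seed = NULL) {
  D_bio <- as.matrix(D_bio)
  stopifnot(nrow(env) == nrow(D_bio))
  if (!is.null(rownames(env)) && !is.null(rownames(D_bio))) {
    check_pairing(D_bio, env)
    env <- env[rownames(D_bio), , drop = FALSE]
  }
  env <- filter_collinear(env, collin_cut, collin_mode)
  if (ncol(env) < 2L) stopf("fewer than 2 variables left after collinearity filter")
  with_seed(seed, {
    runs <- lapply(seq_len(n_restarts), function(i) {
      start <- names(env)[runif(ncol(env)) < 0.5]
      if (!length(start)) start <- sample(names(env), 1L)
      bvstep_search(D_bio, env, start, rho_stop, delta_stop)
    })
    key <- vapply(runs, function(r) paste(r$vars, collapse = "+"), character(1L))
    tab <- sort(table(key), decreasing = TRUE)
    models <- data.frame(
      model = names(tab),
      rho = vapply(names(tab), function(k) runs[[match(k, key)]]$rho, numeric(1L)),
      frequency = as.numeric(tab) / n_restarts,
      stringsAsFactors = FALSE, row.names = NULL)
    best <- runs[[match(names(tab)[1L], key)]]
    p <- NA_real_
    if (n_perm > 0L) {
      n <- nrow(D_bio)
      exceed <- 0L
      for (i in seq_len(n_perm)) {
        pp <- sample.int(n)
        Dp <- D_bio[pp, pp]
        start <- names(env)[runif(ncol(env)) < 0.5]
        if (!length(start)) start <- sample(names(env), 1L)
        rp <- bvstep_search(Dp, env, start, rho_stop, delta_stop)$rho
        if (rp >= best$rho - 1e-12) exceed <- exceed + 1L
      }
      p <- (exceed + 1) / (n_perm + 1)
    }
    structure(list(best = best, models = models, p = p,
                   dropped = attr(env, "dropped")),
              class = "cd_bioenv")
  })
}

#' @export
print.cd_bioenv <- function(x, ...) {
  cat(sprintf("BVSTEP best model: {%s}, rho = %.3f (frequency %.1f%%%s)\n",
              paste(x$best$vars, collapse = ", "), x$best$rho,
              100 * x$models$frequency[1L],
              if (is.na(x$p)) "" else sprintf(", p = %.3g", x$p)))
  invisible(x)
}

#' Exhaustive BIO-ENV over all variable subsets
#'
#' Evaluates the Spearman correlation for every non-empty subset of the
#' environmental variables (feasible up to ~15 variables). Used as the
#' reference maximum that the stepwise search cannot exceed.
#'
#' @param D_bio Biotic dissimilarity matrix.
#' @param env Normalized environmental table.
#' @return List: `vars`, `rho` of the best subset, `all` (data frame).
#' @export
bioenv_exhaustive <- function(D_bio, env) {
  D_bio <- as.matrix(D_bio)
  v <- names(env)
  if (length(v) > 15L) stopf("too many variables for exhaustive search")
  lt <- lower.tri(D_bio)
  dvec <- D_bio[lt]
  subsets <- unlist(lapply(seq_along(v), function(k) {
    combn(v, k, simplify = FALSE)
  }), recursive = FALSE)
  rho <- vapply(subsets, function(s) {
    cor(dvec, dist_vec(env[, s, drop = FALSE]), method = "spearman")
  }, numeric(1L))
  best <- which.max(rho)
  list(vars = subsets[[best]], rho = rho[best],
       all = data.frame(model = vapply(subsets, paste, character(1L),
                                       collapse = "+"),
                        rho = rho, stringsAsFactors = FALSE))
}
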