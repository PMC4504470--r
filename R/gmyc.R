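## Generalized mixed Yule-coalescent (GMYC) delimitation.
##
## A delimitation is represented internally by its set of entity "crown"
## nodes: an antichain of nodes (tips allowed) whose clades partition the tip
## set. Edges inside a crown clade belong to that entity's coalescent class;
## every other edge -- including the stem above each crown -- belongs to the
## between-entity diversification class. A single threshold time T maps onto
## the antichain of highest nodes younger than T; the boundary T = root height
## yields one entity containing everything, which reproduces the null
## (one-class) model exactly and so guarantees that the threshold model nests
## the null.

gmyc_prep <- function(tree, tol = 1e-6) {
  if (!inherits(tree, "phylo")) stopf("tree must be a 'phylo' object")
  if (!ape::is.binary(tree)) stopf("tree must be binary")
  if (!ape::is.rooted(tree)) stopf("tree must be rooted")
  assert_ultrametric(tree, tol)
  tree <- ape::reorder.phylo(tree, "cladewise")  # parents precede children
  ntip <- ape::Ntip(tree)
  h <- node_heights(tree)
  parent <- integer(ntip + tree$Nnode)
  parent[tree$edge[, 2L]] <- tree$edge[, 1L]
  list(tree = tree, ntip = ntip, nnode = tree$Nnode, h = h,
       parent = parent, edge = tree$edge, root = ntip + 1L,
       H = h[ntip + 1L], tips = tree$tip.label)
}

# Antichain of crown nodes induced by a horizontal cut at height t.
# For t strictly inside (0, H): crowns are nodes v with h(v) < t whose parent
# sits at or above t. t = H is the boundary case with the root as sole crown.
cut_antichain <- function(prep, t) {
  if (t <= 0 || t > prep$H) stopf("threshold %g outside (0, tree height %g]", t, prep$H)
  if (t >= prep$H) return(prep$root)
  v <- seq_len(prep$ntip + prep$nnode)
  ph <- rep(Inf, length(v))
  ph[prep$parent > 0L] <- prep$h[prep$parent[prep$parent > 0L]]
  v[prep$h < t & ph >= t]
}

# owner[v] = crown node whose clade contains v (itself included), 0 if v is
# above every crown. Relies on cladewise edge order (parents first).
crown_owner <- function(prep, crowns) {
  owner <- integer(prep$ntip + prep$nnode)
  is_crown <- logical(length(owner))
  is_crown[crowns] <- TRUE
  if (is_crown[prep$root]) owner[prep$root] <- prep$root
  for (e in seq_len(nrow(prep$edge))) {
    p <- prep$edge[e, 1L]; c <- prep$edge[e, 2L]
    owner[c] <- if (owner[p] > 0L) owner[p] else if (is_crown[c]) c else 0L
  }
  if (any(owner[seq_len(prep$ntip)] == 0L)) {
    stopf("crown set does not cover all tips")
  }
  owner
}

# Tip -> entity id (1..n_entities, numbered by first tip occurrence).
crown_partition <- function(prep, crowns) {
  owner <- crown_owner(prep, crowns)[seq_len(prep$ntip)]
  setNames(match(owner, unique(owner)), prep$tips)
}

# Interval rows for a delimitation: waiting time x, diversification lineage
# count k, and per-entity coalescent lineage counts stored as triplets
# (row index coal_r, pair count coal_m = n*(n-1), restricted to n >= 2).
build_rows <- function(prep, crowns) {
  owner <- crown_owner(prep, crowns)
  hp <- prep$h[prep$edge[, 1L]]
  hc <- prep$h[prep$edge[, 2L]]
  ent <- owner[prep$edge[, 1L]]       # > 0: coalescent edge of that entity
  bp <- sort(unique(c(0, prep$h[(prep$ntip + 1L):(prep$ntip + prep$nnode)])),
             decreasing = TRUE)
  eps <- prep$H * 1e-9
  nr <- length(bp) - 1L
  x <- bp[-length(bp)] - bp[-1L]
  k <- integer(nr)
  coal_r <- integer(0); coal_m <- numeric(0); coal_n <- integer(0)
  coal_e <- integer(0)
  for (i in seq_len(nr)) {
    top <- bp[i]; bot <- bp[i + 1L]
    cross <- hc <= bot + eps & hp >= top - eps
    k[i] <- sum(cross & ent == 0L)
    ce <- ent[cross & ent > 0L]
    if (length(ce)) {
      cnt <- table(ce)
      keep <- cnt >= 2L
      if (any(keep)) {
        nn <- as.integer(cnt[keep])
        coal_r <- c(coal_r, rep.int(i, sum(keep)))
        coal_n <- c(coal_n, nn)
        coal_m <- c(coal_m, nn * (nn - 1))
        coal_e <- c(coal_e, as.integer(names(cnt)[keep]))
      }
    }
  }
  keep <- x > eps
  if (!all(keep)) {
    remap <- cumsum(keep)
    sel <- keep[coal_r]
    coal_r <- remap[coal_r][sel]
    coal_m <- coal_m[sel]; coal_n <- coal_n[sel]; coal_e <- coal_e[sel]
    x <- x[keep]; k <- k[keep]
  }
  list(x = x, k = k, coal_r = coal_r, coal_m = coal_m, coal_n = coal_n,
       coal_e = coal_e, n_rows = length(x))
}

#' Interval decomposition of an ultrametric tree at a threshold
#'
#' Splits the tree into ordered inter-node intervals (root to tips) and, given
#' a threshold time, classifies each lineage into the between-entity
#' diversification class or the within-entity coalescent class of its entity.
#' Entities are the clades subtended where lineages cross the threshold; an
#' edge whose parent node is older than the threshold counts as a
#' diversification lineage for its whole length.
#'
#' @param tree Ultrametric `phylo` object.
#' @param threshold Time before present in `(0, height]`; the boundary value
#'   `height` gives a single entity.
#' @return A list of class `cd_intervals`: `x` (waiting times, summing to the
#'   tree height), `k` (diversification lineage counts), `n` (interval x
#'   entity matrix of coalescent lineage counts), `entities` (tip -> entity
#'   map) and `threshold`.
#' @export
interval_decomposition <- function(tree, threshold) {
  prep <- gmyc_prep(tree)
  crowns <- cut_antichain(prep, threshold)
  rows <- build_rows(prep, crowns)
  part <- crown_partition(prep, crowns)
  ents <- sort(unique(part))
  n <- matrix(0L, rows$n_rows, length(ents))
  if (length(rows$coal_r)) {
    owner_tip <- crown_owner(prep, crowns)[seq_len(prep$ntip)]
    ent_of_crown <- part[match(rows$coal_e, owner_tip)]
    for (j in seq_along(rows$coal_r)) {
      n[rows$coal_r[j], ent_of_crown[j]] <- rows$coal_n[j]
    }
  }
  structure(list(x = rows$x, k = rows$k, n = n, entities = part,
                 threshold = threshold, rows = rows),
            class = "cd_intervals")
}

#' GMYC log-likelihood of an interval table
#'
#' Per interval `i` the hazard is
#' `b_i = lambda_div * k_i^p_div + lambda_coal * sum_j (n_ij (n_ij - 1))^p_coal`
#' (absent classes contribute zero, regardless of the exponent), and the
#' log-likelihood is `sum_i (log b_i - b_i x_i)`. A zero hazard on an interval
#' with positive waiting time yields `-Inf` explicitly.
#'
#' @param intervals A [interval_decomposition()] result.
#' @param lambda_div,lambda_coal Non-negative rate parameters.
#' @param p_div,p_coal Scaling exponents.
#' @return Log-likelihood (finite, or `-Inf` when a hazard vanishes).
#' @export
model_loglik <- function(intervals, lambda_div, p_div, lambda_coal, p_coal) {
  stopifnot(lambda_div >= 0, lambda_coal >= 0)
  rows <- intervals$rows %||% intervals
  b <- row_hazard(rows, lambda_div, p_div, lambda_coal, p_coal)
  if (any(b <= 0 & rows$x > 0)) return(-Inf)
  sum(log(b) - b * rows$x)
}

row_hazard <- function(rows, ld, pd, lc, pc) {
  K <- numeric(rows$n_rows)
  idx <- rows$k > 0L
  K[idx] <- rows$k[idx]^pd
  C <- numeric(rows$n_rows)
  if (length(rows$coal_r)) {
    cs <- rowsum(rows$coal_m^pc, rows$coal_r)
    C[as.integer(rownames(cs))] <- cs[, 1L]
  }
  ld * K + lc * C
}

# Negative log-likelihood with analytic gradient in
# theta = (log lambda_div, p_div, log lambda_coal, p_coal).
gmyc_negll <- function(theta, rows) {
  ld <- exp(theta[1L]); pd <- theta[2L]
  lc <- exp(theta[3L]); pc <- theta[4L]
  K <- numeric(rows$n_rows); lnkK <- numeric(rows$n_rows)
  idx <- rows$k > 0L
  if (any(idx)) {
    K[idx] <- rows$k[idx]^pd
    lnkK[idx] <- K[idx] * log(rows$k[idx])
  }
  C <- numeric(rows$n_rows); Cln <- numeric(rows$n_rows)
  if (length(rows$coal_r)) {
    mp <- rows$coal_m^pc
    cs <- rowsum(cbind(mp, mp * log(rows$coal_m)), rows$coal_r)
    ri <- as.integer(rownames(cs))
    C[ri] <- cs[, 1L]; Cln[ri] <- cs[, 2L]
  }
  b <- ld * K + lc * C
  if (any(b <= 0)) return(structure(1e10, gradient = rep(0, 4)))
  r <- 1 / b - rows$x
  ll <- sum(log(b) - b * rows$x)
  g <- c(sum(r * ld * K), sum(r * ld * lnkK),
         sum(r * lc * C), sum(r * lc * Cln))
  structure(-ll, gradient = -g)
}

gmyc_starts <- function(rows, n_starts = 5L) {
  b0 <- rows$n_rows / sum(rows$x)
  base_rate <- function(p) {
    kb <- if (any(rows$k > 0L)) mean(rows$k[rows$k > 0L]^p) else 1
    cb <- if (length(rows$coal_m)) {
      mean(rowsum(rows$coal_m^p, rows$coal_r)[, 1L])
    } else 1
    c(div = max(kb, 1e-8), coal = max(cb, 1e-8))
  }
  starts <- list()
  for (p in c(0.5, 1, 1.5)) {
    bb <- base_rate(p)
    starts[[length(starts) + 1L]] <-
      c(log(0.5 * b0 / bb["div"]), p, log(0.5 * b0 / bb["coal"]), p)
  }
  bb <- base_rate(1)
  starts[[4L]] <- c(log(b0 / bb["div"]), 1, log(0.05 * b0 / bb["coal"]), 1)
  starts[[5L]] <- c(log(0.05 * b0 / bb["div"]), 1, log(b0 / bb["coal"]), 1)
  lapply(starts[seq_len(min(n_starts, 5L))],
         function(s) pmin(pmax(unname(s), c(-10, 0, -10, 0)), c(10, 3, 10, 3)))
}

# Maximize the 4-parameter likelihood for a fixed delimitation.
fit_rows <- function(rows, n_starts = 5L) {
  best <- NULL
  fails <- character(0)
  for (s in gmyc_starts(rows, n_starts)) {
    res <- tryCatch(
      optim(s, fn = function(th) as.numeric(gmyc_negll(th, rows)),
            gr = function(th) attr(gmyc_negll(th, rows), "gradient"),
            method = "L-BFGS-B",
            lower = c(-10, 0, -10, 0), upper = c(10, 3, 10, 3),
            control = list(maxit = 500L, factr = 1e4)),
      error = function(e) e)
    if (inherits(res, "error")) { fails <- c(fails, conditionMessage(res)); next }
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best)) {
    stopf("GMYC optimization failed at every start: %s",
          paste(unique(fails), collapse = "; "))
  }
  list(loglik = -best$value,
       params = c(lambda_div = exp(best$par[1L]), p_div = best$par[2L],
                  lambda_coal = exp(best$par[3L]), p_coal = best$par[4L]))
}

gmyc_fit_obj <- function(model, prep, crowns, fit, profile, conf, extra = list()) {
  part <- crown_partition(prep, crowns)
  structure(c(list(model = model, crowns = crowns, partition = part,
                   n_entities = length(unique(part)),
                   loglik = fit$loglik, params = fit$params,
                   profile = profile, conf_entities = conf,
                   n_free = switch(model, null = 2L,
                                   single = 5L,
                                   multiple = 4L + extra$n_thresholds),
                   tree_height = prep$H, n_tips = prep$ntip), extra),
            class = "cd_gmyc")
}

#' @export
print.cd_gmyc <- function(x, ...) {
  cat(sprintf("GMYC %s model: %d entities, logL = %.4f\n",
              x$model, x$n_entities, x$loglik))
  if (!is.null(x$conf_entities)) {
    cat(sprintf("  entity-count confidence set: %d-%d\n",
                min(x$conf_entities), max(x$conf_entities)))
  }
  invisible(x)
}

#' Fit the one-class null model
#'
#' All lineages form a single class with hazard
#' `lambda * (n_i (n_i - 1))^p`, i.e. the threshold-at-root boundary of the
#' mixed model.
#'
#' @param tree Ultrametric `phylo` object.
#' @return A `cd_gmyc` fit with `model = "null"`.
#' @export
fit_gmyc_null <- function(tree) {
  prep <- gmyc_prep(tree)
  rows <- build_rows(prep, prep$root)
  fit <- fit_rows(rows)
  gmyc_fit_obj("null", prep, prep$root, fit, profile = NULL, conf = NULL)
}

# Candidate cut heights: midpoints between consecutive distinct node heights
# (tips at 0 included, so the deepest candidate yields all-singleton entities)
# plus the threshold-at-root boundary.
gmyc_threshold_candidates <- function(prep) {
  hh <- sort(unique(c(0, prep$h[(prep$ntip + 1L):(prep$ntip + prep$nnode)])))
  c((hh[-length(hh)] + hh[-1L]) / 2, prep$H)
}

#' Fit the single-threshold GMYC model
#'
#' Scans candidate thresholds at midpoints between consecutive distinct node
#' heights (plus the root boundary), maximizing the four rate/exponent
#' parameters at each candidate by bounded quasi-Newton optimization with
#' deterministic multi-starts, and returns the global optimum. The confidence
#' set collects entity counts of all candidates within 2 log-likelihood units
#' of the maximum.
#'
#' @param tree Ultrametric `phylo` object with at least 4 tips.
#' @param n_starts Number of optimizer starts per candidate (default 5).
#' @return A `cd_gmyc` fit with `model = "single"`, including the threshold
#'   profile (`profile`), the tip partition and the entity-count confidence
#'   set.
#' @export
fit_gmyc <- function(tree, n_starts = 5L) {
  prep <- gmyc_prep(tree)
  if (prep$ntip < 4L) stopf("need at least 4 tips for GMYC fitting")
  cand <- gmyc_threshold_candidates(prep)
  # scan from shallow to deep cuts so likelihood ties resolve to fewer entities
  cand <- sort(cand, decreasing = TRUE)
  prof <- data.frame(threshold = cand, n_entities = NA_integer_,
                     loglik = NA_real_)
  best <- NULL; best_i <- NA_integer_
  fits <- vector("list", length(cand))
  for (i in seq_along(cand)) {
    crowns <- cut_antichain(prep, cand[i])
    rows <- build_rows(prep, crowns)
    fit <- fit_rows(rows, n_starts)
    fits[[i]] <- list(crowns = crowns, fit = fit)
    prof$n_entities[i] <- length(crowns)
    prof$loglik[i] <- fit$loglik
    if (is.null(best) || fit$loglik > best$fit$loglik + 1e-9) {
      best <- fits[[i]]; best_i <- i
    }
  }
  conf <- sort(unique(prof$n_entities[prof$loglik >= max(prof$loglik) - 2]))
  out <- gmyc_fit_obj("single", prep, best$crowns, best$fit,
                      profile = prof, conf = conf,
                      extra = list(threshold = cand[best_i]))
  out
}

#' Fit the multiple-threshold GMYC model
#'
#' Greedy search over clade-local thresholds: starting from the best
#' single-threshold delimitation, repeatedly applies the clade-local threshold
#' change that most improves the log-likelihood. A change either lowers a
#' local threshold (splitting an entity at its crown node) or raises one
#' (merging two sibling entities into their parent clade). The search stops
#' when the best improvement drops below `1e-6`, or when `max_thresholds`
#' clade-local thresholds are in use. The result always satisfies
#' `logLik(multiple) >= logLik(single)`.
#'
#' @param tree Ultrametric `phylo` object with at least 4 tips.
#' @param max_thresholds Maximum number of clade-local thresholds (default 10).
#' @param n_starts Optimizer starts per candidate move (default 3).
#' @return A `cd_gmyc` fit with `model = "multiple"`.
#' @export
fit_gmyc_multiple <- function(tree, max_thresholds = 10L, n_starts = 3L) {
  prep <- gmyc_prep(tree)
  single <- fit_gmyc(tree)
  cur <- list(crowns = single$crowns,
              fit = list(loglik = single$loglik, params = single$params))
  n_thresholds <- 1L
  prof <- data.frame(n_entities = single$n_entities, loglik = single$loglik)
  children <- split(prep$edge[, 2L], prep$edge[, 1L])
  repeat {
    moves <- list()
    if (n_thresholds < max_thresholds) {
      for (v in cur$crowns[cur$crowns > prep$ntip]) {  # splits
        moves[[length(moves) + 1L]] <- list(
          crowns = c(setdiff(cur$crowns, v), children[[as.character(v)]]),
          dthresh = +1L)
      }
    }
    pa <- prep$parent[cur$crowns]
    for (p in unique(pa[duplicated(pa) & pa > 0L])) {  # sibling merges
      sibs <- cur$crowns[pa == p]
      moves[[length(moves) + 1L]] <- list(
        crowns = c(setdiff(cur$crowns, sibs), p), dthresh = -1L)
    }
    if (!length(moves)) break
    best_move <- NULL
    for (mv in moves) {
      fit <- fit_rows(build_rows(prep, mv$crowns), n_starts)
      if (is.null(best_move) || fit$loglik > best_move$fit$loglik) {
        best_move <- c(mv, list(fit = fit))
      }
    }
    if (is.null(best_move) ||
        best_move$fit$loglik <= cur$fit$loglik + 1e-6) break
    cur <- list(crowns = best_move$crowns, fit = best_move$fit)
    n_thresholds <- max(1L, n_thresholds + best_move$dthresh)
    prof <- rbind(prof, data.frame(n_entities = length(cur$crowns),
                                   loglik = cur$fit$loglik))
  }
  # refine the final state with the full multi-start budget
  cur$fit <- fit_rows(build_rows(prep, cur$crowns), 5L)
  conf <- sort(unique(prof$n_entities[prof$loglik >= max(prof$loglik) - 2]))
  gmyc_fit_obj("multiple", prep, cur$crowns, cur$fit, profile = prof,
               conf = conf, extra = list(n_thresholds = n_thresholds))
}

#' Fit the GMYC rate parameters for a fixed delimitation
#'
#' Maximizes the four rate/exponent parameters while holding the partition of
#' tips into entities fixed (each entity must be a clade). Useful for scoring
#' a hypothesized delimitation, e.g. the true partition of a simulation,
#' against fitted ones.
#'
#' @param tree Ultrametric `phylo` object.
#' @param partition Named vector mapping every tip label to an entity.
#' @return A `cd_gmyc` fit with `model = "multiple"` and `n_thresholds` set to
#'   the number of entities (upper bound on distinct local thresholds).
#' @export
fit_gmyc_partition <- function(tree, partition) {
  prep <- gmyc_prep(tree)
  if (!setequal(names(partition), prep$tips)) {
    stopf("partition must cover exactly the tree's tips")
  }
  crowns <- vapply(split(names(partition), partition), function(tips) {
    if (length(tips) == 1L) return(match(tips, prep$tips))
    mrca <- ape::getMRCA(prep$tree, tips)
    if (length(tip_descendants(prep, mrca)) != length(tips)) {
      stopf("entities must be clades: {%s} is not monophyletic",
            paste(tips, collapse = ", "))
    }
    mrca
  }, integer(1L))
  fit <- fit_rows(build_rows(prep, crowns), 5L)
  gmyc_fit_obj("multiple", prep, crowns, fit, profile = NULL, conf = NULL,
               extra = list(n_thresholds = length(crowns)))
}

#' Likelihood ratio test of a GMYC fit against the one-class null
#'
#' `LR = 2 (logLik(model) - logLik(null))`, referred to a chi-square with
#' degrees of freedom equal to the difference in free parameter counts
#' (3 for the single-threshold model; `2 + n_thresholds` for the multiple-
#' threshold model). A negative LR (optimizer failure on nested models) is
#' clamped to zero with a warning and flagged.
#'
#' @param null A `cd_gmyc` null fit (or any fit with smaller parameter count).
#' @param model A `cd_gmyc` threshold-model fit on the same tree.
#' @return List of class `cd_lrt`: `L_null`, `L_model`, `LR`, `df`, `p`,
#'   `significance` (stars at 0.05/0.01/0.001), `clamped`.
#' @export
likelihood_ratio_test <- function(null, model) {
  L0 <- if (inherits(null, "cd_gmyc")) null$loglik else as.numeric(null)
  L1 <- if (inherits(model, "cd_gmyc")) model$loglik else as.numeric(model)
  df <- if (inherits(model, "cd_gmyc") && inherits(null, "cd_gmyc")) {
    model$n_free - null$n_free
  } else 3L
  LR <- 2 * (L1 - L0)
  clamped <- FALSE
  if (LR < 0) {
    warnf("model log-likelihood below null (LR = %.3g); clamping to 0", LR)
    LR <- 0; clamped <- TRUE
  }
  p <- pchisq(LR, df = df, lower.tail = FALSE)
  structure(list(L_null = L0, L_model = L1, LR = LR, df = df, p = p,
                 significance = signif_stars(p), clamped = clamped),
            class = "cd_lrt")
}

#' @export
print.cd_lrt <- function(x, ...) {
  cat(sprintf("LR = %.5f (df = %d), p = %.4g %s\n",
              x$LR, x$df, x$p, x$significance))
  invisible(x)
}
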