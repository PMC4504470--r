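#' Node heights of an ultrametric tree
#'
#' Heights follow the time-before-present convention: tips sit at height 0 and
#' the root at the tree height. This is the scale on which GMYC thresholds
#' live.
#'
#' @param tree An ultrametric `phylo` object.
#' @return Numeric vector of length `n_tips + n_internal`, indexed like
#'   `ape`'s node numbering (tips first).
#' @export
node_heights <- function(tree) {
  depth <- ape::node.depth.edgelength(tree)
  h <- max(depth[seq_len(ape::Ntip(tree))]) - depth
  # clamp tiny negative round-off at the tips
  h[abs(h) < .Machine$double.eps * 1e3] <- 0
  h
}

#' Test whether a tree is ultrametric within a relative tolerance
#'
#' @param tree A `phylo` object.
#' @param tol Maximum spread of root-to-tip path lengths relative to tree
#'   height (default `1e-6`).
#' @return Logical scalar.
#' @export
is_ultrametric_tree <- function(tree, tol = 1e-6) {
  depth <- ape::node.depth.edgelength(tree)[seq_len(ape::Ntip(tree))]
  H <- max(depth)
  if (H <= 0) return(FALSE)
  (max(depth) - min(depth)) / H <= tol
}

assert_ultrametric <- function(tree, tol = 1e-6, what = "tree") {
  if (!is_ultrametric_tree(tree, tol)) {
    stopf("%s is not ultrametric within relative tolerance %g", what, tol)
  }
  invisible(tree)
}

#' Indices retained after burn-in and thinning
#'
#' Discards the first `floor(burnin_frac * n)` samples and keeps every
#' `thin`-th of the remainder, starting with the first survivor.
#'
#' @param n Number of samples in the chain.
#' @param burnin_frac Proportion in `[0, 1)` discarded from the start.
#' @param thin Keep every `thin`-th sample (integer `>= 1`).
#' @return Integer vector of retained indices.
#' @export
retained_indices <- function(n, burnin_frac = 0, thin = 1L) {
  stopifnot(n >= 0, burnin_frac >= 0, burnin_frac < 1, thin >= 1)
  drop <- floor(burnin_frac * n)
  if (drop >= n) return(integer(0))
  seq.int(drop + 1L, n, by = as.integer(thin))
}

#' Posterior-style sample of ultrametric trees
#'
#' @param trees List of `phylo` objects over an identical tip set.
#' @param provenance Optional list recording burn-in/thinning applied.
#' @param tol Ultrametricity tolerance passed to [is_ultrametric_tree()].
#' @return A `cd_treesample` object (list with `trees` and `provenance`).
#' @export
tree_sample <- function(trees, provenance = list(), tol = 1e-6) {
  if (length(trees) == 0L) stopf("tree sample is empty")
  tips <- sort(trees[[1L]]$tip.label)
  for (i in seq_along(trees)) {
    if (!identical(sort(trees[[i]]$tip.label), tips)) {
      stopf("tree %d has a different tip set", i)
    }
    if (!is_ultrametric_tree(trees[[i]], tol)) {
      stopf("tree %d is not ultrametric within relative tolerance %g", i, tol)
    }
  }
  structure(list(trees = trees, provenance = provenance),
            class = "cd_treesample")
}

#' @export
print.cd_treesample <- function(x, ...) {
  cat(sprintf("Tree sample: %d trees, %d tips\n",
              length(x$trees), ape::Ntip(x$trees[[1L]])))
  invisible(x)
}

#' @export
length.cd_treesample <- function(x) length(x$trees)

#' Read a posterior tree sample from NEXUS or Newick
#'
#' NEXUS translate tables, `tree STATE_x = ...` labels and square-bracket
#' comments are handled by the `ape` readers. Burn-in and thinning are applied
#' before the ultrametricity check so only retained trees must validate.
#'
#' @param path Path to a multi-tree NEXUS or Newick file.
#' @param burnin_frac Proportion of initial trees discarded (default 0).
#' @param thin Keep every `thin`-th remaining tree (default 1).
#' @param tol Ultrametricity tolerance (relative; default `1e-6`).
#' @return A [tree_sample()] object.
#' @export
read_tree_sample <- function(path, burnin_frac = 0, thin = 1L, tol = 1e-6) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  first <- readLines(path, n = 1L)
  trees <- if (grepl("^\\s*#NEXUS", first, ignore.case = TRUE)) {
    ape::read.nexus(path)
  } else {
    ape::read.tree(path)
  }
  if (inherits(trees, "phylo")) trees <- list(trees)
  if (!is.null(attr(trees, "TipLabel"))) {
    trees <- ape::.uncompressTipLabel(trees)  # translate-table storage
  }
  trees <- unclass(trees)
  attr(trees, "TipLabel") <- NULL
  keep <- retained_indices(length(trees), burnin_frac, thin)
  if (length(keep) == 0L) stopf("no trees retained from %s", path)
  tree_sample(trees[keep],
              provenance = list(path = path, n_read = length(trees),
                                burnin_frac = burnin_frac, thin = thin),
              tol = tol)
}

#' Write a tree sample as multi-line Newick
#'
#' @param ts A [tree_sample()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tree_sample <- function(ts, path) {
  stopifnot(inherits(ts, "cd_treesample"))
  writeLines(vapply(ts$trees, ape::write.tree, character(1L)), path)
  invisible(path)
}
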