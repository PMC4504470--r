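## Statistical-parsimony haplotype networks: mutational step matrix over a
## five-state alphabet (gaps as the fifth character), a probabilistic
## connection limit, and agglomerative network construction.

#' Pairwise mutational steps between haplotypes
#'
#' Counts, per aligned column, one step for each difference over the
#' five-state alphabet `{A, C, G, T, gap}` when `gap_as_fifth = TRUE`; with
#' the flag off, positions where either sequence carries a gap are skipped for
#' that pair. Ambiguity codes count as a step only when the IUPAC state sets
#' are disjoint.
#'
#' @param haps A `cd_haplotypes` object from [collapse_haplotypes()], or a
#'   named character vector of equal-length aligned sequences.
#' @param gap_as_fifth Read gaps as an informative fifth state (default
#'   `TRUE`).
#' @return Symmetric integer matrix of mutational steps.
#' @export
pairwise_steps <- function(haps, gap_as_fifth = TRUE) {
  seqs <- if (inherits(haps, "cd_haplotypes")) {
    setNames(haps$haplotypes$sequence, haps$haplotypes$id)
  } else haps
  seqs <- toupper(seqs)
  if (length(unique(nchar(seqs))) != 1L) stopf("sequences are not aligned")
  n <- length(seqs)
  chars <- lapply(seqs, function(s) strsplit(s, "")[[1L]])
  S <- matrix(0L, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      a <- chars[[i]]; b <- chars[[j]]
      use <- if (gap_as_fifth) rep(TRUE, length(a)) else a != "-" & b != "-"
      diffpos <- which(use & a != b)
      steps <- sum(vapply(diffpos,
                          function(p) !iupac_compatible(a[p], b[p]),
                          logical(1L)))
      S[i, j] <- S[j, i] <- as.integer(steps)
    }
  }
  S
}

#' Statistical-parsimony connection limit
#'
#' Returns the largest number of mutational steps `j*` for which the
#' probability of a parsimonious connection is at least `prob`. The default
#' estimator treats the `j` mutations separating two haplotypes as uniform
#' draws over the `seq_len` sites and takes the probability that all hit
#' distinct sites, `P_j = prod_{i=1}^{j-1} (1 - i/seq_len)`; superimposed
#' changes are what break parsimony. The estimator is pluggable and a fixed
#' limit can be given as `"fixed:N"` for bit-reproducible runs.
#'
#' @param seq_len Number of aligned sites.
#' @param prob Required probability of parsimony (default 0.95).
#' @param estimator `"uniform"` (default), or `"fixed:N"`.
#' @return Integer step limit `j* >= 1`.
#' @export
connection_limit <- function(seq_len, prob = 0.95, estimator = "uniform") {
  if (grepl("^fixed:", estimator)) {
    return(as.integer(sub("^fixed:", "", estimator)))
  }
  stopifnot(seq_len >= 1, prob > 0, prob < 1)
  p <- 1
  j <- 1L
  repeat {
    p_next <- p * (1 - j / seq_len)   # P_{j+1} = P_j * (1 - j/L)
    if (p_next < prob || j >= seq_len) break
    p <- p_next
    j <- j + 1L
  }
  j
}

#' Build a statistical-parsimony haplotype network
#'
#' Agglomerative construction: haplotype pairs are processed in increasing
#' step order and a connection is recorded whenever the pair distance does not
#' exceed the limit and the pair joins two different components
#' (`distance - 1` inferred intermediate nodes are inserted along the new
#' path). Pairs at the same distance that would re-join components already
#' connected within that distance tier are also recorded, flagged ambiguous
#' (loops). Components never merge above the limit and become the subnetworks.
#'
#' @param steps Symmetric step matrix from [pairwise_steps()].
#' @param limit Maximum connectable steps, e.g. from [connection_limit()].
#' @param freq Optional haplotype sample counts (node annotation).
#' @return List of class `cd_parsnet`: `nodes` (data frame: id, inferred,
#'   size), `edges` (unit-step edge list over observed and inferred nodes),
#'   `connections` (haplotype-level links: from, to, steps, ambiguous),
#'   `subnetwork` (component id per observed haplotype), `limit`.
#' @export
build_network <- function(steps, limit, freq = NULL) {
  S <- as.matrix(steps)
  n <- nrow(S)
  if (n == 0L) stopf("empty step matrix")
  check_dissimilarity(S)
  ids <- rownames(S) %||% paste0("H", seq_len(n))
  comp <- seq_len(n)
  pairs <- which(upper.tri(S), arr.ind = TRUE)
  pairs <- pairs[order(S[pairs], pairs[, 1L], pairs[, 2L]), , drop = FALSE]
  conn <- list()
  for (d in sort(unique(S[pairs]))) {
    if (d > limit) break
    if (d == 0) next
    tier <- pairs[S[pairs] == d, , drop = FALSE]
    comp_at_tier <- comp  # ambiguity judged against the pre-tier components
    for (r in seq_len(nrow(tier))) {
      i <- tier[r, 1L]; j <- tier[r, 2L]
      if (comp_at_tier[i] == comp_at_tier[j]) next  # was joined at an earlier tier
      ambiguous <- comp[i] == comp[j]               # joined within this tier: loop
      conn[[length(conn) + 1L]] <- data.frame(
        from = ids[i], to = ids[j], steps = d, ambiguous = ambiguous,
        stringsAsFactors = FALSE)
      if (!ambiguous) comp[comp == comp[j]] <- comp[i]
    }
  }
  connections <- if (length(conn)) do.call(rbind, conn) else
    data.frame(from = character(0), to = character(0),
               steps = integer(0), ambiguous = logical(0))
  # expand connections into unit-step edges through inferred intermediates
  nodes <- data.frame(id = ids, inferred = FALSE,
                      size = if (is.null(freq)) rep(NA_integer_, n) else
                        as.integer(freq[ids]),
                      stringsAsFactors = FALSE)
  edges <- list()
  m <- 0L
  for (r in seq_len(nrow(connections))) {
    d <- connections$steps[r]
    path <- connections$from[r]
    if (d > 1L) {
      inter <- paste0("med", m + seq_len(d - 1L))
      m <- m + d - 1L
      nodes <- rbind(nodes, data.frame(id = inter, inferred = TRUE,
                                       size = 0L, stringsAsFactors = FALSE))
      path <- c(path, inter)
    }
    path <- c(path, connections$to[r])
    edges[[r]] <- data.frame(from = path[-length(path)], to = path[-1L],
                             steps = 1L, connection = r,
                             stringsAsFactors = FALSE)
  }
  edges <- if (length(edges)) do.call(rbind, edges) else
    data.frame(from = character(0), to = character(0),
               steps = integer(0), connection = integer(0))
  sub <- match(comp, unique(comp))
  structure(list(nodes = nodes, edges = edges, connections = connections,
                 subnetwork = setNames(sub, ids), limit = limit),
            class = "cd_parsnet")
}

#' @export
print.cd_parsnet <- function(x, ...) {
  cat(sprintf("Parsimony network: %d haplotypes, %d subnetworks (limit %d steps)\n",
              sum(!x$nodes$inferred), max(x$subnetwork), x$limit))
  invisible(x)
}

#' Write a parsimony network to GraphML and a TSV edge list
#'
#' Nodes carry the haplotype id, sample size and inferred/observed flag; edges
#' carry their step count and subnetwork id. The TSV edge list round-trips
#' through [read_network_edges()].
#'
#' @param net A `cd_parsnet` object.
#' @param path Base path; `.graphml` and `.tsv` files are written.
#' @return Named character vector of the two paths written, invisibly.
#' @export
write_network <- function(net, path) {
  stopifnot(inherits(net, "cd_parsnet"))
  base <- sub("\\.(graphml|tsv)$", "", path)
  g <- igraph::graph_from_data_frame(
    net$edges[, c("from", "to", "steps", "connection")],
    directed = FALSE, vertices = net$nodes)
  sub_of <- function(id) {
    obs <- id %in% names(net$subnetwork)
    out <- rep(NA_integer_, length(id))
    out[obs] <- net$subnetwork[id[obs]]
    out
  }
  conn <- net$connections
  conn$subnetwork <- sub_of(conn$from)
  graphml <- paste0(base, ".graphml")
  tsv <- paste0(base, ".tsv")
  igraph::write_graph(g, graphml, format = "graphml")
  write.table(conn, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(graphml = graphml, tsv = tsv))
}

#' Read back a network edge list written by [write_network()]
#'
#' @param path Path to the TSV edge list.
#' @return Data frame with `from`, `to`, `steps`, `ambiguous`, `subnetwork`.
#' @export
read_network_edges <- function(path) {
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  df$steps <- as.integer(df$steps)
  df$ambiguous <- as.logical(df$ambiguous)
  df
}
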