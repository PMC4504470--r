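## Haplotype collapsing and per-group genetic diversity statistics.

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T", U = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"), "?" = c("A", "C", "G", "T", "-"),
  "-" = "-"
)

iupac_compatible <- function(a, b) {
  length(intersect(IUPAC_SETS[[a]], IUPAC_SETS[[b]])) > 0L
}

seqs_compatible <- function(s1, s2) {
  c1 <- strsplit(s1, "")[[1L]]; c2 <- strsplit(s2, "")[[1L]]
  all(mapply(iupac_compatible, c1, c2))
}

is_unambiguous <- function(s) !grepl("[^ACGT-]", s)

#' Collapse an alignment into haplotypes
#'
#' In `exact` mode sequences are grouped when byte-identical (gap characters
#' included). In `ambiguity-aware` mode a sequence additionally joins an
#' existing haplotype when every site is compatible under the IUPAC codes and
#' the haplotype has at least one fully unambiguous member. Haplotypes are
#' numbered by first occurrence.
#'
#' @param aln A [alignment()] object.
#' @param mode `"exact"` (default) or `"ambiguity"`.
#' @return List of class `cd_haplotypes`: `haplotypes` (data frame: id,
#'   sequence, size), `members` (list of member id vectors), `assignment`
#'   (sequence id -> haplotype id).
#' @export
collapse_haplotypes <- function(aln, mode = c("exact", "ambiguity")) {
  stopifnot(inherits(aln, "cd_alignment"))
  mode <- match.arg(mode)
  if (length(aln$ids) == 0L) stopf("empty alignment")
  reps <- character(0)          # representative sequence per haplotype
  members <- list()
  unamb <- logical(0)           # does the haplotype have an unambiguous member
  assign <- integer(length(aln$ids))
  for (i in seq_along(aln$ids)) {
    s <- aln$seqs[[i]]
    hit <- which(reps == s)
    if (!length(hit) && mode == "ambiguity") {
      for (h in seq_along(reps)) {
        if ((unamb[h] || is_unambiguous(s)) && seqs_compatible(s, reps[h])) {
          hit <- h
          break
        }
      }
    }
    if (length(hit)) {
      h <- hit[1L]
      members[[h]] <- c(members[[h]], aln$ids[i])
      if (!unamb[h] && is_unambiguous(s)) {
        unamb[h] <- TRUE
        reps[h] <- s  # prefer an unambiguous representative
      }
    } else {
      reps <- c(reps, s)
      members[[length(reps)]] <- aln$ids[i]
      unamb[length(reps)] <- is_unambiguous(s)
      h <- length(reps)
    }
    assign[i] <- h
  }
  ids <- paste0("H", seq_along(reps))
  structure(list(
    haplotypes = data.frame(id = ids, sequence = reps,
                            size = lengths(members), stringsAsFactors = FALSE),
    members = setNames(members, ids),
    assignment = setNames(ids[assign], aln$ids)),
    class = "cd_haplotypes")
}

#' @export
print.cd_haplotypes <- function(x, ...) {
  cat(sprintf("%d haplotypes from %d sequences\n",
              nrow(x$haplotypes), sum(x$haplotypes$size)))
  invisible(x)
}

# Columns retained under the site-deletion policy: complete deletion drops
# any column containing a gap or an ambiguity code.
retained_columns <- function(aln) {
  m <- aln_matrix(aln)
  which(apply(m, 1L, function(col) all(col %in% c("A", "C", "G", "T"))))
}

#' Number of segregating (polymorphic) sites
#'
#' Counts alignment columns with more than one nucleotide state. Under the
#' default complete-deletion policy, columns containing a gap or an ambiguity
#' code are excluded before counting.
#'
#' @param aln A [alignment()] object.
#' @param deletion `"complete"` (default) or `"none"` (count states among
#'   unambiguous bases in every column).
#' @return Integer count `S`.
#' @export
segregating_sites <- function(aln, deletion = c("complete", "none")) {
  deletion <- match.arg(deletion)
  m <- aln_matrix(aln)
  cols <- if (deletion == "complete") retained_columns(aln) else seq_len(aln$length)
  if (!length(cols)) return(0L)
  poly <- vapply(cols, function(j) {
    st <- unique(m[j, ])
    length(intersect(st, c("A", "C", "G", "T"))) >= 2L
  }, logical(1L))
  sum(poly)
}

#' Haplotype diversity and its standard deviation
#'
#' `Hd = n/(n-1) * (1 - sum p_h^2)`: the probability that two haplotypes drawn
#' at random from the sample differ. The standard deviation is the square root
#' of the sampling variance
#' `V = 2/(n(n-1)) * (2(n-2) (sum p^3 - (sum p^2)^2) + sum p^2 - (sum p^2)^2)`.
#'
#' @param counts Haplotype counts (or frequencies summing to 1 when `n` is
#'   given separately).
#' @param n Sample size (default `sum(counts)`).
#' @return List with `Hd` and `sd`.
#' @export
haplotype_diversity <- function(counts, n = NULL) {
  if (is.null(n)) {
    n <- sum(counts)
    p <- counts / n
  } else {
    p <- counts / sum(counts)
  }
  if (n < 2) stopf("haplotype diversity needs at least 2 sequences")
  s2 <- sum(p^2); s3 <- sum(p^3)
  Hd <- n / (n - 1) * (1 - s2)
  V <- 2 / (n * (n - 1)) * (2 * (n - 2) * (s3 - s2^2) + s2 - s2^2)
  list(Hd = Hd, sd = sqrt(max(V, 0)))
}

#' Nucleotide diversity
#'
#' `pi = mean over sequence pairs of the proportion of differing sites`, the
#' per-site probability that two randomly drawn sequences differ. Sites are
#' first filtered by the deletion policy: `"complete"` drops any column with a
#' gap or ambiguity; `"pairwise"` compares, for each pair, only the sites
#' where both sequences carry an unambiguous base.
#'
#' @param aln A [alignment()] object with at least 2 sequences.
#' @param deletion `"complete"` (default) or `"pairwise"`.
#' @return Numeric `pi` (per site).
#' @export
nucleotide_diversity <- function(aln, deletion = c("complete", "pairwise")) {
  deletion <- match.arg(deletion)
  n <- length(aln$ids)
  if (n < 2L) stopf("nucleotide diversity needs at least 2 sequences")
  m <- aln_matrix(aln)
  if (deletion == "complete") {
    cols <- retained_columns(aln)
    if (!length(cols)) stopf("no sites retained under complete deletion")
    m <- m[cols, , drop = FALSE]
    d <- combn(n, 2L, function(ij) mean(m[, ij[1L]] != m[, ij[2L]]))
  } else {
    d <- combn(n, 2L, function(ij) {
      ok <- m[, ij[1L]] %in% c("A", "C", "G", "T") &
            m[, ij[2L]] %in% c("A", "C", "G", "T")
      if (!any(ok)) stopf("no sites retained for a pair under pairwise deletion")
      mean(m[ok, ij[1L]] != m[ok, ij[2L]])
    })
  }
  mean(d)
}

#' Per-group genetic diversity table
#'
#' Computes, for each group of sequences, the sample size, haplotype count,
#' segregating sites, haplotype diversity with standard deviation and
#' nucleotide diversity. Groups below the minimum sample size are reported
#' with `NA` statistics, mirroring the rule of evaluating a region only when
#' more than 9 sequences are available.
#'
#' @param aln A [alignment()] object.
#' @param groups Named character/factor vector mapping sequence ids to groups.
#' @param min_n Minimum sequences per evaluated group (default 10).
#' @return Data frame with one row per group: `group`, `n_seq`, `n_hap`, `S`,
#'   `Hd`, `Hd_sd`, `pi`.
#' @export
diversity_table <- function(aln, groups, min_n = 10L) {
  stopifnot(inherits(aln, "cd_alignment"))
  if (is.null(names(groups))) stopf("groups must be named by sequence id")
  miss <- setdiff(aln$ids, names(groups))
  if (length(miss)) stopf("no group for sequence(s): %s", paste(miss, collapse = ", "))
  out <- lapply(sort(unique(as.character(groups[aln$ids]))), function(g) {
    ids <- aln$ids[as.character(groups[aln$ids]) == g]
    sub <- alignment(aln$seqs[ids])
    haps <- collapse_haplotypes(sub)
    row <- data.frame(group = g, n_seq = length(ids),
                      n_hap = nrow(haps$haplotypes),
                      S = NA_integer_, Hd = NA_real_, Hd_sd = NA_real_,
                      pi = NA_real_, stringsAsFactors = FALSE)
    if (length(ids) >= min_n) {
      hd <- haplotype_diversity(haps$haplotypes$size)
      row$S <- segregating_sites(sub)
      row$Hd <- hd$Hd; row$Hd_sd <- hd$sd
      row$pi <- nucleotide_diversity(sub)
    }
    row
  })
  do.call(rbind, out)
}
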