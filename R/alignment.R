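#' Multiple sequence alignment container
#'
#' A light container for an aligned set of sequences over the DNA alphabet
#' plus gaps and IUPAC ambiguity codes. All sequences must have equal length
#' and unique identifiers; sequences are stored uppercased.
#'
#' @param seqs Named character vector of equal-length aligned sequences.
#' @return An object of class `cd_alignment` with elements `ids`, `seqs`
#'   (named, uppercased) and `length` (number of sites).
#' @export
alignment <- function(seqs) {
  if (length(seqs) == 0L) stopf("alignment is empty")
  ids <- names(seqs)
  if (is.null(ids) || any(!nzchar(ids))) stopf("all sequences must be named")
  if (anyDuplicated(ids)) {
    stopf("duplicate sequence id: %s", ids[duplicated(ids)][1L])
  }
  seqs <- toupper(seqs)
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L) {
    bad <- ids[lens != lens[1L]][1L]
    stopf("ragged alignment: sequence '%s' has length %d, expected %d",
          bad, nchar(seqs[[bad]]), lens[1L])
  }
  if (lens[1L] == 0L) stopf("alignment has zero sites")
  allowed <- c("A", "C", "G", "T", "U", "N", "-", "?",
               "R", "Y", "S", "W", "K", "M", "B", "D", "H", "V")
  chars <- unique(strsplit(paste(seqs, collapse = ""), "")[[1L]])
  if (length(setdiff(chars, allowed))) {
    stopf("invalid character(s) in alignment: %s",
          paste(setdiff(chars, allowed), collapse = ", "))
  }
  structure(list(ids = ids, seqs = seqs, length = unname(lens[1L])),
            class = "cd_alignment")
}

#' Read an aligned FASTA file
#'
#' @param path Path to a FASTA file of aligned sequences.
#' @return A [alignment()] object preserving input record order.
#' @export
read_alignment <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stopf("no FASTA records in %s", path)
  seqs <- as.character(set)
  # FASTA headers may carry descriptions after whitespace; keep the first word
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  alignment(seqs)
}

#' Write an alignment to FASTA
#'
#' @param aln A [alignment()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path) {
  stopifnot(inherits(aln, "cd_alignment"))
  writeLines(paste0(">", aln$ids, "\n", aln$seqs), path)
  invisible(path)
}

#' @export
print.cd_alignment <- function(x, ...) {
  cat(sprintf("Alignment: %d sequences x %d sites\n", length(x$ids), x$length))
  invisible(x)
}

# sites x sequences character matrix view
aln_matrix <- function(aln) {
  m <- vapply(aln$seqs, function(s) strsplit(s, "")[[1L]],
              character(aln$length))
  if (aln$length == 1L) m <- matrix(m, nrow = 1L, dimnames = list(NULL, aln$ids))
  m
}
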