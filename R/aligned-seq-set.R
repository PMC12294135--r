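#' Construct an aligned sequence set
#'
#' An `aligned_seq_set` holds equal-length gapped nucleotide sequences with a
#' group label per record (e.g. the color morph each individual belongs to)
#' and a marker name (e.g. `"COI"` or `"ITS1"`). The allowed alphabet is
#' `A, C, G, T, -, N`; lowercase input is uppercased.
#'
#' @param ids character vector of record identifiers (unique, non-empty).
#' @param groups character vector of group labels, one per record.
#' @param seqs character vector of aligned sequences, all of equal length.
#' @param marker single string naming the marker.
#' @return An object of class `aligned_seq_set`: a list with elements
#'   `ids`, `groups`, `seqs` and `marker`.
#' @examples
#' aligned_seq_set(c("r1", "g1"), c("red", "green"), c("ACGT", "ACGA"), "COI")
#' @export
aligned_seq_set <- function(ids, groups, seqs, marker = "marker") {
  ids <- as.character(ids)
  groups <- as.character(groups)
  seqs <- toupper(as.character(seqs))
  if (length(ids) < 1L)
    stop("aligned_seq_set needs at least one record")
  if (length(groups) != length(ids) || length(seqs) != length(ids))
    stop("ids, groups and seqs must have equal length")
  if (anyDuplicated(ids))
    stop("duplicate record ids: ", paste(ids[duplicated(ids)], collapse = ", "))
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L) {
    off <- ids[lens != stats::median(lens)]
    stop("alignment error: unequal sequence lengths for ids: ",
         paste(off, collapse = ", "))
  }
  if (lens[1L] < 1L)
    stop("alignment error: zero-length sequences")
  bad <- regexpr("[^ACGTN-]", seqs)
  if (any(bad > 0L)) {
    i <- which(bad > 0L)[1L]
    stop(sprintf("alphabet error: illegal character '%s' in '%s' at position %d",
                 substr(seqs[i], bad[i], bad[i]), ids[i], bad[i]))
  }
  structure(list(ids = ids, groups = groups, seqs = seqs,
                 marker = as.character(marker)[1L]),
            class = "aligned_seq_set")
}

#' @export
print.aligned_seq_set <- function(x, ...) {
  cat(sprintf("Aligned sequence set '%s': %d records x %d columns\n",
              x$marker, length(x$ids), nchar(x$seqs[1L])))
  tab <- table(x$groups)
  cat("  groups:", paste(sprintf("%s (n=%d)", names(tab), tab), collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
length.aligned_seq_set <- function(x) length(x$ids)

# character matrix view, records x columns
seq_matrix <- function(s) {
  m <- do.call(rbind, strsplit(s$seqs, "", fixed = TRUE))
  rownames(m) <- s$ids
  m
}

# subset records by index or id, keeping class invariants
seq_subset <- function(s, i) {
  if (is.character(i)) i <- match(i, s$ids)
  aligned_seq_set(s$ids[i], s$groups[i], s$seqs[i], s$marker)
}

#' Majority-rule consensus sequence of an aligned set
#'
#' Per column, the most frequent unambiguous base; gaps and `N` win a column
#' only when no unambiguous base is present there. Ties are broken
#' alphabetically for determinism.
#'
#' @param s an [aligned_seq_set()].
#' @return Single consensus sequence string.
#' @export
consensus_sequence <- function(s) {
  m <- seq_matrix(s)
  cons <- apply(m, 2L, function(col) {
    col2 <- col[!col %in% c("-", "N")]
    if (length(col2) == 0L) return("-")
    tab <- table(col2)
    names(tab)[which.max(tab)][1L]  # which.max takes first = alphabetical
  })
  paste(cons, collapse = "")
}
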