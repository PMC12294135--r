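# Canonical trait column order shared by reader, writer and simulator.
TRAIT_COLS <- c("CL", "CW", "CH", "BW", "FOMW", "FFLC", "MLC", "PW", "ST")
META_COLS <- c("individual_id", "sex", "morph")

#' Read a morphometric trait table from CSV
#'
#' Expects a UTF-8 CSV whose header names the metadata columns
#' `individual_id`, `sex` (M/F), `morph` (red/green) and the nine
#' measurements `CL, CW, CH, BW, FOMW, FFLC, MLC, PW, ST` (lengths in mm,
#' body weight `BW` in g). Unknown columns are preserved untouched.
#'
#' @param path path to the CSV file.
#' @return A `trait_table`: a data.frame with the mandatory columns
#'   validated (unique ids, closed sex/morph vocabularies, `CW > 0`).
#' @seealso [write_trait_csv()], [compute_ratios()]
#' @export
read_trait_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  as_trait_table(df)
}

#' Validate a data.frame as a trait table
#'
#' @param df data.frame with the mandatory trait-table columns.
#' @return The validated `trait_table`.
#' @export
as_trait_table <- function(df) {
  missing <- setdiff(c(META_COLS, TRAIT_COLS), names(df))
  if (length(missing))
    stop("format error: missing mandatory column(s): ",
         paste(missing, collapse = ", "))
  for (col in TRAIT_COLS) {
    v <- df[[col]]
    if (!is.numeric(v)) {
      suppressWarnings(num <- as.numeric(v))
      if (anyNA(num) && !anyNA(v))
        stop(sprintf("row-level error: non-numeric value in column %s at row %d",
                     col, which(is.na(num))[1L]))
      df[[col]] <- num
    }
  }
  df$individual_id <- as.character(df$individual_id)
  if (anyDuplicated(df$individual_id))
    stop("duplicate individual_id: ",
         paste(unique(df$individual_id[duplicated(df$individual_id)]),
               collapse = ", "))
  if (!all(df$sex %in% c("M", "F")))
    stop("sex must be 'M' or 'F'")
  if (!all(df$morph %in% c("red", "green")))
    stop("morph must be 'red' or 'green'")
  if (any(!is.finite(df$CW)) || any(df$CW <= 0))
    stop("CW must be positive for every individual; offending id: ",
         df$individual_id[which(!(df$CW > 0))[1L]])
  extras <- setdiff(names(df), c(META_COLS, TRAIT_COLS))
  df <- df[, c(META_COLS, TRAIT_COLS, extras), drop = FALSE]
  class(df) <- c("trait_table", "data.frame")
  df
}

#' Write a trait table to canonical CSV
#'
#' Columns are emitted in canonical order (metadata, the nine traits, then
#' any extras); decimal separator is always a dot. Reading the file back
#' with [read_trait_csv()] and writing it again is byte-stable.
#'
#' @param t a `trait_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trait_csv <- function(t, path) {
  utils::write.csv(as.data.frame(t), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an aligned FASTA file with group labels
#'
#' Headers carry the group label after a delimiter, `>id|group` by default.
#' All sequences must have equal aligned length over the alphabet
#' `A, C, G, T, -, N` (lowercase accepted and uppercased).
#'
#' @param path path to the FASTA file.
#' @param delim single character separating id and group in the header.
#' @param marker marker name stored on the returned set; defaults to the
#'   file name without extension.
#' @return An [aligned_seq_set()].
#' @export
read_fasta_aligned <- function(path, delim = "|", marker = NULL) {
  recs <- seqinr::read.fasta(path, as.string = TRUE, forceDNAtolower = FALSE,
                             whole.header = TRUE)
  headers <- vapply(recs, function(r) attr(r, "name"), character(1L))
  seqs <- vapply(recs, function(r) as.character(r)[1L], character(1L))
  parts <- strsplit(headers, delim, fixed = TRUE)
  ids <- vapply(parts, `[`, character(1L), 1L)
  groups <- vapply(parts, function(p) if (length(p) >= 2L) p[2L] else "", character(1L))
  if (is.null(marker))
    marker <- tools::file_path_sans_ext(basename(path))
  aligned_seq_set(ids, groups, seqs, marker)
}

#' Write an aligned sequence set to FASTA
#'
#' @param s an [aligned_seq_set()].
#' @param path output path.
#' @param delim delimiter placed between id and group in the header.
#' @return `path`, invisibly.
#' @export
write_fasta_aligned <- function(s, path, delim = "|") {
  headers <- ifelse(s$groups == "", s$ids, paste(s$ids, s$groups, sep = delim))
  seqinr::write.fasta(as.list(s$seqs), names = headers, file.out = path,
                      nbchar = 80)
  invisible(path)
}

#' Write a phylogenetic tree as Newick
#'
#' Branch lengths are printed with a fixed number of decimal places so the
#' output is byte-stable. Leaf labels containing Newick metacharacters
#' (`(),:;`, quotes or whitespace) raise an error rather than being quoted
#' silently.
#'
#' @param tree an object of class `phylo` (as returned by [nj_build()] or
#'   [upgma_build()]).
#' @param path output path.
#' @param digits decimal places for branch lengths (default 6).
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path, digits = 6) {
  stopifnot(inherits(tree, "phylo"))
  labs <- tree$tip.label
  bad <- grepl("[][(),:;'\"[:space:]]", labs)
  if (any(bad))
    stop("label error: Newick metacharacters in leaf label(s): ",
         paste(labs[bad], collapse = ", "))
  writeLines(newick_string(tree, digits), path)
  invisible(path)
}

# Recursive Newick serialization of an ape phylo object with fixed-width
# branch lengths.
newick_string <- function(tree, digits = 6) {
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L
  kids <- split(seq_len(nrow(tree$edge)), tree$edge[, 1L])
  fmt <- paste0("%.", digits, "f")
  rec <- function(node) {
    rows <- kids[[as.character(node)]]
    if (is.null(rows)) return(tree$tip.label[node])
    inner <- vapply(rows, function(e) {
      child <- tree$edge[e, 2L]
      paste0(rec(child), ":", sprintf(fmt, tree$edge.length[e]))
    }, character(1L))
    paste0("(", paste(inner, collapse = ","), ")")
  }
  paste0(rec(root), ";")
}

#' Write a distance matrix in square PHYLIP format
#'
#' First line holds the number of taxa; each following line holds the label
#' and its full row of distances.
#'
#' @param dm a [distance_matrix()] object or plain symmetric matrix with
#'   dimnames.
#' @param path output path.
#' @param digits decimal places (default 6).
#' @return `path`, invisibly.
#' @export
write_distance_matrix <- function(dm, path, digits = 6) {
  d <- if (inherits(dm, "distance_matrix")) dm$d else as.matrix(dm)
  labels <- rownames(d)
  if (!isSymmetric(unname(d), tol = 1e-9))
    stop("matrix error: distance matrix must be symmetric")
  fmt <- paste0("%.", digits, "f")
  lines <- c(format(nrow(d)),
             vapply(seq_len(nrow(d)), function(i) {
               paste(c(labels[i], sprintf(fmt, d[i, ])), collapse = "  ")
             }, character(1L)))
  writeLines(lines, path)
  invisible(path)
}

#' Read a square PHYLIP distance matrix
#'
#' @param path path written by [write_distance_matrix()].
#' @return A [distance_matrix()] with model tag `"unknown"`.
#' @export
read_distance_matrix <- function(path) {
  lines <- readLines(path)
  n <- as.integer(trimws(lines[1L]))
  fields <- strsplit(trimws(lines[1L + seq_len(n)]), "[[:space:]]+")
  labels <- vapply(fields, `[`, character(1L), 1L)
  d <- t(vapply(fields, function(f) as.numeric(f[-1L]), numeric(n)))
  dimnames(d) <- list(labels, labels)
  distance_matrix_obj(d, model = "unknown", gap_policy = "unknown")
}
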