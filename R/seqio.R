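#' Sequence sets
#'
#' An ordered, named collection of unaligned residue strings.  Order is stable
#' and defines the sequence indices used by every other function in the
#' package (1-based in R; residue positions are 0-based throughout, matching
#' the cut convention "position c means the first c residues lie left of the
#' cut").
#'
#' @param residues Character vector of residue strings (no gap characters).
#' @param ids Character vector of unique sequence identifiers.
#' @return An object of class \code{"sequence_set"}.
#' @export
sequence_set <- function(residues, ids = names(residues)) {
  if (is.null(ids)) ids <- paste0("seq", seq_along(residues))
  residues <- toupper(as.character(residues))
  ids <- as.character(ids)
  if (length(residues) < 1L) stop("a sequence set needs at least one sequence")
  if (length(ids) != length(residues)) stop("ids and residues differ in length")
  if (anyDuplicated(ids)) {
    stop("duplicate sequence id: ", ids[duplicated(ids)][1L])
  }
  if (any(!nzchar(ids))) stop("empty sequence id")
  bad <- grepl("[-.]", residues)
  if (any(bad)) {
    stop("gap character in unaligned input sequence '", ids[bad][1L], "'")
  }
  bad <- grepl("[^A-Z]", residues)
  if (any(bad)) {
    stop("illegal character in sequence '", ids[bad][1L], "'")
  }
  structure(list(ids = ids, residues = unname(residues)),
            class = "sequence_set")
}

#' @export
print.sequence_set <- function(x, ...) {
  cat(sprintf("A sequence set of %d sequence(s), lengths %d..%d\n",
              length(x$ids), min(nchar(x$residues)), max(nchar(x$residues))))
  for (i in seq_along(x$ids)) {
    r <- x$residues[i]
    cat(sprintf("  %-12s %s%s (%d)\n", x$ids[i],
                substr(r, 1L, 50L), if (nchar(r) > 50L) "..." else "",
                nchar(r)))
  }
  invisible(x)
}

#' @export
length.sequence_set <- function(x) length(x$ids)

seq_lengths <- function(seqs) nchar(seqs$residues)

#' Read unaligned sequences from a FASTA file
#'
#' Whitespace is stripped and letters uppercased; gap characters ('-' or '.'),
#' non-letter symbols, duplicate ids and empty files are format errors.
#'
#' @param path Path to a FASTA file.
#' @return A \code{\link{sequence_set}} in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("not a readable FASTA file: ", path,
                                           " (", conditionMessage(e), ")"))
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(set))
  sequence_set(gsub("\\s", "", as.character(set)), ids)
}

#' Write unaligned sequences to a FASTA file
#'
#' @param seqs A \code{\link{sequence_set}}.
#' @param path Output path.
#' @param width Line-wrap width.
#' @return \code{path}, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  x <- Biostrings::BStringSet(seqs$residues)
  names(x) <- seqs$ids
  Biostrings::writeXStringSet(x, path, width = width)
  invisible(path)
}

#' Load a substitution matrix
#'
#' Reads a whitespace-delimited square similarity matrix with a header row of
#' symbols and one labelled row per symbol; lines starting with '#' are
#' comments.  The bundled \code{"gonnet160"} matrix is a Gonnet-family
#' amino-acid matrix at 160 PAM (units of 10*log10 odds), derived from the
#' published 250-PAM Gonnet-Cohen-Benner data by Markov-chain time rescaling.
#'
#' @param name_or_path Either the built-in name \code{"gonnet160"} or a path
#'   to a matrix file.
#' @return An object of class \code{"subst_matrix"}: a list with elements
#'   \code{alphabet} (ordered character vector) and \code{scores} (symmetric
#'   numeric matrix with symbol dimnames).
#' @export
load_matrix <- function(name_or_path = "gonnet160") {
  path <- name_or_path
  if (identical(name_or_path, "gonnet160")) {
    path <- system.file("extdata", "gonnet160.txt", package = "msaclust",
                        mustWork = TRUE)
  }
  if (!file.exists(path)) stop("no such substitution matrix file: ", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (length(lines) < 2L) stop("substitution matrix file has no data: ", path)
  toks <- strsplit(trimws(lines), "\\s+")
  alphabet <- toupper(toks[[1L]])
  n <- length(alphabet)
  rows <- toks[-1L]
  if (length(rows) != n) {
    stop("ragged substitution matrix: ", n, " symbols but ", length(rows),
         " rows")
  }
  scores <- matrix(NA_real_, n, n, dimnames = list(alphabet, alphabet))
  for (r in rows) {
    if (length(r) != n + 1L) {
      stop("ragged substitution matrix row for symbol '", r[1L], "'")
    }
    sym <- toupper(r[1L])
    if (!sym %in% alphabet) stop("row symbol '", sym, "' not in header")
    scores[sym, ] <- as.numeric(r[-1L])
  }
  if (anyNA(scores)) stop("missing rows in substitution matrix")
  if (max(abs(scores - t(scores))) > 1e-8) {
    stop("substitution matrix is not symmetric")
  }
  structure(list(alphabet = alphabet, scores = scores),
            class = "subst_matrix")
}

#' Build a substitution matrix from a score table
#'
#' Convenience constructor for toy alphabets in examples and tests.
#'
#' @param scores Symmetric numeric matrix with symbol dimnames.
#' @return A \code{"subst_matrix"} object.
#' @export
subst_matrix <- function(scores) {
  scores <- as.matrix(scores)
  alphabet <- rownames(scores)
  if (is.null(alphabet) || !identical(alphabet, colnames(scores))) {
    stop("scores must have matching row/column symbol names")
  }
  if (max(abs(scores - t(scores))) > 1e-8) stop("scores must be symmetric")
  structure(list(alphabet = alphabet, scores = scores),
            class = "subst_matrix")
}

check_alphabet <- function(seqs, matrix) {
  ok <- paste(matrix$alphabet, collapse = "")
  bad <- grepl(sprintf("[^%s]", ok), seqs$residues)
  if (any(bad)) {
    stop("sequence '", seqs$ids[bad][1L],
         "' contains symbols outside the substitution-matrix alphabet")
  }
  invisible(TRUE)
}

#' Multiple alignments as residue-position matrices
#'
#' An alignment is stored as a k x L integer matrix \code{pos}: entry
#' \code{pos[s, col]} is the 0-based residue position of sequence \code{s}
#' placed in that column, or \code{NA} for a gap.  Per sequence, the non-NA
#' entries read left to right are exactly 0, 1, ..., len-1; every column holds
#' at least one residue and at most one residue per sequence (guaranteed by
#' the matrix representation).
#'
#' @param ids Character vector of sequence ids (row order = sequence order).
#' @param pos Integer matrix of residue positions with NA gaps.
#' @return An object of class \code{"msa_alignment"}.
#' @export
new_alignment <- function(ids, pos) {
  pos <- as.matrix(pos)
  storage.mode(pos) <- "integer"
  rownames(pos) <- ids
  structure(list(ids = as.character(ids), pos = pos),
            class = "msa_alignment")
}

#' Validate alignment invariants
#'
#' Checks that every column is non-empty and that each sequence's residue
#' positions are strictly increasing and (when sequence lengths are supplied)
#' cover 0..len-1 exactly once.
#'
#' @param aln An \code{"msa_alignment"}.
#' @param lens Optional integer vector of true sequence lengths.
#' @return TRUE invisibly; otherwise an error.
#' @export
validate_alignment <- function(aln, lens = NULL) {
  pos <- aln$pos
  if (nrow(pos) != length(aln$ids)) stop("alignment ids/pos mismatch")
  if (ncol(pos) > 0L && any(colSums(!is.na(pos)) == 0L)) {
    stop("alignment contains an all-gap column")
  }
  for (s in seq_len(nrow(pos))) {
    p <- pos[s, !is.na(pos[s, ])]
    if (length(p) && (any(diff(p) <= 0L) || p[1L] != 0L)) {
      stop("residue positions of sequence '", aln$ids[s],
           "' are not 0..len-1 in increasing order")
    }
    if (!is.null(lens) && !identical(as.integer(length(p)), as.integer(lens[s]))) {
      stop("sequence '", aln$ids[s], "' has ", lens[s],
           " residues but the alignment places ", length(p))
    }
    if (length(p) && p[length(p)] != length(p) - 1L) {
      stop("residue positions of sequence '", aln$ids[s], "' have holes")
    }
  }
  invisible(TRUE)
}

#' Render an alignment as gapped residue strings
#'
#' @param aln An \code{"msa_alignment"}.
#' @param seqs The underlying \code{\link{sequence_set}}.
#' @return Named character vector of equal-length gapped rows.
#' @export
alignment_strings <- function(aln, seqs) {
  if (!identical(aln$ids, seqs$ids)) stop("alignment/sequence id mismatch")
  validate_alignment(aln, seq_lengths(seqs))
  k <- length(seqs$ids)
  out <- character(k)
  for (s in seq_len(k)) {
    chars <- rep("-", ncol(aln$pos))
    keep <- !is.na(aln$pos[s, ])
    res <- strsplit(seqs$residues[s], "")[[1L]]
    chars[keep] <- res[aln$pos[s, keep] + 1L]
    out[s] <- paste(chars, collapse = "")
  }
  names(out) <- seqs$ids
  out
}

#' Build an alignment from gapped rows
#'
#' @param rows Named character vector of equal-length gapped strings
#'   ('-' or '.' read as gaps).
#' @return A list with the degapped \code{seqs} (\code{sequence_set}) and the
#'   \code{aln} (\code{msa_alignment}).
#' @export
alignment_from_strings <- function(rows) {
  ids <- names(rows)
  if (is.null(ids)) ids <- paste0("seq", seq_along(rows))
  rows <- toupper(rows)
  L <- unique(nchar(rows))
  if (length(L) != 1L) stop("aligned rows differ in length")
  k <- length(rows)
  pos <- matrix(NA_integer_, k, L)
  for (s in seq_len(k)) {
    ch <- strsplit(rows[s], "")[[1L]]
    keep <- !(ch %in% c("-", "."))
    pos[s, keep] <- seq_len(sum(keep)) - 1L
  }
  pos <- pos[, colSums(!is.na(pos)) > 0L, drop = FALSE]
  seqs <- sequence_set(gsub("[-.]", "", rows), ids)
  list(seqs = seqs, aln = new_alignment(ids, pos))
}

#' Write an alignment to a file
#'
#' @param aln An \code{"msa_alignment"}.
#' @param seqs The underlying \code{\link{sequence_set}}.
#' @param path Output path.
#' @param format \code{"afasta"} (aligned FASTA, the default) or
#'   \code{"clustal"} (blocks of at most 60 columns with a name margin).
#' @return \code{path}, invisibly.
#' @export
write_alignment <- function(aln, seqs, path, format = c("afasta", "clustal")) {
  format <- match.arg(format)
  rows <- alignment_strings(aln, seqs)
  if (format == "afasta") {
    x <- Biostrings::BStringSet(rows)
    names(x) <- seqs$ids
    Biostrings::writeXStringSet(x, path, width = 60L)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("CLUSTAL multiple sequence alignment\n", con)
    L <- ncol(aln$pos)
    margin <- max(nchar(seqs$ids)) + 3L
    for (start in seq(1L, max(L, 1L), by = 60L)) {
      stop_ <- min(start + 59L, L)
      for (s in seq_along(rows)) {
        writeLines(sprintf("%-*s%s", margin, seqs$ids[s],
                           substr(rows[s], start, stop_)), con)
      }
      writeLines("", con)
    }
  }
  invisible(path)
}

#' Read an aligned FASTA file
#'
#' @param path Path to an aligned FASTA file (all rows the same length; '-'
#'   or '.' as gaps).
#' @return A list with \code{seqs} (degapped \code{sequence_set}) and
#'   \code{aln} (\code{msa_alignment}).
#' @export
read_alignment <- function(path) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty alignment file: ", path)
  rows <- gsub("\\s", "", as.character(set))
  names(rows) <- sub("\\s.*$", "", names(set))
  alignment_from_strings(rows)
}

#' Identity alignment of a single-sequence set (or stacked residue columns)
#'
#' Each residue of the single sequence becomes its own column.
#'
#' @param seqs A \code{\link{sequence_set}} with one sequence.
#' @return An \code{"msa_alignment"}.
#' @export
identity_alignment <- function(seqs) {
  stopifnot(length(seqs$ids) == 1L)
  n <- nchar(seqs$residues[1L])
  new_alignment(seqs$ids, matrix(seq_len(n) - 1L, nrow = 1L))
}

#' @export
print.msa_alignment <- function(x, ...) {
  cat(sprintf("Multiple alignment: %d sequence(s), %d column(s)\n",
              length(x$ids), ncol(x$pos)))
  invisible(x)
}
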