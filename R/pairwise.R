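# Integer-encode a residue string against a substitution matrix alphabet.
encode_seq <- function(x, matrix) {
  ch <- strsplit(x, "")[[1L]]
  idx <- match(ch, matrix$alphabet)
  if (anyNA(idx)) {
    stop("residue '", ch[is.na(idx)][1L],
         "' is not in the substitution-matrix alphabet")
  }
  idx
}

#' Statistical weight of a pairwise alignment
#'
#' Scores a gapped pairwise alignment with the standard similarity function
#' (matches by the substitution matrix; affine gaps: \code{gap_open} for the
#' first column of an internal gap run, \code{gap_ext} for each further
#' column; every column of a terminal run -- one touching either end of
#' either sequence -- scores \code{terminal_gap}) and returns the Boltzmann
#' weight \eqn{e^{\beta S(A)}}.
#'
#' @param row_a,row_b Equal-length gapped strings (gap character '-').
#' @param params An \code{\link{align_params}} object.
#' @param matrix A \code{\link{subst_matrix}} (or the result of
#'   \code{\link{load_matrix}}).
#' @return The alignment weight (a positive number).
#' @export
alignment_weight <- function(row_a, row_b, params, matrix) {
  exp(params$beta * alignment_score(row_a, row_b, params, matrix))
}

# Similarity score S(A) of a gapped pairwise alignment.
alignment_score <- function(row_a, row_b, params, matrix) {
  ca <- strsplit(row_a, "")[[1L]]
  cb <- strsplit(row_b, "")[[1L]]
  if (length(ca) != length(cb)) stop("alignment rows differ in length")
  if (any(ca == "-" & cb == "-")) stop("all-gap column in pairwise alignment")
  m <- sum(ca != "-")
  n <- sum(cb != "-")
  S <- 0
  i <- 0L; j <- 0L          # residues consumed so far
  state <- "M"              # M, E (gap in a), F (gap in b)
  for (col in seq_along(ca)) {
    if (ca[col] != "-" && cb[col] != "-") {
      S <- S + matrix$scores[ca[col], cb[col]]
      i <- i + 1L; j <- j + 1L
      state <- "M"
    } else if (ca[col] == "-") {
      terminal <- (i == 0L || i == m)
      open <- state != "E"
      S <- S + if (terminal) params$terminal_gap
               else if (open) params$gap_open else params$gap_ext
      j <- j + 1L
      state <- "E"
    } else {
      terminal <- (j == 0L || j == n)
      open <- state != "F"
      S <- S + if (terminal) params$terminal_gap
               else if (open) params$gap_open else params$gap_ext
      i <- i + 1L
      state <- "F"
    }
  }
  S
}

#' Forward partition function under affine gaps
#'
#' Computes the three-state (match / gap-in-a / gap-in-b) partition-function
#' tables by the sum-over-paths analogue of the Gotoh algorithm: every
#' \code{max} of the score recursion becomes a sum of Boltzmann weights.
#' Under the \code{"adjacent"} variant a gap in one sequence may directly
#' follow a gap in the other; under \code{"noadjacent"} such transitions are
#' excluded, so insertions and deletions must be separated by at least one
#' match/mismatch column.  Terminal gap runs (touching either end of either
#' sequence) are scored with \code{terminal_gap} in place of both open and
#' extension penalties.
#'
#' Tables are stored with per-row rescaling: row \code{i} of each table holds
#' values divided by \code{exp(logscale[i + 1])}, which keeps every stored
#' number in a safe floating-point range for arbitrarily long sequences while
#' preserving exact ratios.
#'
#' @param a,b Residue strings (no gaps).
#' @param params An \code{\link{align_params}}.
#' @param matrix A \code{\link{subst_matrix}}.
#' @return An object of class \code{"partition_tables"}: list with scaled
#'   tables \code{M}, \code{E}, \code{F} of dimension (m+1) x (n+1), the
#'   per-row log scale \code{logscale}, sequence lengths \code{m}, \code{n}
#'   and \code{log_total} (the log partition function \eqn{\log Z}).
#' @export
forward_partition <- function(a, b, params, matrix) {
  ia <- if (nzchar(a)) encode_seq(a, matrix) else integer(0)
  ib <- if (nzchar(b)) encode_seq(b, matrix) else integer(0)
  m <- length(ia); n <- length(ib)
  beta <- params$beta
  eo <- exp(beta * params$gap_open)
  ee <- exp(beta * params$gap_ext)
  tg <- exp(beta * params$terminal_gap)
  adjacent <- params$indel_variant == "adjacent"
  sc <- matrix$scores

  M <- matrix(0, m + 1L, n + 1L)
  E <- matrix(0, m + 1L, n + 1L)
  F_ <- matrix(0, m + 1L, n + 1L)
  ls <- numeric(m + 1L)

  M[1L, 1L] <- 1
  if (n > 0L) {
    # gaps in a before a_1: terminal
    E[1L, 2L] <- tg
    for (j in seq_len(n - 1L) + 1L) E[1L, j + 1L] <- E[1L, j] * tg
  }
  for (i in seq_len(m)) {
    r <- i + 1L       # row index of i in the tables
    ei <- exp(beta * sc[ia[i], ib])   # match weights vs every b_j (len n)
    # F: gap in b consuming a_i; terminal at j == 0 or j == n
    F_[r, 1L] <- (M[r - 1L, 1L] + F_[r - 1L, 1L]) * tg
    if (n > 0L) {
      for (j in seq_len(n)) {
        cc <- j + 1L
        wo <- if (j == n) tg else eo
        we <- if (j == n) tg else ee
        open_src <- M[r - 1L, cc] + if (adjacent) E[r - 1L, cc] else 0
        F_[r, cc] <- open_src * wo + F_[r - 1L, cc] * we
        M[r, cc] <- (M[r - 1L, cc - 1L] + E[r - 1L, cc - 1L] +
                       F_[r - 1L, cc - 1L]) * ei[j]
      }
      # E within row i: gap in a after a_i; terminal when i == m
      wo <- if (i == m) tg else eo
      we <- if (i == m) tg else ee
      for (j in seq_len(n)) {
        cc <- j + 1L
        open_src <- M[r, cc - 1L] + if (adjacent) F_[r, cc - 1L] else 0
        E[r, cc] <- open_src * wo + E[r, cc - 1L] * we
      }
    }
    mx <- max(M[r, ], E[r, ], F_[r, ])
    if (mx > 0) {
      M[r, ] <- M[r, ] / mx
      E[r, ] <- E[r, ] / mx
      F_[r, ] <- F_[r, ] / mx
      ls[r] <- ls[r - 1L] + log(mx)
    } else {
      ls[r] <- ls[r - 1L]
    }
  }
  tot <- M[m + 1L, n + 1L] + E[m + 1L, n + 1L] + F_[m + 1L, n + 1L]
  structure(list(M = M, E = E, F = F_, logscale = ls, m = m, n = n,
                 log_total = log(tot) + ls[m + 1L]),
            class = "partition_tables")
}

#' Reverse (suffix) partition function
#'
#' Runs the same recursion from the ends of the sequences: the returned
#' tables are those of \code{\link{forward_partition}} applied to the
#' reversed sequences.  Entry \eqn{\hat Z_{i,j}} (the partition function over
#' alignments of the suffixes \eqn{a_i..a_m}, \eqn{b_j..b_n}) is recovered as
#' the reversed-table total at (m - i + 1, n - j + 1); its log is exposed via
#' \code{\link{log_z_table}}.
#'
#' @inheritParams forward_partition
#' @return A \code{"partition_tables"} object for the reversed sequences.
#' @export
reverse_partition <- function(a, b, params, matrix) {
  rev_str <- function(x) paste(rev(strsplit(x, "")[[1L]]), collapse = "")
  forward_partition(rev_str(a), rev_str(b), params, matrix)
}

#' Log partition-function totals over all prefix cells
#'
#' @param pt A \code{"partition_tables"} object.
#' @return An (m+1) x (n+1) matrix whose (i+1, j+1) entry is
#'   \eqn{\log Z_{i,j}}, the log partition function over alignments of the
#'   length-i and length-j prefixes (\code{-Inf} where no alignment exists).
#' @export
log_z_table <- function(pt) {
  tot <- pt$M + pt$E + pt$F
  log(tot) + pt$logscale
}

#' Total partition function
#'
#' @param pt A \code{"partition_tables"} object.
#' @param log Return the log value (default) or the plain value.
#' @return \eqn{\log Z} or \eqn{Z}.
#' @export
partition_total <- function(pt, log = TRUE) {
  if (log) pt$log_total else exp(pt$log_total)
}

#' Posterior residue-pairing probabilities for one sequence pair
#'
#' For every residue pair computes the posterior probability that the two
#' residues share an alignment column, marginalised over all gapped
#' alignments of the pair under the Boltzmann distribution:
#' \deqn{P(a_i \sim b_j) = Z_{i-1,j-1}\, e^{\beta s(a_i,b_j)}\,
#'       \hat Z_{i+1,j+1} / Z.}
#' The product is evaluated in log space from the rescaled forward and
#' reverse tables.  Entries strictly below \code{params$cutoff} are dropped
#' and the matrix is stored sparsely.
#'
#' @inheritParams forward_partition
#' @return A sparse \code{Matrix::dgCMatrix} of dimension m x n (rows index
#'   residues of \code{a}, 1-based; columns residues of \code{b}).
#' @export
posterior_matrix <- function(a, b, params, matrix) {
  m <- nchar(a); n <- nchar(b)
  if (m == 0L || n == 0L) {
    return(Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                                dims = c(m, n)))
  }
  fw <- forward_partition(a, b, params, matrix)
  rv <- reverse_partition(a, b, params, matrix)
  lzf <- log_z_table(fw)
  lzr <- log_z_table(rv)
  ia <- encode_seq(a, matrix)
  ib <- encode_seq(b, matrix)
  S <- matrix$scores[ia, ib, drop = FALSE]
  # prefix part: Z_{i-1,j-1} for i=1..m, j=1..n; suffix: Zhat_{i+1,j+1}
  lp <- lzf[1:m, 1:n, drop = FALSE] + params$beta * S +
    lzr[m:1, n:1, drop = FALSE] - fw$log_total
  P <- exp(lp)
  P[P < params$cutoff] <- 0
  Matrix::drop0(as_dgc(P))
}

#' Write a posterior matrix as a 3-column text table
#'
#' Debug dump: rows of \code{i j p} with 0-based residue indices.
#'
#' @param P A sparse posterior matrix.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
dump_posterior <- function(P, path) {
  tr <- Matrix::summary(P)
  ord <- order(tr$i, tr$j)
  utils::write.table(
    data.frame(i = tr$i[ord] - 1L, j = tr$j[ord] - 1L, p = tr$x[ord]),
    path, row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}
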