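# Independent oracles used across the suite.  These deliberately avoid the
# package's DP/graph code paths: the partition-function oracle enumerates
# alignments one by one, the consistency oracle works on dense matrices, the
# partitioner oracle enumerates every feasible cut.

toy_matrix <- function(match = 2, mismatch = -1,
                       alphabet = c("A", "B", "C")) {
  n <- length(alphabet)
  m <- matrix(mismatch, n, n, dimnames = list(alphabet, alphabet))
  diag(m) <- match
  subst_matrix(m)
}

random_toy_seq <- function(len, alphabet = c("A", "B", "C")) {
  if (len == 0L) return("")
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

# Exhaustive enumeration of all gapped alignments of a and b.  Walks the
# three-state step tree (match / gap-in-a / gap-in-b), scoring incrementally
# with the same run conventions the recurrences encode: a gap run in a is
# terminal iff it sits before a_1 or after a_m (likewise for b), and under
# the "noadjacent" variant a gap column in one sequence may not directly
# follow a gap column in the other.  Returns Z and the matrix of posterior
# numerators (sum of weights of alignments pairing a_i with b_j).
enumerate_pair <- function(a, b, params, matrix) {
  ca <- if (nzchar(a)) strsplit(a, "")[[1]] else character(0)
  cb <- if (nzchar(b)) strsplit(b, "")[[1]] else character(0)
  m <- length(ca); n <- length(cb)
  beta <- params$beta
  adjacent <- params$indel_variant == "adjacent"
  Z <- 0
  num <- matrix(0, max(m, 1L), max(n, 1L))
  match_i <- integer(m + n)
  match_j <- integer(m + n)

  rec <- function(i, j, last, score, nm) {
    if (i == m && j == n) {
      w <- exp(beta * score)
      Z <<- Z + w
      if (nm > 0L) {
        for (t in seq_len(nm)) {
          num[match_i[t], match_j[t]] <<- num[match_i[t], match_j[t]] + w
        }
      }
      return(invisible(NULL))
    }
    if (i < m && j < n) {
      match_i[nm + 1L] <<- i + 1L
      match_j[nm + 1L] <<- j + 1L
      rec(i + 1L, j + 1L, "M",
          score + matrix$scores[ca[i + 1L], cb[j + 1L]], nm + 1L)
    }
    if (j < n && (adjacent || last != "F")) {        # gap in a
      g <- if (i == 0L || i == m) params$terminal_gap
           else if (last == "E") params$gap_ext else params$gap_open
      rec(i, j + 1L, "E", score + g, nm)
    }
    if (i < m && (adjacent || last != "E")) {        # gap in b
      g <- if (j == 0L || j == n) params$terminal_gap
           else if (last == "F") params$gap_ext else params$gap_open
      rec(i + 1L, j, "F", score + g, nm)
    }
    invisible(NULL)
  }
  rec(0L, 0L, "M", 0, 0L)
  list(Z = Z, posterior = if (m && n) num[1:m, 1:n, drop = FALSE] / Z
                          else matrix(0, m, n))
}

# Dense literal evaluation of the consistency transformation.
dense_consistency_oracle <- function(mats, lens, W, iters, cutoff,
                                     prune_each = TRUE) {
  k <- length(lens)
  get_dense <- function(a, b) {
    if (a == b) return(diag(lens[a]))
    if (a < b) mats[[paste0(a, "_", b)]] else t(mats[[paste0(b, "_", a)]])
  }
  for (it in seq_len(iters)) {
    new <- list()
    for (a in 1:(k - 1)) {
      for (b in (a + 1):k) {
        num <- matrix(0, lens[a], lens[b])
        den <- 0
        for (cc in 1:k) {
          wp <- W[a, cc] * W[cc, b]
          num <- num + wp * (get_dense(a, cc) %*% get_dense(cc, b))
          den <- den + wp
        }
        P <- num / den
        if (prune_each || it == iters) P[P < cutoff] <- 0
        new[[paste0(a, "_", b)]] <- P
      }
    }
    mats <- new
  }
  mats
}

# Random sparse posterior-like matrices with row/column sums <= 1, wrapped
# as a posterior_store.
random_store <- function(lens, density = 0.4) {
  k <- length(lens)
  mats <- list()
  for (a in 1:(k - 1)) {
    for (b in (a + 1):k) {
      M <- matrix(stats::runif(lens[a] * lens[b]) *
                    (stats::runif(lens[a] * lens[b]) < density),
                  lens[a], lens[b])
      scale <- max(1, max(rowSums(M)), max(colSums(M)))
      mats[[paste0(a, "_", b)]] <- as_test_sparse(M / scale)
    }
  }
  structure(list(k = k, ids = paste0("s", 1:k), lens = as.integer(lens),
                 matrices = mats),
            class = "posterior_store")
}

as_test_sparse <- function(M) {
  Matrix::drop0(methods::as(methods::as(methods::as(Matrix::Matrix(M),
    "CsparseMatrix"), "generalMatrix"), "dMatrix"))
}

# Enumerate every balance-feasible cut of the full region of a graph and
# return the minimum cut weight (the partitioner's target optimum).
exhaustive_best_cut <- function(graph) {
  k <- graph$k
  lens <- graph$lens
  tot <- sum(lens)
  minside <- max(0, floor((tot - k) / 2))
  grid <- expand.grid(lapply(lens, function(n) 0:n))
  reg <- region(rep(0L, k), lens)
  best <- Inf
  for (r in seq_len(nrow(grid))) {
    cut <- as.integer(grid[r, ])
    L <- sum(cut)
    if (min(L, tot - L) < minside) next
    w <- cut_weight(graph, reg, cut)
    if (w < best) best <- w
  }
  best
}

# Build an alignment graph from random sparse pair matrices.
random_alignment_graph <- function(k, lens, density = 0.35) {
  mats <- list()
  for (a in 1:(k - 1)) {
    for (b in (a + 1):k) {
      M <- matrix(stats::runif(lens[a] * lens[b]) *
                    (stats::runif(lens[a] * lens[b]) < density),
                  lens[a], lens[b])
      mats[[paste0(a, "_", b)]] <- as_test_sparse(M)
    }
  }
  store <- structure(list(k = k, ids = paste0("s", 1:k),
                          lens = as.integer(lens), matrices = mats),
                     class = "posterior_store")
  seqs <- sequence_set(vapply(lens, function(n)
    paste(rep("A", n), collapse = ""), character(1)), paste0("s", 1:k))
  build_alignment_graph(store, seqs)
}

# Independent maximum-expected-accuracy value for a two-sequence dense
# posterior matrix: simple monotone-matching DP (no gap states needed at
# zero gap penalty).
nw_oracle_value <- function(P) {
  m <- nrow(P); n <- ncol(P)
  f <- matrix(0, m + 1, n + 1)
  for (i in seq_len(m)) {
    for (j in seq_len(n)) {
      f[i + 1, j + 1] <- max(f[i, j] + P[i, j], f[i, j + 1], f[i + 1, j])
    }
  }
  f[m + 1, n + 1]
}

# A store whose only pair matrix is a strong diagonal: handy for pipeline
# and refinement fixtures.
diagonal_store <- function(k, len, p = 0.9) {
  mats <- list()
  for (a in 1:(k - 1)) {
    for (b in (a + 1):k) {
      mats[[paste0(a, "_", b)]] <- as_test_sparse(diag(p, len))
    }
  }
  structure(list(k = k, ids = paste0("s", 1:k),
                 lens = rep(as.integer(len), k), matrices = mats),
            class = "posterior_store")
}
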