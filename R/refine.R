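#' Expected accuracy of an alignment under a posterior store
#'
#' Sums, over all columns and all within-column residue pairs from different
#' sequences, the stored posterior pairing probability (0 for entries pruned
#' below the cutoff).  This is the objective that iterative refinement can
#' never decrease.
#'
#' @param aln An \code{"msa_alignment"}.
#' @param store A \code{"posterior_store"} over the same sequences.
#' @return A non-negative number.
#' @export
expected_accuracy <- function(aln, store) {
  k <- store$k
  if (k < 2L || ncol(aln$pos) == 0L) return(0)
  total <- 0
  for (a in 1:(k - 1L)) {
    for (b in (a + 1L):k) {
      ia <- aln$pos[a, ]; ib <- aln$pos[b, ]
      both <- !is.na(ia) & !is.na(ib)
      if (!any(both)) next
      P <- store$matrices[[store_key(a, b)]]
      total <- total + sum(P[cbind(ia[both] + 1L, ib[both] + 1L)])
    }
  }
  total
}

# Dense posterior lookup cache (one dense matrix per pair) used by the
# refinement scorer; pads a zero row/column so NA positions can index it.
dense_store <- function(store) {
  k <- store$k
  out <- vector("list", k * k)
  dim(out) <- c(k, k)
  if (k >= 2L) {
    for (a in 1:(k - 1L)) {
      for (b in (a + 1L):k) {
        D <- as.matrix(store$matrices[[store_key(a, b)]])
        out[[a, b]] <- rbind(cbind(D, 0), 0)          # pad: gap row/col
        out[[b, a]] <- rbind(cbind(t(D), 0), 0)
      }
    }
  }
  out
}

# Project an alignment onto a sequence subset: keep those rows, drop
# columns that become all-gap.
project_alignment <- function(aln, rows) {
  pos <- aln$pos[rows, , drop = FALSE]
  pos[, colSums(!is.na(pos)) > 0L, drop = FALSE]
}

#' Re-align two sequence groups by maximum expected accuracy
#'
#' Projects the alignment onto each group of the split (dropping columns
#' that become all-gap), scores every pair of projected columns by the sum
#' of posteriors over their non-gap residue pairs, and merges the two
#' profiles with a global Needleman-Wunsch alignment at zero gap penalty.
#' Because the input alignment corresponds to one admissible path through
#' that score matrix, the optimal path never decreases the expected
#' accuracy.  Traceback ties break diagonal over up over left for
#' deterministic output.
#'
#' @param aln An \code{"msa_alignment"}.
#' @param group Integer vector of 1-based sequence indices forming one side
#'   of the split (the other side is the complement); both sides must be
#'   non-empty.
#' @param store A \code{"posterior_store"}.
#' @param dense Optional precomputed \code{dense_store(store)} cache.
#' @return The merged \code{"msa_alignment"}.
#' @export
group_realign <- function(aln, group, store, dense = NULL) {
  k <- store$k
  group <- sort(unique(as.integer(group)))
  rest <- setdiff(seq_len(k), group)
  if (length(group) == 0L || length(rest) == 0L) {
    stop("split must leave both groups non-empty")
  }
  if (is.null(dense)) dense <- dense_store(store)
  A <- project_alignment(aln, group)
  B <- project_alignment(aln, rest)
  U <- ncol(A); V <- ncol(B)
  # profile-profile score matrix
  M <- matrix(0, U, V)
  for (ga in seq_along(group)) {
    for (gb in seq_along(rest)) {
      D <- dense[[group[ga], rest[gb]]]
      m <- nrow(D) - 1L; n <- ncol(D) - 1L
      ia <- A[ga, ] + 1L; ia[is.na(ia)] <- m + 1L
      ib <- B[gb, ] + 1L; ib[is.na(ib)] <- n + 1L
      M <- M + D[ia, ib, drop = FALSE]
    }
  }
  # global NW, zero gap penalty
  H <- matrix(0, U + 1L, V + 1L)
  for (u in seq_len(U)) {
    hu <- H[u, ]; hv <- H[u + 1L, ]
    for (v in seq_len(V)) {
      hv[v + 1L] <- max(hu[v] + M[u, v], hu[v + 1L], hv[v])
    }
    H[u + 1L, ] <- hv
  }
  # traceback, diagonal > up > left
  u <- U; v <- V
  steps <- integer(U + V)
  ns <- 0L
  while (u > 0L || v > 0L) {
    ns <- ns + 1L
    if (u > 0L && v > 0L &&
        H[u + 1L, v + 1L] == H[u, v] + M[u, v]) {
      steps[ns] <- 0L; u <- u - 1L; v <- v - 1L
    } else if (u > 0L && H[u + 1L, v + 1L] == H[u, v + 1L]) {
      steps[ns] <- 1L; u <- u - 1L
    } else {
      steps[ns] <- 2L; v <- v - 1L
    }
  }
  steps <- rev(steps[seq_len(ns)])
  pos <- matrix(NA_integer_, k, ns)
  u <- 0L; v <- 0L
  for (t in seq_len(ns)) {
    if (steps[t] != 2L) u <- u + 1L
    if (steps[t] != 1L) v <- v + 1L
    if (steps[t] != 2L) pos[group, t] <- A[, u]
    if (steps[t] != 1L) pos[rest, t] <- B[, v]
  }
  new_alignment(aln$ids, pos)
}

#' Iterative refinement of a clustered alignment
#'
#' Phase 1 re-aligns each sequence in order against the remaining ones
#' (very effective at collapsing superfluous near-all-gap columns left by
#' clustering); phase 2 performs \code{params$refine_iters} iterations, each
#' re-aligning a uniformly drawn non-trivial sequence subset (size uniform
#' on 1..k-1, then a uniform subset of that size) against the rest.  Both
#' phases only ever replace the alignment with a maximum-expected-accuracy
#' merge, so the objective of \code{\link{expected_accuracy}} never
#' decreases.  Randomness comes from R's global RNG; seed it (or let
#' \code{\link{msaclust}} do so) for reproducible runs.
#'
#' @param aln An \code{"msa_alignment"}.
#' @param store A \code{"posterior_store"}.
#' @param params An \code{\link{align_params}} (\code{refine},
#'   \code{refine_iters}).
#' @return The refined \code{"msa_alignment"}.
#' @export
iterative_refine <- function(aln, store, params = align_params()) {
  k <- store$k
  if (!params$refine || k < 2L) return(aln)
  dense <- dense_store(store)
  for (s in seq_len(k)) {
    aln <- group_realign(aln, s, store, dense = dense)
  }
  if (params$refine_iters > 0L && k >= 2L) {
    for (it in seq_len(params$refine_iters)) {
      size <- sample.int(k - 1L, 1L)
      group <- sample.int(k, size)
      aln <- group_realign(aln, group, store, dense = dense)
    }
  }
  aln
}
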