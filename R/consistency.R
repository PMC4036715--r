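#' All-pairs posterior store
#'
#' Computes the sparse posterior residue-pairing matrix for every unordered
#' pair of sequences in the set.  The store is the central container for the
#' consistency transformation, the alignment graph and the refinement
#' objective.  Self-pairings are represented implicitly by identity matrices
#' (see \code{\link{store_get}}).
#'
#' @param seqs A \code{\link{sequence_set}}.
#' @param params An \code{\link{align_params}}.
#' @param matrix A \code{\link{subst_matrix}}.
#' @return An object of class \code{"posterior_store"}: list with \code{k},
#'   \code{ids}, \code{lens} and \code{matrices}, a named list keyed
#'   \code{"a_b"} (1-based sequence indices, a < b) of sparse matrices.
#' @export
posterior_store <- function(seqs, params, matrix) {
  check_alphabet(seqs, matrix)
  k <- length(seqs$ids)
  mats <- list()
  if (k >= 2L) {
    for (a in 1:(k - 1L)) {
      for (b in (a + 1L):k) {
        mats[[store_key(a, b)]] <-
          posterior_matrix(seqs$residues[a], seqs$residues[b], params, matrix)
      }
    }
  }
  structure(list(k = k, ids = seqs$ids, lens = seq_lengths(seqs),
                 matrices = mats),
            class = "posterior_store")
}

store_key <- function(a, b) paste0(a, "_", b)

#' Fetch a pairwise matrix from a posterior store
#'
#' @param store A \code{"posterior_store"}.
#' @param a,b 1-based sequence indices.  For a > b the stored transpose is
#'   returned; for a == b a sparse identity (the self-pairing convention).
#' @return A sparse matrix of dimension len(a) x len(b).
#' @export
store_get <- function(store, a, b) {
  if (a == b) return(Matrix::Diagonal(store$lens[a]))
  if (a < b) store$matrices[[store_key(a, b)]]
  else Matrix::t(store$matrices[[store_key(b, a)]])
}

#' Pair similarity weight
#'
#' The total posterior mass of a pairwise matrix divided by the shorter
#' sequence length.  Row/column sums of a posterior matrix bound 1, so the
#' value lies in [0, 1]: it is close to 1 for similar sequences (most
#' residues of the shorter sequence confidently paired) and close to 0 for
#' dissimilar ones.
#'
#' @param P A pairwise posterior matrix.
#' @param len_a,len_b The two sequence lengths.
#' @return A number in [0, 1].
#' @export
pair_weight <- function(P, len_a, len_b) {
  if (min(len_a, len_b) == 0L) return(0)
  w <- sum(P) / min(len_a, len_b)
  min(w, 1)
}

#' Pair-weight matrix of a store
#'
#' @param store A \code{"posterior_store"}.
#' @param weighted If FALSE all weights are 1 (the unweighted transform).
#' @return A symmetric k x k matrix with unit diagonal.
#' @export
pair_weights <- function(store, weighted = TRUE) {
  k <- store$k
  W <- matrix(1, k, k)
  if (weighted && k >= 2L) {
    for (a in 1:(k - 1L)) {
      for (b in (a + 1L):k) {
        W[a, b] <- W[b, a] <-
          pair_weight(store_get(store, a, b), store$lens[a], store$lens[b])
      }
    }
  }
  W
}

#' Consistency transformation
#'
#' Re-estimates each pairwise matrix through all sequences of the set:
#' \deqn{P'_{ab} \gets \frac{\sum_{c} w_{ac} w_{cb}\, P_{ac} P_{cb}}
#'                          {\sum_{c'} w_{ac'} w_{c'b}},}
#' where the sum runs over every sequence \code{c} including \code{a} and
#' \code{b} themselves (self matrices are identities, so those terms
#' interpolate toward the current matrix).  Pair weights come from
#' \code{\link{pair_weight}} when \code{params$weighted_consistency} is TRUE
#' and are computed once from the input store; with all weights equal the
#' transform reduces to the unweighted average.  Within an iteration all new
#' matrices are computed from the previous iteration's store (synchronous
#' update); after each iteration entries below \code{params$cutoff} are
#' pruned, keeping the matrices sparse.
#'
#' @param store A \code{"posterior_store"}.
#' @param params An \code{\link{align_params}} (uses
#'   \code{consistency_iters}, \code{weighted_consistency}, \code{cutoff}).
#' @param prune_each Prune below-cutoff entries after every iteration
#'   (default) or only after the last one.
#' @return The transformed \code{"posterior_store"}.
#' @export
consistency_transform <- function(store, params, prune_each = TRUE) {
  iters <- params$consistency_iters
  if (iters == 0L || store$k < 2L) return(store)
  W <- pair_weights(store, params$weighted_consistency)
  k <- store$k
  for (it in seq_len(iters)) {
    new_mats <- list()
    for (a in 1:(k - 1L)) {
      for (b in (a + 1L):k) {
        num <- NULL
        den <- 0
        for (cc in 1:k) {
          wp <- W[a, cc] * W[cc, b]
          if (wp == 0) next
          term <- wp * (store_get(store, a, cc) %*% store_get(store, cc, b))
          num <- if (is.null(num)) term else num + term
          den <- den + wp
        }
        P <- as_dgc(num / den)
        if (prune_each || it == iters) {
          P@x[P@x < params$cutoff] <- 0
        }
        new_mats[[store_key(a, b)]] <- Matrix::drop0(P)
      }
    }
    store$matrices <- new_mats
  }
  store
}
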