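#' Align a sequence set by residue clustering
#'
#' Runs the full non-progressive pipeline: all-pairs partition-function
#' posteriors, consistency transformation, k-partite alignment-graph
#' construction, recursive order-constrained Fiduccia-Mattheyses clustering
#' into columns, and posterior-driven iterative refinement.  A single-
#' sequence input short-circuits to the identity alignment; two sequences
#' still run the full path.
#'
#' @param x A \code{\link{sequence_set}} or a path to an unaligned FASTA
#'   file.
#' @param params An \code{\link{align_params}}.
#' @param matrix A \code{\link{subst_matrix}}, or a matrix name/path for
#'   \code{\link{load_matrix}} (default the bundled Gonnet-family 160 PAM
#'   matrix).
#' @param trace Emit per-partition trace messages.
#' @return An object of class \code{"msaclust"}: list with the input
#'   \code{seqs}, \code{params}, the final \code{alignment}, the
#'   pre-refinement \code{clustering} alignment, the transformed posterior
#'   \code{store}, and the expected-accuracy objective before
#'   (\code{ea_clustering}) and after (\code{ea_final}) refinement.
#' @seealso \code{\link{write_alignment}}, \code{\link{sp_tc_score}}
#' @export
#' @examples
#' seqs <- sequence_set(c(a = "HEAGAWGHEE", b = "PAWHEAE", c = "HEAGWGHE"))
#' fit <- msaclust(seqs, align_params(refine_iters = 10, seed = 1))
#' fit
#' as.character(fit)
msaclust <- function(x, params = align_params(), matrix = "gonnet160",
                     trace = FALSE) {
  seqs <- if (inherits(x, "sequence_set")) x else read_fasta(x)
  if (!inherits(matrix, "subst_matrix")) matrix <- load_matrix(matrix)
  set.seed(params$seed)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(name, ": ", conditionMessage(e), call. = FALSE)
    })
  }
  k <- length(seqs$ids)
  if (k == 1L) {
    aln <- identity_alignment(seqs)
    store <- stage("posterior", posterior_store(seqs, params, matrix))
    return(structure(list(seqs = seqs, params = params, alignment = aln,
                          clustering = aln, store = store,
                          ea_clustering = 0, ea_final = 0,
                          call = match.call()),
                     class = "msaclust"))
  }
  store <- stage("posterior", posterior_store(seqs, params, matrix))
  store <- stage("consistency", consistency_transform(store, params))
  graph <- stage("graph", build_alignment_graph(store, seqs))
  clustering <- stage("clustering",
                      divisive_cluster(graph, seqs, params, trace = trace))
  final <- stage("refinement", iterative_refine(clustering, store, params))
  validate_alignment(final, seq_lengths(seqs))
  structure(list(seqs = seqs, params = params, alignment = final,
                 clustering = clustering, store = store,
                 ea_clustering = expected_accuracy(clustering, store),
                 ea_final = expected_accuracy(final, store),
                 call = match.call()),
            class = "msaclust")
}

#' @export
print.msaclust <- function(x, ...) {
  cat("Residue-clustering multiple sequence alignment\n")
  cat(sprintf("  %d sequences, lengths %d..%d; %d alignment columns\n",
              length(x$seqs$ids), min(seq_lengths(x$seqs)),
              max(seq_lengths(x$seqs)), ncol(x$alignment$pos)))
  cat(sprintf("  expected accuracy: %.3f (clustering) -> %.3f (refined)\n",
              x$ea_clustering, x$ea_final))
  invisible(x)
}

#' @export
summary.msaclust <- function(object, ...) {
  rows <- alignment_strings(object$alignment, object$seqs)
  cat("Residue-clustering multiple sequence alignment\n\n")
  print(object$params)
  cat(sprintf("\nColumns: %d (clustering produced %d)\n",
              ncol(object$alignment$pos), ncol(object$clustering$pos)))
  cat(sprintf("Expected accuracy: %.4f (clustering) -> %.4f (refined)\n\n",
              object$ea_clustering, object$ea_final))
  width <- max(nchar(object$seqs$ids)) + 2L
  for (start in seq(1L, nchar(rows[1L]), by = 60L)) {
    for (s in seq_along(rows)) {
      cat(sprintf("%-*s%s\n", width, object$seqs$ids[s],
                  substr(rows[s], start, start + 59L)))
    }
    cat("\n")
  }
  invisible(object)
}

#' @export
as.character.msaclust <- function(x, ...) {
  alignment_strings(x$alignment, x$seqs)
}

#' Per-column posterior support profile
#'
#' Plots, for each alignment column, the mean stored posterior over its
#' within-column residue pairs (0 for single-residue columns) -- a quick
#' visual of which regions of the alignment are confidently aligned.
#'
#' @param x An \code{"msaclust"} object.
#' @param ... Passed to \code{barplot}.
#' @return The support vector, invisibly.
#' @export
plot.msaclust <- function(x, ...) {
  pos <- x$alignment$pos
  k <- nrow(pos)
  support <- numeric(ncol(pos))
  if (k >= 2L && ncol(pos)) {
    for (col in seq_len(ncol(pos))) {
      pres <- which(!is.na(pos[, col]))
      if (length(pres) < 2L) next
      tot <- 0; np <- 0L
      for (ai in seq_along(pres)[-length(pres)]) {
        for (bi in (ai + 1L):length(pres)) {
          a <- pres[ai]; b <- pres[bi]
          P <- x$store$matrices[[store_key(a, b)]]
          tot <- tot + P[pos[a, col] + 1L, pos[b, col] + 1L]
          np <- np + 1L
        }
      }
      support[col] <- tot / np
    }
  }
  graphics::barplot(support, border = NA, space = 0,
                    xlab = "alignment column", ylab = "mean pair posterior",
                    ylim = c(0, 1), ...)
  invisible(support)
}
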