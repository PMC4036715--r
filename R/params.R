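#' Alignment parameters
#'
#' Bundles the scoring and pipeline parameters used throughout the aligner.
#' Defaults follow the Probalign-style parameterisation for the Gonnet-family
#' 160 PAM matrix: inverse temperature \code{beta = 0.2}, affine gap penalties
#' of -22 (open) and -1 (extension), terminal gaps free, a posterior cutoff of
#' 0.01 below which sparse matrix entries are dropped, two iterations of the
#' weighted consistency transformation and 100 iterations of random-subset
#' refinement.
#'
#' @param beta Positive inverse temperature scaling the similarity score in
#'   the Boltzmann weight \eqn{e^{\beta S(A)}}.
#' @param gap_open Gap-open score (applies to the first residue of an internal
#'   gap run); must be \eqn{\le} \code{gap_ext} \eqn{\le 0}.
#' @param gap_ext Gap-extension score per additional gap column in a run.
#' @param terminal_gap Score per gap column in a terminal run (a run touching
#'   either end of either sequence); replaces both open and extension there.
#' @param indel_variant \code{"adjacent"} allows an insertion run immediately
#'   followed by a deletion run (and vice versa); \code{"noadjacent"} requires
#'   at least one match/mismatch column between them.
#' @param cutoff Posterior probabilities strictly below this value are set to
#'   zero and dropped from the sparse matrices; in (0, 1).
#' @param consistency_iters Number of consistency-transformation iterations.
#' @param weighted_consistency Use similarity-derived pair weights (TRUE) or
#'   uniform weights (FALSE) in the consistency transformation.
#' @param multilevel Use the multilevel coarsening scheme around the
#'   Fiduccia-Mattheyses bipartitioner.
#' @param refine_iters Number of random-subset refinement iterations (the
#'   leave-one-out sweep always runs unless \code{refine = FALSE}).
#' @param refine If FALSE, skip refinement entirely.
#' @param seed Integer seed for the run's random number generator (consumed
#'   only by the random-subset refinement phase).
#'
#' @return An object of class \code{"align_params"} (a validated list).
#' @export
#' @examples
#' p <- align_params(beta = 0.2, refine_iters = 10)
#' p$gap_open
align_params <- function(beta = 0.2,
                         gap_open = -22,
                         gap_ext = -1,
                         terminal_gap = 0,
                         indel_variant = c("adjacent", "noadjacent"),
                         cutoff = 0.01,
                         consistency_iters = 2L,
                         weighted_consistency = TRUE,
                         multilevel = FALSE,
                         refine_iters = 100L,
                         refine = TRUE,
                         seed = 1L) {
  indel_variant <- match.arg(indel_variant)
  stopifnot(is.numeric(beta), length(beta) == 1L, beta > 0)
  stopifnot(is.numeric(gap_open), is.numeric(gap_ext), is.numeric(terminal_gap))
  if (!(gap_open <= gap_ext && gap_ext <= 0)) {
    stop("gap penalties must satisfy gap_open <= gap_ext <= 0")
  }
  stopifnot(is.numeric(cutoff), length(cutoff) == 1L, cutoff > 0, cutoff < 1)
  consistency_iters <- as.integer(consistency_iters)
  refine_iters <- as.integer(refine_iters)
  stopifnot(consistency_iters >= 0L, refine_iters >= 0L)
  structure(
    list(beta = beta, gap_open = gap_open, gap_ext = gap_ext,
         terminal_gap = terminal_gap, indel_variant = indel_variant,
         cutoff = cutoff, consistency_iters = consistency_iters,
         weighted_consistency = isTRUE(weighted_consistency),
         multilevel = isTRUE(multilevel), refine_iters = refine_iters,
         refine = isTRUE(refine), seed = as.integer(seed)),
    class = "align_params"
  )
}

#' @export
print.align_params <- function(x, ...) {
  cat("Alignment parameters:\n")
  cat(sprintf("  beta = %g; gaps open/ext/terminal = %g/%g/%g (%s indels)\n",
              x$beta, x$gap_open, x$gap_ext, x$terminal_gap, x$indel_variant))
  cat(sprintf("  posterior cutoff = %g; consistency: %d iteration(s), %s\n",
              x$cutoff, x$consistency_iters,
              if (x$weighted_consistency) "weighted" else "unweighted"))
  cat(sprintf("  clustering: %s FM; refinement: %s (%d random-subset iters); seed = %d\n",
              if (x$multilevel) "multilevel" else "flat",
              if (x$refine) "on" else "off", x$refine_iters, x$seed))
  invisible(x)
}
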