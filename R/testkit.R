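#' Simulate a sequence family with a known true alignment
#'
#' Draws a random ancestor sequence and derives each of k leaves
#' independently (a star phylogeny): every ancestral site is substituted
#' with probability \code{sub_rate} (uniformly over the alphabet minus the
#' current residue), deleted with probability \code{indel_rate} (run length
#' geometric with mean \code{mean_indel}), and insertions of geometric
#' length arise with probability \code{indel_rate} at every inter-site gap.
#' The induced multiple alignment of the leaves is recorded through the
#' ancestor coordinate system: one column per surviving ancestral site, and
#' one private column per inserted residue (insertions of different leaves
#' are never aligned to each other).
#'
#' @param k Number of leaf sequences (>= 2).
#' @param ancestor_len Ancestor length.
#' @param sub_rate Per-site substitution probability, in [0, 1).
#' @param indel_rate Per-site/per-gap indel initiation probability, in
#'   [0, 1).
#' @param mean_indel Mean indel run length (>= 1).
#' @param seed Integer seed; the same seed reproduces the family exactly.
#' @param alphabet Character vector of residue symbols.
#' @return An object of class \code{"synthetic_family"}: list with
#'   \code{seqs} (a \code{\link{sequence_set}}), \code{aln} (the true
#'   \code{"msa_alignment"}) and the generating \code{parameters}.
#' @export
simulate_family <- function(k = 4L, ancestor_len = 60L, sub_rate = 0.1,
                            indel_rate = 0.02, mean_indel = 1.5,
                            seed = 1L,
                            alphabet = c("A", "R", "N", "D", "C", "Q", "E",
                                         "G", "H", "I", "L", "K", "M", "F",
                                         "P", "S", "T", "W", "Y", "V")) {
  stopifnot(k >= 2L, ancestor_len >= 1L,
            sub_rate >= 0, sub_rate < 1, indel_rate >= 0, indel_rate < 1,
            mean_indel >= 1)
  set.seed(as.integer(seed))
  p_geo <- 1 / mean_indel
  for (attempt in 1:50) {
    anc <- sample(alphabet, ancestor_len, replace = TRUE)
    # per leaf: residues, and for each residue its column key
    # column keys: ancestral site i -> c(i, 0, 0); insertion at gap g of
    # leaf s, occurrence t -> c(g, s, t)
    leaf_res <- vector("list", k)
    leaf_key <- vector("list", k)
    for (s in seq_len(k)) {
      res <- character(0)
      key <- list()
      emit <- function(r, kk) {
        res[[length(res) + 1L]] <<- r
        key[[length(key) + 1L]] <<- kk
      }
      ins_at <- function(g) {
        if (stats::runif(1) < indel_rate) {
          len <- stats::rgeom(1, p_geo) + 1L
          for (t in seq_len(len)) emit(sample(alphabet, 1L), c(g, s, t))
        }
      }
      del_left <- 0L
      for (i in seq_len(ancestor_len)) {
        ins_at(i - 1L)
        if (del_left > 0L) {
          del_left <- del_left - 1L
          next
        }
        if (stats::runif(1) < indel_rate) {
          del_left <- stats::rgeom(1, p_geo)    # this site plus del_left more
          next
        }
        r <- anc[i]
        if (stats::runif(1) < sub_rate) {
          r <- sample(setdiff(alphabet, r), 1L)
        }
        emit(r, c(i, 0L, 0L))
      }
      ins_at(ancestor_len)
      leaf_res[[s]] <- unlist(res)
      leaf_key[[s]] <- key
    }
    if (any(vapply(leaf_res, length, 1L) == 0L)) next
    # assemble columns: ancestral site i has key (i,0,0); an insertion at
    # gap g of leaf s, occurrence t, has key (g,s,t) with s >= 1, which
    # sorts between sites g and g+1 -- so column order is the
    # lexicographic order of the key triples
    all_keys <- unique(do.call(rbind, lapply(leaf_key, function(x)
      do.call(rbind, x))))
    all_keys <- all_keys[order(all_keys[, 1L], all_keys[, 2L], all_keys[, 3L]),
                         , drop = FALSE]
    keys <- paste(all_keys[, 1L], all_keys[, 2L], all_keys[, 3L])
    col_of <- seq_along(keys)
    names(col_of) <- keys
    pos <- matrix(NA_integer_, k, length(keys))
    for (s in seq_len(k)) {
      kk <- vapply(leaf_key[[s]], paste, character(1), collapse = " ")
      pos[s, col_of[kk]] <- seq_along(kk) - 1L
    }
    ids <- paste0("leaf", seq_len(k))
    seqs <- sequence_set(vapply(leaf_res, paste, character(1), collapse = ""),
                         ids)
    aln <- new_alignment(ids, pos)
    validate_alignment(aln, seq_lengths(seqs))
    return(structure(list(seqs = seqs, aln = aln,
                          parameters = list(k = k, ancestor_len = ancestor_len,
                                            sub_rate = sub_rate,
                                            indel_rate = indel_rate,
                                            mean_indel = mean_indel,
                                            seed = seed)),
                     class = "synthetic_family"))
  }
  stop("failed to simulate a family with non-empty leaves in 50 attempts")
}

#' @export
print.synthetic_family <- function(x, ...) {
  cat(sprintf("Synthetic family: k=%d, ancestor length %d, sub %.3g, indel %.3g (seed %d)\n",
              x$parameters$k, x$parameters$ancestor_len, x$parameters$sub_rate,
              x$parameters$indel_rate, x$parameters$seed))
  invisible(x)
}

aligned_pairs <- function(pos, cols = seq_len(ncol(pos))) {
  out <- character(0)
  k <- nrow(pos)
  for (col in cols) {
    pres <- which(!is.na(pos[, col]))
    if (length(pres) < 2L) next
    for (ai in seq_along(pres)[-length(pres)]) {
      for (bi in (ai + 1L):length(pres)) {
        a <- pres[ai]; b <- pres[bi]
        out[[length(out) + 1L]] <-
          paste(a, pos[a, col], b, pos[b, col])
      }
    }
  }
  out
}

column_signatures <- function(pos, cols = seq_len(ncol(pos))) {
  vapply(cols, function(col) {
    pres <- which(!is.na(pos[, col]))
    paste(pres, pos[pres, col], sep = ":", collapse = ",")
  }, character(1))
}

#' Sum-of-pairs and total-column scores against a reference alignment
#'
#' SP is the fraction of the reference's aligned residue pairs (restricted
#' to core columns if a mask is given) that also share a column in the test
#' alignment; TC is the fraction of reference (core) columns whose full
#' residue content appears as an identical column of the test alignment.
#' Reference columns holding a single residue contribute no SP pairs and
#' count toward TC only when the test alignment isolates that residue in a
#' column of its own.
#'
#' @param test,ref \code{"msa_alignment"} objects over the same sequences
#'   (matched by id; sequence order may differ).
#' @param core Optional integer vector of 0-based reference column indices
#'   to score (a core mask).
#' @return A list with elements \code{sp} and \code{tc}, both in [0, 1].
#' @export
sp_tc_score <- function(test, ref, core = NULL) {
  ord <- match(ref$ids, test$ids)
  if (anyNA(ord)) stop("test and reference alignments hold different sequences")
  tpos <- test$pos[ord, , drop = FALSE]
  rpos <- ref$pos
  if (!identical(rowSums(!is.na(tpos)), rowSums(!is.na(rpos)))) {
    stop("test and reference alignments place different residue sets")
  }
  cols <- if (is.null(core)) seq_len(ncol(rpos)) else as.integer(core) + 1L
  if (any(cols < 1L | cols > ncol(rpos))) stop("core mask outside reference")
  rp <- aligned_pairs(rpos, cols)
  tp <- aligned_pairs(tpos)
  sp <- if (length(rp)) length(intersect(rp, tp)) / length(rp) else NA_real_
  tsig <- column_signatures(tpos)
  rsig <- column_signatures(rpos, cols)
  tc <- if (length(rsig)) mean(rsig %in% tsig) else NA_real_
  list(sp = sp, tc = tc)
}

#' Read a core-column mask
#'
#' Plain-text file with one 0-based reference column index per line; blank
#' lines and '#' comments ignored.
#'
#' @param path Path to the mask file.
#' @return Integer vector of 0-based column indices.
#' @export
read_core_mask <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  as.integer(lines)
}
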