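#' Build the k-partite alignment graph
#'
#' Nodes are all residues of all sequences; every surviving posterior entry
#' of the (transformed) store becomes one weighted undirected edge between
#' residues of different sequences.  Edges are held in flat vectors indexed
#' by edge id together with a per-node adjacency index.
#'
#' @param store A \code{"posterior_store"} (usually consistency-transformed).
#' @param seqs The underlying \code{\link{sequence_set}}.
#' @return An object of class \code{"alignment_graph"}: list with \code{k},
#'   \code{lens}, \code{offsets}, per-node \code{node_seq} / \code{node_pos}
#'   (0-based positions), edge vectors \code{eu}, \code{ev}, \code{ew}
#'   (1-based global node ids, eu < ev) and adjacency list \code{adj} of
#'   incident edge ids per node.
#' @export
build_alignment_graph <- function(store, seqs) {
  lens <- seq_lengths(seqs)
  stopifnot(identical(store$ids, seqs$ids))
  k <- store$k
  offsets <- c(0L, cumsum(lens))[seq_len(k)]
  n_nodes <- sum(lens)
  node_seq <- rep.int(seq_len(k), lens)
  node_pos <- unlist(lapply(lens, function(n) seq_len(n) - 1L), use.names = FALSE)
  if (is.null(node_pos)) node_pos <- integer(0)

  eu <- integer(0); ev <- integer(0); ew <- numeric(0)
  if (k >= 2L) {
    parts_u <- list(); parts_v <- list(); parts_w <- list(); np <- 0L
    for (a in 1:(k - 1L)) {
      for (b in (a + 1L):k) {
        tr <- Matrix::summary(store$matrices[[store_key(a, b)]])
        if (nrow(tr) == 0L) next
        np <- np + 1L
        parts_u[[np]] <- offsets[a] + tr$i
        parts_v[[np]] <- offsets[b] + tr$j
        parts_w[[np]] <- tr$x
      }
    }
    eu <- as.integer(unlist(parts_u, use.names = FALSE))
    ev <- as.integer(unlist(parts_v, use.names = FALSE))
    ew <- as.numeric(unlist(parts_w, use.names = FALSE))
    if (is.null(eu)) { eu <- integer(0); ev <- integer(0); ew <- numeric(0) }
  }
  adj <- rep(list(integer(0)), n_nodes)
  if (length(eu)) {
    ids <- c(seq_along(eu), seq_along(eu))
    ends <- c(eu, ev)
    sp <- split(ids, ends)
    adj[as.integer(names(sp))] <- sp
  }
  structure(list(k = k, lens = lens, offsets = offsets, n_nodes = n_nodes,
                 node_seq = node_seq, node_pos = node_pos,
                 eu = eu, ev = ev, ew = ew, adj = adj),
            class = "alignment_graph")
}

#' Region of an alignment graph
#'
#' A per-sequence set of half-open residue intervals \code{[lo_s, hi_s)}
#' (0-based) delimiting the subproblem under recursive partitioning.
#'
#' @param lo,hi Integer vectors, one entry per sequence.
#' @return A list with components \code{lo} and \code{hi}.
#' @export
region <- function(lo, hi) {
  stopifnot(length(lo) == length(hi), all(lo <= hi))
  list(lo = as.integer(lo), hi = as.integer(hi))
}

#' Weight of a cut within a region
#'
#' Sums the weights of region-internal edges whose endpoints fall on
#' opposite sides of the cut (node at position p of sequence s is on the
#' left iff p < cut[s]).
#'
#' @param graph An \code{"alignment_graph"}.
#' @param reg A \code{\link{region}}.
#' @param cut Integer vector of per-sequence cut positions, in
#'   \code{[lo_s, hi_s]}.
#' @return The total crossing weight.
#' @export
cut_weight <- function(graph, reg, cut) {
  if (!length(graph$eu)) return(0)
  su <- graph$node_seq[graph$eu]; pu <- graph$node_pos[graph$eu]
  sv <- graph$node_seq[graph$ev]; pv <- graph$node_pos[graph$ev]
  inside <- pu >= reg$lo[su] & pu < reg$hi[su] &
    pv >= reg$lo[sv] & pv < reg$hi[sv]
  lu <- pu < cut[su]; lv <- pv < cut[sv]
  sum(graph$ew[inside & (lu != lv)])
}

# ---------------------------------------------------------------------------
# Level graphs: the local, possibly coarsened, representation a single
# bipartitioning call works on.  Nodes of sequence s are 0..len_s-1 (local),
# node ids are 1-based over the flattened sequence-major order.

#' Extract the region-internal subgraph as a level graph
#'
#' Only edges with both endpoints inside the region are kept: edges leaving
#' the region are already cut and unaffected by internal moves.
#'
#' @param graph An \code{"alignment_graph"}.
#' @param reg A \code{\link{region}}.
#' @return An object of class \code{"level_graph"}: list with \code{k},
#'   \code{len} (local interval lengths), \code{off} (local node-id offsets),
#'   \code{node_w} (node weights, 1 at the finest level), edge vectors
#'   \code{eu}, \code{ev}, \code{ew} in local node ids, and \code{origin}
#'   (the region's \code{lo}, for mapping cuts back to global coordinates).
#' @export
extract_region_graph <- function(graph, reg) {
  len <- reg$hi - reg$lo
  k <- graph$k
  off <- c(0L, cumsum(len))[seq_len(k)]
  keep <- logical(length(graph$eu))
  if (length(graph$eu)) {
    su <- graph$node_seq[graph$eu]; pu <- graph$node_pos[graph$eu]
    sv <- graph$node_seq[graph$ev]; pv <- graph$node_pos[graph$ev]
    keep <- pu >= reg$lo[su] & pu < reg$hi[su] &
      pv >= reg$lo[sv] & pv < reg$hi[sv]
    eu <- off[su[keep]] + (pu[keep] - reg$lo[su[keep]]) + 1L
    ev <- off[sv[keep]] + (pv[keep] - reg$lo[sv[keep]]) + 1L
    ew <- graph$ew[keep]
  } else {
    eu <- integer(0); ev <- integer(0); ew <- numeric(0)
  }
  structure(list(k = k, len = len, off = off,
                 node_w = rep(1, sum(len)),
                 eu = as.integer(eu), ev = as.integer(ev), ew = ew,
                 origin = reg$lo),
            class = "level_graph")
}

lg_node_seq <- function(lg) rep.int(seq_len(lg$k), lg$len)
lg_node_pos <- function(lg) {
  out <- unlist(lapply(lg$len, function(n) seq_len(n) - 1L), use.names = FALSE)
  if (is.null(out)) integer(0) else out
}

lg_cut_weight <- function(lg, cut) {
  if (!length(lg$eu)) return(0)
  ns <- lg_node_seq(lg); np <- lg_node_pos(lg)
  lu <- np[lg$eu] < cut[ns[lg$eu]]
  lv <- np[lg$ev] < cut[ns[lg$ev]]
  sum(lg$ew[lu != lv])
}

#' Coarsen a level graph
#'
#' Within each sequence interval, merges consecutive node pairs at relative
#' positions (0,1), (2,3), ...; an odd leftover node stays single.  Node
#' weights add; parallel edges merge with summed weights (intra-pair edges
#' cannot exist in a k-partite graph).
#'
#' @param lg A \code{"level_graph"}.
#' @return A list with the coarser \code{graph} and a \code{map} (per
#'   sequence, the integer vector \code{starts} of fine start positions of
#'   each coarse node, with a terminal sentinel equal to the fine length).
#' @export
coarsen_graph <- function(lg) {
  clen <- (lg$len + 1L) %/% 2L
  coff <- c(0L, cumsum(clen))[seq_len(lg$k)]
  map <- lapply(seq_len(lg$k), function(s) {
    starts <- seq.int(0L, by = 2L, length.out = clen[s])
    c(starts, lg$len[s])
  })
  ns <- lg_node_seq(lg); np <- lg_node_pos(lg)
  cid <- coff[ns] + (np %/% 2L) + 1L
  nw2 <- numeric(sum(clen))
  if (length(cid)) {
    agg <- tapply(lg$node_w, cid, sum)
    nw2[as.integer(names(agg))] <- agg
  }
  if (length(lg$eu)) {
    cu <- cid[lg$eu]; cv <- cid[lg$ev]
    key <- paste(pmin(cu, cv), pmax(cu, cv))
    agg <- tapply(lg$ew, key, sum)
    pairs <- do.call(rbind, strsplit(names(agg), " "))
    eu <- as.integer(pairs[, 1L]); ev <- as.integer(pairs[, 2L])
    ew <- as.numeric(agg)
    o <- order(eu, ev)
    eu <- eu[o]; ev <- ev[o]; ew <- ew[o]
  } else {
    eu <- integer(0); ev <- integer(0); ew <- numeric(0)
  }
  cg <- structure(list(k = lg$k, len = clen, off = coff, node_w = nw2,
                       eu = eu, ev = ev, ew = ew, origin = lg$origin),
                  class = "level_graph")
  list(graph = cg, map = map)
}

#' Project a coarse cut back to the finer level
#'
#' Each coarse cut position expands to the fine start position of the first
#' right-side coarse node, so the projected cut separates exactly the same
#' node sets and has the same cut weight.
#'
#' @param cut Integer vector of coarse per-sequence cut positions.
#' @param map The \code{map} returned by \code{\link{coarsen_graph}}.
#' @return The fine cut (integer vector).
#' @export
uncoarsen_project <- function(cut, map) {
  vapply(seq_along(cut), function(s) map[[s]][cut[s] + 1L], integer(1))
}

# Midpoint initial cut: smallest position with at least half the interval's
# node weight on the left (plain midpoint when all node weights are 1).
midpoint_cut <- function(lg) {
  vapply(seq_len(lg$k), function(s) {
    n <- lg$len[s]
    if (n == 0L) return(0L)
    w <- lg$node_w[lg$off[s] + seq_len(n)]
    cw <- c(0, cumsum(w))
    as.integer(which.min(abs(cw - sum(w) / 2))) - 1L
  }, integer(1))
}

# Core Fiduccia-Mattheyses pass loop on a level graph.
#
# Moves are block moves: shifting one sequence's cut to any unlocked
# position moves the whole block of residues between the old and new cut
# position to the other side.  A block's nodes are locked for the rest of
# the pass.  Gains are exact (no intra-block edges in a k-partite graph).
# Balance: no accepted state may leave a side with node weight below
# max(0, floor((total - kbal) / 2)); ties between equal-gain moves break by
# smaller block size, lower sequence index, then leftward direction.
#
# When a pass brings no improvement, up to `max_kicks` continuation passes
# are run from the trajectory's end state (instead of terminating at the
# reverted best state): a deterministic kick that lets the search leave the
# basin of the first greedy trajectory.  The returned cut is still the best
# state ever visited.
fm_core <- function(lg, init_cut, kbal, max_passes = 100L, max_kicks = 1L) {
  k <- lg$k
  n_nodes <- sum(lg$len)
  ns <- lg_node_seq(lg); np <- lg_node_pos(lg)
  tw <- sum(lg$node_w)
  minside <- max(0, floor((tw - kbal) / 2))

  # adjacency as flat vectors for speed
  nbr <- rep(list(NULL), n_nodes)
  if (length(lg$eu)) {
    idx <- c(seq_along(lg$eu), seq_along(lg$eu))
    ends <- c(lg$eu, lg$ev)
    others <- c(lg$ev, lg$eu)
    sp_o <- split(others, ends)
    sp_w <- split(lg$ew[idx], ends)
    for (nm in names(sp_o)) nbr[[as.integer(nm)]] <-
        list(o = sp_o[[nm]], w = sp_w[[nm]])
  }

  state_from_cut <- function(cut) {
    left <- np < cut[ns]
    wl <- numeric(n_nodes); wr <- numeric(n_nodes)
    if (length(lg$eu)) {
      ends <- c(lg$eu, lg$ev)
      others <- c(lg$ev, lg$eu)
      w2 <- c(lg$ew, lg$ew)
      agg <- rowsum(cbind(w2 * left[others], w2 * !left[others]), ends)
      at <- as.integer(rownames(agg))
      wl[at] <- agg[, 1L]
      wr[at] <- agg[, 2L]
    }
    list(cut = cut, left = left, wl = wl, wr = wr,
         Lw = sum(lg$node_w[left]), Rw = sum(lg$node_w[!left]),
         W = sum(lg$ew[(np[lg$eu] < cut[ns[lg$eu]]) !=
                         (np[lg$ev] < cut[ns[lg$ev]])]))
  }

  if (n_nodes == 0L) return(init_cut)
  eps <- 1e-12
  # a feasible state always beats an infeasible one (the initial cut can
  # violate the balance bound at coarse levels, where node weights are > 1)
  feasible <- function(s) min(s$Lw, s$Rw) >= minside - eps
  st <- state_from_cut(init_cut)
  best_cut <- st$cut
  best_W <- st$W
  best_ok <- feasible(st)
  kicks <- 0L

  for (pass in seq_len(max_passes)) {
    pass_start_W <- st$W
    pass_start_ok <- feasible(st)
    lockmin <- integer(k)          # cut may not go below
    lockmax <- lg$len              # nor above
    pass_best_W <- st$W
    pass_best_ok <- pass_start_ok
    pass_best_cut <- st$cut
    repeat {
      pick <- NULL    # list(gain, d, s, dir, mw)
      for (s in seq_len(k)) {
        cs <- st$cut[s]
        # rightward shift: nodes at local pos cs .. lockmax-1 move R -> L
        if (cs < lockmax[s]) {
          ids <- lg$off[s] + (cs:(lockmax[s] - 1L)) + 1L
          g <- cumsum(st$wl[ids] - st$wr[ids])
          mw <- cumsum(lg$node_w[ids])
          mina <- pmin(st$Lw + mw, st$Rw - mw)
          feas <- (mina >= minside - eps) | (mina > min(st$Lw, st$Rw) + eps)
          if (any(feas)) {
            gf <- g; gf[!feas] <- -Inf
            d <- which.max(gf)          # smallest d on ties
            cand <- list(gain = g[d], d = d, s = s, dir = 1L, mw = mw[d])
            better <- is.null(pick) || cand$gain > pick$gain + eps ||
              (abs(cand$gain - pick$gain) <= eps &&
                 (cand$d < pick$d ||
                    (cand$d == pick$d && cand$s < pick$s)))
            if (better) pick <- cand
          }
        }
        # leftward shift: nodes at cs-1 .. lockmin move L -> R
        if (cs > lockmin[s]) {
          ids <- lg$off[s] + ((cs - 1L):lockmin[s]) + 1L
          g <- cumsum(st$wr[ids] - st$wl[ids])
          mw <- cumsum(lg$node_w[ids])
          mina <- pmin(st$Rw + mw, st$Lw - mw)
          feas <- (mina >= minside - eps) | (mina > min(st$Lw, st$Rw) + eps)
          if (any(feas)) {
            gf <- g; gf[!feas] <- -Inf
            d <- which.max(gf)
            cand <- list(gain = g[d], d = d, s = s, dir = -1L, mw = mw[d])
            better <- is.null(pick) || cand$gain > pick$gain + eps ||
              (abs(cand$gain - pick$gain) <= eps &&
                 (cand$d < pick$d ||
                    (cand$d == pick$d && (cand$s < pick$s ||
                       (cand$s == pick$s && pick$dir == 1L)))))
            if (better) pick <- cand
          }
        }
      }
      if (is.null(pick)) break
      s <- pick$s; d <- pick$d
      cs0 <- st$cut[s]
      if (pick$dir == 1L) {
        moved <- lg$off[s] + (cs0:(cs0 + d - 1L)) + 1L
        st$cut[s] <- cs0 + d
        lockmin[s] <- st$cut[s]
        to_left <- TRUE
      } else {
        moved <- lg$off[s] + ((cs0 - 1L):(cs0 - d)) + 1L
        st$cut[s] <- cs0 - d
        lockmax[s] <- st$cut[s]
        to_left <- FALSE
      }
      # a block move of size d is a trajectory of d unit moves; its
      # intermediate states are feasible visited states too, so the
      # classical best-prefix rule applies to them
      if (d > 1L) {
        gains <- if (to_left) st$wl[moved] - st$wr[moved]
                 else st$wr[moved] - st$wl[moved]
        cg <- cumsum(gains)
        mwp <- cumsum(lg$node_w[moved])
        for (t in seq_len(d - 1L)) {
          Wt <- st$W - cg[t]
          Lt <- if (to_left) st$Lw + mwp[t] else st$Lw - mwp[t]
          Rt <- if (to_left) st$Rw - mwp[t] else st$Rw + mwp[t]
          okt <- min(Lt, Rt) >= minside - eps
          if ((okt && !pass_best_ok) ||
              (okt == pass_best_ok && Wt < pass_best_W - eps)) {
            pass_best_W <- Wt
            pass_best_ok <- okt
            pass_best_cut <- st$cut
            pass_best_cut[s] <- cs0 + if (to_left) t else -t
          }
        }
      }
      for (u in moved) {
        st$left[u] <- to_left
        nb <- nbr[[u]]
        if (!is.null(nb)) {
          if (to_left) {
            for (t in seq_along(nb$o)) {
              v <- nb$o[t]
              st$wr[v] <- st$wr[v] - nb$w[t]
              st$wl[v] <- st$wl[v] + nb$w[t]
            }
          } else {
            for (t in seq_along(nb$o)) {
              v <- nb$o[t]
              st$wl[v] <- st$wl[v] - nb$w[t]
              st$wr[v] <- st$wr[v] + nb$w[t]
            }
          }
        }
      }
      if (to_left) {
        st$Lw <- st$Lw + pick$mw; st$Rw <- st$Rw - pick$mw
      } else {
        st$Lw <- st$Lw - pick$mw; st$Rw <- st$Rw + pick$mw
      }
      st$W <- st$W - pick$gain
      ok <- feasible(st)
      if ((ok && !pass_best_ok) ||
          (ok == pass_best_ok && st$W < pass_best_W - eps)) {
        pass_best_W <- st$W
        pass_best_ok <- ok
        pass_best_cut <- st$cut
      }
    }
    if ((pass_best_ok && !best_ok) ||
        (pass_best_ok == best_ok && pass_best_W < best_W - eps)) {
      best_W <- pass_best_W
      best_ok <- pass_best_ok
      best_cut <- pass_best_cut
    }
    improved <- (pass_best_ok && !pass_start_ok) ||
      (pass_best_ok == pass_start_ok && pass_best_W < pass_start_W - eps)
    if (improved) {
      st <- state_from_cut(pass_best_cut)
      kicks <- 0L
    } else if (kicks < max_kicks &&
               !identical(as.integer(st$cut), as.integer(pass_best_cut))) {
      kicks <- kicks + 1L          # continue from the trajectory end state
    } else {
      break
    }
  }
  attr(best_cut, "weight") <- best_W
  attr(best_cut, "passes") <- pass
  best_cut
}

#' Order-constrained Fiduccia-Mattheyses bipartition of a region
#'
#' Starting from the per-sequence midpoint cut, repeatedly shifts single
#' sequences' cut positions (block moves) by maximum gain under the balance
#' bound (side node weights may not drop below
#' \code{max(0, floor((total - k)/2))}, i.e. sides differ by at most k),
#' in passes in which each residue moves at most once; the best cut seen in
#' a pass seeds the next, and the search stops when a pass brings no
#' improvement.
#'
#' @param graph An \code{"alignment_graph"}.
#' @param reg A \code{\link{region}} with at least 2 residues (degenerate
#'   regions short-circuit to the midpoint cut).
#' @param params An \code{\link{align_params}} (unused fields ignored).
#' @return Integer vector of global cut positions with attributes
#'   \code{"weight"} (cut weight) and \code{"passes"}.
#' @export
fm_bipartition <- function(graph, reg, params = align_params()) {
  lg <- extract_region_graph(graph, reg)
  init <- midpoint_cut(lg)
  if (sum(lg$len) < 2L) {
    out <- reg$lo + init
    attr(out, "weight") <- 0
    return(out)
  }
  cut <- fm_core(lg, init, kbal = graph$k)
  out <- reg$lo + as.integer(cut)
  attributes(out) <- c(attributes(out), attributes(cut)[c("weight", "passes")])
  out
}

#' Multilevel bipartition of a region
#'
#' Coarsens the region subgraph by merging consecutive residue pairs until
#' every sequence interval has at most 2 nodes, partitions the coarsest
#' graph with the Fiduccia-Mattheyses core, then projects the cut back level
#' by level, re-running the FM refinement (seeded with the projected cut) at
#' each level down to the original graph.
#'
#' @inheritParams fm_bipartition
#' @return Integer vector of global cut positions with a \code{"weight"}
#'   attribute.
#' @export
multilevel_bipartition <- function(graph, reg, params = align_params()) {
  lg <- extract_region_graph(graph, reg)
  if (sum(lg$len) < 2L) {
    out <- reg$lo + midpoint_cut(lg)
    attr(out, "weight") <- 0
    return(out)
  }
  levels <- list(lg)
  maps <- list()
  while (any(levels[[length(levels)]]$len > 2L)) {
    co <- coarsen_graph(levels[[length(levels)]])
    maps[[length(maps) + 1L]] <- co$map
    levels[[length(levels) + 1L]] <- co$graph
  }
  nl <- length(levels)
  cut <- fm_core(levels[[nl]], midpoint_cut(levels[[nl]]), kbal = graph$k)
  if (nl > 1L) {
    for (lev in (nl - 1L):1L) {
      cut <- uncoarsen_project(as.integer(cut), maps[[lev]])
      cut <- fm_core(levels[[lev]], cut, kbal = graph$k)
    }
  }
  out <- reg$lo + as.integer(cut)
  attributes(out) <- c(attributes(out), attributes(cut)[c("weight", "passes")])
  out
}

#' Divisive residue clustering into alignment columns
#'
#' Recursively bipartitions the alignment graph (leftmost-first, depth
#' first): every cut is a single set of per-sequence split positions, so the
#' emerging clustering is conflict-free by construction, and recursion stops
#' when a region holds at most one residue per sequence (ambiguity-free);
#' such terminal regions become alignment columns, concatenated left to
#' right.  A degenerate cut that leaves one side empty while the region is
#' non-terminal is replaced by a forced midpoint split of the longest
#' sequence interval.
#'
#' @param graph An \code{"alignment_graph"}.
#' @param seqs The underlying \code{\link{sequence_set}}.
#' @param params An \code{\link{align_params}} (\code{multilevel} selects the
#'   partitioner).
#' @param trace If TRUE, emit one message per partition step (region bounds,
#'   chosen cut, cut weight, pass count).
#' @return An \code{"msa_alignment"}.
#' @export
divisive_cluster <- function(graph, seqs, params = align_params(),
                             trace = FALSE) {
  k <- graph$k
  lens <- graph$lens
  bipart <- if (params$multilevel) multilevel_bipartition else fm_bipartition
  cols <- new.env(parent = emptyenv())
  cols$list <- vector("list", 2L * sum(lens) + 1L)
  cols$n <- 0L

  rec <- function(lo, hi) {
    size <- hi - lo
    tot <- sum(size)
    if (tot == 0L) return(invisible(NULL))
    if (all(size <= 1L)) {
      col <- rep(NA_integer_, k)
      col[size == 1L] <- lo[size == 1L]
      cols$n <- cols$n + 1L
      cols$list[[cols$n]] <- col
      return(invisible(NULL))
    }
    reg <- region(lo, hi)
    cut <- as.integer(bipart(graph, reg, params))
    if (all(cut == lo) || all(cut == hi)) {
      smax <- which.max(size)
      cut <- lo
      cut[smax] <- lo[smax] + size[smax] %/% 2L
      if (cut[smax] == lo[smax]) cut[smax] <- lo[smax] + 1L
    }
    if (trace) {
      message(sprintf("region [%s) cut %s weight %.4g",
                      paste(lo, hi, sep = ",", collapse = " "),
                      paste(cut, collapse = " "),
                      cut_weight(graph, reg, cut)))
    }
    rec(lo, cut)
    rec(cut, hi)
  }
  rec(rep(0L, k), lens)
  pos <- do.call(cbind, cols$list[seq_len(cols$n)])
  if (is.null(pos)) pos <- matrix(NA_integer_, k, 0L)
  aln <- new_alignment(seqs$ids, pos)
  validate_alignment(aln, lens)
  aln
}
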