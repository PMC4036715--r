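test_that("the alignment graph mirrors the store exactly", {
  # single sequence: nodes only
  seqs1 <- sequence_set(c(a = "ABC"))
  st1 <- structure(list(k = 1L, ids = "a", lens = 3L, matrices = list()),
                   class = "posterior_store")
  g1 <- build_alignment_graph(st1, seqs1)
  expect_equal(g1$n_nodes, 3)
  expect_length(g1$eu, 0)

  set.seed(14)
  st <- random_store(c(4, 5, 3))
  seqs <- sequence_set(c(s1 = "AAAA", s2 = "AAAAA", s3 = "AAA"))
  g <- build_alignment_graph(st, seqs)
  nnz <- sum(vapply(st$matrices, Matrix::nnzero, 1))
  expect_length(g$ew, nnz)
  expect_equal(sum(g$ew), sum(vapply(st$matrices, sum, 1)))
  # k-partite: no intra-sequence edges
  expect_true(all(g$node_seq[g$eu] != g$node_seq[g$ev]))
})

test_that("cut_weight matches a brute-force recount and boundary cuts cost 0", {
  set.seed(15)
  for (rep in 1:20) {
    k <- sample(2:3, 1)
    lens <- sample(2:6, k, replace = TRUE)
    g <- random_alignment_graph(k, lens)
    reg <- region(rep(0L, k), lens)
    expect_equal(cut_weight(g, reg, rep(0L, k)), 0)
    expect_equal(cut_weight(g, reg, lens), 0)
    cut <- vapply(lens, function(n) sample(0:n, 1), integer(1))
    brute <- 0
    for (e in seq_along(g$eu)) {
      lu <- g$node_pos[g$eu[e]] < cut[g$node_seq[g$eu[e]]]
      lv <- g$node_pos[g$ev[e]] < cut[g$node_seq[g$ev[e]]]
      if (lu != lv) brute <- brute + g$ew[e]
    }
    expect_equal(cut_weight(g, reg, cut), brute)
  }
})

test_that("FM never worsens the midpoint cut and usually finds the optimum", {
  set.seed(123)
  n_inst <- 200
  gaps <- numeric(n_inst)
  for (rep in seq_len(n_inst)) {
    k <- sample(2:3, 1)
    lens <- sample(2:6, k, replace = TRUE)
    g <- random_alignment_graph(k, lens)
    reg <- region(rep(0L, k), lens)
    mid <- lens %/% 2L      # the partitioner's midpoint initialization
    cut <- fm_bipartition(g, reg)
    w <- cut_weight(g, reg, as.integer(cut))
    expect_lte(w, cut_weight(g, reg, mid) + 1e-12)
    best <- exhaustive_best_cut(g)
    expect_gte(w, best - 1e-12)
    gaps[rep] <- if (best > 1e-12) (w - best) / best else as.numeric(w > 1e-12)
  }
  expect_gte(mean(gaps < 1e-9), 0.9)
  expect_lt(mean(gaps), 0.05)
})

test_that("a pre-separated graph keeps its zero midpoint cut", {
  # two sequences, edges only within left halves and within right halves
  M <- matrix(0, 4, 4)
  M[1, 1] <- M[2, 2] <- M[3, 3] <- M[4, 4] <- 0.9
  st <- structure(list(k = 2L, ids = c("a", "b"), lens = c(4L, 4L),
                       matrices = list("1_2" = as_test_sparse(M))),
                  class = "posterior_store")
  seqs <- sequence_set(c(a = "AAAA", b = "AAAA"))
  g <- build_alignment_graph(st, seqs)
  cut <- fm_bipartition(g, region(c(0L, 0L), c(4L, 4L)))
  expect_equal(as.integer(cut), c(2L, 2L))
  expect_equal(attr(cut, "weight"), 0)
})

test_that("coarsening pairs consecutive nodes and conserves weight", {
  set.seed(31)
  g <- random_alignment_graph(3, c(5, 4, 2))
  lg <- extract_region_graph(g, region(rep(0L, 3), c(5L, 4L, 2L)))
  co <- coarsen_graph(lg)
  expect_equal(co$graph$len, c(3L, 2L, 1L))
  expect_equal(co$graph$node_w[1:3], c(2, 2, 1))     # lengths 5 -> (2,2,1)
  expect_equal(sum(co$graph$node_w), sum(lg$node_w))
  expect_equal(sum(co$graph$ew), sum(lg$ew))
  # projection preserves the separated node sets and the cut weight
  cut <- c(2L, 1L, 1L)
  fine <- uncoarsen_project(cut, co$map)
  expect_equal(fine, c(4L, 2L, 2L))
  reg <- region(rep(0L, 3), c(5L, 4L, 2L))
  lg_w <- vapply(list(cut), function(cc) {
    # coarse cut weight computed on the coarse graph
    ns <- rep.int(1:3, co$graph$len)
    np <- unlist(lapply(co$graph$len, function(n) seq_len(n) - 1L))
    lu <- np[co$graph$eu] < cc[ns[co$graph$eu]]
    lv <- np[co$graph$ev] < cc[ns[co$graph$ev]]
    sum(co$graph$ew[lu != lv])
  }, numeric(1))
  expect_equal(cut_weight(g, reg, fine), lg_w)
})

test_that("multilevel bipartition matches FM behaviour and the oracle family", {
  set.seed(77)
  for (rep in 1:20) {
    k <- sample(2:3, 1)
    lens <- sample(2:6, k, replace = TRUE)
    g <- random_alignment_graph(k, lens)
    reg <- region(rep(0L, k), lens)
    cut <- multilevel_bipartition(g, reg)
    w <- cut_weight(g, reg, as.integer(cut))
    expect_gte(w, exhaustive_best_cut(g) - 1e-12)
  }
  # a region that is already coarsest reduces to plain FM
  g <- random_alignment_graph(2, c(2, 2))
  reg <- region(c(0L, 0L), c(2L, 2L))
  expect_equal(as.integer(multilevel_bipartition(g, reg)),
               as.integer(fm_bipartition(g, reg)))
})

test_that("divisive clustering yields a valid, residue-conserving alignment", {
  # identical length-6 sequences with strongly diagonal affinities align
  # gaplessly
  st <- diagonal_store(3, 6)
  seqs <- sequence_set(c(s1 = "ABCABC", s2 = "ABCABC", s3 = "ABCABC"))
  g <- build_alignment_graph(st, seqs)
  aln <- divisive_cluster(g, seqs)
  expect_equal(ncol(aln$pos), 6)
  expect_true(all(!is.na(aln$pos)))
  expect_equal(aln$pos[1, ], 0:5, ignore_attr = TRUE)

  # random graphs: invariants audited by validate_alignment
  set.seed(19)
  for (rep in 1:10) {
    k <- sample(2:4, 1)
    lens <- sample(1:7, k, replace = TRUE)
    g <- random_alignment_graph(k, lens, density = 0.3)
    seqs <- sequence_set(vapply(lens, function(n)
      paste(rep("A", n), collapse = ""), character(1)), paste0("s", 1:k))
    aln <- divisive_cluster(g, seqs)
    expect_true(validate_alignment(aln, lens))
    expect_lte(max(colSums(!is.na(aln$pos))), k)
  }
})

test_that("FM pass loop terminates on graphs with no edges", {
  g <- random_alignment_graph(2, c(3, 3), density = 0)
  reg <- region(c(0L, 0L), c(3L, 3L))
  cut <- fm_bipartition(g, reg)
  expect_equal(attr(cut, "weight"), 0)
})
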