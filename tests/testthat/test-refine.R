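test_that("expected_accuracy sums stored posteriors over within-column pairs", {
  # single sequence: no pairs
  st1 <- structure(list(k = 1L, ids = "a", lens = 4L, matrices = list()),
                   class = "posterior_store")
  aln1 <- new_alignment("a", matrix(0:3, 1))
  expect_equal(expected_accuracy(aln1, st1), 0)

  st <- diagonal_store(2, 4, p = 0.9)
  aln <- new_alignment(c("s1", "s2"), matrix(rep(0:3, each = 2), 2))
  expect_equal(expected_accuracy(aln, st), 3.6)
  # recomputation equals the definitional double loop on a random case
  set.seed(4)
  st2 <- random_store(c(5, 4, 6))
  fam_pos <- rbind(c(0:4, NA), c(NA, 0:3, NA) , 0:5)
  aln2 <- new_alignment(c("s1", "s2", "s3"), fam_pos)
  manual <- 0
  for (col in 1:6) {
    pres <- which(!is.na(fam_pos[, col]))
    if (length(pres) >= 2) {
      for (a in pres[-length(pres)]) for (b in pres[pres > a]) {
        manual <- manual +
          as.matrix(store_get(st2, a, b))[fam_pos[a, col] + 1, fam_pos[b, col] + 1]
      }
    }
  }
  expect_equal(expected_accuracy(aln2, st2), manual)
})

test_that("two-sequence group realignment attains the dense NW optimum", {
  set.seed(8)
  toy <- toy_matrix()
  p <- align_params(beta = 0.5, gap_open = -4, gap_ext = -1, cutoff = 1e-9)
  for (rep in 1:10) {
    a <- random_toy_seq(sample(3:8, 1))
    b <- random_toy_seq(sample(3:8, 1))
    seqs <- sequence_set(c(x = a, y = b))
    st <- posterior_store(seqs, p, toy)
    # start from the ugliest valid alignment: fully staggered, no pairs
    pos <- matrix(NA_integer_, 2, nchar(a) + nchar(b))
    pos[1, seq_len(nchar(a))] <- seq_len(nchar(a)) - 1L
    pos[2, nchar(a) + seq_len(nchar(b))] <- seq_len(nchar(b)) - 1L
    aln <- new_alignment(c("x", "y"), pos)
    out <- group_realign(aln, 1L, st)
    expect_true(validate_alignment(out, c(nchar(a), nchar(b))))
    expect_equal(expected_accuracy(out, st),
                 nw_oracle_value(as.matrix(store_get(st, 1, 2))),
                 tolerance = 1e-12)
  }
})

test_that("realigning an already optimal split leaves the objective unchanged", {
  st <- diagonal_store(2, 5, p = 0.8)
  aln <- new_alignment(c("s1", "s2"), matrix(rep(0:4, each = 2), 2))
  out <- group_realign(aln, 1L, st)
  expect_equal(expected_accuracy(out, st), expected_accuracy(aln, st))
})

test_that("a zero-posterior store still produces a valid merge", {
  st <- structure(list(k = 2L, ids = c("s1", "s2"), lens = c(3L, 4L),
                       matrices = list("1_2" = as_test_sparse(matrix(0, 3, 4)))),
                  class = "posterior_store")
  pos <- matrix(NA_integer_, 2, 7)
  pos[1, 1:3] <- 0:2; pos[2, 4:7] <- 0:3
  out <- group_realign(new_alignment(c("s1", "s2"), pos), 1L, st)
  expect_true(validate_alignment(out, c(3L, 4L)))
})

test_that("refinement is monotone in expected accuracy at every step", {
  set.seed(12)
  toy <- toy_matrix()
  p <- align_params(beta = 0.4, gap_open = -3, gap_ext = -1, cutoff = 0.01,
                    consistency_iters = 0)
  seqs <- sequence_set(c(a = "ABCABBA", b = "ABCBBA", c = "BCABBAC",
                         d = "ABCABB"))
  st <- posterior_store(seqs, p, toy)
  g <- build_alignment_graph(st, seqs)
  aln <- divisive_cluster(g, seqs, p)
  ea <- expected_accuracy(aln, st)
  dense <- msaclust:::dense_store(st)
  for (s in 1:4) {
    aln <- group_realign(aln, s, st, dense = dense)
    ea2 <- expected_accuracy(aln, st)
    expect_gte(ea2, ea - 1e-9)
    ea <- ea2
  }
  for (it in 1:25) {
    grp <- sample.int(4, sample.int(3, 1))
    aln <- group_realign(aln, grp, st, dense = dense)
    ea2 <- expected_accuracy(aln, st)
    expect_gte(ea2, ea - 1e-9)
    ea <- ea2
  }
  expect_true(validate_alignment(aln, seq_lengths(seqs)))
})

test_that("phase 1 collapses superfluous near-all-gap columns", {
  # three identical sequences, padded so the last residue of each sits in a
  # private column: 3 extra columns that refinement should merge
  st <- diagonal_store(3, 4, p = 0.9)
  pos <- matrix(NA_integer_, 3, 6)
  pos[, 1:3] <- rep(0:2, each = 3)
  pos[1, 4] <- 3L; pos[2, 5] <- 3L; pos[3, 6] <- 3L
  aln <- new_alignment(paste0("s", 1:3), pos)
  p <- align_params(refine_iters = 0)
  out <- iterative_refine(aln, st, p)
  expect_lt(ncol(out$pos), 6)
  expect_gte(expected_accuracy(out, st), expected_accuracy(aln, st))
  expect_equal(ncol(out$pos), 4)      # fully collapsed to the diagonal
})

test_that("refinement is deterministic under a fixed seed and skippable", {
  set.seed(3)
  st <- random_store(c(5, 5, 5))
  pos <- matrix(rep(0:4, each = 3), 3)
  aln <- new_alignment(paste0("s", 1:3), pos)
  p <- align_params(refine_iters = 20)
  set.seed(99); out1 <- iterative_refine(aln, st, p)
  set.seed(99); out2 <- iterative_refine(aln, st, p)
  expect_identical(out1$pos, out2$pos)
  off <- align_params(refine = FALSE)
  expect_identical(iterative_refine(aln, st, off)$pos, aln$pos)
})
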