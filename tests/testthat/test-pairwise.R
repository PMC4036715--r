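toy <- toy_matrix()
tp <- function(cutoff = 1e-12, ...) {
  align_params(beta = 0.4, gap_open = -3, gap_ext = -1, terminal_gap = 0,
               cutoff = cutoff, ...)
}

test_that("alignment_weight scores match, gap and terminal conventions", {
  p <- tp()
  expect_equal(alignment_weight("", "", p, toy), 1)
  expect_equal(alignment_weight("A", "A", p, toy), exp(0.4 * 2))
  # AC- / A-G: match A:A, then gap in b (internal? b has 'AG', the gap in b
  # at column 2 is followed by G -> internal for neither end? column 2 is a
  # gap in b's row between A and G: j=1, n=2 -> internal open; column 3 is
  # a gap in a's row after both a-residues consumed: i=2=m -> terminal
  w <- alignment_weight("AC-", "A-G", p, toy)
  expect_equal(w, exp(0.4 * (2 + p$gap_open + p$terminal_gap)))
  # leading gap is terminal
  expect_equal(alignment_weight("-A", "BA", p, toy),
               exp(0.4 * (p$terminal_gap + 2)))
})

test_that("tiny partition functions match hand enumeration", {
  p <- tp()
  # a = b = "A": match, and the two orderings of the terminal gap pair
  expect_equal(partition_total(forward_partition("A", "A", p, toy), log = FALSE),
               exp(0.4 * 2) + 2)
  # noadjacent forbids the all-gap orderings entirely
  pn <- tp(indel_variant = "noadjacent")
  expect_equal(partition_total(forward_partition("A", "A", pn, toy), log = FALSE),
               exp(0.4 * 2))
  # empty vs empty: only the empty alignment
  expect_equal(partition_total(forward_partition("", "", p, toy), log = FALSE), 1)
  # one-sided: single terminal gap run of weight 1
  expect_equal(partition_total(forward_partition("AB", "", p, toy), log = FALSE), 1)
})

test_that("partition function equals the enumeration oracle on random pairs", {
  set.seed(42)
  for (variant in c("adjacent", "noadjacent")) {
    p <- tp(indel_variant = variant)
    for (rep in 1:40) {
      a <- random_toy_seq(sample(0:5, 1))
      b <- random_toy_seq(sample(0:5, 1))
      oracle <- enumerate_pair(a, b, p, toy)
      z <- partition_total(forward_partition(a, b, p, toy), log = FALSE)
      expect_equal(z, oracle$Z, tolerance = 1e-9)
      if (nzchar(a) && nzchar(b)) {
        P <- as.matrix(posterior_matrix(a, b, p, toy))
        expect_equal(P, unname(oracle$posterior), tolerance = 1e-8,
                     ignore_attr = TRUE)
      }
    }
  }
})

test_that("forward and reverse totals agree and reversal transposes tables", {
  set.seed(7)
  p <- tp()
  for (rep in 1:20) {
    a <- random_toy_seq(sample(1:50, 1))
    b <- random_toy_seq(sample(1:50, 1))
    lf <- partition_total(forward_partition(a, b, p, toy))
    lr <- partition_total(reverse_partition(a, b, p, toy))
    expect_equal(lf, lr, tolerance = 1e-9)
  }
})

test_that("posterior rows and columns are probability-bounded and symmetric", {
  set.seed(11)
  p <- align_params(cutoff = 1e-6)
  g <- load_matrix("gonnet160")
  aas <- g$alphabet
  for (rep in 1:10) {
    a <- paste(sample(aas, sample(5:50, 1), TRUE), collapse = "")
    b <- paste(sample(aas, sample(5:50, 1), TRUE), collapse = "")
    P <- posterior_matrix(a, b, p, g)
    expect_lte(max(Matrix::rowSums(P)), 1 + 1e-6)
    expect_lte(max(Matrix::colSums(P)), 1 + 1e-6)
    Pt <- posterior_matrix(b, a, p, g)
    expect_equal(as.matrix(Pt), t(as.matrix(P)), tolerance = 1e-9)
  }
})

test_that("large beta concentrates the posterior on the optimal alignment", {
  # unique optimal alignment: identical sequences align on the diagonal
  p <- align_params(beta = 5, gap_open = -3, gap_ext = -1, cutoff = 1e-9)
  P <- as.matrix(posterior_matrix("ABCA", "ABCA", p, toy))
  expect_true(all(diag(P) > 0.99))
  best <- arrayInd(which(P == max(P)), dim(P))
  expect_true(all(best[, 1] == best[, 2]))
})

test_that("raising the cutoff never adds posterior entries", {
  set.seed(3)
  a <- random_toy_seq(12); b <- random_toy_seq(10)
  lo <- posterior_matrix(a, b, tp(), toy)
  hi <- posterior_matrix(a, b, tp(cutoff = 0.05), toy)
  slo <- Matrix::summary(lo); shi <- Matrix::summary(hi)
  expect_true(all(paste(shi$i, shi$j) %in% paste(slo$i, slo$j)))
  expect_gte(length(slo$x), length(shi$x))
})

test_that("posterior dumps are 0-based three-column tables", {
  p <- tp()
  P <- posterior_matrix("AB", "AB", p, toy)
  f <- withr::local_tempfile()
  dump_posterior(P, f)
  tab <- utils::read.table(f)
  expect_equal(ncol(tab), 3)
  expect_gte(min(tab[, 1]), 0)
  expect_equal(nrow(tab), Matrix::nnzero(P))
})
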