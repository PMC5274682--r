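# Cyclic-profile local alignment and weight-matrix normalization.

test_that("column normalization matches the mean-0/variance-1 definition", {
  M <- weight_matrix(cbind(c(1, 1, 1, 1), c(2, 0, 0, 0)), normalize = TRUE)
  expect_equal(unname(M[, 1]), rep(0, 4))
  expect_equal(unname(M[, 2]), c(3, -1, -1, -1) / sqrt(3), tolerance = 1e-9)
  # idempotence
  expect_equal(unclass(normalize_weight_matrix(M)), unclass(M),
               tolerance = 1e-9)
  # every column of a random normalized matrix has mean 0, pop variance 1
  R <- random_weight_matrix(9, seed = 4)
  expect_equal(unname(colMeans(R)), rep(0, 9), tolerance = 1e-9)
  expect_equal(unname(colMeans(R^2)), rep(1, 9), tolerance = 1e-9)
  expect_error(weight_matrix(matrix(c(1, NA, 1, 1, 1, 1, 1, 1), 4)),
               "finite")
})

test_that("trivial alignments behave as forced: zero matrix and perfect tandem", {
  S <- "ACGTACGT"
  zero <- weight_matrix(matrix(0, 4, 4), normalize = FALSE)
  expect_equal(local_align_periodic(S, zero)$score, 0)
  M <- consensus_weight_matrix("ACGT")
  a <- local_align_periodic(S, M)
  expect_equal(sum(a$path$op == "match"), 8)
  expect_equal(a$phase, 1L)
  expect_equal(a$seq_start, 1L)
  expect_equal(a$seq_end, 8L)
  # every step scores the consensus weight of a (+1,-1,-1,-1) column
  expect_equal(a$score, 8 * sqrt(3), tolerance = 1e-9)
  # empty sequence: score 0, empty path
  e <- local_align_periodic("", M)
  expect_equal(e$score, 0)
  expect_equal(nrow(e$path), 0L)
})

test_that("DP equals the unrolled-profile Smith-Waterman oracle", {
  set.seed(42)
  for (t in 1:400) {
    n <- sample(2:3, 1)
    N <- sample(4:10, 1)
    codes <- sample(0:4, N, replace = TRUE,
                    prob = c(0.1, rep(0.225, 4)))
    M <- random_weight_matrix(n)
    open <- runif(1, 0.5, 6)
    ext <- runif(1, 0, open)
    expect_equal(score_periodic(codes, M, gap_params(open, ext)),
                 sw_unrolled(codes, unclass(M), open, ext),
                 tolerance = 1e-9)
  }
})

test_that("returned paths rescore to F_max and are structurally valid", {
  set.seed(7)
  for (t in 1:60) {
    n <- sample(2:8, 1)
    N <- sample(20:80, 1)
    codes <- sample(0:4, N, replace = TRUE, prob = c(0.05, rep(0.2375, 4)))
    M <- random_weight_matrix(n)
    g <- gap_params(runif(1, 1, 6), runif(1, 0.2, 1))
    a <- local_align_periodic(codes, M, g)
    expect_gte(a$score, 0)
    expect_equal(rescore_alignment(a, codes, M, g), a$score,
                 tolerance = 1e-6)
    p <- a$path
    if (nrow(p) > 0) {
      # seq positions strictly increasing over seq-consuming steps
      sp <- p$seq_pos[p$op != "deletion"]
      expect_true(all(diff(sp) > 0))
      # period columns advance cyclically on column-consuming steps
      cl <- p$col[p$op != "insertion"]
      if (length(cl) > 1)
        expect_true(all((diff(cl) %% n + n) %% n %in% c(1 %% n)))
      # alignments start and end with a non-N match
      expect_identical(p$op[1], "match")
      expect_identical(p$op[nrow(p)], "match")
      expect_true(codes[a$seq_start] > 0 && codes[a$seq_end] > 0)
    }
  }
})

test_that("F_max dominates single positive cells and is gap-monotone", {
  set.seed(11)
  for (t in 1:30) {
    n <- sample(2:6, 1)
    codes <- sample(1:4, 40, replace = TRUE)
    M <- random_weight_matrix(n)
    f <- score_periodic(codes, M, gap_params(4, 1))
    # >= best single matched cell anywhere in S
    best_cell <- max(vapply(seq_along(codes), function(i)
      max(M[codes[i], ]), 0))
    expect_gte(f, best_cell - 1e-9)
    # decreasing gap penalties never decreases F_max
    expect_gte(score_periodic(codes, M, gap_params(2, 0.5)) + 1e-9, f)
  }
})

test_that("N bases score zero and never terminate an alignment", {
  M <- consensus_weight_matrix("ACGT")
  a <- local_align_periodic("NNACGTACGTNN", M)
  expect_equal(a$seq_start, 3L)
  expect_equal(a$seq_end, 10L)
  expect_equal(a$score, 8 * sqrt(3), tolerance = 1e-9)
  # all-N sequence: nothing to align
  expect_equal(local_align_periodic("NNNNNNNN", M)$score, 0)
})

test_that("consensus strings follow the majority / two-base ambiguity rule", {
  F1 <- fmat(c(40, 0, 0, 0))
  # single-column matrices are padded to n = 2 for the constructor
  F2 <- fmat(c(40, 0, 0, 0), c(3, 2, 15, 20))
  expect_equal(consensus_from_matrix(F2), "A(T/G)")
  F3 <- fmat(c(10, 9, 9, 9), c(0, 0, 0, 0))
  expect_equal(consensus_from_matrix(F3), "AN")
  # runner-up at exactly one third does not trigger the ambiguity form
  F4 <- fmat(c(24, 12, 0, 0), c(22, 13, 1, 0))
  expect_equal(consensus_from_matrix(F4), "A(A/C)")
})

test_that("matrix TSV round trip and alignment dump", {
  M <- random_weight_matrix(7, seed = 3)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_weight_matrix(M, path)
  expect_equal(unclass(read_weight_matrix(path)), unclass(M),
               tolerance = 1e-12)
  a <- local_align_periodic("ACGTACGT", consensus_weight_matrix("ACGT"))
  txt <- format_alignment(a, "ACGTACGT")
  expect_true(any(grepl("ACGTACGT", txt)))
  expect_true(any(grepl("\\|{8}", txt)))
})
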