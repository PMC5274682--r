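# Information distance between frequency matrices and unique-repeat
# counting.

test_that("distance identities: zero at identity, symmetric, non-negative", {
  set.seed(3)
  for (t in 1:200) {
    n <- sample(2:8, 1)
    Fk <- frequency_matrix(matrix(rpois(4 * n, 8), 4))
    Fl <- frequency_matrix(matrix(rpois(4 * n, 8), 4))
    I <- matrix_distance(Fk, Fl)
    expect_gte(I, 0)
    expect_equal(I, matrix_distance(Fl, Fk), tolerance = 1e-12)
    expect_equal(matrix_distance(Fk, Fk), 0, tolerance = 1e-9)
  }
  expect_error(matrix_distance(frequency_matrix(matrix(1, 4, 3)),
                               frequency_matrix(matrix(1, 4, 4))),
               "equal period")
})

test_that("distance equals an independent term-by-term evaluation", {
  # toy 4 x 2 matrices evaluated by hand-written sums
  Fk <- fmat(c(10, 0, 0, 0), c(0, 10, 0, 0))
  Fl <- fmat(c(5, 5, 0, 0), c(0, 5, 5, 0))
  xlx <- function(x) if (x > 0) x * log(x) else 0
  manual <- 0
  for (j in 1:2) {
    for (i in 1:4)
      manual <- manual + xlx(Fk[i, j]) + xlx(Fl[i, j]) - xlx(Fk[i, j] + Fl[i, j])
    sk <- sum(Fk[, j]); sl <- sum(Fl[, j])
    manual <- manual + xlx(sk + sl) - xlx(sk) - xlx(sl)
  }
  manual <- as.numeric(manual)
  expect_equal(matrix_distance(Fk, Fl), manual, tolerance = 1e-12)
  expect_gt(manual, 0)
})

test_that("normal transform is zero at 4I = 2df - 1 and monotone", {
  n <- 5
  df <- 3 * (n - 1)
  expect_equal(distance_to_normal((2 * df - 1) / 4, n), 0)
  expect_gt(distance_to_normal(10, n), distance_to_normal(5, n))
  expect_error(distance_to_normal(3, 1), "at least 2")
})

test_that("2I is chi-square 3(n-1) under the composition-fixing null", {
  set.seed(11)
  for (n in c(3, 5, 11)) {
    base <- frequency_matrix(matrix(10, 4, n))  # 40 bases per column
    v <- replicate(1000, 2 * matrix_distance(randomize_frequency_matrix(base),
                                             randomize_frequency_matrix(base)))
    expect_lt(abs(mean(v) - 3 * (n - 1)) / (3 * (n - 1)), 0.10)
  }
  # and the normal transform is close to N(0, 1)
  n <- 5
  base <- frequency_matrix(matrix(10, 4, n))
  X <- replicate(1500, distance_to_normal(
    matrix_distance(randomize_frequency_matrix(base),
                    randomize_frequency_matrix(base)), n))
  expect_gte(mean(X), -0.2); expect_lte(mean(X), 0.2)
  expect_gte(sd(X), 0.8); expect_lte(sd(X), 1.2)
})

test_that("randomization preserves row totals and column sums", {
  set.seed(2)
  F0 <- frequency_matrix(matrix(rpois(4 * 6, 7), 4))
  Fr <- randomize_frequency_matrix(F0, seed = 1)
  expect_equal(rowSums(Fr), rowSums(F0))
  expect_equal(colSums(Fr), colSums(F0))
  expect_identical(unclass(randomize_frequency_matrix(F0, seed = 1)),
                   unclass(Fr))
})

test_that("self-comparison yields no unique repeats", {
  set.seed(4)
  A <- lapply(1:6, function(k) frequency_matrix(matrix(rpois(4 * 5, 9), 4)))
  rep <- unique_repeat_count(A, A, seed = 3)
  # each matrix finds its identical partner: far-left X, nothing unique
  expect_true(all(rep$x_min$X_min <= 0))
  expect_equal(rep$unique_count, 0)
})

test_that("a planted disjoint family is counted as unique", {
  set.seed(9)
  n <- 6
  make_family <- function(consensus_seed, members, spread = 2) {
    cons <- random_weight_matrix(n, seed = consensus_seed)
    peak <- apply(unclass(cons), 2, which.max)
    lapply(1:members, function(m) {
      f <- matrix(3, 4, n)                    # flat background counts
      f[cbind(peak, 1:n)] <- 40               # strong family consensus
      jitter <- matrix(rpois(4 * n, spread), 4)
      frequency_matrix(f + jitter)
    })
  }
  shared_A <- make_family(1, 8)
  shared_B <- make_family(1, 8)
  unique_A <- make_family(2, 10)              # only in A
  repa <- unique_repeat_count(c(shared_A, unique_A), shared_B,
                              ratio = 20, seed = 5)
  expect_true(repa$found)
  expect_gte(repa$unique_count, 8)
  expect_lte(repa$unique_count, 12)
  # increasing the required ratio never increases the unique count
  repb <- unique_repeat_count(c(shared_A, unique_A), shared_B,
                              ratio = 50, seed = 5)
  expect_lte(repb$unique_count, repa$unique_count)
})

test_that("phase shifts are absorbed by the cyclic minimum", {
  F0 <- fmat(c(30, 0, 0, 0), c(0, 30, 0, 0), c(0, 0, 30, 0))
  F1 <- fmat(c(0, 0, 30, 0), c(30, 0, 0, 0), c(0, 30, 0, 0))  # shifted copy
  expect_gt(matrix_distance(F0, F1), 0)
  expect_equal(matrix_normal_distance(F0, F1),
               distance_to_normal(0, 3), tolerance = 1e-9)
})
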