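# Scanning protocol: window arithmetic, merge resolution, frequency
# matrices, overlap comparison, and an end-to-end implant scan.

test_that("window enumeration matches the closed form", {
  cfg <- scan_config(window = 600, step = 200, ga = fast_cfg())
  expect_equal(nrow(iter_windows(600L, cfg)), 1L)
  expect_equal(iter_windows(600L, cfg)$start, 1L)
  expect_equal(nrow(iter_windows(599L, cfg)), 0L)
  w <- iter_windows(1400L, cfg)
  expect_equal(w$start, c(1L, 201L, 401L, 601L, 801L))
  expect_equal(w$end - w$start + 1L, rep(600L, 5))
  for (N in c(0L, 1L, 599L, 601L, 799L, 800L, 1234L, 5000L)) {
    expected <- if (N >= 600) (N - 600) %/% 200 + 1 else 0
    expect_equal(nrow(iter_windows(N, cfg)), expected)
  }
})

make_region <- function(seq_id, start, end, mF, n = 10)
  structure(list(seq_id = seq_id, start = start, end = end, n = n,
                 mF_max = mF, triplet_Z = 0, consensus = "",
                 alignment = NULL, seq = NULL),
            class = "periodic_region")

test_that("intersecting candidates are resolved by the larger score", {
  a <- make_region("c1", 1, 700, 400)
  b <- make_region("c1", 300, 900, 500)
  kept <- merge_overlapping(list(a, b))
  expect_length(kept, 1)
  expect_equal(kept[[1]]$start, 300)
  # disjoint survive unchanged
  d <- make_region("c1", 2000, 2400, 100)
  expect_length(merge_overlapping(list(a, d)), 2)
  # same coordinates on different records never compete
  e <- make_region("c2", 1, 700, 100)
  expect_length(merge_overlapping(list(a, e)), 2)
  # chain A-B, B-C with B maximal: keep B only
  A <- make_region("c1", 1, 500, 300)
  B <- make_region("c1", 400, 1000, 600)
  C <- make_region("c1", 900, 1400, 300)
  kept <- merge_overlapping(list(A, B, C))
  expect_length(kept, 1)
  expect_equal(kept[[1]]$mF_max, 600)
  # brute force over conflict-free subsets confirms greedy on small sets
  set.seed(5)
  for (t in 1:20) {
    cands <- lapply(1:5, function(i) {
      s <- sample(1:50, 1)
      make_region("c1", s, s + sample(5:30, 1), runif(1, 100, 900))
    })
    kept <- merge_overlapping(cands)
    f <- vapply(cands, `[[`, 0, "mF_max")
    s <- vapply(cands, `[[`, 0, "start")
    e <- vapply(cands, `[[`, 0, "end")
    # greedy keeps the global top scorer and returns no intersecting pair
    expect_true(max(f) %in% vapply(kept, `[[`, 0, "mF_max"))
    ks <- vapply(kept, `[[`, 0, "start")
    ke <- vapply(kept, `[[`, 0, "end")
    if (length(kept) > 1)
      for (i in 1:(length(kept) - 1))
        for (j in (i + 1):length(kept))
          expect_true(ks[i] > ke[j] || ks[j] > ke[i])
  }
})

test_that("frequency matrices count matched bases only", {
  S <- strrep("ACGT", 10)
  M <- consensus_weight_matrix("ACGT")
  a <- local_align_periodic(S, M)
  F <- frequency_matrix_from_alignment(a, S)
  expect_equal(sum(F), 40)
  expect_equal(unname(diag(unclass(F))), rep(10, 4))
  expect_equal(sum(F) , sum(a$path$op == "match"))
  # indel steps contribute nothing: the total equals match steps
  S2 <- "ACGTACGGTACGTACGT"                               # one inserted G
  a2 <- local_align_periodic(S2, M, gap_params(2, 1))
  F2 <- frequency_matrix_from_alignment(a2, S2)
  expect_equal(sum(F2), sum(a2$path$op == "match"))
  expect_lt(sum(F2), nchar(S2))
})

test_that("region overlap comparison applies the inclusive 30% rule", {
  A <- data.frame(seq_id = "c1", start = 1, end = 600)
  # 50/600 ~ 8.3%: unmatched
  B1 <- data.frame(seq_id = "c1", start = 551, end = 1150)
  cc1 <- overlap_compare(A, B1)
  expect_equal(cc1$matched_A, 0L)
  # 180/600 = 30% exactly: matched (inclusive)
  B2 <- data.frame(seq_id = "c1", start = 421, end = 1020)
  cc2 <- overlap_compare(A, B2)
  expect_equal(cc2$matched_A, 1L)
  # identity
  cc3 <- overlap_compare(A, A)
  expect_equal(cc3$matched_A, cc3$total_A)
  # disjoint seq_id universes warn and match nothing
  B3 <- data.frame(seq_id = "c9", start = 1, end = 600)
  expect_warning(cc4 <- overlap_compare(A, B3), "seq_id")
  expect_equal(cc4$matched_A, 0L)
  # fraction is measured against the query's own length (asymmetric)
  A5 <- data.frame(seq_id = "c1", start = 1, end = 100)
  B5 <- data.frame(seq_id = "c1", start = 91, end = 1090)
  expect_equal(overlap_compare(A5, B5)$matched_A, 0L)  # 10/100 < 30%
  expect_equal(overlap_compare(A5, B5, 0.1)$matched_A, 1L)
})

test_that("scanning recovers perfect implants and skips short input", {
  cfg <- scan_config(window = 600, step = 200, n_min = 2, n_max = 11,
                     F0 = 330, ga = fast_cfg(seed = 4))
  # input shorter than the window: no regions
  expect_length(scan_periodicity(random_dna(400, seed = 1), cfg), 0)
  # three perfect tandem arrays in random background are all found
  hits <- 0L
  emitted <- 0L
  overlapped <- 0L
  for (k in 1:3) {
    sp <- implant_spec(random_dna(10, seed = 500 + k), copies = 90,
                       substitution_rate = 0, indel_rate = 0,
                       background_length = 2000, seed = 510 + k)
    sim <- simulate_latent_periodic(sp)
    regs <- scan_periodicity(c(chr = sim$sequence), cfg, seed = 520 + k)
    df <- as.data.frame(regs)
    emitted <- emitted + nrow(df)
    tr <- sim$truth
    if (nrow(df)) {
      ov <- pmin(df$end, tr$implant_end) - pmax(df$start, tr$implant_start) + 1
      if (any(ov >= 0.3 * (tr$implant_end - tr$implant_start + 1)))
        hits <- hits + 1L
      overlapped <- overlapped + sum(ov > 0)
    }
  }
  expect_equal(hits, 3L)
  # every emitted region overlaps an implant (no false positives here)
  expect_equal(overlapped, emitted)
  # emitted regions respect the threshold and are non-intersecting
})

test_that("scan results are deterministic given a seed", {
  sp <- implant_spec(random_dna(8, seed = 42), copies = 100,
                     substitution_rate = 0, indel_rate = 0,
                     background_length = 1500, seed = 43)
  sim <- simulate_latent_periodic(sp)
  cfg <- scan_config(window = 600, step = 300, n_min = 2, n_max = 9,
                     F0 = 330, ga = fast_cfg(seed = 4))
  r1 <- as.data.frame(scan_periodicity(c(s = sim$sequence), cfg, seed = 9))
  r2 <- as.data.frame(scan_periodicity(c(s = sim$sequence), cfg, seed = 9))
  expect_identical(r1, r2)
})

test_that("triplet-periodic windows are skipped by the scanner", {
  S <- strrep("ACG", 400)  # 1200 nt of perfect coding-like triplet
  cfg <- scan_config(window = 600, step = 200, n_min = 2, n_max = 6,
                     F0 = 100, z_skip = 3, ga = fast_cfg(seed = 2))
  expect_length(scan_periodicity(c(x = S), cfg), 0)
  # with the filter disabled the same input is (trivially) periodic
  cfg2 <- scan_config(window = 600, step = 200, n_min = 2, n_max = 6,
                      F0 = 100, z_skip = Inf, ga = fast_cfg(seed = 2))
  expect_gt(length(scan_periodicity(c(x = S), cfg2)), 0)
})
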