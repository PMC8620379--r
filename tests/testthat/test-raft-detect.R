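test_that("raft mask thresholds mobility strictly below tau", {
  m <- matrix(0.5, 30, 30)
  m[11:20, 11:20] <- 0
  expect_false(any(raft_mask(m, 0)))
  expect_true(all(raft_mask(m, 1.01)))
  mk <- raft_mask(m, 0.1)
  expect_equal(unclass(mk), m < 0.1, ignore_attr = TRUE)
  expect_equal(sum(mk), 100)
})

test_that("raft area fraction is non-decreasing in tau", {
  set.seed(7)
  m <- matrix(runif(2500), 50, 50)
  areas <- vapply(seq(0, 1, by = 0.1), function(tau) mean(raft_mask(m, tau)), 0)
  expect_true(all(diff(areas) >= 0))
})

test_that("row scanning recovers exact run statistics on simple shapes", {
  full <- matrix(TRUE, 200, 200)
  expect_equal(raft_size_rowscan(full)$mean_size, 200)
  sq <- matrix(FALSE, 64, 64)
  sq[20:29, 40:49] <- TRUE
  sz <- raft_size_rowscan(sq)
  expect_equal(sz$mean_size, 10)
  expect_equal(sz$sd_size, 0)
  empty <- raft_size_rowscan(matrix(FALSE, 10, 10))
  expect_equal(empty$mean_size, 0)
  expect_length(empty$runs, 0)
})

test_that("row scanning merges runs across the periodic boundary", {
  m <- matrix(FALSE, 4, 10)
  m[2, c(1, 2, 9, 10)] <- TRUE   # one wrapped run of length 4
  expect_equal(raft_size_rowscan(m)$runs, 4)
})

test_that("mean run length on a disc approximates the analytic mean chord", {
  m <- disc_mask(20)
  expect_equal(raft_size_rowscan(m)$mean_size, pi * 20 / 2, tolerance = 0.05)
})

test_that("chord-corrected circular count matches disc geometry", {
  expect_identical(raft_count(matrix(FALSE, 10, 10)), 0L)
  m <- disc_mask(20)
  sz <- raft_size_rowscan(m)$mean_size
  expect_identical(raft_count(m, sz, chord_correction = TRUE), 1L)
  # the raw chord reading understates the diameter and over-counts
  expect_identical(raft_count(m, sz, chord_correction = FALSE), 2L)
})

test_that("count estimator agrees with component labeling on disjoint discs", {
  set.seed(42)
  for (case in 1:8) {
    k <- sample(1:10, 1)
    r <- sample(5:25, 1)
    side <- ceiling(sqrt(k))
    H <- side * (2 * r + 6) + 8
    centers <- cbind(
      (seq_len(k) - 1) %/% side * (2 * r + 6) + r + 5,
      (seq_len(k) - 1) %% side * (2 * r + 6) + r + 5)
    m <- disc_mask(r, H, H, centers = centers)
    est <- raft_count(m, raft_size_rowscan(m)$mean_size)
    lab <- length(label_domains(m)$sizes)
    expect_identical(lab, k)
    expect_lte(abs(est - lab), 1)
  }
})

test_that("component labeling is exact, periodic, and partitions the mask", {
  sq <- matrix(FALSE, 32, 32)
  sq[5:14, 5:14] <- TRUE
  lab <- label_domains(sq)
  expect_length(lab$sizes, 1)
  expect_identical(lab$sizes, 100L)
  expect_equal(unname(lab$centroids[1, ]), c(9.5, 9.5))
  # checkerboard: isolated cells, one component each
  cb <- outer(1:8, 1:8, function(i, j) (i + j) %% 2 == 0)
  cb[1, ] <- FALSE; cb[, 1] <- FALSE  # break periodic adjacency of edges
  expect_length(label_domains(cb)$sizes, sum(cb))
  # a square crossing both periodic edges stays one component
  wrap <- matrix(FALSE, 20, 20)
  wrap[c(19, 20, 1, 2), c(19, 20, 1, 2)] <- TRUE
  expect_length(label_domains(wrap)$sizes, 1)
  # partition property on random masks
  set.seed(13)
  for (i in 1:5) {
    m <- matrix(runif(900) < 0.35, 30, 30)
    lab <- label_domains(m)
    expect_identical(sum(lab$sizes), sum(m))
  }
})

test_that("size histograms preserve run counts and support bounds", {
  sq <- matrix(FALSE, 32, 32)
  sq[5:14, 5:14] <- TRUE
  h <- size_histogram(raft_size_rowscan(sq)$runs, bins = 0:12)
  expect_identical(sum(h$counts), 10L)
  expect_identical(h$counts[10], 10L)  # all runs have length 10
  h0 <- size_histogram(integer(0), bins = 5)
  expect_true(all(h0$counts == 0))
  # chords of a rasterized disc of radius r cannot exceed 2r + 1 cells
  runs <- raft_size_rowscan(disc_mask(20))$runs
  expect_true(all(runs >= 1 & runs <= 41))
})

test_that("domain composition splits inside/outside and normalizes to 100", {
  lat <- initialize_lattice(scenarios$membrane$Control, c(40, 40), seed = 2)
  mask <- matrix(FALSE, 40, 40)
  mask[1:10, 1:10] <- TRUE
  dc <- domain_composition(lat, mask)
  expect_s3_class(dc$inside, "membrane_composition")
  expect_equal(sum(dc$inside), 100)
  expect_equal(sum(dc$outside), 100)
  # full mask reduces to the whole-lattice composition
  dcf <- domain_composition(lat, matrix(TRUE, 40, 40))
  expect_equal(unclass(dcf$inside), unclass(lattice_composition(lat)))
  expect_null(dcf$outside)
  expect_error(domain_composition(lat, matrix(FALSE, 40, 40)), "empty")
})
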