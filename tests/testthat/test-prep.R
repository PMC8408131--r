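test_that("counts_to_tpm matches the closed-form TPM formula", {
  counts <- matrix(c(10, 10), 2, 1, dimnames = list(c("g1", "g2"), "s1"))
  tpm <- counts_to_tpm(counts, lengths = c(1000, 2000))
  expect_equal(as.numeric(tpm), c(2e6 / 3, 1e6 / 3), tolerance = 1e-12)

  # single gene and symmetric cases
  expect_equal(as.numeric(counts_to_tpm(matrix(7, 1, 1), 500)), 1e6)
  m <- matrix(5, 4, 2, dimnames = list(paste0("g", 1:4), c("a", "b")))
  expect_equal(unname(counts_to_tpm(m, rep(100, 4))),
               matrix(2.5e5, 4, 2), tolerance = 1e-12)
})

test_that("counts_to_tpm conserves column sums and flags zero columns", {
  set.seed(1)
  counts <- matrix(rpois(60, 50), 10, 6,
                   dimnames = list(paste0("g", 1:10), paste0("s", 1:6)))
  tpm <- counts_to_tpm(counts, lengths = runif(10, 500, 3000))
  expect_equal(unname(colSums(tpm)), rep(1e6, 6), tolerance = 1e-6)

  counts[, 3] <- 0
  expect_warning(tpm0 <- counts_to_tpm(counts, rep(1000, 10)), "all-zero")
  expect_equal(sum(tpm0[, 3]), 0)
  expect_error(counts_to_tpm(counts, c(rep(1000, 9), -1)), "positive")
})

test_that("tissue_means averages replicates in design order", {
  x <- matrix(c(4, 6, 1, 2, 6), 1, 5,
              dimnames = list("g1", paste0("s", 1:5)))
  design <- data.frame(sample_id = paste0("s", 1:5),
                       tissue = c("A", "A", "B", "B", "B"),
                       replicate = c(1, 2, 1, 2, 3))
  tm <- tissue_means(x, design)
  expect_equal(as.numeric(tm), c(5, 3))
  expect_equal(colnames(tm), c("A", "B"))
  expect_error(tissue_means(x[, 1:4, drop = FALSE], design), "absent")
  # single replicate is the identity
  d1 <- data.frame(sample_id = "s1", tissue = "A")
  expect_equal(as.numeric(tissue_means(x[, 1, drop = FALSE], d1)), 4)
})

test_that("expression filter applies the TPM floor per mode", {
  prof <- rbind(low = rep(0.5, 10),
                one = c(2, rep(0, 9)),
                all2 = rep(2, 10),
                dip = c(2, 0.9, rep(2, 8)))
  colnames(prof) <- paste0("T", 1:10)
  expect_equal(filter_expressed(prof, 1), c("one", "all2", "dip"))
  expect_equal(filter_expressed(prof, 1, mode = "all_tissues"), "all2")
  # boundary: strict by default, >= with ge = TRUE
  b <- rbind(edge = rep(1, 3))
  expect_length(filter_expressed(b, 1), 0)
  expect_equal(filter_expressed(b, 1, ge = TRUE), "edge")
})

test_that("network filter removes flat and low-variance genes", {
  prof <- rbind(const100 = rep(100, 10),
                spike = c(1000, rep(0, 9)),
                lowvar = c(0.5, 0.5, 1.2, rep(0.5, 7)))
  colnames(prof) <- paste0("T", 1:10)
  expect_equal(filter_for_network(prof), "spike")
  expect_lt(var(prof["lowvar", ]), 1)
})

test_that("quantile normalization equals the rank-mean oracle and is idempotent", {
  x <- cbind(a = c(1, 2, 3), b = c(6, 4, 5))
  qn <- quantile_normalize(x)
  expect_equal(sort(qn[, 1]), sort(qn[, 2]))
  expect_equal(unname(qn[, "a"]), c(2.5, 3.5, 4.5))
  expect_equal(unname(qn[, "b"]), c(4.5, 2.5, 3.5))

  same <- cbind(c(1, 5, 9), c(1, 5, 9))
  expect_equal(quantile_normalize(same), same)

  set.seed(2)
  y <- matrix(rexp(50), 10, 5)
  q1 <- quantile_normalize(y)
  expect_equal(quantile_normalize(q1), q1, tolerance = 1e-12)
  srt <- apply(q1, 2, sort)
  for (j in 2:5) expect_equal(srt[, j], srt[, 1])
})

test_that("normalize_profile keeps absent genes at zero", {
  x <- cbind(a = c(0, 2, 3), b = c(6, 0, 5))
  np <- normalize_profile(x)
  expect_equal(unname(np[1, "a"]), 0)
  expect_equal(unname(np[2, "b"]), 0)
  expect_true(all(np[x > 0] > 0))
})

test_that("BIN levels honor the 0-10 contract and monotonicity", {
  set.seed(3)
  x <- matrix(rexp(200, 1 / 50), 20, 10,
              dimnames = list(paste0("g", 1:20), paste0("T", 1:10)))
  x[1, ] <- 0
  x[2, 1] <- max(x[, 1]) * 2  # force a known per-tissue maximum
  bins <- assign_bins(x)
  expect_true(all(bins >= 0 & bins <= 10))
  expect_equal(unname(bins[1, ]), rep(0L, 10))
  for (j in 1:10) expect_equal(bins[which.max(x[, j]), j], 10L)
  # monotone within each tissue
  for (j in 1:10) {
    ord <- order(x[, j])
    expect_true(all(diff(bins[ord, j]) >= 0))
  }
  # value exactly midway in the log2 grid gets level 5
  M <- 2^10 - 1
  v <- c(2^5 - 1, M, 0)
  expect_equal(unname(assign_bins(cbind(v, v))[, 1]), c(5L, 10L, 0L))
})

test_that("alternative BIN grids keep the same contract", {
  set.seed(4)
  x <- matrix(rexp(100, 1 / 20), 20, 5)
  dimnames(x) <- list(paste0("g", 1:20), paste0("T", 1:5))
  x[3, ] <- 0
  for (method in c("logwidth", "decile")) {
    bins <- assign_bins(x, method = method)
    expect_true(all(bins >= 0 & bins <= 10))
    expect_equal(unname(bins[3, ]), rep(0L, 5))
    for (j in 1:5) expect_equal(bins[which.max(x[, j]), j], 10L)
  }
})

test_that("row z-scores standardize rows and zero out constants", {
  x <- rbind(a = c(1, 2, 3), b = c(10, 20, 60))
  z <- row_zscore(x)
  expect_equal(unname(z["a", ]), c(-1, 0, 1))
  expect_equal(unname(rowMeans(z)), c(0, 0), tolerance = 1e-12)
  expect_equal(unname(apply(z, 1, sd)), c(1, 1), tolerance = 1e-12)
  expect_warning(zc <- row_zscore(rbind(c(5, 5, 5))), "constant")
  expect_equal(as.numeric(zc), c(0, 0, 0))
})
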