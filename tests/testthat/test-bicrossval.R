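test_that("partition splits rows and columns exhaustively", {
  withr::with_seed(1, {
    Y4 <- matrix(1, 4, 4)
    p <- partition_matrix(Y4)
    expect_equal(lengths(p[c("rows1", "rows2", "cols1", "cols2")]),
                 c(rows1 = 2L, rows2 = 2L, cols1 = 2L, cols2 = 2L))
    Y3 <- matrix(1, 3, 3)
    p3 <- partition_matrix(Y3)
    expect_equal(sort(c(p3$rows1, p3$rows2)), 1:3)
    expect_equal(sort(c(p3$cols1, p3$cols2)), 1:3)
    expect_equal(lengths(p3[c("rows1", "rows2", "cols1", "cols2")]),
                 c(rows1 = 2L, rows2 = 1L, cols1 = 2L, cols2 = 1L))
  })
  expect_error(partition_matrix(matrix(1, 1, 5)), "too small")
})

test_that("held-out block reconstruction is exact at the true rank", {
  # rank-1 outer product, spec'd split
  Y <- outer(1:4, 1:4)
  P <- Y[1:2, 1:2]; Q <- Y[1:2, 3:4]; R <- Y[3:4, 1:2]; S <- Y[3:4, 3:4]
  expect_equal(reconstruct_block(Q, S, R, 1), P, tolerance = 1e-12)

  # rank-k random instances: identity within 1e-9 (Eq-2 property, 100 draws)
  withr::with_seed(2, {
    for (i in 1:100) {
      k <- sample(1:3, 1)
      W <- matrix(runif(10 * k, 0.5, 2), 10, k)
      H <- matrix(runif(k * 8, 0.5, 2), k, 8)
      Y <- W %*% H
      P <- Y[1:5, 1:4]; Q <- Y[1:5, 5:8]; R <- Y[6:10, 1:4]; S <- Y[6:10, 5:8]
      expect_lt(max(abs(reconstruct_block(Q, S, R, k) - P)), 1e-9)
    }
  })

  # singular S with rank 1 still yields finite output via the pseudoinverse
  S1 <- outer(c(1, 2), c(1, 1))
  out <- reconstruct_block(matrix(1, 2, 2), S1, matrix(1, 2, 2), 1)
  expect_true(all(is.finite(out)))
  expect_error(reconstruct_block(matrix(1, 2, 2), S1, matrix(1, 2, 2), 3),
               "outside")
})

test_that("error table has the right shape and vanishes at the true rank", {
  withr::with_seed(3, {
    Y <- outer(runif(8, 1, 2), runif(8, 1, 2))
    tbl <- bcv_error_table(Y, k_max = 3, n_resamples = 40)
    expect_equal(dim(tbl), c(40L, 3L))
    expect_true(all(tbl[, 1] < 1e-9))

    # noiseless rank-2: error at the true rank never exceeds error at k = 1
    W <- matrix(runif(16, 0.5, 2), 8, 2); H <- matrix(runif(16, 0.5, 2), 2, 8)
    tbl2 <- bcv_error_table(W %*% H, k_max = 2, n_resamples = 40)
    expect_true(all(tbl2[, 2] <= tbl2[, 1] + 1e-9))
    expect_warning(bcv_error_table(Y, k_max = 7, n_resamples = 5), "truncated")
  })
})

test_that("rank selection picks the smallest statistically minimal rank", {
  withr::with_seed(4, {
    # synthetic table: k1 >> k2 ~ k3; k* = argmin median, k-hat = 2
    tbl <- cbind(k1 = rnorm(250, 10, 0.1), k2 = rnorm(250, 1, 0.1),
                 k3 = rnorm(250, 0.99, 0.1))
    expect_equal(estimate_num_transcripts(tbl), 2L)

    # noiseless rank-2 gene via the full procedure
    g <- simulate_gene(2, n_samples = 12, n_probesets = 6,
                       noise = noise_params(0, 0), seed = 42)
    tbl2 <- bcv_error_table(g$Y, k_max = 4, n_resamples = 60, seed = 5)
    expect_equal(estimate_num_transcripts(tbl2), 2L)

    # single-transcript noiseless gene
    g1 <- simulate_gene(1, n_samples = 10, n_probesets = 5,
                        noise = noise_params(0, 0), seed = 43)
    tbl1 <- bcv_error_table(g1$Y, k_max = 3, n_resamples = 60, seed = 6)
    # rank-1 noiseless input reconstructs exactly at every k: degenerate table
    expect_warning(k_one <- estimate_num_transcripts(tbl1), "degenerate")
    expect_equal(k_one, 1L)

    expect_warning(k0 <- estimate_num_transcripts(matrix(1, 20, 3)), "degenerate")
    expect_equal(k0, 1L)
    # never exceeds the argmin-median rank
    for (i in 1:20) {
      tb <- matrix(rexp(200), 50, 4)
      expect_lte(estimate_num_transcripts(tb), which.min(apply(tb, 2, median)))
    }
  })
})

test_that("outlier correction flags planted outliers and nothing else", {
  withr::with_seed(6, {
    Y <- outer(runif(8, 1, 3), runif(8, 1, 3))
    clean <- detect_and_correct_outliers(Y, n_resamples = 60)
    expect_equal(sum(clean$mask), 0)
    expect_equal(clean$Y_corrected, Y, ignore_attr = TRUE)

    Yo <- Y
    Yo[3, 5] <- Yo[3, 5] * 20
    res <- detect_and_correct_outliers(Yo, n_resamples = 120, seed = 7)
    expect_equal(res$mask[3, 5], 1)
    # the planted entry is flagged; at most one neighbour may be grazed
    expect_lte(sum(res$mask), 2)
    expect_equal(res$Y_corrected[3, 5], Y[3, 5], tolerance = 0.1)

    # idempotent: a second pass flags (almost) nothing
    res2 <- detect_and_correct_outliers(res$Y_corrected, n_resamples = 120, seed = 8)
    expect_lte(sum(res2$mask), 1)
  })
  expect_error(detect_and_correct_outliers(matrix(1, 4, 4) + diag(4), n_resamples = 5),
               ">= 10")
})

test_that("one-call rank estimation recovers a noiseless rank-2 gene", {
  g <- simulate_gene(2, n_samples = 12, n_probesets = 6,
                     noise = noise_params(0, 0), seed = 44)
  k <- estimate_transcript_number(g$Y, k_max = 4, n_resamples = 60, seed = 9)
  expect_equal(as.integer(k), 2L)
  expect_equal(dim(attr(k, "table"))[1], 60L)
})
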