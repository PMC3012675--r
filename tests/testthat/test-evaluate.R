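test_that("confusion counts and structure metrics follow the definitions", {
  G <- rbind(c(1, 0), c(1, 1))
  pred <- rbind(c(1, 1), c(1, 0))
  counts <- confusion_counts(G, pred)
  expect_equal(counts, c(TP = 2, TN = 0, FP = 1, FN = 1))
  expect_equal(unname(confusion_counts(G, G)[c("FP", "FN")]), c(0, 0))
  expect_equal(unname(confusion_counts(G, 1 - G)[c("TP", "TN")]), c(0, 0))
  expect_error(confusion_counts(G, matrix(1, 3, 2)), "shape")

  m <- structure_metrics(c(TP = 2, TN = 0, FP = 1, FN = 1))
  expect_equal(m$HD, 0.5)
  expect_equal(m$SN, 2 / 3)
  expect_equal(m$SP, 0)
  perfect <- structure_metrics(confusion_counts(G, G))
  expect_equal(c(perfect$HD, perfect$SN, perfect$SP), c(0, 1, 1))
  expect_equal(structure_metrics(confusion_counts(G, 1 - G))$HD, 1)
  # HD + accuracy = 1
  withr::with_seed(40, {
    for (i in 1:10) {
      a <- matrix(rbinom(24, 1, 0.5), 6, 4)
      b <- matrix(rbinom(24, 1, 0.5), 6, 4)
      mm <- structure_metrics(confusion_counts(a, b))
      expect_equal(mm$HD + (mm$TP + mm$TN) / mm$N, 1)
    }
  })
  expect_true(is.na(structure_metrics(c(TP = 0, TN = 3, FP = 1, FN = 0))$SN))
})

test_that("pooled threshold sweep behaves at the limits and sums per-gene counts", {
  withr::with_seed(41, {
    truth <- lapply(1:3, function(i) {
      G <- matrix(rbinom(18, 1, 0.6), 6, 3)
      G[rowSums(G) == 0, 1] <- 1
      G
    })
    preds <- lapply(truth, function(G) pmin(pmax(G + matrix(rnorm(18, 0, 0.3), 6, 3), 0), 1))
    curve <- roc_curve(truth, preds, thresholds = c(0.01, seq(0.1, 0.9, 0.1), 0.99),
                       match = FALSE)
    expect_equal(curve$SN[1], 1)           # everything called 1 at th ~ 0
    expect_equal(curve$SP[nrow(curve)], 1) # everything called 0 at th ~ 1
    # pooled counts equal the sum of per-gene counts
    th <- 0.5
    per_gene <- Reduce(`+`, Map(function(g, p) confusion_counts(g, (p > th) * 1),
                                truth, preds))
    row <- curve[curve$th == 0.5, ]
    expect_equal(c(TP = row$TP, TN = row$TN, FP = row$FP, FN = row$FN), per_gene)
    # monotone after pooling
    expect_true(all(diff(curve$SN) <= 1e-12))
    expect_true(all(diff(curve$SP) >= -1e-12))
  })
})

test_that("crossing point interpolates SN = SP", {
  curve <- tibble::tibble(th = c(0.2, 0.5, 0.8),
                          SN = c(1, 0.9, 0.8), SP = c(0.6, 0.9, 1.0))
  cp <- crossing_point(curve)
  expect_equal(cp$th, 0.5)
  expect_equal(cp$value, 0.9)
  expect_false(cp$boundary)

  # interpolation between grid points: SN = SP within numerical tolerance
  curve2 <- tibble::tibble(th = c(0.2, 0.8), SN = c(1, 0.4), SP = c(0.5, 0.9))
  cp2 <- crossing_point(curve2)
  sn_at <- approx(curve2$th, curve2$SN, cp2$th)$y
  sp_at <- approx(curve2$th, curve2$SP, cp2$th)$y
  expect_equal(sn_at, sp_at, tolerance = 1e-9)
  expect_equal(cp2$value, sn_at, tolerance = 1e-9)

  tie <- crossing_point(tibble::tibble(th = c(0.3, 0.6), SN = c(0.7, 0.7),
                                       SP = c(0.7, 0.7)))
  expect_true(tie$tie)
  expect_warning(
    bd <- crossing_point(tibble::tibble(th = c(0.3, 0.6), SN = c(1, 0.9),
                                        SP = c(0.1, 0.2))),
    "boundary|above"
  )
  expect_true(bd$boundary)
})

test_that("splicing call rates count the two error directions", {
  rates <- splicing_call_rates(c(1, 1, 2, 3), c(1, 2, 1, 3))
  expect_equal(rates$FPR, 0.5)
  expect_equal(rates$FNR, 0.5)
  expect_equal(splicing_call_rates(c(1, 2), c(1, 2)), list(FPR = 0, FNR = 0))
  all1 <- splicing_call_rates(c(1, 2, 3), c(1, 1, 1))
  expect_equal(all1$FPR, 0)
  expect_equal(all1$FNR, 1)
  expect_true(is.na(splicing_call_rates(c(2, 3), c(1, 1))$FPR))
  expect_error(splicing_call_rates(1:3, 1:2), "paired")
})

test_that("concentration MAE is scale-aligned unless told otherwise", {
  T_true <- matrix(c(1, 1), 1, 2)
  expect_equal(concentration_mae(T_true, T_true), 0)
  expect_equal(concentration_mae(T_true, 2 * T_true), 0, tolerance = 1e-12)
  expect_equal(concentration_mae(T_true, matrix(c(0.5, 1.5), 1, 2), align = FALSE), 50)
  expect_error(concentration_mae(matrix(0, 1, 2), T_true), "zero")
  expect_error(concentration_mae(T_true, matrix(1, 2, 2)), "shape")
})
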