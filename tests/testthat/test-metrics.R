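cc_row <- function(tp, fp, fn, tn) tibble::tibble(tp = tp, fp = fp, fn = fn, tn = tn)

test_that("metric formulas and empty-image conventions", {
  expect_equal(precision(cc_row(95, 5, 0, 0)), 0.95)
  expect_equal(recall(cc_row(92, 0, 8, 0)), 0.92)
  expect_equal(dice(cc_row(1, 1, 1, 0)), 0.5)
  expect_equal(accuracy(cc_row(0, 8, 0, 8)), 0.5)
  # correctly empty prediction is perfect, not undefined
  empty <- cc_row(0, 0, 0, 100)
  expect_equal(precision(empty), 1)
  expect_equal(recall(empty), 1)
  expect_equal(dice(empty), 1)
  expect_equal(accuracy(empty), 1)
  # empty prediction that misses foreground scores zero precision
  expect_equal(precision(cc_row(0, 0, 4, 96)), 0)
  expect_error(accuracy(cc_row(0, 0, 0, 0)), "empty")
})

test_that("metrics match an independent formula evaluation on random counts", {
  withr::with_seed(3, {
    for (k in 1:200) {
      cc <- cc_row(sample(0:50, 1), sample(0:50, 1), sample(0:50, 1), sample(1:50, 1))
      ref <- brute_metrics(unlist(cc))
      expect_equal(precision(cc), ref[["precision"]])
      expect_equal(recall(cc), ref[["recall"]])
      expect_equal(dice(cc), ref[["dice"]])
      expect_equal(accuracy(cc), ref[["accuracy"]])
      # dice equals the harmonic mean of P and R where defined, and lies
      # between them
      p <- precision(cc); r <- recall(cc)
      if (p + r > 0) {
        expect_equal(dice(cc), 2 * p * r / (p + r), tolerance = 1e-12)
        expect_gte(dice(cc) + 1e-12, min(p, r))
        expect_lte(dice(cc) - 1e-12, max(p, r))
      }
    }
  })
})

test_that("corrective_confusion equals the apply-then-compare composition", {
  pred <- binary_mask(matrix(rep(c(TRUE, FALSE), c(10, 26)), 6, 6))
  g <- matrix(FALSE, 6, 6); g[1:3, 1] <- TRUE         # 3 green inside pred
  r <- matrix(FALSE, 6, 6); r[5:6, 6] <- TRUE         # 2 red outside pred
  cc <- corrective_confusion(pred, annotation_mask(g, r))
  expect_equal(unlist(cc), c(tp = 7, fp = 3, fn = 2, tn = 24))

  withr::with_seed(5, {
    for (k in 1:60) {
      pred <- rand_mask()
      ann <- rand_annotation()
      direct <- corrective_confusion(pred, ann)
      composed <- confusion(pred, apply_correction(pred, ann))
      expect_identical(direct, composed)
    }
  })
})

test_that("empty annotation means a perfect prediction by assumption", {
  pred <- rand_mask(10, 10)
  ann <- annotation_mask(matrix(FALSE, 10, 10), matrix(FALSE, 10, 10))
  cc <- corrective_confusion(pred, ann)
  expect_equal(cc$fp, 0)
  expect_equal(cc$fn, 0)
  expect_equal(c(precision(cc), recall(cc), dice(cc), accuracy(cc)), rep(1, 4))
  expect_equal(area_error(pred, ann), 0)
})

test_that("area error is green-in-pred minus red-out-of-pred", {
  pred <- binary_mask(matrix(rep(c(TRUE, FALSE), c(10, 15)), 5, 5))
  g <- matrix(FALSE, 5, 5); g[1:3, 1] <- TRUE
  r <- matrix(FALSE, 5, 5); r[4:5, 5] <- TRUE
  expect_equal(area_error(pred, annotation_mask(g, r)), 1)
  withr::with_seed(9, {
    for (k in 1:30) {
      pred <- rand_mask(); ann <- rand_annotation()
      expect_equal(area_error(pred, ann), brute_corrective(pred, ann)$area_error)
    }
  })
})

test_that("area error of a dilated disk approximates the analytic ring", {
  truth <- disk_mask(40)
  pred <- binary_mask(corrseg:::dilate_disc(unclass(truth), 2))
  ann <- derive_annotation(pred, truth, completeness = 1, seed = 1)
  ring <- pi * (42^2 - 40^2)
  expect_lt(abs(area_error(pred, ann) - ring) / ring, 0.10)
  expect_gt(area_error(pred, ann), 0)  # dilation means over-prediction
})

test_that("evaluate_sequence scores pairs in order with per-image context", {
  expect_error(evaluate_sequence(data.frame(x = 1)), "list-columns")
  pred <- rand_mask(8, 8)
  perfect <- annotation_mask(matrix(FALSE, 8, 8), matrix(FALSE, 8, 8))
  pairs <- tibble::tibble(pred = list(pred, pred), ann = list(perfect, perfect))
  log <- evaluate_sequence(pairs)
  expect_s3_class(log, "training_log")
  expect_equal(log$index, 0:1)
  expect_true(all(log$dice == 1) && all(log$area_error_px == 0))

  bad <- tibble::tibble(image_id = c("a", "b"),
                        pred = list(pred, rand_mask(4, 4)),
                        ann = list(perfect, perfect))
  expect_error(evaluate_sequence(bad), "image 'b'")
})

test_that("sequence evaluation is order-equivariant", {
  withr::with_seed(21, {
    pairs <- tibble::tibble(
      image_id = sprintf("im%02d", 1:8),
      pred = purrr::map(1:8, ~ rand_mask()),
      ann = purrr::map(1:8, ~ rand_annotation()))
    log <- evaluate_sequence(pairs)
    perm <- sample(8)
    log_perm <- evaluate_sequence(pairs[perm, ])
    metric_cols <- c("precision", "recall", "dice", "accuracy", "area_error_px")
    expect_equal(as.data.frame(log_perm[, metric_cols]),
                 as.data.frame(log[perm, metric_cols]),
                 ignore_attr = TRUE)
  })
})

test_that("rolling mean matches naive per-window recomputation", {
  log <- tibble::tibble(index = 0:19, dice = c(rep(0.5, 10), rep(1, 10)))
  expect_equal(rolling_mean(log, "dice", 1)$roll_mean, log$dice)
  const <- tibble::tibble(index = 0:9, dice = rep(0.7, 10))
  expect_equal(rolling_mean(const, "dice", 3)$roll_mean, rep(0.7, 8))
  withr::with_seed(13, {
    x <- stats::runif(40)
    lg <- tibble::tibble(index = seq_along(x) - 1L, dice = x)
    for (n in c(1, 5, 10, 40)) {
      rm <- rolling_mean(lg, "dice", n)
      expect_equal(rm$roll_mean, naive_rolling_mean(x, n))
      expect_equal(rm$index, seq.int(n - 1L, 39L))
    }
    expect_equal(nrow(rolling_mean(lg[1:5, ], "dice", 10)), 0)
  })
})

test_that("stopping index fires at the first sustained window", {
  short <- tibble::tibble(index = 0:8, dice = rep(1, 9))
  expect_true(is.na(stopping_index(short, stopping_rule(10, 0.95))))

  log <- tibble::tibble(index = 0:29, dice = c(rep(0.5, 10), rep(1, 20)))
  expect_equal(stopping_index(log, stopping_rule(10, 0.95)), 19L)
  # a window mean sitting exactly at the threshold only counts if inclusive
  expect_equal(stopping_index(log, stopping_rule(10, 0.95), inclusive = TRUE), 18L)
  all_perfect <- tibble::tibble(index = 0:14, dice = rep(1, 15))
  expect_true(is.na(stopping_index(all_perfect, stopping_rule(10, 1))))
  expect_equal(stopping_index(all_perfect, stopping_rule(10, 1), inclusive = TRUE), 9L)

  # threshold zero fires as soon as the window is full
  expect_equal(stopping_index(log, stopping_rule(10, 1e-9)), 9L)

  # monotone non-decreasing in threshold
  withr::with_seed(17, {
    lg <- tibble::tibble(index = 0:59, dice = pmin(1, cumsum(stats::runif(60, 0, 0.05))))
    idx <- vapply(c(0.2, 0.5, 0.8, 0.95),
                  function(th) {
                    i <- stopping_index(lg, stopping_rule(10, th))
                    if (is.na(i)) 1000L else i
                  }, integer(1))
    expect_true(all(diff(idx) >= 0))
  })
})

test_that("training-log CSV round trip preserves the contract columns", {
  withr::with_seed(23, {
    pairs <- tibble::tibble(pred = purrr::map(1:5, ~ rand_mask()),
                            ann = purrr::map(1:5, ~ rand_annotation()))
    log <- evaluate_sequence(pairs)
    path <- withr::local_tempfile(fileext = ".csv")
    write_training_log(log, path)
    back <- read_training_log(path)
    cols <- c("image_id", "index", "precision", "recall", "dice", "accuracy",
              "predicted_area_px", "corrected_area_px", "area_error_px")
    expect_equal(names(back), cols)
    expect_equal(as.data.frame(back), as.data.frame(log[, cols]), ignore_attr = TRUE)
  })
})
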