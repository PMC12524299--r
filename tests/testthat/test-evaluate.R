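test_that("leave-one-pairing-out splits partition the conditions", {
  ds <- small_dataset(4)
  for (p in pairing_ids()) {
    sp <- loco_split(ds, p)
    expect_length(sp$train, 7)
    expect_false(p %in% names(sp$train))
    expect_setequal(c(names(sp$train), p), names(ds))
    expect_length(sp$test, 4)
    expect_true(all(vapply(sp$test, `[[`, "", "condition_id") == p))
  }
  expect_error(loco_split(ds, "plain"), "single-item")
  expect_error(loco_split(ds[1:4], "plain_peanut"), "no replicates")
})

test_that("curve RMSE matches the elementwise definition", {
  expect_identical(curve_rmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_identical(curve_rmse(c(2, 3, 4), c(1, 2, 3)), 1)
  for (s in 1:20) {
    set.seed(s)
    a <- runif(101, 0, 9)
    b <- runif(101, 0, 9)
    oracle <- 0
    for (i in 1:101) oracle <- oracle + (a[i] - b[i])^2
    expect_lt(abs(curve_rmse(a, b) - sqrt(oracle / 101)), 1e-12)
  }
  expect_error(curve_rmse(1:5, 1:4), "grids")
})

test_that("median and IQR agree with an order-statistics oracle", {
  q7 <- function(x, p) {
    x <- sort(x)
    h <- (length(x) - 1) * p + 1
    lo <- floor(h)
    x[lo] + (h - lo) * (x[min(lo + 1, length(x))] - x[lo])
  }
  for (s in 1:10) {
    set.seed(s)
    v <- runif(sample(3:100, 1))
    st <- tdsliking:::rmse_stats(v)
    expect_equal(st$median, q7(v, 0.5))
    expect_equal(st$q1, q7(v, 0.25))
    expect_equal(st$q3, q7(v, 0.75))
    expect_lte(st$q1, st$median)
    expect_lte(st$median, st$q3)
  }
})

test_that("stub predictors give the closed-form evaluation results", {
  ds <- small_dataset(4)
  perfect <- evaluate_architecture(
    ds, predict_fun = function(train, test) test$y
  )
  expect_identical(perfect$pooled$median, 0)
  expect_true(all(unlist(lapply(perfect$per_pairing, `[[`, "values")) == 0))

  zero <- evaluate_architecture(
    ds, predict_fun = function(train, test) {
      lapply(test$y, function(y) rep(0, length(y)))
    }
  )
  expected <- unlist(lapply(pairing_ids(), function(p) {
    vapply(ds[[p]], function(s) sqrt(mean(s$tl^2)), 1)
  }))
  expect_equal(sort(unname(unlist(
    lapply(zero$per_pairing, `[[`, "values")))), sort(expected))

  expect_identical(length(zero$pooled$values), 4L * 4L)
})

test_that("evaluation is deterministic in the seed", {
  ds <- small_dataset(4)
  a <- evaluate_architecture(ds, n_neurons = 32, aux_config = "none",
                             seed = 5)
  b <- evaluate_architecture(ds, n_neurons = 32, aux_config = "none",
                             seed = 5)
  expect_equal(a$pooled, b$pooled)
  expect_equal(a$per_pairing, b$per_pairing)
})

test_that("pooling modes give the pooled median or the median of medians", {
  ds <- small_dataset(4)
  # a stub whose error is a known per-pairing constant: the brand flags of
  # the encoded test inputs identify the held-out pairing
  offs <- c(plain_peanut = 0.5, sesame_peanut = 1,
            plain_strawberry = 2, sesame_strawberry = 4)
  stub <- function(train, test) {
    f <- test$x[[1]][1, c("premium", "sesame", "peanut", "strawberry")]
    cid <- paste(if (f[["premium"]] == 1) "plain" else "sesame",
                 if (f[["peanut"]] == 1) "peanut" else "strawberry",
                 sep = "_")
    lapply(test$y, function(y) y + offs[[cid]])
  }
  pooled <- evaluate_architecture(ds, aux_config = "brand",
                                  predict_fun = stub)
  mom <- evaluate_architecture(ds, aux_config = "brand",
                               predict_fun = stub,
                               pooling = "median_of_medians")
  expect_equal(sort(unname(vapply(pooled$per_pairing, `[[`, 1, "median"))),
               sort(unname(offs)), tolerance = 1e-12)
  # pooled: type-7 median of the 16 concatenated values {.5 x4, 1 x4, 2 x4, 4 x4}
  expect_equal(pooled$pooled$median, 1.5, tolerance = 1e-12)
  # median of the four per-pairing medians {.5, 1, 2, 4}
  expect_equal(mom$pooled$median, 1.5, tolerance = 1e-12)
  expect_equal(mom$pooled$median,
               stats::median(vapply(mom$per_pairing, `[[`, 1, "median")))
})

test_that("ranking orders by pooled median with stable tie-breaks", {
  ds <- small_dataset(4)
  mk_offset_eval <- function(off, n) {
    evaluate_architecture(ds, n_neurons = n, predict_fun =
      function(train, test) lapply(test$y, function(y) y + off))
  }
  r1 <- mk_offset_eval(3.58, 64)
  r2 <- mk_offset_eval(0.44, 128)
  tab <- rank_architectures(list(r1, r2))
  expect_equal(tab$pooled_median, c(0.44, 3.58), tolerance = 1e-12)
  expect_identical(tab$rank, 1:2)
  expect_identical(tab$neurons, c(128L, 64L))
  # permutation invariance
  tab2 <- rank_architectures(list(r2, r1))
  expect_identical(tab[-1], tab2[-1])
  expect_identical(names(tab),
                   c("rank", "neurons", "aux_dim", "aux_config",
                     "pooled_median", "pooled_q1", "pooled_q3",
                     "all_pairs", pairing_ids()))
  expect_identical(rank_architectures(list(r1))$rank, 1L)
  expect_error(rank_architectures(list()), "no results")
})
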