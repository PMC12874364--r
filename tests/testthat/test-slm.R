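make_labeled_segments <- function(n, f = function(m) 3 + 0.1 * m, jitter = 0,
                                  seed = 1) {
  # labelled segment table with log_remaining a known function of the mean
  set.seed(seed)
  m <- runif(n, -50, 0)
  tibble::tibble(
    realization = rep(seq_len(max(1, n %/% 4)), length.out = n),
    segment = sequence(rle(rep(seq_len(max(1, n %/% 4)), length.out = n))$lengths),
    start = 1L, end = 10L, n = 10L,
    mean = m, sd = abs(rnorm(n, 1, 0.1)), trend = rnorm(n, 0, 0.05),
    onset = 10, remaining = 10^(f(m) + rnorm(n, 0, jitter)),
    log_remaining = log10(remaining),
    t_fas = remaining + 10
  )
}

test_that("truncation keeps assembled runs cut at their first assembly", {
  ens <- slm_synthetic_ensemble(3, seed = 2)
  runs <- ensemble_runs(ens)
  # mark run 2 as never assembling
  runs$assembled[2] <- FALSE
  attr(ens, "runs") <- runs
  prep <- slm_truncate(ens)
  expect_equal(ensemble_runs(prep)$realization, c(1L, 3L))
  tr <- tibble::as_tibble(prep)
  for (k in c(1L, 3L)) {
    expect_equal(max(tr$sweep[tr$realization == k]),
                 runs$t_fas[runs$realization == k])
  }
  runs$assembled[] <- FALSE
  attr(ens, "runs") <- runs
  expect_error(slm_truncate(ens), "no assembled")
})

test_that("a single-segment landscape answers every query with its label", {
  seg <- make_labeled_segments(1)
  land <- slm_landscape(seg, bias_reps = 0)
  q <- make_labeled_segments(20, seed = 3)
  pred <- predict(land, q)
  expect_true(all(pred$y_raw == seg$log_remaining))
})

test_that("well-separated coordinate clusters map to their own labels", {
  a <- make_labeled_segments(40, f = function(m) 3 + 0 * m, seed = 4)
  a$mean <- rnorm(40, -60, 0.5); a$remaining <- 1e3; a$log_remaining <- 3
  b <- make_labeled_segments(40, f = function(m) 5 + 0 * m, seed = 5)
  b$mean <- rnorm(40, -5, 0.5); b$remaining <- 1e5; b$log_remaining <- 5
  land <- slm_landscape(dplyr::bind_rows(a, b), bias_reps = 0)
  qa <- a[1:5, ]; qb <- b[1:5, ]
  expect_true(all(predict(land, qa)$y_raw == 3))
  expect_true(all(predict(land, qb)$y_raw == 5))
})

test_that("duplicated training segments leave the landscape unchanged", {
  seg <- make_labeled_segments(30, seed = 6)
  land1 <- slm_landscape(seg, bias_reps = 0)
  land2 <- slm_landscape(dplyr::bind_rows(seg, seg), bias_reps = 0)
  q <- make_labeled_segments(25, seed = 7)
  expect_equal(predict(land1, q)$y_raw, predict(land2, q)$y_raw)
})

test_that("bias correction recovers an injected constant offset", {
  seg <- make_labeled_segments(400, jitter = 0.02, seed = 8)
  # self-consistent landscape: corrections ~ 0
  bias0 <- slm_bias_correction(seg, seed = 1)
  expect_lt(max(abs(bias0$correction)), 0.15)
  # inject a +0.3 offset into the fitted map: the per-bin median signed error
  # (the quantity the correction estimates) should be about -0.3
  land <- slm_landscape(seg, bias_reps = 0)
  land$cells$value <- land$cells$value + 0.3
  land$global_median <- land$global_median + 0.3
  pred <- predict(land, seg)
  per_bin <- tibble::tibble(
    bin = floor(pred$y_raw / 0.5), err = pred$y - pred$y_raw
  ) |>
    dplyr::summarise(med = stats::median(err), n = dplyr::n(), .by = "bin") |>
    dplyr::filter(n >= 10)
  expect_true(all(abs(per_bin$med + 0.3) < 0.15))
  # and the full fit's correction does not worsen the training-side error
  land2 <- slm_landscape(seg, bias_reps = 10, seed = 5)
  pred2 <- predict(land2, make_labeled_segments(100, jitter = 0.02, seed = 20))
  expect_lte(stats::median(abs(pred2$y - pred2$y_bc)),
             stats::median(abs(pred2$y - pred2$y_raw)) + 0.05)
})

test_that("prediction output respects its contracts", {
  seg <- make_labeled_segments(200, jitter = 0.05, seed = 9)
  land <- slm_landscape(seg, seed = 3)
  test <- make_labeled_segments(60, jitter = 0.05, seed = 10)
  pred <- predict(land, test)
  expect_equal(nrow(pred), 60)
  r <- prediction_r(pred)
  expect_true(r >= -1 && r <= 1)
  expect_gt(r, 0.9)  # labels are a near-deterministic function of the mean
  be <- prediction_bin_errors(pred)
  expect_true(all(be$err_slm >= 0) && all(be$err_baseline >= 0))
  # a single test segment yields an undefined correlation but errors remain
  p1 <- predict(land, test[1, ])
  expect_true(is.na(prediction_r(p1)))
  expect_equal(nrow(prediction_bin_errors(p1)), 1)
})

test_that("the synthetic generator is deterministic and honestly labelled", {
  a <- slm_synthetic_ensemble(4, seed = 31)
  b <- slm_synthetic_ensemble(4, seed = 31)
  expect_identical(tibble::as_tibble(a), tibble::as_tibble(b))
  runs <- ensemble_runs(a)
  tr <- tibble::as_tibble(a)
  for (k in runs$realization) {
    expect_equal(sum(tr$realization == k), runs$t_fas[runs$realization == k])
  }
  # segment labels derived by slm_segments agree with the construction
  segs <- slm_segments(a)
  expect_true(all(segs$remaining > 0))
  expect_equal(segs$remaining, segs$t_fas - segs$start)
})

test_that("noiseless synthetic changepoints are recovered exactly", {
  ens <- slm_synthetic_ensemble(4, noise_sd = 0, seed = 6)
  truth <- attr(ens, "truth")
  segs <- slm_segments(ens)
  for (k in 1:4) {
    tr <- truth$start[truth$realization == k]
    fit <- segs$start[segs$realization == k]
    expect_equal(length(fit), length(tr))
    expect_true(all(abs(fit - tr) <= 2))
  }
})

test_that("end-to-end evaluation recovers signal and rejects noise", {
  ens <- slm_synthetic_ensemble(60, noise_sd = 0.5, seed = 5)
  pred <- slm_evaluate(ens, seed = 9)
  expect_gt(prediction_r(pred), 0.9)
  # tiny split contract: (4, 1) on 5 trajectories runs without error
  small <- slm_synthetic_ensemble(5, seed = 12)
  expect_s3_class(slm_evaluate(small, seed = 1), "slm_prediction")
})

test_that("shuffled labels destroy the correlation", {
  ens <- slm_synthetic_ensemble(170, noise_sd = 0.5, seed = 21)
  pred <- slm_evaluate(ens, seed = 2, shuffle_labels = TRUE)
  expect_gte(nrow(pred), 200)
  expect_lte(abs(prediction_r(pred)), 0.15)
})

test_that("predictions are invariant to training-set ordering", {
  seg <- make_labeled_segments(120, jitter = 0.05, seed = 13)
  q <- make_labeled_segments(30, jitter = 0.05, seed = 14)
  land1 <- slm_landscape(seg, bias_reps = 0)
  land2 <- slm_landscape(seg[sample.int(120), ], bias_reps = 0)
  expect_equal(predict(land1, q)$y_raw, predict(land2, q)$y_raw)
})

test_that("landscapes round-trip through their JSON serialisation", {
  seg <- make_labeled_segments(80, jitter = 0.05, seed = 15)
  land <- slm_landscape(seg, seed = 4)
  path <- withr::local_tempfile(fileext = ".json")
  write_landscape(land, path)
  back <- read_landscape(path)
  q <- make_labeled_segments(20, jitter = 0.05, seed = 16)
  expect_equal(predict(back, q)$y_bc, predict(land, q)$y_bc)
})
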