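space <- synth_grid(16)

test_that("ground truth is seeded-deterministic and respects map contracts", {
  t1 <- make_ground_truth(space, K = 4, A = 1, seed = 7)
  t2 <- make_ground_truth(space, K = 4, A = 1, seed = 7)
  expect_identical(t1$maps, t2$maps)
  expect_equal(colSums(t1$maps^2), rep(1, 5), tolerance = 1e-12,
               ignore_attr = TRUE)
  # pairwise correlations of non-overlapping sources stay below the bound
  C <- abs(cor(t1$maps))
  expect_true(all(C[upper.tri(C)] < 0.4))
  # artifact energy outside gray matter
  gm_in_mask <- as.vector(space$masks$gm)[as.vector(space$grid$brain_mask)]
  art <- t1$maps[, 5]
  expect_lt(sum(art[gm_in_mask]^2), 0.2)
  expect_error(make_ground_truth(space, K = 0, A = 1), "at least K = 2")
  expect_error(make_ground_truth(space, K = 500, A = 0), "infeasible")
})

test_that("overlap option plants exactly one pair with r in [0.4, 0.7]", {
  tr <- make_ground_truth(space, K = 5, A = 0, seed = 3, overlap = TRUE)
  C <- cor(tr$maps)
  ut <- C[upper.tri(C)]
  in_band <- ut >= 0.4 & ut <= 0.7
  expect_equal(sum(in_band), 1)
  expect_true(all(abs(ut[!in_band]) < 0.4))
})

test_that("simulated subjects are seeded-deterministic with valid geometry", {
  tr <- make_ground_truth(space, K = 2, A = 1, seed = 2)
  d1 <- suppressWarnings(simulate_subject(tr, 2, 32, subject_seed = 11))
  d2 <- suppressWarnings(simulate_subject(tr, 2, 32, subject_seed = 11))
  expect_identical(d1$data, d2$data)
  expect_error(simulate_subject(tr, 2, 4, subject_seed = 1), "at least 8")
  expect_warning(simulate_subject(tr, 2, 32, subject_seed = 1), "64")
})

test_that("noiseless unjittered data lies exactly in the span of the maps", {
  tr <- make_ground_truth(space, K = 3, A = 1, seed = 4)
  ds <- simulate_subject(tr, 2, 80, subject_seed = 5, noise_sd = 0,
                         jitter = FALSE)
  V <- matrix(ds$data, prod(tr$grid$dims))[as.vector(tr$grid$brain_mask), ]
  M <- tr$maps
  resid <- V - M %*% solve(crossprod(M), crossprod(M, V))
  expect_lt(sqrt(sum(resid^2)) / sqrt(sum(V^2)), 1e-8)
  # temporal rank equals the number of planted sources
  expect_equal(qr(V)$rank, 4)
})

test_that("generated timecourses obey their spectral contracts", {
  tr <- make_ground_truth(space, K = 2, A = 1, seed = 6)
  ds <- simulate_subject(tr, 2, 200, subject_seed = 9)
  TC <- attr(ds, "truth_draw")$timecourses
  frac_below <- function(x, f) {
    ps <- power_spectrum(x, 2)
    sum(ps$power[ps$frequencies < f]) / sum(ps$power)
  }
  for (k in 1:2) {  # networks: >= 80% of power below 0.1 Hz
    expect_gt(frac_below(TC[k, ], 0.1), 0.8)
    ps <- power_spectrum(TC[k, ], 2)
    expect_gt(power_ratio(ps$frequencies, ps$power), 4)
  }
  # artifact: >= 40% of power above 0.15 Hz
  ps <- power_spectrum(TC[3, ], 2)
  expect_gt(sum(ps$power[ps$frequencies > 0.15]) / sum(ps$power), 0.4)
})

test_that("cohorts have the right shape and duration bookkeeping", {
  co <- shared_run()$co
  expect_length(co$subjects, 12)
  expect_equal(nrow(co$table), 3)
  expect_equal(co$manifest$duration_s, co$manifest$TR * co$manifest$volumes)
  expect_equal(range(co$table$duration_s), c(216, 590))
})

test_that("longer scans do not decrease the median estimated model order", {
  sp <- synth_grid(12)
  tr <- make_ground_truth(sp, K = 2, A = 0, seed = 1)
  med_order <- function(volumes, rep) {
    orders <- vapply(1:2, function(s) {
      ds <- suppressWarnings(
        simulate_subject(tr, 2, volumes, subject_seed = 1000 * rep + s))
      V <- matrix(ds$data, prod(tr$grid$dims))[as.vector(tr$grid$brain_mask), ]
      estimate_model_order(bandpass_filter(V, 2), q_max = 40)
    }, 0L)
    stats::median(orders)
  }
  short <- vapply(1:10, function(r) med_order(64, r), 0)
  long <- vapply(1:10, function(r) med_order(128, r), 0)
  expect_true(all(long >= short))
  expect_gt(stats::median(long), stats::median(short))
})
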