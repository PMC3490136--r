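test_that("back reconstruction solves the exact joint regression", {
  set.seed(1)
  M <- qr.Q(qr(matrix(rnorm(500 * 3), 500, 3)))   # orthonormal maps
  TC <- matrix(rnorm(3 * 60), 3, 60)
  B <- back_reconstruct(M, M %*% TC)
  expect_equal(unname(B), TC, tolerance = 1e-8)
  # overlapping maps (r = 0.5): joint regression still exact
  a <- rnorm(500); b <- rnorm(500)
  m1 <- a
  m2 <- 0.5 * a + sqrt(0.75) * b
  Mo <- cbind(m1, m2)
  TCo <- matrix(rnorm(2 * 40), 2, 40)
  Bo <- back_reconstruct(Mo, Mo %*% TCo)
  expect_equal(unname(Bo), TCo, tolerance = 1e-6)
  # marginal (map-by-map) regression would NOT recover the truth here
  marg <- crossprod(Mo, Mo %*% TCo) / colSums(Mo^2)
  expect_gt(max(abs(marg - TCo)), 0.1)
  expect_error(back_reconstruct(cbind(m1, 0 * m1), Mo %*% TCo), "rank")
  expect_error(back_reconstruct(M, matrix(0, 400, 10)), "grid")
})

test_that("periodogram concentrates a pure tone and conserves variance", {
  tr <- 2; nt <- 200
  tt <- (0:(nt - 1)) * tr
  x <- sin(2 * pi * 0.05 * tt)   # exactly bin 20 of 200 at TR 2
  ps <- power_spectrum(x, tr)
  k <- which.max(ps$power)
  expect_equal(ps$frequencies[k], 0.05)
  expect_gt(ps$power[k] / sum(ps$power), 0.99)
  set.seed(2)
  w <- rnorm(257)
  psw <- power_spectrum(w, 1.5)
  expect_equal(sum(psw$power), mean((w - mean(w))^2), tolerance = 1e-6)
  expect_warning(psc <- power_spectrum(rep(4, 64), 2), "constant")
  expect_true(all(psc$power == 0))
  expect_error(power_spectrum(rnorm(5), 2), "short")
})

test_that("dynamic range is peak power minus post-peak minimum", {
  expect_equal(dynamic_range(1:5 / 10, c(1, 4, 2, 1, 3)), 3)
  expect_equal(dynamic_range(1:4 / 10, rep(2, 4)), 0)
  expect_warning(dr <- dynamic_range(1:4 / 10, c(1, 2, 3, 4)), "last bin")
  expect_equal(dr, 0)
})

test_that("power ratio integrates below 0.1 Hz over above 0.15 Hz", {
  f <- seq(0, 0.25, by = 0.005)
  expect_equal(power_ratio(f, rep(3, length(f))), 1)
  p_lo <- ifelse(f < 0.1, 1, 0)
  expect_equal(power_ratio(f, p_lo), Inf)
  p_hi <- ifelse(f > 0.15, 1, 0)
  expect_equal(power_ratio(f, p_hi), 0)
  expect_error(power_ratio(seq(0, 0.12, by = 0.01), rep(1, 13)), "0.15")
  # scale invariance of the ratio; linear scaling of the dynamic range
  set.seed(3)
  p <- abs(rnorm(length(f))) + 0.1
  expect_equal(power_ratio(f, 7 * p), power_ratio(f, p))
  expect_equal(dynamic_range(f, 7 * p), 7 * dynamic_range(f, p))
})

test_that("group spectra average unit-normalized subject spectra", {
  set.seed(4)
  x <- rnorm(128)
  s1 <- power_spectrum(x, 2)
  gp <- group_spectrum(list(s1, s1, s1))
  # identical subjects: the mean equals each normalized spectrum
  expect_equal(gp$mean_power, gp$spectra[, 1])
  expect_equal(fenica:::trapz(gp$frequencies, gp$mean_power), 1,
               tolerance = 1e-9)
  # heterogeneous TRs: common grid ends at the smallest Nyquist
  s2 <- power_spectrum(rnorm(100), 2.5)
  gp2 <- group_spectrum(list(s1, s2))
  expect_equal(max(gp2$frequencies), 0.2, tolerance = 1e-9)
})

test_that("artifact components score lowest on both spectral metrics", {
  run <- shared_run()
  mt <- match_to_truth(group_maps(run$pl$fit), run$co$truth)
  met <- run$pl$metrics[mt$best_map, ]
  art <- mt$is_artifact
  expect_true(all(met$power_ratio[art] < min(met$power_ratio[!art])))
  expect_true(all(met$dynamic_range[art] < min(met$dynamic_range[!art])))
})
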