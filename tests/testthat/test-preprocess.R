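test_that("smoothing matches a direct convolution oracle", {
  set.seed(2)
  x <- array(rnorm(6 * 7 * 8), c(6, 7, 8))
  fwhm <- 6; vox <- 3
  y <- smooth_volumes(x, fwhm, vox)
  sig <- fwhm / (2 * sqrt(2 * log(2))) / vox
  r <- ceiling(4 * sig)
  w <- exp(-(-r:r)^2 / (2 * sig^2)); w <- w / sum(w)
  kv <- function(d) ifelse(abs(d) <= r, w[pmin(pmax(d + r + 1, 1), 2 * r + 1)], 0)
  ref <- array(0, dim(x))
  for (i in 1:6) for (j in 1:7) for (k in 1:8) {
    acc <- 0
    for (a in 1:6) for (b in 1:7) for (d in 1:8)
      acc <- acc + x[a, b, d] * kv(i - a) * kv(j - b) * kv(k - d)
    ref[i, j, k] <- acc
  }
  expect_equal(y, ref, tolerance = 1e-12)
})

test_that("smoothing identity, constancy and impulse-peak contracts hold", {
  set.seed(3)
  x <- array(rnorm(10^3 * 2), c(10, 10, 10, 2))
  expect_identical(smooth_volumes(x, 0, 3), x)
  # interior voxels (further than the kernel radius from any edge) of a
  # constant volume are unchanged; edges decay from zero padding
  cst <- array(5, c(15, 15, 15))
  sm <- smooth_volumes(cst, 8, 3)
  expect_equal(sm[7:9, 7:9, 7:9], cst[7:9, 7:9, 7:9], tolerance = 1e-9)
  imp <- array(0, c(15, 15, 15)); imp[8, 8, 8] <- 1
  pk <- smooth_volumes(imp, 8, 3)[8, 8, 8]
  sig <- 8 / (2 * sqrt(2 * log(2))) / 3
  expect_equal(pk, (2 * pi * sig^2)^(-3 / 2), tolerance = 0.01)
  expect_error(smooth_volumes(x, -1, 3), "fwhm")
})

make_test_ds <- function(data_fun, nt = 40, dm = c(8, 8, 8), tr = 2) {
  masks <- list(gm = array(FALSE, dm), wm = array(FALSE, dm),
                csf = array(FALSE, dm))
  masks$gm[2:7, 2:7, 2:4] <- TRUE
  masks$wm[2:7, 2:7, 5:6] <- TRUE
  masks$csf[2:7, 2:7, 7] <- TRUE
  dat <- data_fun(dm, nt, masks)
  subject_dataset(dat, tr, masks)
}

test_that("nuisance traces are tissue means; degenerate columns drop", {
  ds <- make_test_ds(function(dm, nt, masks) {
    d <- array(rnorm(prod(dm) * nt), c(dm, nt))
    for (t in seq_len(nt)) {
      v <- d[, , , t]
      v[masks$csf] <- 5
      d[, , , t] <- v
    }
    d
  })
  expect_message(nu <- build_nuisance(ds), "motion")
  expect_equal(unname(nu$traces$csf), rep(5, 40))
  expect_false(any(grepl("motion", nu$names)))
  # empty tissue mask errors with the tissue named
  ds2 <- ds
  ds2$masks$csf[] <- FALSE
  expect_error(build_nuisance(ds2), "csf")
})

test_that("gray-matter trace tracks the dominant network timecourse", {
  set.seed(8)
  nt <- 60
  tc <- as.vector(bandpass_filter(rnorm(nt), 2, 0.01, 0.1))
  ds <- make_test_ds(function(dm, nt, masks) {
    map <- array(0, dm)
    map[masks$gm] <- runif(sum(masks$gm), 0.5, 1)
    array(outer(as.vector(map), tc) + 0.01 * rnorm(prod(dm) * nt), c(dm, nt))
  }, nt = nt)
  nu <- suppressMessages(build_nuisance(ds))
  expect_gt(abs(cor(nu$matrix[, "gm"], tc)), 0.9)
})

test_that("nuisance regression residualizes exactly and robustly", {
  set.seed(4)
  nt <- 50
  D <- cbind(1, scale(1:nt), rnorm(nt), rnorm(nt))
  V <- matrix(rnorm(20 * nt), 20)
  V[1, ] <- D[, 3]                      # voxel equal to a regressor
  R <- regress_out(V, D)
  expect_lt(max(abs(R[1, ])), 1e-10)
  # residuals orthogonal to every regressor
  expect_lt(max(abs(crossprod(t(R), D))) /
              (sqrt(max(rowSums(R^2))) * sqrt(max(colSums(D^2)))), 1e-6)
  # a voxel orthogonal to all regressors is unchanged
  v <- rnorm(nt)
  v <- v - D %*% solve(crossprod(D), crossprod(D, v))
  R2 <- regress_out(matrix(v, 1), D)
  expect_equal(as.vector(R2), as.vector(v), tolerance = 1e-10)
  # duplicated regressor: same residuals as without it (pseudo-inverse oracle)
  Ddup <- cbind(D, D[, 3])
  expect_warning(Rdup <- regress_out(V, Ddup), "collinear")
  P <- Ddup %*% MASS::ginv(Ddup)   # pseudo-inverse projection oracle
  expect_equal(Rdup, V - V %*% P, tolerance = 1e-8)
  expect_equal(Rdup, R, tolerance = 1e-8)
})

test_that("bandpass retains the pass band and kills DC and stop band", {
  nt <- 256; tr <- 2
  tt <- (0:(nt - 1)) * tr
  x05 <- sin(2 * pi * 0.05 * tt)
  x20 <- sin(2 * pi * 0.20 * tt)
  expect_equal(sd(bandpass_filter(x05, tr)) / sd(x05), 1, tolerance = 0.05)
  expect_lt(sd(bandpass_filter(x20, tr)) / sd(x20), 0.05)
  expect_lt(max(abs(bandpass_filter(rep(7, nt), tr))), 1e-10)
  expect_error(bandpass_filter(x05, tr_s = 6, f_hi = 0.1), "Nyquist")
  # zero-phase: a retained pure tone keeps its phase (small spectral
  # leakage at a non-bin frequency aside)
  y <- bandpass_filter(x05, tr)
  expect_gt(cor(y, x05), 0.99)
  # idempotence within tolerance
  y1 <- bandpass_filter(x05 + x20 + 3, tr)
  y2 <- bandpass_filter(y1, tr)
  expect_equal(y1, y2, tolerance = 0.01)
})

test_that("preprocess_subject applies smooth -> regress -> bandpass", {
  set.seed(5)
  ds <- make_test_ds(function(dm, nt, masks)
    array(rnorm(prod(dm) * nt), c(dm, nt)))
  out <- suppressMessages(preprocess_subject(ds, fwhm_mm = 6))
  expect_s3_class(out, "subject_dataset")
  V <- matrix(out$data, prod(dim(out$data)[1:3]))
  # filtered data has no DC component
  expect_lt(max(abs(rowMeans(V))), 1e-8)
  # out-of-mask voxels are zeroed by the masked smoothing
  expect_true(all(V[!as.vector(out$grid$brain_mask), ] == 0))
})
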