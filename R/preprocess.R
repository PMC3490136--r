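# Weissenbacher-style preprocessing: spatial smoothing, nuisance regression
# against mean tissue signals and motion, and 0.01-0.1 Hz bandpass filtering.
# The pipeline order is fixed: smooth -> regress_out -> bandpass.

gauss_kernel_matrix <- function(n, sigma) {
  if (sigma <= 0) return(diag(n))
  r <- max(1L, ceiling(4 * sigma))
  w <- exp(-(-r:r)^2 / (2 * sigma^2))
  w <- w / sum(w)
  K <- matrix(0, n, n)
  for (k in -r:r) {
    idx <- seq_len(n)
    j <- idx + k
    ok <- j >= 1 & j <= n
    K[cbind(idx[ok], j[ok])] <- K[cbind(idx[ok], j[ok])] + w[k + r + 1]
  }
  K
}

#' Spatial Gaussian smoothing of a 4D time series
#'
#' Convolves each volume with a separable isotropic Gaussian of the given
#' full width at half maximum; `sigma_vox = fwhm / (2 sqrt(2 ln 2)) /
#' voxel_size`. Boundaries are zero-padded (the kernel is normalized over its
#' full support, not renormalized at edges) and the brain mask, when given,
#' is applied after smoothing.
#'
#' @param data 4D array (x, y, z, t) or 3D array (one volume).
#' @param fwhm_mm kernel FWHM in mm (default 8, the standard single-subject
#'   smoothing for 3 mm group grids); 0 is the identity.
#' @param voxel_size_mm voxel size in mm (scalar or length 3).
#' @param mask optional logical array; out-of-mask voxels are zeroed after
#'   smoothing.
#' @return Array of the same shape.
#' @export
smooth_volumes <- function(data, fwhm_mm = 8, voxel_size_mm = 3, mask = NULL) {
  if (fwhm_mm < 0) stop("fwhm must be >= 0")
  data <- as.array(data)
  d3 <- length(dim(data)) == 3
  if (d3) dim(data) <- c(dim(data), 1L)
  dm <- dim(data)
  vs <- rep_len(voxel_size_mm, 3)
  sig <- fwhm_mm / (2 * sqrt(2 * log(2))) / vs
  if (fwhm_mm > 0) {
    for (ax in 1:3) {
      perm <- c(ax, setdiff(1:4, ax))
      x <- aperm(data, perm)
      pd <- dim(x)
      K <- gauss_kernel_matrix(pd[1], sig[ax])
      x <- K %*% matrix(x, pd[1])
      dim(x) <- pd
      data <- aperm(x, order(perm))
    }
  }
  if (!is.null(mask)) {
    data <- array(as.vector(data) * rep(as.vector(mask), dm[4]), dm)
  }
  if (d3) dim(data) <- dm[1:3]
  data
}

#' Assemble the nuisance regressor set
#'
#' Builds the per-timepoint nuisance design: intercept, linear trend, mean
#' CSF, white-matter and gray-matter signals (the mean over each tissue mask
#' at every timepoint), and the six motion traces. All-constant motion
#' columns (e.g. the all-zero traces of simulated data) are dropped with a
#' message.
#'
#' @param ds a [subject_dataset()].
#' @param trend include a linear trend column (default TRUE).
#' @return A list of class `nuisance_set` with the design `matrix` (t x p),
#'   its column `names`, and the raw tissue `traces` (kept even when a
#'   degenerate constant column is dropped from the design).
#' @export
build_nuisance <- function(ds, trend = TRUE) {
  nt <- n_timepoints(ds)
  full <- matrix(ds$data, prod(ds$grid$dims), nt)
  cols <- list(intercept = rep(1, nt))
  if (trend) cols$trend <- seq_len(nt) - (nt + 1) / 2
  for (tis in c("csf", "wm", "gm")) {
    m <- as.vector(ds$masks[[tis]])
    if (!any(m)) stop("empty tissue mask: ", tis)
    cols[[tis]] <- colMeans(full[m, , drop = FALSE])
  }
  keep_mot <- apply(ds$motion, 2, function(v) stats::sd(v) > 0)
  if (any(!keep_mot))
    message("dropping ", sum(!keep_mot), " constant motion trace(s)")
  for (j in which(keep_mot)) cols[[paste0("motion", j)]] <- ds$motion[, j]
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  traces <- cols[intersect(c("csf", "wm", "gm"), names(cols))]
  # drop accidentally constant signal columns (they duplicate the intercept)
  cs <- apply(X[, -1, drop = FALSE], 2, stats::sd) < 1e-12
  if (any(cs)) {
    message("dropping constant nuisance column(s): ",
            paste(colnames(X)[-1][cs], collapse = ", "))
    X <- X[, c(TRUE, !cs), drop = FALSE]
  }
  structure(list(matrix = X, names = colnames(X), traces = traces),
            class = "nuisance_set")
}

#' Regress nuisance signals out of a time series
#'
#' Per-voxel least-squares residualization against the nuisance design.
#' Collinear design columns are dropped (with a warning) via a pivoted QR
#' decomposition, so duplicated regressors leave the residuals unchanged.
#' Residuals are orthogonal to every retained regressor.
#'
#' @param data voxels x time matrix, or a 4D array.
#' @param nuisance a [build_nuisance()] result or a plain t x p matrix.
#' @return Residual data of the same shape/class as the input.
#' @export
regress_out <- function(data, nuisance) {
  D <- if (inherits(nuisance, "nuisance_set")) nuisance$matrix else as.matrix(nuisance)
  arr <- is.array(data) && length(dim(data)) == 4
  V <- if (arr) matrix(data, prod(dim(data)[1:3])) else as.matrix(data)
  nt <- ncol(V)
  if (nrow(D) != nt) stop("nuisance design has ", nrow(D), " rows for ", nt, " timepoints")
  if (nt <= ncol(D) + 1) stop("need t > number of regressors + 1")
  qrD <- qr(D)
  if (qrD$rank < ncol(D)) {
    warning("rank-deficient nuisance design: dropping ",
            ncol(D) - qrD$rank, " collinear column(s)")
    D <- D[, qrD$pivot[seq_len(qrD$rank)], drop = FALSE]
    qrD <- qr(D)
  }
  Q <- qr.Q(qrD)
  R <- V - (V %*% Q) %*% t(Q)
  if (arr) array(R, dim(data)) else R
}

#' Zero-phase bandpass filter
#'
#' Discrete-Fourier masking: each voxel's time series is linearly detrended,
#' transformed, frequency bins outside `[f_lo, f_hi]` (including DC) are
#' zeroed, and the series is inverse-transformed. The realization is exactly
#' zero-phase and idempotent up to the detrending step.
#'
#' @param data voxels x time matrix, 4D array, or a single numeric vector.
#' @param tr_s sampling interval (repetition time) in seconds.
#' @param f_lo,f_hi pass band in Hz (defaults 0.01 and 0.1, the canonical
#'   resting-state fluctuation band). `f_hi` must stay below the Nyquist
#'   frequency `1 / (2 tr_s)`.
#' @return Filtered data of the same shape.
#' @export
bandpass_filter <- function(data, tr_s, f_lo = 0.01, f_hi = 0.1) {
  stopifnot(tr_s > 0, f_lo >= 0, f_hi > f_lo)
  nyq <- 1 / (2 * tr_s)
  if (f_hi >= nyq)
    stop(sprintf("upper band edge %.4g Hz reaches the Nyquist frequency %.4g Hz",
                 f_hi, nyq))
  vec <- is.null(dim(data))
  arr <- !vec && length(dim(data)) == 4
  V <- if (vec) matrix(data, 1) else if (arr) matrix(data, prod(dim(data)[1:3])) else as.matrix(data)
  nt <- ncol(V)
  if (nt < 8) stop("need at least 8 timepoints to filter, got ", nt)
  # linear detrend
  tt <- seq_len(nt)
  D <- cbind(1, tt - mean(tt))
  Q <- qr.Q(qr(D))
  V <- V - (V %*% Q) %*% t(Q)
  f <- (seq_len(nt) - 1) / (nt * tr_s)
  fmir <- pmin(f, 1 / tr_s - f)  # two-sided spectrum folded to [0, Nyquist]
  keep <- fmir >= f_lo & fmir <= f_hi
  Ft <- stats::mvfft(t(V))
  Ft[!keep, ] <- 0
  out <- t(Re(stats::mvfft(Ft, inverse = TRUE))) / nt
  if (vec) as.vector(out) else if (arr) array(out, dim(data)) else out
}

#' Run the full preprocessing chain on a subject
#'
#' Fixed order: spatial smoothing, nuisance regression (tissue means,
#' motion, trend), temporal bandpass. Nuisance regressors are built from the
#' smoothed data and are not themselves filtered; stages can be switched off
#' individually (e.g. `bandpass = FALSE` yields the wide-band residual data
#' used for spectral characterization).
#'
#' @param ds a [subject_dataset()].
#' @param fwhm_mm smoothing kernel FWHM in mm (default 8; 0 disables).
#' @param band length-2 pass band in Hz, or `NULL` to skip filtering.
#' @param regress apply nuisance regression (default TRUE).
#' @return The dataset with `data` replaced by the preprocessed series.
#' @export
preprocess_subject <- function(ds, fwhm_mm = 8, band = c(0.01, 0.1),
                               regress = TRUE) {
  stopifnot(inherits(ds, "subject_dataset"))
  x <- smooth_volumes(ds$data, fwhm_mm, ds$grid$voxel_size_mm,
                      mask = ds$grid$brain_mask)
  ds$data <- x
  if (regress) ds$data <- regress_out(ds$data, build_nuisance(ds))
  if (!is.null(band))
    ds$data <- bandpass_filter(ds$data, ds$tr_s, band[1], band[2])
  ds
}
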