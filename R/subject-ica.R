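# Per-subject spatial ICA with automated model-order estimation.
#
# The model order is the Laplace-approximated evidence maximizer of a
# probabilistic-PCA model on the time x time covariance eigenvalues (Minka's
# criterion, the published meaning of MELODIC's "LAP"). The ICA itself is a
# symmetric fixed-point negentropy-maximizing algorithm on the spatial
# dimension (voxels as observations), i.e. spatial ICA.

# Minka's Laplace log-evidence for a k-component PPCA model given the
# covariance eigenvalues lam (descending), N samples, ambient dimension d.
minka_log_evidence <- function(lam, k, n, d) {
  v <- mean(lam[(k + 1):d])
  m <- d * k - k * (k + 1) / 2
  j <- seq_len(k)
  lpu <- -k * log(2) +
    sum(lgamma((d - j + 1) / 2) - ((d - j + 1) / 2) * log(pi))
  lamh <- c(lam[j], rep(v, d - k))
  laz <- 0
  for (i in j) {
    jj <- (i + 1):d
    laz <- laz + sum(log(pmax(1 / lamh[jj] - 1 / lamh[i], 1e-300)) +
                       log(pmax(lam[i] - lam[jj], 1e-300)) + log(n))
  }
  lpu - n / 2 * sum(log(lam[j])) - n * (d - k) / 2 * log(v) +
    (m + k) / 2 * log(2 * pi) - laz / 2 - k / 2 * log(n)
}

#' Estimate the ICA model order of one dataset
#'
#' Returns the dimensionality `q` maximizing the Laplace-approximated log
#' evidence of a probabilistic-PCA model, computed from the eigenvalues of
#' the time-by-time covariance with voxels as observations. When the
#' covariance is numerically rank deficient (exactly low-rank data, or time
#' series whose temporal filtering annihilated out-of-band dimensions) the
#' likelihood is unbounded at the numerical rank, which is then returned
#' (capped at `q_max`): the data determine at most that many components.
#' The result is deterministic and invariant to rescaling the data; note
#' that the evidence depends on the voxel count beyond the covariance
#' (likelihood sharpness), so it is not a pure function of the eigen-spectrum
#' shape.
#'
#' @param data voxels x time matrix (or a `subject_dataset`, flattened over
#'   its brain mask).
#' @param q_max largest admissible order (default 40; must be < t).
#' @return Integer model order in `[1, q_max]`.
#' @export
estimate_model_order <- function(data, q_max = 40) {
  if (inherits(data, "subject_dataset")) data <- mask_matrix(data)
  X <- as.matrix(data)
  if (!all(is.finite(X))) stop("non-finite values in data")
  n <- nrow(X)
  d <- ncol(X)
  if (d < 8) stop("need at least 8 timepoints, got ", d)
  if (q_max >= d) stop("q_max must be smaller than the number of timepoints")
  Xc <- sweep(X, 2, colMeans(X))
  lam <- eigen(crossprod(Xc) / n, symmetric = TRUE, only.values = TRUE)$values
  lam <- pmax(lam, 0)
  rank <- sum(lam > lam[1] * 1e-9)
  if (rank < d) return(as.integer(min(rank, q_max)))
  ks <- seq_len(min(q_max, d - 1))
  ev <- vapply(ks, minka_log_evidence, numeric(1), lam = lam, n = n, d = d)
  as.integer(ks[which.max(ev)])
}

#' Spatial ICA by a fixed-point negentropy algorithm
#'
#' Whitens the data to its `q` leading principal components over the spatial
#' dimension and runs a symmetric fixed-point ICA (tanh contrast) so that the
#' spatial maps are the independent sources and the mixing weights are the
#' component timecourses. Maps are z-scored over voxels, and each component's
#' sign is fixed so its voxelwise skewness is non-negative (networks are
#' sparse positive activations, so this resolves the ICA sign ambiguity
#' before any cross-subject matching). Deterministic given `seed`; on
#' non-convergence the run is retried with derived seeds (up to 5) before
#' erroring.
#'
#' @param data voxels x time matrix (or `subject_dataset`).
#' @param q number of components to extract.
#' @param seed integer seed for the random orthogonal initialization.
#' @param maxit,tol fixed-point iteration limit and convergence tolerance on
#'   the unmixing rotation.
#' @param subject_id,study_label identity carried into the result.
#' @return An object of class `component_set`: z-scored `maps` (in-mask
#'   voxels x q), `timecourses` (q x t), `order`, and identity fields.
#' @export
run_spatial_ica <- function(data, q, seed = 1, maxit = 200, tol = 1e-4,
                            subject_id = "subject", study_label = "study") {
  grid <- NULL
  if (inherits(data, "subject_dataset")) {
    grid <- data$grid
    subject_id <- data$subject_id
    study_label <- data$study_label
    data <- mask_matrix(data)
  }
  X <- as.matrix(data)
  n <- nrow(X)
  nt <- ncol(X)
  stopifnot(q >= 1, q <= min(n, nt))
  Xc <- sweep(X, 2, colMeans(X))
  sv <- svd(Xc, nu = q, nv = 0)
  if (sv$d[q] < sv$d[1] * 1e-12)
    stop("data rank below requested model order q = ", q)
  Z <- sv$u * sqrt(n)  # n x q, unit spatial covariance

  W <- NULL
  for (try in 0:4) {
    W0 <- with_seed(derive_seed(seed, try),
                    qr.Q(qr(matrix(stats::rnorm(q * q), q, q))))
    W1 <- fastica_symm(Z, W0, maxit, tol)
    if (!is.null(W1)) { W <- W1; break }
  }
  if (is.null(W))
    stop("fixed-point ICA failed to converge after 5 seeded restarts")

  S <- Z %*% t(W)                       # n x q spatial sources
  A <- solve(crossprod(S), crossprod(S, Xc))  # q x t mixing timecourses
  # z-convention and positive-skewness sign fix
  S <- zscore_cols(S, "component map")
  for (j in seq_len(q)) {
    if (sample_skewness(S[, j]) < 0) {
      S[, j] <- -S[, j]
      A[j, ] <- -A[j, ]
    }
  }
  structure(list(subject_id = subject_id, study_label = study_label,
                 order = as.integer(q), maps = S, timecourses = A,
                 grid = grid),
            class = "component_set")
}

# Symmetric fixed-point iteration with tanh nonlinearity on whitened data Z
# (n x q). Returns the unmixing rotation W (q x q) or NULL on non-convergence.
fastica_symm <- function(Z, W, maxit, tol) {
  n <- nrow(Z)
  for (it in seq_len(maxit)) {
    Y <- Z %*% t(W)
    G <- tanh(Y)
    W1 <- crossprod(G, Z) / n - diag(colMeans(1 - G^2), ncol(W)) %*% W
    # symmetric decorrelation
    e <- eigen(W1 %*% t(W1), symmetric = TRUE)
    W1 <- e$vectors %*% diag(1 / sqrt(pmax(e$values, 1e-300)), ncol(W)) %*%
      t(e$vectors) %*% W1
    conv <- max(abs(abs(diag(W1 %*% t(W))) - 1))
    W <- W1
    if (conv < tol) return(W)
  }
  NULL
}

#' @export
print.component_set <- function(x, ...) {
  cat(sprintf("component_set %s/%s: q = %d components, %d voxels, t = %d\n",
              x$study_label, x$subject_id, x$order, nrow(x$maps),
              ncol(x$timecourses)))
  invisible(x)
}

#' Estimate order and run spatial ICA for one preprocessed subject
#'
#' @param ds a preprocessed [subject_dataset()].
#' @param q_max cap on the estimated model order.
#' @param q optional fixed order overriding the estimate.
#' @inheritParams run_spatial_ica
#' @return A `component_set`.
#' @export
subject_ica <- function(ds, q_max = 40, q = NULL, seed = 1) {
  stopifnot(inherits(ds, "subject_dataset"))
  X <- mask_matrix(ds)
  if (is.null(q)) q <- estimate_model_order(X, q_max)
  run_spatial_ica(ds, q, seed = seed)
}
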