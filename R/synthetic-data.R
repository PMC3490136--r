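# Multi-study synthetic resting-state cohorts: planted spatial networks in
# gray matter with low-frequency timecourses, CSF-concentrated artifact
# sources with flatter (high-frequency-dominant) spectra, per-subject
# spatial jitter and amplitude variability, and study-level heterogeneity
# in TR and scan duration.

#' Build a spherical-phantom grid with tissue masks
#'
#' A brain-like ball on a cubic grid, partitioned into a central CSF
#' (ventricle-like) core, a white-matter shell and an outer gray-matter
#' shell. The phantom is intentionally simple: it provides disjoint tissue
#' compartments on a common grid, not anatomy.
#'
#' @param dim edge length in voxels (default 20).
#' @param voxel_size_mm voxel size in mm (default 3, the group grid).
#' @return List with `grid` (a [volume_grid()]) and logical `masks`
#'   (`gm`, `wm`, `csf`).
#' @export
synth_grid <- function(dim = 20, voxel_size_mm = 3) {
  stopifnot(dim >= 10)
  c0 <- (dim + 1) / 2
  ax <- seq_len(dim) - c0
  d2 <- outer(outer(ax^2, ax^2, "+"), ax^2, "+")
  dist <- array(sqrt(d2), rep(dim, 3))
  brain <- dist <= 0.45 * dim
  csf <- dist <= 0.18 * dim
  wm <- dist > 0.18 * dim & dist <= 0.32 * dim
  gm <- brain & !csf & !wm
  list(grid = volume_grid(rep(dim, 3), voxel_size_mm, brain),
       masks = list(gm = gm, wm = wm, csf = csf))
}

gaussian_blob <- function(dims, center, sigma) {
  ax <- lapply(1:3, function(k) (seq_len(dims[k]) - center[k])^2)
  d2 <- outer(outer(ax[[1]], ax[[2]], "+"), ax[[3]], "+")
  array(exp(-d2 / (2 * sigma^2)), dims)
}

#' Generate ground-truth spatial sources
#'
#' Plants `K` unit-norm network maps (Gaussian blobs centered in gray
#' matter, pairwise spatial correlation below `max_abs_r`) and `A` artifact
#' maps confined to the CSF/white-matter core (zero energy in gray matter).
#' Networks are tagged with a low-frequency-dominant spectral profile
#' (0.01-0.1 Hz), artifacts with a flatter profile placing most power above
#' 0.15 Hz, emulating pulsation-driven CSF signals. With `overlap = TRUE`
#' the last two network maps share a common lobe (spatial correlation in
#' [0.4, 0.7]), mimicking an anterior/posterior split of one network.
#'
#' @param space a [synth_grid()] result (or compatible list).
#' @param K number of networks (>= 2).
#' @param A number of artifact sources (>= 0).
#' @param seed integer seed; the result is deterministic given it.
#' @param blob_sigma_vox Gaussian blob width in voxels (default 1.8).
#' @param max_abs_r pairwise correlation bound for non-overlapping maps.
#' @param overlap plant one overlapping map pair (default FALSE).
#' @param jitter_sd_mm,amp_sd per-subject spatial jitter (mm) and relative
#'   amplitude variability used downstream by [simulate_subject()].
#' @param artifact_sigma_vox width of artifact blobs (default 1.1): finer
#'   than the CSF compartment, so that the spatially structured part of the
#'   artifact survives mean-CSF nuisance regression — the mechanism by which
#'   consistent CSF artifacts appear in real analyses despite that
#'   regression.
#' @param amp_network,amp_artifact mean source amplitudes. Networks sit at
#'   the noise scale (mean 1, BOLD-like contrast); artifacts are stronger
#'   (mean 3; CSF pulsation is among the largest fMRI signal sources),
#'   compensating for their mostly out-of-band spectral weight and the
#'   CSF-mean regression.
#' @return An object of class `ground_truth`: `maps` (in-mask voxels x
#'   (K+A), unit L2 norm), `is_artifact` flags, spectral profile
#'   parameters, and the subject-variability parameters.
#' @export
make_ground_truth <- function(space, K, A = 0, seed = 1, blob_sigma_vox = 1.8,
                              max_abs_r = 0.4, overlap = FALSE,
                              artifact_sigma_vox = 1.1,
                              jitter_sd_mm = 1.5, amp_sd = 0.25,
                              amp_network = 1, amp_artifact = 3) {
  grid <- space$grid
  masks <- space$masks
  if (K < 2) stop("need at least K = 2 network maps")
  n_mask <- sum(grid$brain_mask)
  if (K + A > n_mask / 100)
    stop("K + A = ", K + A, " sources infeasible for ", n_mask, " in-mask voxels")
  bm <- as.vector(grid$brain_mask)
  gm_idx <- which(as.vector(masks$gm))
  csf_idx <- which(as.vector(masks$csf))
  dims <- grid$dims
  vox_center <- function(i) {
    arrayInd(i, dims)[1, ]
  }
  blob_vec <- function(center, zero_gm = FALSE, sigma = blob_sigma_vox) {
    b <- gaussian_blob(dims, center, sigma)
    if (zero_gm) b[masks$gm] <- 0
    v <- as.vector(b)[bm]
    nv <- sqrt(sum(v^2))
    if (nv == 0) stop("degenerate blob")
    v / nv
  }
  with_seed(seed, {
    maps <- matrix(NA_real_, n_mask, K + A)
    n_free <- if (overlap) K - 2 else K
    k <- 0
    tries <- 0
    while (k < n_free) {
      if ((tries <- tries + 1) > 500)
        stop("could not place ", K, " networks with |r| < ", max_abs_r)
      v <- blob_vec(vox_center(sample(gm_idx, 1)))
      if (k > 0) {
        r <- cross_cor(v, maps[, seq_len(k), drop = FALSE])
        if (max(abs(r)) >= max_abs_r) next
      }
      k <- k + 1
      maps[, k] <- v
    }
    if (overlap) {
      # two maps sharing a common lobe: r = w^2/(1+w^2) ~ 0.5 for
      # near-orthogonal flank blobs at weight w = 1
      repeat {
        ctrs <- lapply(1:3, function(i) vox_center(sample(gm_idx, 1)))
        shared <- blob_vec(ctrs[[1]])
        f1 <- blob_vec(ctrs[[2]])
        f2 <- blob_vec(ctrs[[3]])
        m1 <- f1 + shared
        m2 <- f2 + shared
        m1 <- m1 / sqrt(sum(m1^2))
        m2 <- m2 / sqrt(sum(m2^2))
        r12 <- as.numeric(cross_cor(m1, m2))
        ok_prev <- if (n_free > 0) {
          rp <- cbind(cross_cor(m1, maps[, seq_len(n_free), drop = FALSE]),
                      cross_cor(m2, maps[, seq_len(n_free), drop = FALSE]))
          max(abs(rp)) < max_abs_r
        } else TRUE
        if (r12 >= 0.4 && r12 <= 0.7 && ok_prev) break
      }
      maps[, K - 1] <- m1
      maps[, K] <- m2
    }
    for (a in seq_len(A)) {
      repeat {
        v <- blob_vec(vox_center(sample(csf_idx, 1)), zero_gm = TRUE,
                      sigma = artifact_sigma_vox)
        r <- cross_cor(v, maps[, seq_len(K + a - 1), drop = FALSE])
        if (max(abs(r)) < max_abs_r) break
      }
      maps[, K + a] <- v
    }
    colnames(maps) <- c(paste0("net", seq_len(K)),
                        if (A > 0) paste0("art", seq_len(A)))
    structure(list(grid = grid, masks = masks, maps = maps,
                   is_artifact = c(rep(FALSE, K), rep(TRUE, A)),
                   network_band = c(0.01, 0.1),
                   artifact_highpass = 0.15, artifact_high_weight = 0.65,
                   amp_network = amp_network, amp_artifact = amp_artifact,
                   jitter_sd_mm = jitter_sd_mm, amp_sd = amp_sd,
                   blob_sigma_vox = blob_sigma_vox,
                   artifact_sigma_vox = artifact_sigma_vox, seed = seed),
              class = "ground_truth")
  })
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("ground_truth: %d networks + %d artifacts on %s grid (seed %d)\n",
              sum(!x$is_artifact), sum(x$is_artifact),
              paste(x$grid$dims, collapse = "x"), x$seed))
  invisible(x)
}

# Band-limited unit-sd noise trace; band edges clipped to the grid's
# resolvable range.
bandlimited_noise <- function(nt, tr_s, f_lo, f_hi) {
  nyq <- 1 / (2 * tr_s)
  f_hi <- min(f_hi, 0.999 * nyq)
  x <- bandpass_filter(stats::rnorm(nt), tr_s, f_lo, f_hi)
  s <- stats::sd(x)
  if (s == 0) stop("degenerate band-limited trace")
  x / s
}

# Artifact timecourse: high-frequency-dominant mixture (fraction w_hi of
# variance above `hp` Hz, remainder in the low-frequency band).
artifact_trace <- function(nt, tr_s, hp = 0.15, w_hi = 0.65) {
  nyq <- 1 / (2 * tr_s)
  if (hp >= 0.999 * nyq)
    stop("TR too long to place artifact power above ", hp, " Hz")
  hi <- bandlimited_noise(nt, tr_s, hp, 0.999 * nyq)
  lo <- bandlimited_noise(nt, tr_s, 0.01, 0.1)
  sqrt(w_hi) * hi + sqrt(1 - w_hi) * lo
}

# Integer-voxel translation of an in-mask map (zero fill), plus smooth
# multiplicative field: the per-subject spatial variability model.
jitter_map <- function(v, grid, shift, field) {
  dims <- grid$dims
  full <- numeric(prod(dims))
  full[as.vector(grid$brain_mask)] <- v
  arr <- array(full, dims)
  out <- array(0, dims)
  src <- dst <- vector("list", 3)
  for (k in 1:3) {
    s <- shift[k]
    src[[k]] <- max(1, 1 - s):min(dims[k], dims[k] - s)
    dst[[k]] <- src[[k]] + s
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- arr[src[[1]], src[[2]], src[[3]]]
  w <- as.vector(out)[as.vector(grid$brain_mask)] * field
  nv <- sqrt(sum(w^2))
  if (nv == 0) v else w / nv
}

#' Simulate one subject's 4D dataset from the ground truth
#'
#' Each subject's data is the sum over sources of amplitude x jittered map
#' x timecourse, plus white Gaussian noise. Network timecourses are white
#' noise band-limited to 0.01-0.1 Hz (all power below 0.1 Hz); artifact
#' timecourses place 65% of their variance above 0.15 Hz. Per-subject
#' variability: an integer-voxel spatial translation (sd `jitter_sd_mm`),
#' a smooth multiplicative field, and amplitudes drawn around the truth's
#' `amp_network` / `amp_artifact` means with relative sd `amp_sd`.
#'
#' @param truth a [make_ground_truth()] object.
#' @param tr_s,volumes acquisition parameters (volumes < 64 warns, < 8
#'   errors).
#' @param subject_seed integer seed; identical seeds give identical data.
#' @param noise_sd white-noise standard deviation (default 0.5).
#' @param jitter apply spatial jitter (default TRUE; disable for exact
#'   span/identifiability checks).
#' @param study_label,subject_id identity strings.
#' @return A [subject_dataset()]; the drawn amplitudes and timecourses are
#'   attached as attribute `"truth_draw"`.
#' @export
simulate_subject <- function(truth, tr_s, volumes, subject_seed,
                             noise_sd = 0.5, jitter = TRUE,
                             study_label = "study", subject_id = "subject") {
  stopifnot(inherits(truth, "ground_truth"))
  if (volumes < 8) stop("need at least 8 volumes")
  if (volumes < 64) warning("fewer than 64 volumes: spectra will be unreliable")
  grid <- truth$grid
  n_mask <- sum(grid$brain_mask)
  nsrc <- ncol(truth$maps)
  with_seed(subject_seed, {
    TC <- matrix(NA_real_, nsrc, volumes)
    amp <- numeric(nsrc)
    for (j in seq_len(nsrc)) {
      if (truth$is_artifact[j]) {
        TC[j, ] <- artifact_trace(volumes, tr_s, truth$artifact_highpass,
                                  truth$artifact_high_weight)
        mu <- truth$amp_artifact %||% 3
      } else {
        TC[j, ] <- bandlimited_noise(volumes, tr_s, truth$network_band[1],
                                     truth$network_band[2])
        mu <- truth$amp_network %||% 1
      }
      amp[j] <- max(0.1 * mu, stats::rnorm(1, mu, mu * truth$amp_sd))
    }
    M <- truth$maps
    if (jitter) {
      sd_vox <- truth$jitter_sd_mm / grid$voxel_size_mm[1]
      field_raw <- smooth_volumes(array(stats::rnorm(prod(grid$dims)),
                                        grid$dims),
                                  fwhm_mm = 4 * grid$voxel_size_mm[1],
                                  voxel_size_mm = grid$voxel_size_mm)
      fr <- as.vector(field_raw)[as.vector(grid$brain_mask)]
      field <- 1 + 0.15 * fr / stats::sd(fr)
      M <- vapply(seq_len(nsrc), function(j) {
        shift <- pmax(pmin(round(stats::rnorm(3, 0, sd_vox)), 2L), -2L)
        jitter_map(truth$maps[, j], grid, shift, field)
      }, numeric(n_mask))
    }
    Y <- M %*% (amp * TC)
    if (noise_sd > 0)
      Y <- Y + noise_sd * matrix(stats::rnorm(n_mask * volumes), n_mask)
    ds <- subject_dataset(unmask_matrix(Y, grid), tr_s, truth$masks,
                          grid = grid, study_label = study_label,
                          subject_id = subject_id)
    attr(ds, "truth_draw") <- list(amplitudes = amp, timecourses = TC,
                                   maps = M)
    ds
  })
}

#' Cohort specification
#'
#' @param studies `data.frame` with columns `label`, `n_subjects`, `tr_s`,
#'   `volumes`. The default emulates a small heterogeneous multi-study
#'   collection: 3 studies x 4 subjects with TR 1-2 s and scan durations
#'   spanning 216-590 s.
#' @param dim,voxel_size_mm phantom grid parameters.
#' @param K,A numbers of planted networks and artifact sources.
#' @param noise_sd white-noise sd.
#' @param seed root seed; all subject streams are derived from it.
#' @param overlap plant an overlapping map pair (see
#'   [make_ground_truth()]).
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(studies = NULL, dim = 20, voxel_size_mm = 3, K = 5,
                        A = 1, noise_sd = 0.5, seed = 1, overlap = FALSE) {
  if (is.null(studies))
    studies <- data.frame(label = c("Study_A", "Study_B", "Study_C"),
                          n_subjects = 4,
                          tr_s = c(1.0, 2.0, 2.0),
                          volumes = c(216, 150, 295))
  stopifnot(all(c("label", "n_subjects", "tr_s", "volumes") %in% names(studies)))
  structure(list(studies = studies, dim = dim, voxel_size_mm = voxel_size_mm,
                 K = K, A = A, noise_sd = noise_sd, seed = seed,
                 overlap = overlap),
            class = "cohort_spec")
}

#' Simulate a multi-study cohort
#'
#' Generates the ground truth once and simulates every subject of every
#' study from derived seed streams. The returned study table mirrors the
#' metadata-table layout (label, N, TR, volumes, derived duration).
#'
#' @param spec a [cohort_spec()] (or arguments forwarded to it).
#' @param out_dir optional directory; when given, all volumes and a
#'   manifest TSV are written there.
#' @return A list of class `cohort`: `subjects` (list of
#'   `subject_dataset`s), `table` (a `study_table`), `truth`, `manifest`
#'   and the `spec`.
#' @export
simulate_cohort <- function(spec = cohort_spec(), out_dir = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  space <- synth_grid(spec$dim, spec$voxel_size_mm)
  truth <- make_ground_truth(space, spec$K, spec$A, seed = spec$seed,
                             overlap = spec$overlap)
  st <- spec$studies
  subjects <- list()
  manifest <- NULL
  for (i in seq_len(nrow(st))) {
    for (j in seq_len(st$n_subjects[i])) {
      sid <- sprintf("%s_sub%02d", st$label[i], j)
      ds <- simulate_subject(truth, st$tr_s[i], st$volumes[i],
                             subject_seed = derive_seed(spec$seed, i, j),
                             noise_sd = spec$noise_sd,
                             study_label = st$label[i], subject_id = sid)
      subjects[[sid]] <- ds
      manifest <- rbind(manifest,
                        data.frame(study = st$label[i], subject = sid,
                                   TR = st$tr_s[i], volumes = st$volumes[i],
                                   duration_s = st$tr_s[i] * st$volumes[i]))
    }
  }
  tab <- data.frame(study = st$label, N = st$n_subjects, TR = st$tr_s,
                    volumes = st$volumes)
  tab$duration_s <- tab$TR * tab$volumes
  tab$center <- sub("_[^_]*$", "", tab$study)
  class(tab) <- c("study_table", "data.frame")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (sid in names(subjects))
      write_subject(subjects[[sid]], file.path(out_dir, sid), prefix = sid)
    utils::write.table(manifest, file.path(out_dir, "manifest.tsv"),
                       sep = "\t", row.names = FALSE)
    truth_img <- RNifti::asNifti(unmask_matrix(truth$maps, truth$grid),
                                 datatype = "float")
    RNifti::writeNifti(truth_img, file.path(out_dir, "truth_maps.nii.gz"))
  }
  structure(list(subjects = subjects, table = tab, truth = truth,
                 manifest = manifest, spec = spec),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("cohort: %d subjects in %d studies, %d planted sources (seed %d)\n",
              length(x$subjects), nrow(x$table), ncol(x$truth$maps),
              x$spec$seed))
  invisible(x)
}

#' Match estimated maps against the planted ground truth
#'
#' For every planted source, the best absolute spatial correlation over a
#' set of estimated maps — the end-to-end recovery measure.
#'
#' @param maps voxels x components matrix of estimated maps.
#' @param truth a `ground_truth`.
#' @return `data.frame` with `source`, `is_artifact`, `best_abs_r` and the
#'   index of the best-matching estimated map.
#' @export
match_to_truth <- function(maps, truth) {
  R <- abs(cross_cor(truth$maps, maps))
  data.frame(source = colnames(truth$maps),
             is_artifact = truth$is_artifact,
             best_abs_r = apply(R, 1, max),
             best_map = apply(R, 1, which.max),
             row.names = NULL)
}
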