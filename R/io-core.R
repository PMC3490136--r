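#' Volume grid
#'
#' Describes the common voxel grid all maps and time series live on: the
#' array dimensions, the voxel size in mm, and a brain mask. All spatial maps
#' in the package are flattened over the in-mask voxels in R's native array
#' order (x fastest, 0-based voxel indices when written to file), so vectors
#' from different subjects align element-wise.
#'
#' @param dims integer vector of length 3, voxels per axis.
#' @param voxel_size_mm numeric length 3 (or scalar), voxel edge length in mm.
#'   Defaults to 3 mm isotropic, the resolution group maps are resampled to.
#' @param brain_mask logical array with `dim == dims`; must contain at least
#'   one `TRUE` voxel.
#' @return An object of class `volume_grid`.
#' @export
volume_grid <- function(dims, voxel_size_mm = 3, brain_mask = NULL) {
  dims <- as.integer(dims)
  stopifnot(length(dims) == 3, all(dims > 0))
  voxel_size_mm <- rep_len(as.numeric(voxel_size_mm), 3)
  stopifnot(all(voxel_size_mm > 0))
  if (is.null(brain_mask)) brain_mask <- array(TRUE, dims)
  brain_mask <- array(as.logical(brain_mask), dim(brain_mask))
  if (!identical(dim(brain_mask), dims))
    stop(sprintf("brain mask grid [%s] does not match dims [%s]",
                 paste(dim(brain_mask), collapse = "x"),
                 paste(dims, collapse = "x")))
  if (!any(brain_mask)) stop("brain mask has no TRUE voxel")
  structure(list(dims = dims, voxel_size_mm = voxel_size_mm,
                 brain_mask = brain_mask),
            class = "volume_grid")
}

#' @export
print.volume_grid <- function(x, ...) {
  cat(sprintf("volume_grid: %s voxels @ %s mm, %d in mask\n",
              paste(x$dims, collapse = "x"),
              paste(format(x$voxel_size_mm), collapse = "x"),
              sum(x$brain_mask)))
  invisible(x)
}

#' Single-subject resting-state dataset
#'
#' Bundles one subject's 4D BOLD time series with its repetition time,
#' tissue masks and motion traces. Tissue masks (gray matter, white matter,
#' CSF) must be disjoint subsets of the brain mask; the nominal scan duration
#' is `tr_s * t` seconds.
#'
#' @param data 4D numeric array (x, y, z, t) with t >= 2.
#' @param tr_s repetition time in seconds (positive).
#' @param masks named list with logical arrays `gm`, `wm`, `csf` on the same
#'   grid as `data`.
#' @param grid optional [volume_grid()]; defaults to the union of the tissue
#'   masks as brain mask at 3 mm voxels.
#' @param motion optional t x 6 matrix of rigid-body motion traces (defaults
#'   to all-zero, i.e. no recorded motion).
#' @param study_label,subject_id identifying strings.
#' @return An object of class `subject_dataset`.
#' @export
subject_dataset <- function(data, tr_s, masks, grid = NULL, motion = NULL,
                            study_label = "study", subject_id = "subject") {
  data <- as.array(data)
  if (length(dim(data)) != 4) stop("data must be a 4D array (x, y, z, t)")
  nt <- dim(data)[4]
  if (nt < 2) stop("time series needs t >= 2 volumes, got ", nt)
  if (!all(is.finite(data))) stop("non-finite values in data")
  stopifnot(is.numeric(tr_s), tr_s > 0)
  sdim <- dim(data)[1:3]
  for (tis in c("gm", "wm", "csf")) {
    if (is.null(masks[[tis]])) stop("missing tissue mask: ", tis)
    if (!identical(as.integer(dim(masks[[tis]])), as.integer(sdim)))
      stop(sprintf("mask grid [%s] does not match data grid [%s] (%s)",
                   paste(dim(masks[[tis]]), collapse = "x"),
                   paste(sdim, collapse = "x"), tis))
    masks[[tis]] <- array(as.logical(masks[[tis]]), sdim)
  }
  if (any(masks$gm & masks$wm) || any(masks$gm & masks$csf) ||
      any(masks$wm & masks$csf))
    stop("tissue masks must be disjoint")
  if (is.null(grid))
    grid <- volume_grid(sdim, 3, masks$gm | masks$wm | masks$csf)
  stopifnot(inherits(grid, "volume_grid"),
            identical(grid$dims, as.integer(sdim)))
  if (any((masks$gm | masks$wm | masks$csf) & !grid$brain_mask))
    stop("tissue masks must be subsets of the brain mask")
  if (is.null(motion)) motion <- matrix(0, nt, 6)
  motion <- as.matrix(motion)
  if (nrow(motion) != nt || ncol(motion) != 6)
    stop("motion must be a t x 6 matrix")
  structure(list(study_label = study_label, subject_id = subject_id,
                 data = data, tr_s = as.numeric(tr_s), masks = masks[c("gm", "wm", "csf")],
                 grid = grid, motion = motion),
            class = "subject_dataset")
}

#' @export
print.subject_dataset <- function(x, ...) {
  cat(sprintf("subject_dataset %s/%s: %s x %d volumes, TR %.3g s (%.1f s)\n",
              x$study_label, x$subject_id,
              paste(dim(x$data)[1:3], collapse = "x"), dim(x$data)[4],
              x$tr_s, x$tr_s * dim(x$data)[4]))
  invisible(x)
}

n_timepoints <- function(ds) dim(ds$data)[4]

# Flatten a subject's 4D data to an in-mask voxels x time matrix
# (x-fastest order, the package-wide convention).
mask_matrix <- function(ds, mask = NULL) {
  mask <- mask %||% ds$grid$brain_mask
  nt <- dim(ds$data)[4]
  matrix(ds$data, prod(dim(ds$data)[1:3]), nt)[as.vector(mask), , drop = FALSE]
}

# Inverse of mask_matrix: scatter an in-mask matrix back into a 4D array.
unmask_matrix <- function(m, grid) {
  out <- matrix(0, prod(grid$dims), ncol(m))
  out[as.vector(grid$brain_mask), ] <- m
  array(out, c(grid$dims, ncol(m)))
}

#' Read a subject dataset from NIfTI files
#'
#' @param path_4d path to a 4D NIfTI volume.
#' @param path_masks named list/vector with elements `gm`, `wm`, `csf` giving
#'   paths to tissue mask volumes (non-zero = in mask).
#' @param tr_s repetition time in seconds.
#' @param path_motion optional path to a TSV with 6 motion columns.
#' @inheritParams subject_dataset
#' @return A [subject_dataset()].
#' @export
load_subject <- function(path_4d, path_masks, tr_s, path_motion = NULL,
                         study_label = "study", subject_id = "subject") {
  for (p in c(path_4d, unlist(path_masks)))
    if (!file.exists(p)) stop("file not found: ", p)
  vol <- RNifti::readNifti(path_4d)
  masks <- lapply(path_masks[c("gm", "wm", "csf")], function(p) {
    m <- RNifti::readNifti(p)
    array(as.array(m) != 0, dim(m))
  })
  motion <- NULL
  if (!is.null(path_motion))
    motion <- as.matrix(utils::read.delim(path_motion))
  subject_dataset(as.array(vol), tr_s, masks, motion = motion,
                  study_label = study_label, subject_id = subject_id)
}

#' Write a subject dataset (4D data plus masks) as NIfTI
#'
#' Volumes are stored as 32-bit float (standard neuroimaging practice);
#' computation throughout the package is in double precision.
#'
#' @param ds a [subject_dataset()].
#' @param dir output directory (created if needed).
#' @param prefix file name prefix.
#' @return Invisibly, the named vector of file paths written.
#' @export
write_subject <- function(ds, dir, prefix = ds$subject_id) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  vs <- ds$grid$voxel_size_mm
  paths <- c(data = file.path(dir, paste0(prefix, "_bold.nii.gz")))
  arr <- ds$data
  attr(arr, "pixdim") <- c(vs, ds$tr_s)
  RNifti::writeNifti(RNifti::asNifti(arr, datatype = "float"), paths["data"])
  for (tis in names(ds$masks)) {
    p <- file.path(dir, paste0(prefix, "_", tis, ".nii.gz"))
    m <- array(as.integer(ds$masks[[tis]]), ds$grid$dims)
    attr(m, "pixdim") <- vs
    RNifti::writeNifti(RNifti::asNifti(m, datatype = "uint8"), p)
    paths[tis] <- p
  }
  paths["motion"] <- file.path(dir, paste0(prefix, "_motion.tsv"))
  utils::write.table(ds$motion, paths["motion"], sep = "\t",
                     row.names = FALSE, col.names = paste0("mp", 1:6))
  invisible(paths)
}

#' Read a study metadata table
#'
#' Reads a TSV with one row per study (columns `study`, `N`, `TR`, `volumes`;
#' further columns are carried through). The scan duration is derived as
#' `TR * volumes` seconds; when the file also prints a `duration` column it
#' is cross-checked against the derived value to 0.05 s and the computed
#' value wins (with a warning on mismatch). A `components` column, when
#' present, is interpreted as the per-study median ICA model order. The
#' acquisition center is derived from the study label by stripping a trailing
#' `_suffix` (sub-samples of one center share the prefix).
#'
#' @param path path to the TSV file.
#' @return A `data.frame` of class `study_table` with derived columns
#'   `duration_s` and `center`.
#' @export
load_study_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("study", "N", "TR", "volumes")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("study table lacks columns: ", paste(miss, collapse = ", "))
  if (any(d$TR <= 0)) stop("non-positive TR in study table")
  if (any(d$volumes < 1)) stop("non-positive volume count in study table")
  if (any(d$N < 1)) stop("non-positive subject count in study table")
  d$duration_s <- d$TR * d$volumes
  if ("duration" %in% names(d)) {
    off <- abs(d$duration - d$duration_s) > 0.05
    if (any(off))
      warning("printed duration differs from TR x volumes for: ",
              paste(d$study[off], collapse = ", "), " (computed value used)")
  }
  d$center <- sub("_[^_]*$", "", d$study)
  class(d) <- c("study_table", "data.frame")
  d
}

#' @export
summary.study_table <- function(object, ...) {
  out <- list(n_studies = nrow(object),
              n_subjects = sum(object$N),
              n_centers = length(unique(object$center)),
              duration_range = range(object$duration_s),
              tr_range = range(object$TR))
  class(out) <- "summary.study_table"
  out
}

#' @export
print.summary.study_table <- function(x, ...) {
  cat(sprintf("%d studies from %d centers, %d subjects\n",
              x$n_studies, x$n_centers, x$n_subjects))
  cat(sprintf("scan duration %.1f-%.1f s, TR %.2f-%.2f s\n",
              x$duration_range[1], x$duration_range[2],
              x$tr_range[1], x$tr_range[2]))
  invisible(x)
}

#' The 1000 Functional Connectomes study table
#'
#' The packaged per-study metadata table of the 1000 Functional Connectomes
#' resting-state collection (33 study samples from 26 centers): sample size,
#' TR, volume count, derived scan duration, and the median per-subject ICA
#' model order (`components`).
#'
#' @return A `study_table` data frame with 33 rows.
#' @export
fcon1000_studies <- function() {
  load_study_table(system.file("extdata", "fcon1000_studies.tsv",
                               package = "fenica", mustWork = TRUE))
}
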