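# Spectral characterization of group components: back reconstruction of
# per-subject component timecourses, periodogram power spectra, and the
# dynamic-range and power-ratio summary metrics.

#' Back-reconstruct per-subject component timecourses
#'
#' The spatial-regression stage of dual regression: every timepoint's
#' volume is regressed jointly against the full set of group maps, giving
#' one timecourse per group component. Joint (rather than map-by-map)
#' regression correctly separates spatially overlapping maps.
#'
#' @param maps voxels x components matrix of group maps (full column rank).
#' @param data a `subject_dataset` or an in-mask voxels x time matrix.
#'   Spectral metrics are most informative on data that has not been
#'   low-pass filtered.
#' @return components x time matrix of timecourses.
#' @export
back_reconstruct <- function(maps, data) {
  M <- as.matrix(maps)
  V <- if (inherits(data, "subject_dataset")) mask_matrix(data) else as.matrix(data)
  if (nrow(M) != nrow(V))
    stop("maps (", nrow(M), " voxels) and data (", nrow(V), ") share no grid")
  if (any(apply(M, 2, stats::sd) == 0) || qr(M)$rank < ncol(M))
    stop("group map set is rank deficient (zero-variance or collinear maps)")
  B <- solve(crossprod(M), crossprod(M, V))
  rownames(B) <- colnames(M)
  B
}

#' Periodogram power spectrum of a timecourse
#'
#' Mean-removed discrete-Fourier periodogram on the one-sided frequency
#' grid from 0 to Nyquist; the total power equals the (population) variance
#' of the trace (Parseval). A constant trace yields an all-zero spectrum
#' with a warning.
#'
#' @param trace numeric vector, length >= 8.
#' @param tr_s sampling interval in seconds.
#' @return List with `frequencies` (Hz) and `power`.
#' @export
power_spectrum <- function(trace, tr_s) {
  n <- length(trace)
  if (n < 8) stop("trace too short for a spectrum (need >= 8 points)")
  stopifnot(tr_s > 0)
  x <- trace - mean(trace)
  nh <- floor(n / 2)
  freq <- (0:nh) / (n * tr_s)
  if (stats::sd(x) == 0) {
    warning("constant trace: zero spectrum")
    return(list(frequencies = freq, power = numeric(nh + 1)))
  }
  P <- Mod(stats::fft(x))^2 / n^2
  mult <- rep(2, nh + 1)
  mult[1] <- 1
  if (n %% 2 == 0) mult[nh + 1] <- 1
  list(frequencies = freq, power = mult * P[1:(nh + 1)])
}

#' Dynamic range of a power spectrum
#'
#' The difference between the power at the spectral peak and the minimum
#' power at frequencies strictly above the peak. Low-frequency-dominant
#' BOLD networks have a pronounced peak followed by decay, hence a large
#' dynamic range; flat (artifactual) spectra score near zero. If the peak
#' sits at the last bin the value is 0 with a warning.
#'
#' @param frequencies,power the spectrum (>= 2 bins).
#' @return Nonnegative scalar in power units.
#' @export
dynamic_range <- function(frequencies, power) {
  stopifnot(length(power) >= 2, length(frequencies) == length(power))
  pk <- which.max(power)
  if (pk == length(power)) {
    warning("spectral peak at the last bin: dynamic range 0")
    return(0)
  }
  max(power) - min(power[(pk + 1):length(power)])
}

#' Power ratio of a power spectrum
#'
#' The ratio of the integrated power below 0.1 Hz to the integrated power
#' above 0.15 Hz (trapezoidal integration; both interval bounds exclusive,
#' so the 0.1-0.15 Hz gap contributes to neither integral). Requires the
#' grid to extend beyond 0.15 Hz, i.e. a Nyquist frequency above 0.15 Hz
#' (TR below 1/0.3 s). A near-zero denominator returns `Inf`.
#'
#' @param frequencies,power the spectrum.
#' @param eps denominator tolerance for the infinity flag.
#' @return Nonnegative scalar, possibly `Inf`.
#' @export
power_ratio <- function(frequencies, power, eps = 1e-12) {
  if (max(frequencies) <= 0.15)
    stop(sprintf("frequency grid ends at %.4g Hz; power above 0.15 Hz undefined",
                 max(frequencies)))
  lo <- frequencies < 0.1
  hi <- frequencies > 0.15
  num <- trapz(frequencies[lo], power[lo])
  den <- trapz(frequencies[hi], power[hi])
  if (den < eps * max(num, 1)) return(Inf)
  num / den
}

#' Group-level mean spectrum and spectral metrics for one component
#'
#' Interpolates each subject's spectrum linearly onto a common grid (0 to
#' the smallest Nyquist across subjects, at the finest native resolution),
#' normalizes each to unit total power (so heterogeneous TRs and scan
#' lengths weight subjects equally), and averages. Dynamic range and power
#' ratio are computed on the mean spectrum.
#'
#' @param spectra list of [power_spectrum()] results (>= 1).
#' @param label optional component label.
#' @return List of class `spectral_profile`: common `frequencies`, the
#'   per-subject spectra matrix, the group `mean_power`, `dynamic_range`
#'   and `power_ratio`.
#' @export
group_spectrum <- function(spectra, label = NA_character_) {
  if (!length(spectra)) stop("no spectra to average")
  fmax <- min(vapply(spectra, function(s) max(s$frequencies), 0))
  df <- min(vapply(spectra, function(s) min(diff(s$frequencies)), 0))
  if (fmax <= 0 || df <= 0) stop("incompatible frequency grids")
  grid <- seq(0, fmax, by = df)
  if (max(grid) < fmax - 1e-12) grid <- c(grid, fmax)
  P <- vapply(spectra, function(s) {
    p <- stats::approx(s$frequencies, s$power, xout = grid, rule = 2)$y
    tot <- trapz(grid, p)
    if (tot > 0) p / tot else p
  }, numeric(length(grid)))
  mp <- rowMeans(P)
  structure(list(label = label, frequencies = grid, spectra = P,
                 mean_power = mp,
                 dynamic_range = dynamic_range(grid, mp),
                 power_ratio = power_ratio(grid, mp)),
            class = "spectral_profile")
}

#' @export
print.spectral_profile <- function(x, ...) {
  cat(sprintf("spectral profile %s: %d subjects, dynamic range %.3g, power ratio %.3g\n",
              x$label, ncol(x$spectra), x$dynamic_range, x$power_ratio))
  invisible(x)
}

#' Spectral profiles of all group components over a cohort
#'
#' Back-reconstructs every subject's component timecourses from the group
#' maps and aggregates per-component group spectra and metrics. Use
#' wide-band (not low-pass filtered) subject data so power above 0.15 Hz is
#' observable.
#'
#' @param fit a `fenica` object.
#' @param datasets list of `subject_dataset`s on the fit's grid.
#' @param what which maps to back-project (`"mean"` or `"t"`).
#' @return Named list of [group_spectrum()] profiles, one per component.
#' @export
component_spectra <- function(fit, datasets, what = "mean") {
  stopifnot(inherits(fit, "fenica"))
  M <- group_maps(fit, what)
  per_subject <- lapply(datasets, function(ds) {
    B <- back_reconstruct(M, ds)
    lapply(seq_len(nrow(B)), function(k) power_spectrum(B[k, ], ds$tr_s))
  })
  labels <- colnames(M)
  out <- lapply(seq_along(labels), function(k)
    group_spectrum(lapply(per_subject, `[[`, k), label = labels[k]))
  names(out) <- labels
  out
}

#' Tabulate spectral metrics of a component spectra list
#'
#' @param profiles result of [component_spectra()].
#' @return `data.frame` with `label`, `dynamic_range`, `power_ratio`.
#' @export
spectral_metrics <- function(profiles) {
  data.frame(label = vapply(profiles, `[[`, "", "label"),
             dynamic_range = vapply(profiles, `[[`, 0, "dynamic_range"),
             power_ratio = vapply(profiles, `[[`, 0, "power_ratio"),
             row.names = NULL)
}
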