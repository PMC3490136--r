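# Subject-level consistency distributions and hierarchical clustering of
# group components by Kolmogorov-Smirnov distance between map value
# distributions.

#' Subject-level consistency profile of a group component
#'
#' Reuses the per-subject best-match correlations recorded while the
#' candidate was built: the correlation of the candidate's seed average map
#' (the pairwise average that seeded the group component, not the final
#' group mean) with each subject's best-matching component. Subjects whose
#' correlation falls below `Q1 - 1.5 IQR` are flagged as outliers.
#'
#' @param component a `candidate_group_map` / group component (an element of
#'   `fit$components`).
#' @param sets optional list of `component_set`s for recomputation when the
#'   best-match record is missing (recomputed with a warning).
#' @return A list of class `consistency_profile` with the per-subject `r`
#'   table and summary statistics.
#' @export
consistency_profile <- function(component, sets = NULL) {
  bm <- component$best_match
  if (is.null(bm)) {
    if (is.null(sets)) stop("no best-match record and no component sets to recompute from")
    warning("best-match record missing; recomputing against the seed average")
    rs <- vapply(sets, function(s)
      max(abs(as.vector(cross_cor(component$seed_average, s$maps)))), 0)
    bm <- data.frame(subject = seq_along(sets), comp = NA_integer_, r = rs)
  }
  q <- stats::quantile(bm$r, c(0.25, 0.5, 0.75), names = FALSE)
  iqr <- q[3] - q[1]
  structure(list(label = component$label %||% NA_character_,
                 r = bm,
                 median = q[2], q1 = q[1], q3 = q[3],
                 outliers = bm$subject[bm$r < q[1] - 1.5 * iqr]),
            class = "consistency_profile")
}

#' @export
print.consistency_profile <- function(x, ...) {
  cat(sprintf("consistency %s: median r = %.3f [Q1 %.3f, Q3 %.3f], n = %d",
              x$label, x$median, x$q1, x$q3, nrow(x$r)))
  if (length(x$outliers))
    cat(", outlier subject(s): ", paste(x$outliers, collapse = ", "))
  cat("\n")
  invisible(x)
}

#' Consistency profiles of all components of a FENICA fit
#'
#' @param fit a `fenica` object.
#' @return Named list of [consistency_profile()] objects.
#' @export
consistency_profiles <- function(fit) {
  stopifnot(inherits(fit, "fenica"))
  out <- lapply(fit$components, consistency_profile)
  names(out) <- vapply(fit$components, `[[`, "", "label")
  out
}

#' Kolmogorov-Smirnov distance between two maps
#'
#' The supremum over x of the absolute difference between the empirical
#' CDFs of the two maps' voxel values; a value in `[0, 1]` that is invariant
#' under any common strictly increasing transform of both maps.
#'
#' @param map_a,map_b numeric vectors (all in-mask voxel values; no
#'   thresholding is applied).
#' @return KS distance in `[0, 1]`.
#' @export
ks_distance <- function(map_a, map_b) {
  if (!length(map_a) || !length(map_b)) stop("empty map in KS distance")
  sa <- sort(map_a)
  sb <- sort(map_b)
  z <- sort(unique(c(sa, sb)))
  fa <- findInterval(z, sa) / length(sa)
  fb <- findInterval(z, sb) / length(sb)
  max(abs(fa - fb))
}

#' Hierarchical clustering of group components by KS distance
#'
#' Builds the pairwise Kolmogorov-Smirnov distance matrix between component
#' map value distributions and clusters it agglomeratively. Centroid linkage
#' is the default; complete linkage (whose merge heights are non-decreasing)
#' is available behind the `linkage` flag.
#'
#' @param x a `fenica` fit or a voxels x components matrix of maps.
#' @param linkage `"centroid"` (default) or `"complete"`.
#' @param maps_what which maps of a `fenica` fit to cluster (`"mean"` or
#'   `"t"`); ignored for a matrix input.
#' @return A list of class `component_dendrogram` with the `hclust` tree,
#'   the `dist` matrix and the linkage tag.
#' @export
cluster_components <- function(x, linkage = c("centroid", "complete"),
                               maps_what = "mean") {
  linkage <- match.arg(linkage)
  M <- if (inherits(x, "fenica")) group_maps(x, maps_what) else as.matrix(x)
  m <- ncol(M)
  if (m < 2) stop("need at least 2 components to cluster")
  D <- matrix(0, m, m, dimnames = list(colnames(M), colnames(M)))
  for (i in seq_len(m - 1))
    for (j in (i + 1):m)
      D[i, j] <- D[j, i] <- ks_distance(M[, i], M[, j])
  if (any(!is.finite(D))) stop("non-finite KS distances")
  hc <- stats::hclust(stats::as.dist(D), method = linkage)
  structure(list(hclust = hc, dist = D, linkage = linkage),
            class = "component_dendrogram")
}

#' @export
print.component_dendrogram <- function(x, ...) {
  cat(sprintf("component dendrogram: %d components, %s linkage on KS distance\n",
              nrow(x$dist), x$linkage))
  invisible(x)
}

#' @export
plot.component_dendrogram <- function(x, ...) {
  graphics::plot(x$hclust, ylab = "KS distance", xlab = "", sub = "", ...)
  invisible(x)
}
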