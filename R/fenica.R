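# The FENICA group algorithm: candidate-pair identification over all
# cross-subject component pairs, candidate average maps with voxelwise
# one-sample t-statistics, and greedy threshold-based selection of final
# group components ranked by their positive-part t-sum.

#' Spatial correlation of two maps
#'
#' Pearson correlation over in-mask voxels; the similarity measure used
#' throughout candidate matching and final selection.
#'
#' @param map_a,map_b numeric vectors over the same in-mask voxels.
#' @return Correlation in `[-1, 1]`.
#' @export
spatial_correlation <- function(map_a, map_b) {
  if (length(map_a) != length(map_b))
    stop("maps have different lengths (", length(map_a), " vs ", length(map_b), ")")
  if (stats::sd(map_a) == 0 || stats::sd(map_b) == 0)
    stop("zero-variance map in spatial correlation")
  stats::cor(map_a, map_b)
}

# Stack all subjects' maps into one matrix plus an index table.
stack_maps <- function(sets) {
  maps <- do.call(cbind, lapply(sets, `[[`, "maps"))
  idx <- data.frame(
    subject = rep(seq_along(sets), vapply(sets, `[[`, 0L, "order")),
    comp = unlist(lapply(sets, function(s) seq_len(s$order))))
  idx$subject_id <- vapply(sets, `[[`, "", "subject_id")[idx$subject]
  list(maps = maps, idx = idx)
}

#' Identify candidate component pairs across subjects
#'
#' Computes the spatial correlation of every cross-subject pair of
#' single-subject component maps and returns the top `K_total` pairs by
#' correlation, where `K_total` is the total number of components over all
#' subjects (the automated calibration replacing a hand-set pair threshold).
#' Exact ties are broken lexicographically by (subject_a, comp_a, subject_b,
#' comp_b).
#'
#' @param sets list of `component_set` objects (>= 2 subjects).
#' @param n_pairs number of pairs to return; defaults to the total component
#'   count.
#' @return `data.frame` with columns `subject_a`, `comp_a`, `subject_b`,
#'   `comp_b`, `r`, ordered by decreasing `r`.
#' @export
find_candidate_pairs <- function(sets, n_pairs = NULL) {
  if (length(sets) < 2) stop("need components from at least 2 subjects")
  st <- stack_maps(sets)
  k_total <- nrow(st$idx)
  n_pairs <- n_pairs %||% k_total
  C <- crossprod(zscore_cols(st$maps)) / nrow(st$maps)
  same_subj <- outer(st$idx$subject, st$idx$subject, "==")
  C[same_subj] <- -Inf
  C[lower.tri(C, diag = TRUE)] <- -Inf
  keep <- which(C > -Inf, arr.ind = TRUE)
  pairs <- data.frame(subject_a = st$idx$subject[keep[, 1]],
                      comp_a = st$idx$comp[keep[, 1]],
                      subject_b = st$idx$subject[keep[, 2]],
                      comp_b = st$idx$comp[keep[, 2]],
                      r = C[keep])
  # round the sort key so numerically fuzzy ties resolve lexicographically
  ord <- order(-round(pairs$r, 10), pairs$subject_a, pairs$comp_a,
               pairs$subject_b, pairs$comp_b)
  pairs <- pairs[ord, , drop = FALSE][seq_len(min(n_pairs, nrow(pairs))), ,
                                      drop = FALSE]
  rownames(pairs) <- NULL
  pairs
}

#' Build one candidate group map from a seed pair
#'
#' The seed average is the mean of the pair's two z-maps (the second sign-
#' flipped if their correlation is negative). Every subject contributes the
#' component maximizing signed spatial correlation to the seed average
#' (sign-flipped if that correlation is negative); the candidate's group map
#' is the voxelwise mean of the matched maps, its t-map the voxelwise
#' one-sample t across subjects, and its rank key `t_sum` the sum of
#' positive t-values over voxels. Voxels with zero across-subject variance
#' get `t = t_cap` (where the mean is nonzero). Subjects with zero-variance
#' maps are excluded with a warning; more than 10% exclusions is an error.
#'
#' @param pair one row of [find_candidate_pairs()] output (or a list with
#'   the same fields).
#' @param sets list of `component_set` objects.
#' @param t_cap finite stand-in for infinite t at zero-variance voxels
#'   (default 100).
#' @return A list of class `candidate_group_map`: `seed_average`,
#'   `group_mean_map`, `tmap`, `t_sum`, `best_match` (per-subject component
#'   index and correlation with the seed average), and the seed pair.
#' @export
build_candidate <- function(pair, sets, t_cap = 100) {
  a <- sets[[pair$subject_a]]$maps[, pair$comp_a]
  b <- sets[[pair$subject_b]]$maps[, pair$comp_b]
  r_ab <- spatial_correlation(a, b)
  seed_avg <- (a + if (r_ab < 0) -b else b) / 2
  matched <- matrix(NA_real_, length(seed_avg), length(sets))
  bm <- data.frame(subject = seq_along(sets), comp = NA_integer_, r = NA_real_)
  ok <- rep(TRUE, length(sets))
  for (s in seq_along(sets)) {
    vars <- apply(sets[[s]]$maps, 2, stats::sd)
    if (all(vars == 0)) {
      warning("subject ", sets[[s]]$subject_id,
              " has only zero-variance maps; excluded")
      ok[s] <- FALSE
      next
    }
    rs <- as.vector(cross_cor(seed_avg, sets[[s]]$maps[, vars > 0, drop = FALSE]))
    jbest <- which(vars > 0)[which.max(rs)]
    rbest <- max(rs)
    m <- sets[[s]]$maps[, jbest]
    if (rbest < 0) m <- -m
    matched[, s] <- m
    bm$comp[s] <- jbest
    bm$r[s] <- abs(rbest)
  }
  if (mean(!ok) > 0.10) stop("more than 10% of subjects excluded from candidate")
  matched <- matched[, ok, drop = FALSE]
  nsub <- ncol(matched)
  mu <- rowMeans(matched)
  sdv <- sqrt(rowSums((matched - mu)^2) / (nsub - 1))
  tmap <- ifelse(sdv > 0, mu / (sdv / sqrt(nsub)),
                 ifelse(mu != 0, t_cap * sign(mu), 0))
  structure(list(seed_pair = as.list(pair[c("subject_a", "comp_a",
                                            "subject_b", "comp_b", "r")]),
                 seed_average = seed_avg,
                 best_match = bm[ok, , drop = FALSE],
                 group_mean_map = mu, tmap = tmap,
                 t_sum = sum(pmax(tmap, 0))),
            class = "candidate_group_map")
}

# Build all candidates for a pair table, vectorizing the per-subject
# best-match search (one crossprod per subject instead of one per pair).
build_candidates <- function(pairs, sets, t_cap = 100) {
  npair <- nrow(pairs)
  nv <- nrow(sets[[1]]$maps)
  SA <- matrix(NA_real_, nv, npair)
  for (p in seq_len(npair)) {
    a <- sets[[pairs$subject_a[p]]]$maps[, pairs$comp_a[p]]
    b <- sets[[pairs$subject_b[p]]]$maps[, pairs$comp_b[p]]
    SA[, p] <- (a + if (pairs$r[p] < 0) -b else b) / 2
  }
  SAz <- zscore_cols(SA, "seed average")
  nsub <- length(sets)
  best_j <- matrix(NA_integer_, npair, nsub)
  best_r <- matrix(NA_real_, npair, nsub)
  zmaps <- lapply(sets, function(s) zscore_cols(s$maps))
  for (s in seq_len(nsub)) {
    R <- crossprod(SAz, zmaps[[s]]) / nv  # npair x q_s
    best_j[, s] <- max.col(R, ties.method = "first")
    best_r[, s] <- R[cbind(seq_len(npair), best_j[, s])]
  }
  lapply(seq_len(npair), function(p) {
    matched <- vapply(seq_len(nsub), function(s) {
      m <- sets[[s]]$maps[, best_j[p, s]]
      if (best_r[p, s] < 0) -m else m
    }, numeric(nv))
    mu <- rowMeans(matched)
    sdv <- sqrt(rowSums((matched - mu)^2) / (nsub - 1))
    tmap <- ifelse(sdv > 0, mu / (sdv / sqrt(nsub)),
                   ifelse(mu != 0, t_cap * sign(mu), 0))
    structure(list(seed_pair = as.list(pairs[p, c("subject_a", "comp_a",
                                                  "subject_b", "comp_b", "r")]),
                   seed_average = SA[, p],
                   best_match = data.frame(subject = seq_len(nsub),
                                           comp = best_j[p, ],
                                           r = abs(best_r[p, ])),
                   group_mean_map = mu, tmap = tmap,
                   t_sum = sum(pmax(tmap, 0))),
              class = "candidate_group_map")
  })
}

# Deterministic candidate ordering: t_sum descending, ties by seed-pair
# identity (lexicographic).
candidate_order <- function(candidates) {
  sp <- function(f) vapply(candidates, function(cd) as.numeric(cd$seed_pair[[f]]), 0)
  ts <- vapply(candidates, `[[`, 0, "t_sum")
  # rounded key: numerically fuzzy t-sum ties resolve by seed-pair identity
  order(-round(ts, 8), sp("subject_a"), sp("comp_a"), sp("subject_b"), sp("comp_b"))
}

#' Select final group components by greedy deduplication
#'
#' Candidates are visited in descending `t_sum` order (ties broken by
#' seed-pair identity); a candidate is discarded iff the spatial correlation
#' of its group mean map with any already-accepted candidate exceeds
#' `threshold`. All accepted components therefore have mutual correlation
#' at most `threshold`, and the top-ranked candidate is always kept.
#'
#' @param candidates list of `candidate_group_map` objects.
#' @param threshold similarity threshold in (0, 1].
#' @return A list of class `group_component_list`; each element carries the
#'   candidate plus its `rank` and `label` (C.01-style, by t-sum rank).
#' @export
select_final <- function(candidates, threshold) {
  if (length(candidates) == 0) stop("empty candidate list")
  stopifnot(threshold > 0, threshold <= 1)
  ord <- candidate_order(candidates)
  M <- vapply(candidates, `[[`, numeric(length(candidates[[1]]$group_mean_map)),
              "group_mean_map")
  C <- cross_cor(M, M)
  accepted <- integer(0)
  for (i in ord) {
    if (length(accepted) == 0 || all(C[i, accepted] <= threshold))
      accepted <- c(accepted, i)
  }
  out <- lapply(seq_along(accepted), function(k) {
    g <- candidates[[accepted[k]]]
    g$rank <- k
    g$label <- sprintf("C.%02d", k)
    g
  })
  structure(out, class = "group_component_list", threshold = threshold)
}

#' Data-driven choice of the similarity threshold
#'
#' Evaluates [select_final()] over an ascending threshold grid and returns
#' the lowest grid value whose final component count equals `target_count`
#' (the median single-subject model order in the full pipeline). When no
#' grid value matches exactly, the lowest value whose count first reaches
#' `target_count` is returned with a warning; if the target is never
#' reached, an error lists the achievable counts.
#'
#' @param candidates list of `candidate_group_map` objects.
#' @param target_count desired number of final components (>= 1).
#' @param grid ascending candidate thresholds (default 0.50 to 0.95 by 0.01,
#'   matching the two-decimal resolution the threshold is reported at).
#' @return The selected threshold (with the per-grid counts as attribute
#'   `counts`).
#' @export
select_threshold <- function(candidates, target_count,
                             grid = seq(0.50, 0.95, by = 0.01)) {
  stopifnot(target_count >= 1)
  # greedy selection depends only on the candidate correlation matrix, so
  # compute it once and sweep the grid cheaply
  ord <- candidate_order(candidates)
  M <- vapply(candidates, `[[`, numeric(length(candidates[[1]]$group_mean_map)),
              "group_mean_map")
  C <- cross_cor(M, M)
  counts <- vapply(grid, function(th) {
    acc <- integer(0)
    for (i in ord)
      if (length(acc) == 0 || all(C[i, acc] <= th)) acc <- c(acc, i)
    length(acc)
  }, 0L)
  hit <- which(counts == target_count)
  if (length(hit)) {
    th <- grid[hit[1]]
  } else {
    ge <- which(counts >= target_count)
    if (!length(ge))
      stop("target count ", target_count, " unreachable on the grid; ",
           "achieved counts: ", paste(unique(counts), collapse = ", "))
    th <- grid[ge[1]]
    warning("no grid threshold yields exactly ", target_count,
            " components; using lowest threshold reaching >= target (",
            format(th), ", count ", counts[ge[1]], ")")
  }
  attr(th, "counts") <- data.frame(threshold = grid, count = counts)
  th
}

#' Fit FENICA group components to a cohort of single-subject ICA results
#'
#' The full three-stage group algorithm: (1) candidate pairs of matching
#' maps across subjects, as many as there are single-subject components;
#' (2) candidate average maps with voxelwise one-sample t-statistics over
#' all subjects' best-matching components; (3) greedy selection of final
#' group components in descending t-sum order under a similarity threshold
#' chosen as the lowest grid value yielding a number of final components
#' equal to the median single-subject model order (rounded half up).
#'
#' @param sets list of `component_set` objects, one per subject (>= 2).
#' @param threshold optional fixed similarity threshold; by default chosen
#'   by [select_threshold()].
#' @param target_count optional target for the threshold search; defaults to
#'   the rounded median model order.
#' @param t_cap cap for infinite t-values at degenerate voxels.
#' @param grid threshold search grid.
#' @return An object of class `fenica`: final `components` (a
#'   `group_component_list`), the chosen `threshold`, `target_count`,
#'   per-subject `orders`, the candidate pair table, and bookkeeping.
#' @export
fenica <- function(sets, threshold = NULL, target_count = NULL, t_cap = 100,
                   grid = seq(0.50, 0.95, by = 0.01)) {
  if (length(sets) < 2) stop("FENICA needs at least 2 subjects")
  orders <- vapply(sets, `[[`, 0L, "order")
  target_count <- target_count %||% as.integer(round_half_up(stats::median(orders)))
  pairs <- find_candidate_pairs(sets)
  candidates <- build_candidates(pairs, sets, t_cap = t_cap)
  if (is.null(threshold))
    threshold <- select_threshold(candidates, target_count, grid = grid)
  components <- select_final(candidates, as.numeric(threshold))
  structure(list(components = components,
                 threshold = as.numeric(threshold),
                 threshold_counts = attr(threshold, "counts"),
                 target_count = target_count,
                 orders = orders,
                 pairs = pairs,
                 n_candidates = length(candidates),
                 subject_ids = vapply(sets, `[[`, "", "subject_id"),
                 study_labels = vapply(sets, `[[`, "", "study_label"),
                 grid_space = sets[[1]]$grid),
            class = "fenica")
}

#' Extract the final group maps of a fitted FENICA object
#'
#' @param fit a `fenica` object.
#' @param what `"mean"` for the group mean maps (default) or `"t"` for the
#'   voxelwise t-maps.
#' @return voxels x components matrix with component labels as column names.
#' @export
group_maps <- function(fit, what = c("mean", "t")) {
  what <- match.arg(what)
  f <- if (what == "mean") function(g) g$group_mean_map else function(g) g$tmap
  m <- vapply(fit$components, f, numeric(length(fit$components[[1]]$group_mean_map)))
  colnames(m) <- vapply(fit$components, `[[`, "", "label")
  m
}

#' @export
print.fenica <- function(x, ...) {
  cat(sprintf("FENICA fit: %d group components from %d subjects (%d candidates)\n",
              length(x$components), length(x$orders), x$n_candidates))
  cat(sprintf("similarity threshold %.2f (target count %d, median order %s)\n",
              x$threshold, x$target_count, format(stats::median(x$orders))))
  invisible(x)
}

#' @export
summary.fenica <- function(object, ...) {
  comp <- data.frame(
    label = vapply(object$components, `[[`, "", "label"),
    t_sum = vapply(object$components, `[[`, 0, "t_sum"),
    median_r = vapply(object$components,
                      function(g) stats::median(g$best_match$r), 0),
    seed_r = vapply(object$components,
                    function(g) as.numeric(g$seed_pair$r), 0))
  out <- list(components = comp, threshold = object$threshold,
              n_subjects = length(object$orders),
              orders = object$orders)
  class(out) <- "summary.fenica"
  out
}

#' @export
print.summary.fenica <- function(x, ...) {
  cat(sprintf("%d group components (threshold %.2f, %d subjects, model orders %d-%d)\n",
              nrow(x$components), x$threshold, x$n_subjects,
              min(x$orders), max(x$orders)))
  print(x$components, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Plot a FENICA fit
#'
#' Boxplots of the per-subject consistency correlations of each final group
#' component (the subject-level consistency display), ordered by rank.
#'
#' @param x a `fenica` object.
#' @param ... passed to [graphics::boxplot()].
#' @export
plot.fenica <- function(x, ...) {
  rs <- lapply(x$components, function(g) g$best_match$r)
  names(rs) <- vapply(x$components, `[[`, "", "label")
  graphics::boxplot(rs, las = 2, ylab = "correlation with candidate map",
                    main = "subject-level consistency", ...)
  invisible(x)
}
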