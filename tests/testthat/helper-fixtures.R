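# Shared fixtures. The full cohort pipeline run is expensive (~20 s), so it
# is computed once per test session and reused by every test that inspects
# end-to-end behavior.

.fixture_env <- new.env(parent = emptyenv())

shared_run <- function() {
  if (is.null(.fixture_env$run)) {
    co <- simulate_cohort(cohort_spec(seed = 1))
    pl <- suppressMessages(suppressWarnings(fenica_pipeline(co, seed = 1)))
    .fixture_env$run <- list(co = co, pl = pl)
  }
  .fixture_env$run
}

# Hand-made component set (maps: voxels x q), for unit tests of the group
# stage that do not need real ICA output.
fake_set <- function(maps, subject_id = "s", study_label = "study") {
  maps <- as.matrix(maps)
  structure(list(subject_id = subject_id, study_label = study_label,
                 order = ncol(maps), maps = maps,
                 timecourses = matrix(0, ncol(maps), 2), grid = NULL),
            class = "component_set")
}

# Hand-made candidate (only the fields select_final/select_threshold use).
fake_candidate <- function(map, t_sum, sa = 1, ca = 1, sb = 2, cb = 1) {
  structure(list(seed_pair = list(subject_a = sa, comp_a = ca,
                                  subject_b = sb, comp_b = cb, r = 0.9),
                 seed_average = map, group_mean_map = map,
                 best_match = data.frame(subject = 1:2, comp = 1, r = 0.9),
                 tmap = map, t_sum = t_sum),
            class = "candidate_group_map")
}

# Independent brute-force greedy selection: explicit pairwise checks,
# sharing only the documented ordering contract with the implementation.
oracle_greedy_select <- function(candidates, threshold) {
  ts <- vapply(candidates, `[[`, 0, "t_sum")
  key <- sapply(candidates, function(cd)
    sprintf("%09d_%09d_%09d_%09d", cd$seed_pair$subject_a, cd$seed_pair$comp_a,
            cd$seed_pair$subject_b, cd$seed_pair$comp_b))
  ord <- order(-ts, key)
  kept <- list()
  for (i in ord) {
    ok <- TRUE
    for (g in kept) {
      if (stats::cor(candidates[[i]]$group_mean_map, g$group_mean_map) > threshold) {
        ok <- FALSE
        break
      }
    }
    if (ok) kept <- c(kept, list(candidates[[i]]))
  }
  kept
}

# Independent mutual-argmax partner matching oracle (double loop).
oracle_partner_match <- function(R) {
  out <- NULL
  for (s in seq_len(nrow(R))) for (g in seq_len(ncol(R))) {
    if (sum(R[s, ] == max(R[s, ])) == 1 && which.max(R[s, ]) == g &&
        sum(R[, g] == max(R[, g])) == 1 && which.max(R[, g]) == s)
      out <- rbind(out, data.frame(study_comp = s, group_comp = g, r = R[s, g]))
  }
  if (is.null(out)) data.frame(study_comp = integer(0), group_comp = integer(0),
                               r = numeric(0)) else out
}

# Lance-Williams agglomeration oracle (complete and centroid updates),
# independent of stats::hclust.
oracle_agglomerate <- function(D, method) {
  n <- nrow(D)
  sizes <- rep(1, n)
  active <- seq_len(n)
  id <- -seq_len(n)
  merges <- NULL
  heights <- numeric(0)
  Dm <- D
  diag(Dm) <- Inf
  for (step in seq_len(n - 1)) {
    best <- c(NA, NA); bv <- Inf
    for (a in seq_along(active)) for (b in seq_along(active)) if (a < b) {
      i <- active[a]; j <- active[b]
      if (Dm[i, j] < bv) { bv <- Dm[i, j]; best <- c(i, j) }
    }
    i <- best[1]; j <- best[2]
    merges <- rbind(merges, sort(c(id[i], id[j])))
    heights <- c(heights, bv)
    ni <- sizes[i]; nj <- sizes[j]
    for (k in active) if (k != i && k != j) {
      Dm[i, k] <- Dm[k, i] <-
        if (method == "complete") max(Dm[i, k], Dm[j, k])
        else (ni * Dm[i, k] + nj * Dm[j, k]) / (ni + nj) -
          ni * nj * Dm[i, j] / (ni + nj)^2
    }
    sizes[i] <- ni + nj
    id[i] <- step
    active <- setdiff(active, j)
  }
  list(merge = merges, height = heights)
}
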