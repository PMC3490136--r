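test_that("spatial correlation behaves as a similarity measure", {
  set.seed(1)
  m <- rnorm(500)
  expect_equal(spatial_correlation(m, m), 1)
  expect_equal(spatial_correlation(m, -m), -1)
  expect_error(spatial_correlation(m, rep(1, 500)), "zero-variance")
  expect_error(spatial_correlation(m, rnorm(400)), "lengths")
  # null distribution: independent maps are uncorrelated
  rs <- vapply(1:1000, function(s) {
    set.seed(s)
    cor(rnorm(10000), rnorm(10000))
  }, 0)
  expect_gte(mean(abs(rs) < 0.05), 0.99)
})

test_that("candidate pairs are the top cross-subject correlations", {
  set.seed(2)
  base <- rnorm(300)
  s1 <- fake_set(cbind(base + 0.1 * rnorm(300), rnorm(300)), "a")
  s2 <- fake_set(cbind(base + 0.1 * rnorm(300), rnorm(300)), "b")
  pairs <- find_candidate_pairs(list(s1, s2))
  expect_equal(nrow(pairs), 4)  # K_total = 4 components
  expect_true(all(diff(pairs$r) <= 0))
  # the high-correlation pair (comp 1 vs comp 1) ranks first
  expect_equal(unlist(pairs[1, 1:4]), c(subject_a = 1, comp_a = 1,
                                        subject_b = 2, comp_b = 1))
  expect_error(find_candidate_pairs(list(s1)), "2 subjects")
})

test_that("tied candidate pairs resolve lexicographically and stably", {
  set.seed(3)
  m <- rnorm(200)
  # identical maps everywhere: all cross-subject correlations tie at 1
  s <- lapply(c("a", "b", "c"), function(id) fake_set(cbind(m, m), id))
  p1 <- find_candidate_pairs(s)
  p2 <- find_candidate_pairs(s)
  expect_identical(p1, p2)
  expect_equal(nrow(p1), 6)
  ord <- order(p1$subject_a, p1$comp_a, p1$subject_b, p1$comp_b)
  expect_equal(ord, seq_len(6))  # lexicographic within the tie
})

test_that("candidate t-map follows the one-sample t closed form", {
  set.seed(4)
  base <- rnorm(100)
  maps <- lapply(1:3, function(s) {
    m <- base
    m[1] <- s        # voxel 1 holds (1, 2, 3) across subjects
    m
  })
  sets <- lapply(1:3, function(s) fake_set(maps[[s]], paste0("s", s)))
  pair <- find_candidate_pairs(sets)[1, ]
  cand <- build_candidate(pair, sets)
  expect_equal(cand$tmap[1], 2 / (1 / sqrt(3)), tolerance = 1e-9)
  expect_equal(cand$tmap[1], 3.4641, tolerance = 1e-4)
  expect_equal(cand$group_mean_map[1], 2)
})

test_that("zero across-subject variance voxels hit the t cap", {
  m <- c(rnorm(50), 2, -3, 0)
  sets <- lapply(1:4, function(s) fake_set(m, paste0("s", s)))
  pair <- find_candidate_pairs(sets)[1, ]
  cand <- build_candidate(pair, sets)
  expect_equal(cand$group_mean_map, m)
  expect_equal(cand$tmap[51], 100)    # positive mean, sd 0
  expect_equal(cand$tmap[52], -100)   # negative mean, sd 0
  expect_equal(cand$tmap[53], 0)      # zero mean, sd 0
  expect_equal(cand$t_sum, sum(pmax(cand$tmap, 0)))
})

test_that("greedy selection equals a brute-force oracle on small sets", {
  set.seed(5)
  for (rep in 1:10) {
    n_cand <- sample(3:8, 1)
    # correlated family of maps so thresholds actually bite
    base <- matrix(rnorm(400 * 3), 400, 3)
    cands <- lapply(seq_len(n_cand), function(i) {
      w <- rnorm(3)
      map <- as.vector(base %*% w) + 0.5 * rnorm(400)
      fake_candidate(map, t_sum = round(runif(1, 0, 20)),
                     sa = sample(5, 1), ca = sample(9, 1),
                     sb = sample(5, 1) + 5, cb = sample(9, 1))
    })
    for (th in c(0.3, 0.5, 0.7, 0.9)) {
      got <- select_final(cands, th)
      want <- oracle_greedy_select(cands, th)
      expect_equal(length(got), length(want))
      for (k in seq_along(got))
        expect_identical(got[[k]]$group_mean_map, want[[k]]$group_mean_map)
    }
  }
})

test_that("selection keeps the top candidate and dedupes exact copies", {
  set.seed(6)
  m1 <- rnorm(200); m2 <- rnorm(200)
  cands <- list(fake_candidate(m1, 10, 1, 1, 2, 1),
                fake_candidate(m1, 7, 1, 2, 2, 2),   # duplicate of m1
                fake_candidate(m2, 5, 1, 3, 2, 3))
  sel <- select_final(cands, 0.9)
  expect_equal(length(sel), 2)
  expect_equal(sel[[1]]$t_sum, 10)  # the duplicate with higher t_sum survives
  expect_equal(sel[[1]]$rank, 1)
  expect_equal(sel[[2]]$label, "C.02")
  # all pairwise r below threshold: everything kept
  sel2 <- select_final(cands[c(1, 3)], 0.9)
  expect_equal(length(sel2), 2)
  expect_error(select_final(list(), 0.5), "empty")
})

test_that("selection order is invariant to permuting equal-t_sum input", {
  set.seed(7)
  cands <- lapply(1:6, function(i)
    fake_candidate(rnorm(300), t_sum = 5, sa = i, ca = 1, sb = i + 6, cb = 1))
  lab <- function(sel) vapply(sel, function(g) g$seed_pair$subject_a, 0)
  s1 <- select_final(cands, 0.8)
  s2 <- select_final(rev(cands), 0.8)
  expect_identical(lab(s1), lab(s2))
})

test_that("final component count is non-decreasing in the threshold", {
  set.seed(8)
  base <- matrix(rnorm(400 * 4), 400, 4)
  cands <- lapply(1:20, function(i) {
    map <- as.vector(base %*% rnorm(4)) + 0.3 * rnorm(400)
    fake_candidate(map, t_sum = i, sa = i, ca = 1, sb = i + 20, cb = 1)
  })
  counts <- vapply(seq(0.5, 0.95, by = 0.05),
                   function(th) length(select_final(cands, th)), 0L)
  expect_true(all(diff(counts) >= 0))
})

test_that("threshold search returns the lowest grid value hitting the target", {
  set.seed(9)
  base <- matrix(rnorm(400 * 4), 400, 4)
  cands <- lapply(1:12, function(i) {
    map <- as.vector(base %*% rnorm(4)) + 0.3 * rnorm(400)
    fake_candidate(map, t_sum = i, sa = i, ca = 1, sb = i + 12, cb = 1)
  })
  grid <- seq(0.50, 0.95, by = 0.01)
  counts <- vapply(grid, function(th) length(select_final(cands, th)), 0L)
  target <- counts[20]  # an achievable count
  th <- select_threshold(cands, target)
  expect_equal(as.numeric(th), grid[match(target, counts)])
  # unreachable target errors with the achieved counts listed
  expect_error(select_threshold(cands, max(counts) + 5), "unreachable")
  # mutually dissimilar candidates: count constant, lowest grid value wins
  far <- lapply(1:4, function(i)
    fake_candidate(rnorm(300), i, sa = i, ca = 1, sb = i + 4, cb = 1))
  expect_equal(as.numeric(select_threshold(far, 4)), 0.50)
})

test_that("a degenerate cohort of identical subjects returns its q maps", {
  set.seed(10)
  M <- matrix(rnorm(300 * 3), 300, 3)
  sets <- lapply(1:4, function(s) fake_set(M, paste0("s", s)))
  fit <- fenica(sets)
  expect_s3_class(fit, "fenica")
  expect_equal(length(fit$components), 3)
  G <- group_maps(fit)
  R <- abs(cor(G, M))
  expect_true(all(apply(R, 2, max) > 0.999))
  expect_equal(fit$target_count, 3L)
})

test_that("median-order rounding in the target count rounds half up", {
  set.seed(11)
  M2 <- matrix(rnorm(300 * 2), 300, 2)
  M3 <- matrix(rnorm(300 * 3), 300, 3)
  # orders 2 and 3: median 2.5 rounds half up to 3
  sets <- list(fake_set(M2, "a"), fake_set(M3, "b"))
  fit <- fenica(sets, threshold = 0.95)
  expect_equal(fit$target_count, 3L)
})
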