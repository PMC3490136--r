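# Study-level consistency: the full group analysis re-run per study, and
# bidirectional (mutual-best) partner matching of study components against
# whole-cohort group components.

#' Run FENICA on the subjects of one study
#'
#' Identical pipeline to [fenica()] restricted to one study's subjects,
#' with the study-local median model order as target count.
#'
#' @param sets list of `component_set`s for the whole cohort.
#' @param study_label the study to analyse.
#' @param ... passed to [fenica()].
#' @return A `fenica` fit, or `NULL` (with a warning) when the study has
#'   fewer than 2 subjects.
#' @export
run_study_fenica <- function(sets, study_label, ...) {
  sub <- sets[vapply(sets, `[[`, "", "study_label") == study_label]
  if (length(sub) < 2) {
    warning("study ", study_label, " has fewer than 2 subjects; skipped")
    return(NULL)
  }
  fenica(sub, ...)
}

#' Bidirectional partner matching of two component sets
#'
#' A study component s and group component g are partner-matched iff g is
#' the unique argmax of the correlation of s over all group components and
#' s is the unique argmax over all study components for g (mutual best
#' match). Exact argmax ties void the match.
#'
#' @param R correlation matrix, rows = study components, columns = group
#'   components; or `study_maps` and `group_maps` matrices via `...`.
#' @return `data.frame` with `study_comp`, `group_comp`, `r` (possibly 0
#'   rows).
#' @export
partner_match <- function(R) {
  R <- as.matrix(R)
  if (!nrow(R) || !ncol(R)) stop("empty correlation matrix")
  unique_argmax <- function(v) {
    m <- max(v)
    i <- which(v == m)
    if (length(i) == 1L) i else NA_integer_
  }
  row_best <- apply(R, 1, unique_argmax)
  col_best <- apply(R, 2, unique_argmax)
  s <- which(!is.na(row_best) & col_best[row_best] == seq_len(nrow(R)))
  out <- data.frame(study_comp = s, group_comp = row_best[s],
                    r = R[cbind(s, row_best[s])])
  rownames(out) <- NULL
  out
}

#' Study-by-component match matrix
#'
#' For each study's FENICA result, fills one row with the best-match
#' spatial correlation of every group component (the best match over that
#' study's components, reported whether or not a bidirectional match
#' exists), flags bidirectional (mutual-best) matches and strong matches
#' (bidirectional with r at or above `strong_cutoff`), counts per study the
#' components with no bidirectional partner among the group components, and
#' per group component the number of studies holding a bidirectional match.
#' Components are classified into three descriptive categories from the
#' study-level match fraction and the subject-level median consistency:
#' consistent at both levels, inconsistent at both, or discordant.
#'
#' @param study_fits named list of per-study `fenica` fits (NULL entries
#'   are dropped).
#' @param group_fit the whole-cohort `fenica` fit.
#' @param strong_cutoff correlation cutoff for a strong match (default
#'   0.75).
#' @param high_frac,low_frac study-match fractions bounding the "high" and
#'   "low" study-level categories (defaults 2/3 and 1/2).
#' @return A list of class `match_matrix`: `r` (studies x components
#'   best-match correlations), logical `bidirectional` and `strong`
#'   matrices, `unmatched` per study, `study_count` per component, and the
#'   `category` classification.
#' @export
build_match_matrix <- function(study_fits, group_fit, strong_cutoff = 0.75,
                               high_frac = 2 / 3, low_frac = 1 / 2) {
  study_fits <- Filter(Negate(is.null), study_fits)
  if (!length(study_fits)) stop("no study results")
  G <- group_maps(group_fit)
  labels <- colnames(G)
  ns <- length(study_fits)
  r <- matrix(NA_real_, ns, ncol(G),
              dimnames = list(names(study_fits), labels))
  bidi <- matrix(FALSE, ns, ncol(G), dimnames = dimnames(r))
  unmatched <- integer(ns)
  for (i in seq_len(ns)) {
    S <- group_maps(study_fits[[i]])
    keep <- apply(S, 2, stats::sd) > 0
    if (!all(keep)) {
      warning("zero-variance study component(s) excluded in ",
              names(study_fits)[i])
      S <- S[, keep, drop = FALSE]
    }
    R <- cross_cor(S, G)
    r[i, ] <- apply(R, 2, max)
    pm <- partner_match(R)
    bidi[i, pm$group_comp] <- TRUE
    unmatched[i] <- ncol(S) - nrow(pm)
  }
  strong <- bidi & r >= strong_cutoff
  study_count <- colSums(bidi)
  frac <- study_count / ns
  med_r <- vapply(group_fit$components,
                  function(g) stats::median(g$best_match$r), 0)
  subj_high <- med_r >= stats::median(med_r)
  category <- ifelse(frac >= high_frac & subj_high, "high_both",
                     ifelse(frac <= low_frac & !subj_high, "low_both",
                            "discordant"))
  structure(list(r = r, bidirectional = bidi, strong = strong,
                 unmatched = stats::setNames(unmatched, names(study_fits)),
                 study_count = stats::setNames(study_count, labels),
                 category = stats::setNames(category, labels),
                 strong_cutoff = strong_cutoff),
            class = "match_matrix")
}

#' @export
print.match_matrix <- function(x, ...) {
  cat(sprintf("match matrix: %d studies x %d group components\n",
              nrow(x$r), ncol(x$r)))
  shown <- round(x$r * 100)
  cat("best-match correlations x100 (* bidirectional, ** strong):\n")
  disp <- matrix(paste0(shown, ifelse(x$strong, "**",
                                      ifelse(x$bidirectional, "*", ""))),
                 nrow(x$r), dimnames = dimnames(x$r))
  print(disp, quote = FALSE)
  cat("unmatched study components:",
      paste(sprintf("%s=%d", names(x$unmatched), x$unmatched), collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
plot.match_matrix <- function(x, ...) {
  m <- t(x$r)[, rev(seq_len(nrow(x$r))), drop = FALSE]
  graphics::image(seq_len(nrow(m)), seq_len(ncol(m)), m,
                  col = grDevices::gray.colors(64, 0, 1), axes = FALSE,
                  xlab = "", ylab = "", main = "study-level best-match r", ...)
  graphics::axis(1, seq_len(nrow(m)), rownames(m), las = 2, cex.axis = 0.7)
  graphics::axis(2, seq_len(ncol(m)), colnames(m), las = 1, cex.axis = 0.7)
  invisible(x)
}
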