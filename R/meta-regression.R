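# Meta-regressions across studies/components: ordinary least squares and a
# robust MM-estimator (high-breakdown S-scale followed by a redescending
# bisquare M-step at 95% Gaussian efficiency).

regression_result <- function(slope, intercept, se, p, method, n, extra = list()) {
  structure(c(list(slope = slope, intercept = intercept, slope_se = se,
                   p_value = p, method = method, n = n), extra),
            class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("%s fit (n = %d): slope %.5g (se %.3g), intercept %.5g, p = %.3g\n",
              x$method, x$n, x$slope, x$slope_se, x$intercept, x$p_value))
  invisible(x)
}

#' Ordinary least-squares simple regression
#'
#' Closed-form least squares of y on x with a two-sided slope p-value from
#' the t distribution with n - 2 degrees of freedom.
#'
#' @param x,y numeric vectors, n >= 3; `x` must not be constant.
#' @return A `regression_result` (slope, intercept, slope SE, p, method tag
#'   `"OLS"`).
#' @export
ols_fit <- function(x, y) {
  n <- length(x)
  stopifnot(length(y) == n)
  if (n < 3) stop("need at least 3 observations")
  if (stats::sd(x) == 0) stop("constant x: slope undefined")
  xb <- mean(x); yb <- mean(y)
  sxx <- sum((x - xb)^2)
  slope <- sum((x - xb) * (y - yb)) / sxx
  intercept <- yb - slope * xb
  res <- y - intercept - slope * x
  s2 <- sum(res^2) / (n - 2)
  se <- sqrt(s2 / sxx)
  tstat <- if (se > 0) slope / se else Inf * sign(slope)
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  regression_result(slope, intercept, se, p, "OLS", n)
}

#' Robust MM-estimator simple regression
#'
#' MM-estimation via [MASS::rlm()]: a high-breakdown S-estimate of scale
#' followed by a redescending bisquare M-step at 95% Gaussian efficiency
#' (tuning constant 4.685). The slope p-value is two-sided from the robust
#' standard error with n - 2 degrees of freedom. The S-stage resampling is
#' run under a fixed internal seed so the fit is deterministic.
#'
#' @param x,y numeric vectors, n >= 5.
#' @param seed seed for the S-estimate subsampling (default 1).
#' @param maxit IRLS iteration cap.
#' @return A `regression_result` with method tag `"MM"` and the tuning
#'   constant in `$tuning`.
#' @export
mm_fit <- function(x, y, seed = 1, maxit = 100) {
  n <- length(x)
  stopifnot(length(y) == n)
  if (n < 5) stop("need at least 5 observations for an MM fit")
  if (stats::sd(x) == 0) stop("constant x: slope undefined")
  ls <- ols_fit(x, y)
  res <- y - ls$intercept - ls$slope * x
  if (stats::sd(res) <= 1e-10 * max(stats::sd(y), 1e-300)) {
    # exact fit: residual scale 0, the M-step is undefined and the MM
    # estimate coincides with least squares
    return(regression_result(ls$slope, ls$intercept, 0, 0, "MM", n,
                             extra = list(scale = 0, tuning = 4.685,
                                          efficiency = 0.95)))
  }
  fit <- with_seed(seed,
                   MASS::rlm(y ~ x, method = "MM", maxit = maxit,
                             psi = MASS::psi.bisquare, c = 4.685))
  if (!fit$converged)
    stop("MM-estimator did not converge in ", maxit,
         " iterations (final scale ", format(fit$s), ")")
  cf <- summary(fit)$coefficients
  tstat <- cf["x", "t value"]
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  regression_result(unname(cf["x", "Value"]), unname(cf["(Intercept)", "Value"]),
                    unname(cf["x", "Std. Error"]), p, "MM", n,
                    extra = list(scale = fit$s, tuning = 4.685, efficiency = 0.95))
}

#' Regress per-study median model order on scan duration
#'
#' Fits both OLS and robust MM regressions of the per-study median number
#' of ICA components on scan duration in seconds; the relationship that
#' exposes scan duration as a source of between-study heterogeneity (longer
#' scans support higher estimated model orders).
#'
#' @param study_table a `study_table` with `duration_s` and a model-order
#'   column.
#' @param order_col name of the model-order column (default `"components"`,
#'   falling back to `"median_model_order"`).
#' @return List of class `regression_pair` with elements `ols` and `mm`.
#' @export
duration_order_regression <- function(study_table,
                                      order_col = c("components",
                                                    "median_model_order")) {
  order_col <- intersect(order_col, names(study_table))
  if (!length(order_col)) stop("study table has no model-order column")
  keep <- !is.na(study_table[[order_col[1]]])
  x <- study_table$duration_s[keep]
  y <- study_table[[order_col[1]]][keep]
  if (length(x) < 3) stop("need at least 3 studies with model orders")
  structure(list(ols = ols_fit(x, y), mm = mm_fit(x, y),
                 x = x, y = y,
                 xlab = "scan duration [s]", ylab = "median model order"),
            class = "regression_pair")
}

#' Regress study-level on subject-level component consistency
#'
#' x is each component's median subject-level consistency correlation, y
#' the number of studies in which the component has a bidirectional partner
#' match; fits OLS and MM regressions of y on x.
#'
#' @param profiles list of [consistency_profile()]s (or a `fenica` fit).
#' @param match_matrix a [build_match_matrix()] result.
#' @return A `regression_pair`.
#' @export
consistency_consistency_regression <- function(profiles, match_matrix) {
  if (inherits(profiles, "fenica")) profiles <- consistency_profiles(profiles)
  x <- vapply(profiles, `[[`, 0, "median")
  y <- as.numeric(match_matrix$study_count[names(profiles)])
  if (length(x) < 5) stop("need at least 5 components")
  structure(list(ols = ols_fit(x, y), mm = mm_fit(x, y), x = x, y = y,
                 xlab = "median subject-level r",
                 ylab = "studies with bidirectional match"),
            class = "regression_pair")
}

#' @export
print.regression_pair <- function(x, ...) {
  print(x$ols)
  print(x$mm)
  invisible(x)
}

#' Scatterplot of a regression pair with OLS confidence band
#'
#' @param x a `regression_pair`.
#' @param level confidence level of the OLS band (default 0.95).
#' @param ... passed to [graphics::plot()].
#' @export
plot.regression_pair <- function(x, level = 0.95, ...) {
  graphics::plot(x$x, x$y, xlab = x$xlab, ylab = x$ylab, pch = 19, ...)
  xs <- seq(min(x$x), max(x$x), length.out = 100)
  fit <- stats::lm(y ~ x, data = list(x = x$x, y = x$y))
  ci <- stats::predict(fit, data.frame(x = xs), interval = "confidence",
                       level = level)
  graphics::polygon(c(xs, rev(xs)), c(ci[, "lwr"], rev(ci[, "upr"])),
                    col = grDevices::adjustcolor("gray", 0.5), border = NA)
  graphics::abline(x$ols$intercept, x$ols$slope, col = "black")
  graphics::abline(x$mm$intercept, x$mm$slope, col = "red", lty = 2)
  graphics::legend("topleft", c("OLS", "MM"), col = c("black", "red"),
                   lty = c(1, 2), bty = "n")
  invisible(x)
}
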