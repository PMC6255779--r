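#' Mask volume in mm^3
#'
#' Voxel count multiplied by the voxel size.
#'
#' @param mask a [binary_mask].
#' @return Volume in mm^3.
#' @export
compute_volume <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  sum(mask$values) * prod(mask$spacing)
}

#' Dice similarity coefficient
#'
#' `2 |A n B| / (|A| + |B|)` on voxel counts. Both masks must share one
#' grid (shape and spacing). Two empty masks are defined as Dice 1 with a
#' warning.
#'
#' @param A,B [binary_mask] objects on identical grids.
#' @return A `dice_result` with `value`, `n_a`, `n_b`, `n_intersect`.
#' @export
dice_coefficient <- function(A, B) {
  stopifnot(inherits(A, "binary_mask"), inherits(B, "binary_mask"))
  if (!same_grid(A, B))
    stop("masks must share one grid (shape and spacing)", call. = FALSE)
  na <- sum(A$values); nb <- sum(B$values)
  ni <- sum(A$values & B$values)
  if (na + nb == 0) {
    warning("both masks empty; Dice defined as 1")
    value <- 1
  } else {
    value <- 2 * ni / (na + nb)
  }
  structure(list(value = value, n_a = na, n_b = nb, n_intersect = ni),
            class = "dice_result")
}

#' @export
print.dice_result <- function(x, ...) {
  cat(sprintf("Dice = %.4f  (|A| = %d, |B| = %d, |A n B| = %d)\n",
              x$value, x$n_a, x$n_b, x$n_intersect))
  invisible(x)
}

#' Ordinary least squares of measured on reference volumes
#'
#' `measured ~ reference` with classical t-based 95% confidence intervals
#' (n - 2 df) and `rmse = sqrt(mean(residuals^2))`.
#'
#' @param reference,measured numeric vectors of equal length (n >= 3).
#' @return A `regression_result` with `slope`, `intercept`, `r_squared`,
#'   `rmse`, `slope_ci_95`, `intercept_ci_95`, `n`.
#' @export
linear_regression <- function(reference, measured) {
  if (length(reference) != length(measured))
    stop("inputs must have equal length", call. = FALSE)
  n <- length(reference)
  if (n < 3) stop("need n >= 3", call. = FALSE)
  if (sd(reference) == 0)
    stop("degenerate input: zero variance in reference", call. = FALSE)
  fit <- lm(measured ~ reference)
  ci <- suppressMessages(confint(fit, level = 0.95))
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 r_squared = summary(fit)$r.squared,
                 rmse = sqrt(mean(resid(fit)^2)),
                 slope_ci_95 = unname(ci[2, ]),
                 intercept_ci_95 = unname(ci[1, ]), n = n),
            class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("slope %.3f (%.3f; %.3f), intercept %.3f (%.3f; %.3f) mm^3, R^2 %.4f, RMSE %.2f mm^3 [n = %d]\n",
              x$slope, x$slope_ci_95[1], x$slope_ci_95[2], x$intercept,
              x$intercept_ci_95[1], x$intercept_ci_95[2], x$r_squared,
              x$rmse, x$n))
  invisible(x)
}

#' Bland-Altman limits of agreement
#'
#' Differences are `measured - reference`; the limits are
#' `mean_diff +/- 1.96 * sd_diff` with the sample (n - 1) standard
#' deviation.
#'
#' @param measured,reference numeric vectors of equal length (n >= 2).
#' @return A `bland_altman_result` with `mean_diff`, `sd_diff`, `loa_low`,
#'   `loa_high`, `differences`, `means`.
#' @export
bland_altman <- function(measured, reference) {
  if (length(measured) != length(reference))
    stop("inputs must have equal length", call. = FALSE)
  if (length(measured) < 2) stop("degenerate input: need n >= 2", call. = FALSE)
  d <- measured - reference
  m <- mean(d); s <- sd(d)
  structure(list(mean_diff = m, sd_diff = s, loa_low = m - 1.96 * s,
                 loa_high = m + 1.96 * s, differences = d,
                 means = (measured + reference) / 2),
            class = "bland_altman_result")
}

#' @export
print.bland_altman_result <- function(x, ...) {
  cat(sprintf("mean difference %.2f mm^3, 95%% limits of agreement [%.2f; %.2f]\n",
              x$mean_diff, x$loa_low, x$loa_high))
  invisible(x)
}

#' @export
plot.bland_altman_result <- function(x, xlab = "Mean of measured and reference (mm^3)",
                                     ylab = "Difference (mm^3)", ...) {
  plot(x$means, x$differences, xlab = xlab, ylab = ylab, pch = 19, ...)
  abline(h = x$mean_diff, lwd = 2)
  abline(h = c(x$loa_low, x$loa_high), lty = 2)
  invisible(x)
}

#' Paired two-tailed t-test
#'
#' @param a,b numeric vectors of equal length (n >= 2); the differences
#'   must have nonzero variance.
#' @return A list with `t`, `p`, `df`.
#' @export
paired_t_test <- function(a, b) {
  if (length(a) != length(b)) stop("inputs must have equal length", call. = FALSE)
  if (length(a) < 2) stop("need n >= 2", call. = FALSE)
  if (sd(a - b) == 0)
    stop("degenerate input: zero-variance differences", call. = FALSE)
  ht <- t.test(a, b, paired = TRUE)
  list(t = unname(ht$statistic), p = ht$p.value, df = unname(ht$parameter))
}

#' Kolmogorov-Smirnov normality check
#'
#' One-sample KS test of the standardised differences (z-scores) against
#' the standard normal.
#'
#' @param differences numeric vector, n >= 3, nonzero variance.
#' @return A list with `D` and `p`.
#' @export
ks_normality <- function(differences) {
  x <- as.numeric(differences)
  if (length(x) < 3) stop("need n >= 3", call. = FALSE)
  s <- sd(x)
  if (s == 0) stop("degenerate input: zero variance", call. = FALSE)
  z <- (x - mean(x)) / s
  ht <- suppressWarnings(ks.test(z, "pnorm"))
  list(D = unname(ht$statistic), p = ht$p.value)
}

#' Evaluate a multi-profile nodule experiment
#'
#' Builds the summary tables of a phantom experiment from per-nodule
#' volumes and per-repeat Dice values: a regression table (measured vs
#' reference volume, one row per profile), a Bland-Altman table, a Dice
#' table (mean +/- SD over repeats per nodule and profile) and a pairwise
#' paired t-test matrix on the per-nodule mean Dice values.
#'
#' @param volumes data.frame with columns `profile`, `nodule`,
#'   `reference_mm3`, `measured_mm3` (one row per profile x nodule;
#'   `measured_mm3` averaged over repeats).
#' @param dice data.frame with columns `profile`, `nodule`, `repeat_index`,
#'   `dice`; optionally `kind` and `diameter_mm`.
#' @return An `experiment_report` with elements `regression`,
#'   `bland_altman`, `dice`, `t_tests`.
#' @export
evaluate_experiment <- function(volumes, dice) {
  profiles <- unique(volumes$profile)
  nodules <- unique(volumes$nodule)
  complete <- all(vapply(profiles, function(p)
    all(nodules %in% volumes$nodule[volumes$profile == p]), TRUE))
  if (!complete) warning("missing profile x nodule cells; report is partial")

  reg <- do.call(rbind, lapply(profiles, function(p) {
    v <- volumes[volumes$profile == p, ]
    r <- linear_regression(v$reference_mm3, v$measured_mm3)
    data.frame(profile = p, slope = r$slope,
               slope_lo = r$slope_ci_95[1], slope_hi = r$slope_ci_95[2],
               intercept = r$intercept,
               intercept_lo = r$intercept_ci_95[1],
               intercept_hi = r$intercept_ci_95[2],
               r_squared = r$r_squared, rmse = r$rmse, n = r$n)
  }))
  ba <- do.call(rbind, lapply(profiles, function(p) {
    v <- volumes[volumes$profile == p, ]
    b <- bland_altman(v$measured_mm3, v$reference_mm3)
    data.frame(profile = p, mean_diff = b$mean_diff, sd_diff = b$sd_diff,
               loa_low = b$loa_low, loa_high = b$loa_high)
  }))
  dt <- do.call(rbind, lapply(split(dice, dice[c("profile", "nodule")]),
    function(g) {
      if (nrow(g) == 0) return(NULL)
      out <- data.frame(profile = g$profile[1], nodule = g$nodule[1],
                        dice_mean = mean(g$dice), dice_sd = sd(g$dice),
                        n_repeats = nrow(g))
      if ("kind" %in% names(g)) out$kind <- g$kind[1]
      if ("diameter_mm" %in% names(g)) out$diameter_mm <- g$diameter_mm[1]
      out
    }))
  rownames(dt) <- NULL
  np <- length(profiles)
  tt <- NULL
  if (np >= 2) {
    tt <- matrix(NA_real_, np, np, dimnames = list(profiles, profiles))
    for (i in seq_len(np - 1)) for (j in (i + 1):np) {
      a <- dt$dice_mean[dt$profile == profiles[i]][order(dt$nodule[dt$profile == profiles[i]])]
      b <- dt$dice_mean[dt$profile == profiles[j]][order(dt$nodule[dt$profile == profiles[j]])]
      p <- if (length(a) == length(b) && sd(a - b) > 0)
        paired_t_test(a, b)$p else NA_real_
      tt[i, j] <- tt[j, i] <- p
    }
  } else {
    warning("fewer than two profiles; no t-test matrix")
  }
  structure(list(regression = reg, bland_altman = ba, dice = dt, t_tests = tt),
            class = "experiment_report")
}

#' @export
print.experiment_report <- function(x, digits = 3, ...) {
  cat("== Volume regression (measured ~ reference) ==\n")
  print(x$regression, digits = digits, row.names = FALSE)
  cat("\n== Bland-Altman (measured - reference, mm^3) ==\n")
  print(x$bland_altman, digits = digits, row.names = FALSE)
  cat("\n== Dice (mean +/- SD over repeats) ==\n")
  print(x$dice, digits = digits, row.names = FALSE)
  if (!is.null(x$t_tests)) {
    cat("\n== Pairwise paired t-test p-values (per-nodule Dice) ==\n")
    print(round(x$t_tests, 4))
  }
  invisible(x)
}
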