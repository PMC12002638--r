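#' Ordinary least-squares size-scaling fit
#'
#' Used for the figure-level scaling relationships (spine volume against
#' nanomodule count, mean nanocluster volume against spine volume).
#'
#' @param x,y paired finite numeric vectors, n >= 3.
#' @return Object of class `scaling_fit`: list with `slope`, `slope_se`,
#'   `intercept`, `r_squared`, `n` and the 95% slope confidence bounds.
#' @export
fit_size_scaling <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 paired finite observations")
  if (sd(x) == 0) stop("x is degenerate (zero variance)")
  fit <- lm(y ~ x)
  sm <- summary(fit)
  ci <- stats::confint(fit)["x", ]
  structure(list(slope = unname(coef(fit)[2]),
                 slope_se = sm$coefficients["x", "Std. Error"],
                 intercept = unname(coef(fit)[1]),
                 r_squared = sm$r.squared, n = length(x),
                 conf_low = ci[[1]], conf_high = ci[[2]]),
            class = "scaling_fit")
}

#' @export
print.scaling_fit <- function(x, ...) {
  cat(sprintf("scaling_fit: slope = %.4g +/- %.3g, R^2 = %.4f, n = %d\n",
              x$slope, x$slope_se, x$r_squared, x$n))
  invisible(x)
}

#' Homogeneity-of-slopes test between two groups
#'
#' ANCOVA-style comparison: a pooled linear model `y ~ x * group` is fit
#' and the p-value of the interaction term tests slope equality.
#'
#' @param group_a,group_b data frames (or lists) with elements `x` and
#'   `y`, each n >= 3 with non-degenerate x.
#' @return List with `slope_a`, `slope_b` and `p` (slope equality).
#' @export
compare_slopes <- function(group_a, group_b) {
  fa <- fit_size_scaling(group_a$x, group_a$y)
  fb <- fit_size_scaling(group_b$x, group_b$y)
  dat <- data.frame(x = c(group_a$x, group_b$x),
                    y = c(group_a$y, group_b$y),
                    g = rep(c("a", "b"), c(length(group_a$x),
                                           length(group_b$x))))
  fit <- lm(y ~ x * g, data = dat)
  p <- summary(fit)$coefficients["x:gb", "Pr(>|t|)"]
  list(slope_a = fa$slope, slope_b = fb$slope, p = p)
}

#' Two-sample Kolmogorov-Smirnov comparison
#'
#' @param sample_a,sample_b numeric samples, each n >= 5.
#' @return List with `D`, `p` and the two empirical cumulative curves
#'   (`ecdf_a`, `ecdf_b`) for plotting.
#' @export
ks_compare <- function(sample_a, sample_b) {
  stopifnot(length(sample_a) >= 5, length(sample_b) >= 5)
  kt <- suppressWarnings(ks.test(sample_a, sample_b))
  list(D = unname(kt$statistic), p = kt$p.value,
       ecdf_a = stats::ecdf(sample_a), ecdf_b = stats::ecdf(sample_b))
}

#' Fraction tables over a classified spine population
#'
#' Mirrors the figure-level tables: the TC/CC split, the single- versus
#' multiple-nanomodule fractions per input class (spines with zero
#' aligned nanomodules are excluded from those denominators and reported
#' separately), and the full count distribution over 1..4 nanomodules
#' per class. All denominators are reported.
#'
#' @param spine_table a data frame with columns `input_class` and
#'   `n_modules` (an [analyze_spines()] result qualifies; set
#'   `class_col`/`count_col` to use other columns, e.g. the ground
#'   truth).
#' @param class_col,count_col column names to tabulate.
#' @return List of data frames: `input_fractions`, `module_fractions`,
#'   `count_pmf`, plus `n_total`.
#' @export
fraction_tables <- function(spine_table, class_col = "input_class",
                            count_col = "n_modules") {
  cls <- spine_table[[class_col]]
  cnt <- spine_table[[count_col]]
  stopifnot(!is.null(cls), !is.null(cnt))
  classes <- c("CC", "TC")
  n_tot <- sum(cls %in% classes)
  input_fractions <- data.frame(
    class = classes,
    n = vapply(classes, function(cl) sum(cls == cl, na.rm = TRUE), 0L),
    row.names = NULL)
  input_fractions$pct <- if (n_tot > 0)
    100 * input_fractions$n / n_tot else NA_real_

  mf <- lapply(classes, function(cl) {
    k <- cnt[cls == cl]
    pos <- k[k >= 1]
    data.frame(class = cl, n_with_modules = length(pos),
               n_zero_modules = sum(k == 0),
               pct_single = if (length(pos)) 100 * mean(pos == 1) else NA_real_,
               pct_multiple = if (length(pos)) 100 * mean(pos >= 2) else NA_real_)
  })
  module_fractions <- do.call(rbind, mf)

  pmf <- lapply(classes, function(cl) {
    k <- cnt[cls == cl]
    pos <- k[k >= 1]
    data.frame(class = cl, n_modules = 1:4,
               n = vapply(1:4, function(m) sum(pos == m), 0L),
               pct = if (length(pos))
                 100 * vapply(1:4, function(m) mean(pos == m), 0) else
                   rep(NA_real_, 4))
  })
  count_pmf <- do.call(rbind, pmf)

  list(input_fractions = input_fractions,
       module_fractions = module_fractions,
       count_pmf = count_pmf, n_total = n_tot)
}
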