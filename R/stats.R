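#' Descriptive summary of one condition sample
#'
#' Mean, sample SD (n-1 denominator), median, type-7 (linear
#' interpolation) quartiles, Tukey whiskers (at most 1.5 x IQR beyond the
#' quartiles, clipped to the extreme non-outlier data points) and
#' outliers, matching the boxplot conventions of the figures
#' (centre line median, whiskers 1.5 x interquartile range).
#'
#' @param values numeric sample (angles in degrees or fractions in
#'   percent), n >= 1.
#' @param condition condition name.
#' @return An object of class `condition_summary`.
#' @export
#' @examples
#' summarize_condition(c(1, 2, 3, 4, 5), "demo")
summarize_condition <- function(values, condition = "sample") {
  values <- as.numeric(values)
  if (length(values) == 0L || any(!is.finite(values))) stop("empty or non-finite sample")
  n <- length(values)
  qs <- stats::quantile(values, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  iqr <- qs[3L] - qs[1L]
  lo_fence <- qs[1L] - 1.5 * iqr
  hi_fence <- qs[3L] + 1.5 * iqr
  inliers <- values[values >= lo_fence & values <= hi_fence]
  flags <- character()
  if (n == 1L) flags <- "single-value-sd-undefined"
  structure(list(condition = condition, values = values, n = n,
                 mean = mean(values),
                 sd = if (n > 1L) stats::sd(values) else 0,
                 median = qs[2L], q1 = qs[1L], q3 = qs[3L],
                 whisker_lo = min(inliers), whisker_hi = max(inliers),
                 outliers = values[values < lo_fence | values > hi_fence],
                 quartile_convention = "type-7 linear interpolation",
                 flags = flags),
            class = "condition_summary")
}

#' @export
print.condition_summary <- function(x, ...) {
  cat(sprintf("<condition_summary> %s: %.3g +/- %.3g (SD), n = %d; median %.3g [%.3g, %.3g], %d outliers\n",
              x$condition, x$mean, x$sd, x$n, x$median, x$q1, x$q3,
              length(x$outliers)))
  invisible(x)
}

# exact null distribution of the Mann-Whitney U statistic for sample sizes
# (n, m) with no ties: counts over U = 0..n*m via the shift-algorithm
# recurrence c(n, m, u) = c(n-1, m, u-m) + c(n, m-1, u)
.u_cache <- new.env(parent = emptyenv())

u_null_counts <- function(n, m) {
  key <- paste(n, m)
  hit <- .u_cache[[key]]
  if (!is.null(hit)) return(hit)
  tab <- vector("list", n + 1L)
  for (i in 0:n) {
    tab[[i + 1L]] <- vector("list", m + 1L)
    for (j in 0:m) {
      if (i == 0L || j == 0L) { tab[[i + 1L]][[j + 1L]] <- 1; next }
      len <- i * j + 1L
      a <- tab[[i]][[j + 1L]]     # c(i-1, j, u - j), shifted by j
      b <- tab[[i + 1L]][[j]]     # c(i, j-1, u)
      av <- numeric(len)
      na <- min(len - j, length(a))
      av[j + seq_len(na)] <- a[seq_len(na)]
      bv <- numeric(len)
      bv[seq_len(length(b))] <- b
      tab[[i + 1L]][[j + 1L]] <- av + bv
    }
  }
  out <- tab[[n + 1L]][[m + 1L]]
  .u_cache[[key]] <- out
  out
}

#' Two-tailed Mann-Whitney U test
#'
#' U is computed from midrank sums. When `n1 + n2 <= exact_limit` and the
#' pooled sample has no ties, the two-tailed p value is exact, from the
#' complete null distribution of U (shift algorithm; equivalent to full
#' enumeration of all rank assignments). Otherwise the normal
#' approximation with tie-corrected variance and continuity correction is
#' used. Two-tailed p = min(1, 2 x smaller tail).
#'
#' @param sample1,sample2 nonempty numeric samples.
#' @param exact_limit combined-size cutoff for the exact path, default 20.
#' @return An object of class `mwu_test` with fields `U` (for sample 1),
#'   `U2`, `p_value`, `method` (`"exact"` or `"normal-approximation"`),
#'   `n1`, `n2`.
#' @export
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(4, 5, 6))  # U = 0, p = 0.1
mann_whitney_u <- function(sample1, sample2, exact_limit = 20L) {
  x <- as.numeric(sample1); y <- as.numeric(sample2)
  if (length(x) == 0L || length(y) == 0L) stop("both samples must be nonempty")
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled) # midranks for ties
  r1 <- sum(r[seq_len(n1)])
  U1 <- r1 - n1 * (n1 + 1) / 2
  U2 <- n1 * n2 - U1
  ties <- any(duplicated(pooled))
  if (!ties && n1 + n2 <= exact_limit) {
    f <- u_null_counts(n1, n2)
    tot <- sum(f)
    u_obs <- U1
    p_le <- sum(f[seq_len(floor(u_obs) + 1L)]) / tot
    p_ge <- sum(f[(floor(u_obs) + 1L):length(f)]) / tot
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact"
  } else {
    N <- n1 + n2
    tie_tab <- table(pooled)
    tie_term <- sum(tie_tab^3 - tie_tab) / (N * (N - 1))
    sigma2 <- n1 * n2 / 12 * ((N + 1) - tie_term)
    if (sigma2 <= 0) {
      p <- 1
    } else {
      mu <- n1 * n2 / 2
      z <- (U1 - mu - sign(U1 - mu) * 0.5) / sqrt(sigma2)
      p <- min(1, 2 * stats::pnorm(-abs(z)))
    }
    method <- "normal-approximation"
  }
  structure(list(U = U1, U2 = U2, p_value = p, method = method,
                 n1 = n1, n2 = n2),
            class = "mwu_test")
}

#' @export
print.mwu_test <- function(x, ...) {
  cat(sprintf("<mwu_test> U = %g (n1 = %d, n2 = %d), two-tailed p = %.4g [%s]\n",
              x$U, x$n1, x$n2, x$p_value, x$method))
  invisible(x)
}

#' Compare conditions pairwise with Mann-Whitney U tests
#'
#' Produces one [summarize_condition()] per condition and one
#' [mann_whitney_u()] per requested pair. P values are reported raw
#' (uncorrected), matching how pairwise p values are displayed over
#' boxplots; an optional Holm adjustment can be switched on.
#'
#' @param data data.frame with columns `condition` and `value`.
#' @param pairs list of length-2 character vectors naming condition pairs;
#'   default: all pairs.
#' @param holm logical; add Holm-adjusted p values.
#' @return list of class `condition_report`: `summaries` (named list),
#'   `tests` (data.frame with `condition1`, `condition2`, `U`, `p_value`,
#'   `method`, and `p_holm` if requested).
#' @export
compare_conditions <- function(data, pairs = NULL, holm = FALSE) {
  stopifnot(is.data.frame(data), all(c("condition", "value") %in% names(data)))
  conds <- unique(as.character(data$condition))
  if (length(conds) < 2L) stop("need at least 2 conditions")
  if (is.null(pairs)) {
    cmb <- utils::combn(conds, 2L)
    pairs <- lapply(seq_len(ncol(cmb)), function(i) cmb[, i])
  }
  for (p in pairs)
    if (!all(p %in% conds))
      stop("unknown condition name: ", paste(setdiff(p, conds), collapse = ", "))
  summaries <- lapply(conds, function(cn)
    summarize_condition(data$value[data$condition == cn], cn))
  names(summaries) <- conds
  tests <- do.call(rbind, lapply(pairs, function(p) {
    tr <- mann_whitney_u(data$value[data$condition == p[1L]],
                         data$value[data$condition == p[2L]])
    data.frame(condition1 = p[1L], condition2 = p[2L], U = tr$U,
               p_value = tr$p_value, method = tr$method,
               stringsAsFactors = FALSE)
  }))
  if (holm) tests$p_holm <- stats::p.adjust(tests$p_value, method = "holm")
  structure(list(summaries = summaries, tests = tests, holm = holm),
            class = "condition_report")
}

#' @export
print.condition_report <- function(x, ...) {
  for (s in x$summaries) print(s)
  cat("\nPairwise two-tailed Mann-Whitney U tests",
      if (x$holm) "(raw and Holm-adjusted p):\n" else "(raw p, no multiplicity correction):\n")
  print(x$tests, row.names = FALSE)
  invisible(x)
}

#' Write a condition report to CSV files
#'
#' `summaries.csv` and `tests.csv` under `dir`, both with `#` comment
#' headers declaring the conventions (type-7 quartiles, raw p values).
#'
#' @param report a [compare_conditions()] result.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_condition_report <- function(report, dir) {
  stopifnot(inherits(report, "condition_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sm <- do.call(rbind, lapply(report$summaries, function(s)
    data.frame(condition = s$condition, n = s$n, mean = s$mean, sd = s$sd,
               median = s$median, q1 = s$q1, q3 = s$q3,
               whisker_lo = s$whisker_lo, whisker_hi = s$whisker_hi,
               n_outliers = length(s$outliers))))
  write_report_csv(sm, file.path(dir, "summaries.csv"),
                   c("per-condition descriptive statistics",
                     "quartiles: type-7 linear interpolation; whiskers: 1.5 x IQR clipped to data"))
  write_report_csv(report$tests, file.path(dir, "tests.csv"),
                   c("pairwise two-tailed Mann-Whitney U tests",
                     "exact null distribution when combined n <= 20 and no ties, else normal approximation with tie and continuity correction",
                     if (report$holm) "p_holm: Holm-adjusted" else "p values are raw (uncorrected), as displayed over boxplots"))
  invisible(dir)
}

#' Boxplot of condition samples with the report's conventions
#'
#' @param x a [compare_conditions()] result.
#' @param ... passed to [graphics::boxplot()].
#' @return invisibly, the boxplot stats.
#' @export
plot.condition_report <- function(x, ...) {
  vals <- lapply(x$summaries, function(s) s$values)
  bp <- graphics::boxplot(vals, names = names(x$summaries),
                          ylab = "value", range = 1.5, ...)
  means <- vapply(x$summaries, function(s) s$mean, numeric(1L))
  graphics::points(seq_along(means), means, pch = 21, bg = "grey")
  invisible(bp)
}
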