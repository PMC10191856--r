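#' Two-sample bootstrap hypothesis test (achieved significance level)
#'
#' Tests equality of means by the translation-null bootstrap: both groups are
#' shifted to the pooled mean, resampled with replacement within group, and
#' the two-sided achieved significance level is the add-one-smoothed
#' Monte-Carlo p-value `(1 + #{|d*| >= |d_obs|}) / (n_boot + 1)`, where `d`
#' is the difference of group means (or its studentized version with
#' `statistic = "studentized"`).
#'
#' @param a,b Numeric samples (length >= 2 each).
#' @param n_boot Bootstrap resamples.
#' @param seed Integer seed.
#' @param statistic `"mean_diff"` (default) or `"studentized"`.
#' @return Class `test_result`: `statistic`, `asl`, `n_boot`, `method`.
#' @export
bootstrap_asl_test <- function(a, b, n_boot = 10000, seed = 1L,
                               statistic = c("mean_diff", "studentized")) {
  statistic <- match.arg(statistic)
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2 || length(b) < 2) stopf("both samples need >= 2 values")
  stat <- function(x, y) {
    d <- mean(x) - mean(y)
    if (statistic == "studentized") {
      se <- sqrt(stats::var(x) / length(x) + stats::var(y) / length(y))
      if (se == 0) return(if (d == 0) 0 else Inf)
      d / se
    } else d
  }
  d_obs <- stat(a, b)
  pooled <- mean(c(a, b))
  if (stats::var(c(a, b)) == 0) {
    asl <- if (d_obs == 0) 1 else 1 / (n_boot + 1)
    return(structure(list(statistic = d_obs, asl = asl, n_boot = n_boot,
                          method = paste0("bootstrap_", statistic)),
                     class = "test_result"))
  }
  a0 <- a - mean(a) + pooled
  b0 <- b - mean(b) + pooled
  set.seed(seed)
  am <- matrix(sample(a0, n_boot * length(a), replace = TRUE), n_boot)
  bm <- matrix(sample(b0, n_boot * length(b), replace = TRUE), n_boot)
  if (statistic == "studentized") {
    na <- length(a); nb <- length(b)
    ma <- rowMeans(am); mb <- rowMeans(bm)
    va <- (rowSums(am^2) - na * ma^2) / (na - 1)
    vb <- (rowSums(bm^2) - nb * mb^2) / (nb - 1)
    dstar <- (ma - mb) / sqrt(va / na + vb / nb)
  } else {
    dstar <- rowMeans(am) - rowMeans(bm)
  }
  asl <- (1 + sum(abs(dstar) >= abs(d_obs))) / (n_boot + 1)
  structure(list(statistic = d_obs, asl = asl, n_boot = n_boot,
                 method = paste0("bootstrap_", statistic)), class = "test_result")
}

#' Two-sided Fisher's exact test on active/inactive counts
#'
#' Exact p-value from the 2x2 hypergeometric model (sum of the probabilities
#' of all tables, with fixed margins, no more probable than the observed one).
#'
#' @param n_active_1,n_inactive_1,n_active_2,n_inactive_2 Non-negative counts.
#' @return Class `test_result` with the odds ratio as `statistic`.
#' @export
fisher_active <- function(n_active_1, n_inactive_1, n_active_2, n_inactive_2) {
  cnt <- c(n_active_1, n_inactive_1, n_active_2, n_inactive_2)
  if (any(cnt < 0) || any(cnt != round(cnt))) stopf("counts must be non-negative integers")
  tab <- matrix(cnt, 2, byrow = TRUE)
  ft <- stats::fisher.test(tab, alternative = "two.sided")
  structure(list(statistic = unname(ft$estimate), asl = ft$p.value,
                 n_boot = NA_integer_, method = "fisher_exact"),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p (ASL) = %.4g\n", x$method, x$statistic, x$asl))
  invisible(x)
}

#' Propagate uncertainty through a ratio
#'
#' For independent `x +/- sd_x` and `y +/- sd_y`, `r = x/y` carries
#' `sd_r = sqrt((sd_x/y)^2 + (x sd_y / y^2)^2)` (first-order propagation;
#' equivalent to `|r| sqrt((sd_x/x)^2 + (sd_y/y)^2)` away from `x = 0` but
#' well defined at `x = 0`).
#'
#' @param x,y Values.
#' @param sd_x,sd_y Their standard deviations.
#' @return Named numeric: `value`, `sd`.
#' @export
propagate_ratio <- function(x, sd_x, y, sd_y) {
  if (y == 0) stopf("ratio undefined: denominator is 0")
  c(value = x / y, sd = sqrt((sd_x / y)^2 + (x * sd_y / y^2)^2))
}
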