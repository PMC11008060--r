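# Reliability and inferential statistics: intraclass correlation ICC(A,1)
# (two-way model, absolute agreement, single rating) with the McGraw-Wong
# F-based 95% CI, one-tailed Spearman rank correlation (exact permutation
# null for small n), and median/IQR descriptives.

#' Intraclass correlation ICC(A,1)
#'
#' Single-rating, absolute-agreement, two-way model intraclass correlation
#' from the two-way mean squares: with between-subject `MSR`, between-rating
#' `MSC` and residual `MSE`,
#' `ICC(A,1) = (MSR - MSE) / (MSR + (k-1) MSE + (k/n) (MSC - MSE))`.
#' The 95% confidence interval is the McGraw-Wong F-distribution interval
#' for absolute agreement.
#'
#' @param data n x k numeric matrix or data frame of repeated ratings
#'   (subjects in rows, ratings in columns); `k = 2` in the intended
#'   intra-rater design, `n >= 3`, no missing cells.
#' @param conf_level confidence level (default 0.95).
#' @return Object of class `icc_result`: `estimate`, `ci_low`, `ci_high`,
#'   `n`, `k`, mean squares `ms`, and `degenerate` flag (no between-subject
#'   variance).
#' @export
icc_a1 <- function(data, conf_level = 0.95) {
  x <- as.matrix(data)
  if (any(is.na(x))) stop("missing cells are not allowed")
  n <- nrow(x); k <- ncol(x)
  if (n < 3L) stop("need n >= 3 subjects, got ", n)
  if (k < 2L) stop("need k >= 2 ratings, got ", k)
  gm <- mean(x)
  rm_ <- rowMeans(x); cm <- colMeans(x)
  msr <- k * sum((rm_ - gm)^2) / (n - 1)
  msc <- n * sum((cm - gm)^2) / (k - 1)
  res <- x - outer(rm_, rep(1, k)) - outer(rep(1, n), cm) + gm
  mse <- sum(res^2) / ((n - 1) * (k - 1))
  denom <- msr + (k - 1) * mse + (k / n) * (msc - mse)
  degenerate <- msr <= mse + 1e-300 * abs(mse)
  if (abs(denom) < 1e-300) {
    warning("degenerate ratings: no variance at all; ICC undefined")
    est <- NA_real_
  } else est <- (msr - mse) / denom
  if (degenerate && !is.na(est))
    warning("no between-subject variance beyond residual: ICC estimate <= 0")
  alpha <- 1 - conf_level
  if (!is.na(est) && mse < 1e-300 && msc < 1e-300) {
    ci <- c(1, 1)  # perfect agreement: interval collapses
  } else if (is.na(est)) {
    ci <- c(NA_real_, NA_real_)
  } else {
    r <- est
    a <- (k * r) / (n * (1 - r))
    b <- 1 + (k * r * (n - 1)) / (n * (1 - r))
    v <- (a * msc + b * mse)^2 /
      ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
    f_l <- stats::qf(1 - alpha / 2, n - 1, v)
    f_u <- stats::qf(1 - alpha / 2, v, n - 1)
    lower <- n * (msr - f_l * mse) /
      (f_l * (k * msc + (k * n - k - n) * mse) + n * msr)
    upper <- n * (f_u * msr - mse) /
      (k * msc + (k * n - k - n) * mse + n * f_u * msr)
    ci <- c(lower, upper)
  }
  structure(list(estimate = est, ci_low = ci[1], ci_high = ci[2],
                 n = n, k = k, conf_level = conf_level,
                 ms = list(msr = msr, msc = msc, mse = mse),
                 degenerate = degenerate),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("ICC(A,1) = %.4f, %d%% CI (%.4f; %.4f), n = %d, k = %d%s\n",
              x$estimate, round(100 * x$conf_level), x$ci_low, x$ci_high,
              x$n, x$k, if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' One-tailed Spearman rank correlation
#'
#' Spearman's rho from average ranks (midranks for ties). The one-tailed
#' p-value in the stated direction is exact (full enumeration of the n!
#' permutation null, ties included) for `n <= exact_n_max`, and uses the
#' t-approximation `t = rho * sqrt((n-2) / (1-rho^2))` on `n - 2` degrees of
#' freedom above that.
#'
#' @param x,y equal-length numeric vectors, `n >= 4`, neither constant.
#' @param direction `"positive"` (alternative rho > 0) or `"negative"`.
#' @param exact_n_max largest n for the exact permutation test (default 9).
#' @return Object of class `correlation_result`: `rho`, `p_one_tailed`,
#'   `direction`, `n`, `method`.
#' @export
spearman_one_tailed <- function(x, y, direction = c("positive", "negative"),
                                exact_n_max = 9L) {
  direction <- match.arg(direction)
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 4L) stop("need n >= 4, got ", n)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined correlation: constant input vector")
  rx <- rank(x); ry <- rank(y)
  rho <- rank_cor(rx, ry)
  if (n <= exact_n_max) {
    perms <- permutations_all(n)
    stat <- as.vector(matrix(ry[perms], nrow(perms)) %*% rx)
    obs <- sum(rx * ry)
    p <- if (direction == "positive") mean(stat >= obs - 1e-9)
         else mean(stat <= obs + 1e-9)
    method <- "exact permutation"
  } else {
    if (abs(rho) >= 1 - 1e-15) {
      p <- if ((rho > 0) == (direction == "positive")) 0 else 1
    } else {
      tstat <- rho * sqrt((n - 2) / (1 - rho^2))
      p <- stats::pt(tstat, df = n - 2,
                     lower.tail = (direction == "negative"))
    }
    method <- "t-approximation"
  }
  structure(list(rho = rho, p_one_tailed = p, direction = direction,
                 n = n, method = method),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Spearman rho = %.4f, one-tailed P = %.4g (%s, n = %d, %s)\n",
              x$rho, x$p_one_tailed, x$direction, x$n, x$method))
  invisible(x)
}

# Pearson correlation of two rank vectors (handles midranks)
rank_cor <- function(rx, ry) {
  dx <- rx - mean(rx); dy <- ry - mean(ry)
  sum(dx * dy) / sqrt(sum(dx^2) * sum(dy^2))
}

# all permutations of 1..n as an (n!) x n integer matrix
permutations_all <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- permutations_all(n - 1L)
  m <- nrow(sub)
  out <- matrix(0L, n * m, n)
  v <- seq_len(n)
  for (i in v) {
    rows <- (i - 1L) * m + seq_len(m)
    out[rows, 1L] <- i
    out[rows, -1L] <- matrix(v[-i][sub], m)
  }
  out
}

#' Median and interquartile range
#'
#' Median with 25th and 75th percentiles by linear interpolation
#' (`stats::quantile` type 7), the convention used for all descriptive
#' summaries.
#'
#' @param values numeric vector, `n >= 1`.
#' @return Named numeric vector `median`, `q25`, `q75`.
#' @export
describe <- function(values) {
  if (length(values) < 1L || all(is.na(values))) stop("empty input")
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), names = FALSE,
                       na.rm = FALSE, type = 7)
  c(median = q[2], q25 = q[1], q75 = q[3])
}

#' Per-variable intra-rater reliability table
#'
#' Computes [icc_a1()] for each shared numeric column of two rating tables
#' (same subjects, same variables, two rating sessions) and the arithmetic
#' mean of the estimates (the per-variable estimates are the primary output;
#' the mean is a labelled convenience aggregate).
#'
#' @param ratings1,ratings2 data frames with identical numeric columns; rows
#'   are subjects in the same order.
#' @return List with `table` (variable, estimate, ci_low, ci_high) and
#'   `mean_icc`.
#' @export
icc_table <- function(ratings1, ratings2) {
  vars <- intersect(names(ratings1), names(ratings2))
  vars <- vars[vapply(ratings1[vars], is.numeric, TRUE)]
  if (!length(vars)) stop("no shared numeric variables")
  rows <- lapply(vars, function(v) {
    r <- icc_a1(cbind(ratings1[[v]], ratings2[[v]]))
    data.frame(variable = v, estimate = r$estimate,
               ci_low = r$ci_low, ci_high = r$ci_high)
  })
  tab <- do.call(rbind, rows)
  list(table = tab, mean_icc = mean(tab$estimate))
}
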