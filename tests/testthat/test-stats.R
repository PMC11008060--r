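# ICC(A,1), one-tailed Spearman, descriptives — each checked against an
# independent oracle (aov mean squares; full permutation enumeration via
# base cor; sort-based quantiles)

# oracle: mean squares from anova(aov(...)), plugged into the agreement formula
icc_a1_oracle <- function(x) {
  n <- nrow(x); k <- ncol(x)
  long <- data.frame(y = as.vector(x),
                     subj = factor(rep(seq_len(n), k)),
                     rater = factor(rep(seq_len(k), each = n)))
  ms <- anova(stats::aov(y ~ subj + rater, data = long))[["Mean Sq"]]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
}

test_that("icc_a1 matches the aov mean-squares oracle to 1e-10", {
  withr::local_seed(101)
  for (i in 1:25) {
    n <- sample(4:10, 1)
    subj <- stats::rnorm(n, 0, 2)
    x <- cbind(subj + stats::rnorm(n, 0, 0.5),
               subj + stats::rnorm(n, 0.3, 0.5))
    r <- icc_a1(x)
    expect_equal(r$estimate, icc_a1_oracle(x), tolerance = 1e-10)
    expect_lte(r$ci_low, r$estimate)
    expect_gte(r$ci_high, r$estimate)
  }
})

test_that("icc_a1 endpoints: perfect agreement, independence, degeneracy", {
  subj <- c(1.2, 3.4, -0.5, 2.2, 0.1, 4.4)
  perfect <- icc_a1(cbind(subj, subj))
  expect_equal(perfect$estimate, 1.0)
  expect_equal(c(perfect$ci_low, perfect$ci_high), c(1, 1))

  # no subject effect, independent columns: estimate near zero
  withr::local_seed(7)
  indep <- suppressWarnings(icc_a1(cbind(stats::rnorm(2000), stats::rnorm(2000))))
  expect_lt(abs(indep$estimate), 0.06)

  expect_warning(icc_a1(cbind(rep(1, 5), rep(2, 5))), "between-subject")
  expect_error(icc_a1(matrix(1:4, 2, 2)), "n >= 3")
  expect_error(icc_a1(matrix(c(1, 2, NA, 4, 5, 6), 3, 2)), "missing")
})

test_that("icc_a1 is invariant under common affine rescaling", {
  withr::local_seed(33)
  s <- stats::rnorm(8, 10, 3)
  x <- cbind(s + stats::rnorm(8, 0, 1), s + stats::rnorm(8, 0.5, 1))
  r1 <- icc_a1(x)
  r2 <- icc_a1(3.7 * x + 12)
  expect_equal(r2$estimate, r1$estimate, tolerance = 1e-12)
  expect_equal(r2$ci_low, r1$ci_low, tolerance = 1e-10)
  expect_equal(r2$ci_high, r1$ci_high, tolerance = 1e-10)
})

# oracle: enumeration over all n! orderings, rho via base cor(method="spearman")
spearman_exact_oracle <- function(x, y, direction) {
  n <- length(x)
  rho_obs <- stats::cor(x, y, method = "spearman")
  perm_rho <- apply(perms_oracle(n), 1, function(p)
    stats::cor(x, y[p], method = "spearman"))
  p <- if (direction == "positive") mean(perm_rho >= rho_obs - 1e-12)
       else mean(perm_rho <= rho_obs + 1e-12)
  list(rho = rho_obs, p = p)
}

test_that("spearman_one_tailed matches full-permutation enumeration with ties", {
  cases <- list(
    list(x = c(3, 1, 4, 1, 5, 9, 2), y = c(2, 7, 1, 8, 2, 8, 1)),
    list(x = c(1, 2, 2, 3, 4, 5, 5), y = c(2, 1, 3, 3, 5, 4, 6)),
    list(x = c(10, 20, 30, 40, 50, 60), y = c(3, 1, 4, 1, 5, 9)),
    list(x = c(1, 1, 2, 2, 3), y = c(5, 4, 4, 3, 3)))
  for (cs in cases) for (dir in c("positive", "negative")) {
    got <- spearman_one_tailed(cs$x, cs$y, direction = dir)
    want <- spearman_exact_oracle(cs$x, cs$y, dir)
    expect_equal(got$rho, want$rho, tolerance = 1e-12)
    expect_equal(got$p_one_tailed, want$p, tolerance = 1e-12)
  }
})

test_that("spearman endpoints and permutation-null consistency", {
  x <- 1:6; y <- c(2, 4, 5, 7, 11, 13)
  up <- spearman_one_tailed(x, y, "positive")
  expect_equal(up$rho, 1.0)
  expect_equal(up$p_one_tailed, 1 / factorial(6))   # the exact minimum
  down <- spearman_one_tailed(rev(x), y, "positive")
  expect_equal(down$rho, -1.0)
  expect_equal(down$p_one_tailed, 1.0)

  # P+(T >= t) + P-(T <= t) = 1 + P(T == t) under the exact null
  xt <- c(1, 2, 2, 4, 5, 6); yt <- c(3, 3, 1, 5, 6, 5)
  pp <- spearman_one_tailed(xt, yt, "positive")$p_one_tailed
  pn <- spearman_one_tailed(xt, yt, "negative")$p_one_tailed
  rx <- rank(xt); ry <- rank(yt)
  obs <- sum(rx * ry)
  stat <- apply(perms_oracle(6), 1, function(p) sum(rx * ry[p]))
  expect_equal(pp + pn, 1 + mean(abs(stat - obs) < 1e-9), tolerance = 1e-12)

  expect_error(spearman_one_tailed(1:3, 3:1), "n >= 4")
  expect_error(spearman_one_tailed(rep(1, 5), 1:5), "constant")
})

test_that("t-approximation branch agrees with cor.test's asymptotic p", {
  withr::local_seed(21)
  x <- stats::rnorm(35); y <- 0.4 * x + stats::rnorm(35)
  got <- spearman_one_tailed(x, y, "positive")
  expect_equal(got$method, "t-approximation")
  want <- stats::cor.test(x, y, method = "spearman",
                          alternative = "greater", exact = FALSE)
  expect_equal(got$rho, unname(want$estimate), tolerance = 1e-12)
  expect_equal(got$p_one_tailed, want$p.value, tolerance = 1e-9)
})

test_that("describe returns median and linear-interpolation quartiles", {
  d <- describe(1:5)
  expect_equal(unname(d), c(3, 2, 4))
  expect_equal(unname(describe(7)), c(7, 7, 7))

  # sort-based oracle for the type-7 rule
  q7 <- function(v, p) {
    v <- sort(v); h <- (length(v) - 1) * p + 1
    lo <- floor(h)
    v[lo] + (h - lo) * (v[pmin(lo + 1, length(v))] - v[lo])
  }
  withr::local_seed(3)
  for (i in 1:20) {
    v <- stats::rnorm(sample(1:40, 1))
    d <- describe(v)
    expect_equal(unname(d), c(q7(v, 0.5), q7(v, 0.25), q7(v, 0.75)),
                 tolerance = 1e-12)
    expect_lte(d[["q25"]], d[["median"]])
    expect_gte(d[["q75"]], d[["median"]])
  }
  expect_error(describe(numeric(0)), "empty")
})

test_that("icc_table reports per-variable ICCs and their labelled mean", {
  withr::local_seed(77)
  s1 <- stats::rnorm(7, 0, 3); s2 <- stats::rnorm(7, 10, 5)
  r1 <- data.frame(a = s1 + stats::rnorm(7, 0, 0.1),
                   b = s2 + stats::rnorm(7, 0, 0.2))
  r2 <- data.frame(a = s1 + stats::rnorm(7, 0, 0.1),
                   b = s2 + stats::rnorm(7, 0, 0.2))
  tab <- icc_table(r1, r2)
  expect_equal(nrow(tab$table), 2L)
  expect_equal(tab$mean_icc, mean(tab$table$estimate))
  expect_true(all(tab$table$estimate > 0.9))   # near-duplicate ratings
})
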