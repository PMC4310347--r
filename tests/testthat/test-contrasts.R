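unit4 <- function() set_unit_branch_lengths(parse_newick("((A,B),(C,D));"))

test_that("pic_contrasts reproduces hand-worked values", {
  tr <- parse_newick("(A:1,B:1);")
  p <- pic_contrasts(tr, c(A = 3, B = 1))
  expect_equal(p$contrast, sqrt(2))
  expect_equal(p$variance, 2)

  expect_equal(pic_contrasts(unit4(),
                             c(A = 5, B = 5, C = 5, D = 5))$contrast,
               rep(0, 3))

  # balanced 4-tip unit tree: cherry contrasts (1-2)/sqrt(2),
  # (4-8)/sqrt(2); ancestors 1.5 and 6 on adjusted branch 1.5;
  # root contrast (1.5-6)/sqrt(3)
  p <- pic_contrasts(unit4(), c(A = 1, B = 2, C = 4, D = 8))
  expect_setequal(round(p$variance, 9), c(2, 2, 3))
  expect_equal(sort(p$contrast),
               sort(c(-1 / sqrt(2), -4 / sqrt(2), -4.5 / sqrt(3))),
               tolerance = 1e-12)
})

test_that("contrast count is n-1 and the map whitens the BM covariance", {
  set.seed(5)
  for (i in 1:10) {
    tr <- simulate_yule_tree(sample(4:10, 1),
                             branch_lengths = "exponential")
    n <- length(tr$tip.label)
    T <- contrast_matrix(tr)
    expect_equal(nrow(T), n - 1)
    V <- phylo_covariance(tr)
    expect_equal(T %*% V %*% t(T), diag(n - 1), tolerance = 1e-9,
                 ignore_attr = TRUE)
  }
})

test_that("pic_contrasts agrees with ape::pic up to sign", {
  set.seed(13)
  tr <- simulate_yule_tree(30)
  x <- simulate_bm(tr)
  mine <- pic_contrasts(tr, x)
  ref <- ape::pic(x[tr$tip.label], tr, var.contrasts = TRUE)
  expect_equal(sort(abs(mine$contrast)), sort(abs(unname(ref[, 1]))),
               tolerance = 1e-9)
  expect_equal(sort(mine$variance), sort(unname(ref[, 2])),
               tolerance = 1e-9)
})

test_that("pic_contrasts refuses polytomies and non-positive branches", {
  expect_error(pic_contrasts(set_unit_branch_lengths(parse_newick("(A,B,C);")),
                             c(A = 1, B = 2, C = 3)),
               "resolve_polytomies")
  tr <- parse_newick("((A:0,B:1):1,C:1);")
  expect_error(pic_contrasts(tr, c(A = 1, B = 2, C = 3)), "> 0")
})

test_that("log10_transform is exact and names offenders", {
  expect_equal(log10_transform(1), 0)
  expect_equal(log10_transform(10), 1)
  expect_equal(log10_transform(c(0.24, 76)), c(log10(0.24), log10(76)))
  # the ~2.5 log-unit span of realistic genome sizes
  expect_equal(diff(log10_transform(c(0.24, 76))), 2.5,
               tolerance = 0.01)
  expect_error(log10_transform(c(good = 2, bad = 0)), "bad")
})

test_that("origin_regression handles exact and orthogonal cases", {
  cx <- c(1, 2, 3)
  fit <- origin_regression(cx, 2 * cx)
  expect_equal(fit$slope, 2)
  expect_equal(fit$r_squared, 1)
  expect_equal(sum(fit$residuals^2), 0)

  cy <- c(1, 1, -1)                      # sum(cx*cy) = 1+2-3 = 0
  expect_equal(origin_regression(cx, cy)$slope, 0)
  expect_error(origin_regression(c(0, 0, 0), cy), "zero")
})

test_that("origin_regression satisfies the normal equations and matches
           ape::lmorigin", {
  set.seed(17)
  tr <- simulate_yule_tree(30)
  bv <- simulate_correlated_bm(tr, matrix(c(4, 1.5, 1.5, 1), 2))
  cx <- pic_contrasts(tr, bv$x)
  cy <- pic_contrasts(tr, bv$y)
  fit <- origin_regression(cx, cy)
  expect_equal(sum(fit$residuals * cx$contrast), 0, tolerance = 1e-9)
  invisible(capture.output(
    ref <- ape::lmorigin(cy$contrast ~ cx$contrast, nperm = 0)))
  expect_equal(fit$slope, unname(coef(ref$reg)), tolerance = 1e-9)
  expect_equal(fit$r_squared, summary(ref$reg)$r.squared,
               tolerance = 1e-9)
})

test_that("child-order flips change contrast signs but not the fit", {
  set.seed(25)
  tr <- simulate_yule_tree(12)
  bv <- simulate_correlated_bm(tr, matrix(c(2, 1, 1, 1), 2))
  cx <- pic_contrasts(tr, bv$x)$contrast
  cy <- pic_contrasts(tr, bv$y)$contrast
  fit <- origin_regression(cx, cy)
  # flipping any node's orientation flips both contrasts of that node
  for (k in seq_along(cx)) {
    s <- rep(1, length(cx)); s[k] <- -1
    flipped <- origin_regression(cx * s, cy * s)
    expect_equal(flipped$slope, fit$slope, tolerance = 1e-12)
    expect_equal(flipped$F, fit$F, tolerance = 1e-12)
    expect_equal(flipped$r_squared, fit$r_squared, tolerance = 1e-12)
  }
})

test_that("F and adjusted R2 are internally consistent for every fit", {
  set.seed(29)
  for (i in 1:20) {
    n <- sample(5:50, 1)
    cx <- rnorm(n); cy <- 2 * cx + rnorm(n)
    fit <- origin_regression(cx, cy)
    expect_equal(fit$F, fit$r_squared / (1 - fit$r_squared) * (n - 1),
                 tolerance = 1e-9)
    expect_equal(fit$adj_r_squared,
                 1 - (1 - fit$r_squared) * n / (n - 1), tolerance = 1e-9)
  }
})

test_that("origin permutation p matches exhaustive enumeration at n = 4", {
  cx <- c(0.3, -1.2, 0.8, 2.1)
  cy <- c(0.5, -0.9, 1.4, 1.9)
  p_exact <- origin_exhaustive_p(cx, cy)
  mc <- origin_permutation_test(cx, cy, n_reps = 10000, seed = 8)
  expect_lt(abs(mc$p_value - p_exact), 0.02)
})

test_that("origin permutation test is seed-deterministic", {
  set.seed(33)
  cx <- rnorm(20); cy <- rnorm(20)
  p1 <- origin_permutation_test(cx, cy, n_reps = 499, seed = 4)
  p2 <- origin_permutation_test(cx, cy, n_reps = 499, seed = 4)
  expect_identical(p1, p2)
})

test_that("shapiro_wilk attains W = 1 for evenly spaced n = 3 and
           detects exponential data", {
  expect_equal(shapiro_wilk(c(1, 2, 3))$W, 1, tolerance = 1e-9)
  expect_error(shapiro_wilk(c(2, 2, 2)), "constant")
  set.seed(37)
  expect_lt(shapiro_wilk(rexp(50))$p_value, 0.01)
})

test_that("regression diagnostics flag exact fits and keep residual
           orthogonality", {
  cx <- c(1, 2, 3, 4)
  d <- regression_diagnostics(origin_regression(cx, 2 * cx))
  expect_true(d$degenerate)
  expect_null(d$residual_normality)

  set.seed(41)
  cx <- rnorm(30); cy <- 3 * cx + rnorm(30)
  fit <- origin_regression(cx, cy)
  d <- regression_diagnostics(fit)
  expect_false(d$degenerate)
  expect_equal(sum(d$table$residual * cx), 0, tolerance = 1e-9)
  expect_true(is.finite(d$residual_normality$W))
})

test_that("BM-simulated contrasts pass Shapiro-Wilk at nominal rates", {
  set.seed(45)
  tr <- simulate_yule_tree(40)
  rej <- replicate(500, {
    x <- simulate_bm(tr)
    shapiro_wilk(pic_contrasts(tr, x))$p_value <= 0.05
  })
  expect_gte(mean(rej), 0.03)
  expect_lte(mean(rej), 0.07)
})
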