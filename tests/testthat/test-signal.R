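unit4 <- function() set_unit_branch_lengths(parse_newick("((A,B),(C,D));"))

test_that("Moran's I equals -1 for n = 2 and averages -1/(n-1) over permutations", {
  W <- matrix(c(0, 0.7, 0.7, 0), 2)
  expect_equal(morans_i(c(3, 5), W), -1)

  tr <- unit4()
  x <- c(A = 1, B = 2, C = 4, D = 8)
  W <- inverse_patristic_weights(tr)
  P <- all_perms(4)
  vals <- apply(P, 2, function(id) {
    xp <- setNames(unname(x)[id], names(x))
    morans_i(xp, W)
  })
  expect_equal(mean(vals), -1 / 3, tolerance = 1e-12)
})

test_that("Moran's I agrees with loop oracle and ape on random trees", {
  set.seed(14)
  for (i in 1:10) {
    tr <- simulate_yule_tree(9)
    x <- simulate_bm(tr)
    W <- inverse_patristic_weights(tr)
    expect_equal(morans_i(x, W), moran_oracle(x[rownames(W)], W),
                 tolerance = 1e-12)
    # ape::Moran.I row-normalizes its weights
    Wr <- W / rowSums(W)
    expect_equal(morans_i(x, Wr),
                 ape::Moran.I(x[rownames(W)], W)$observed,
                 tolerance = 1e-9)
  }
})

test_that("Moran's I input validation", {
  W <- matrix(c(0, 1, 1, 0), 2)
  expect_error(morans_i(c(1, 1), W), "zero variance")
  expect_error(morans_i(c(1, 2), -W), "negative")
  expect_error(morans_i(c(1, 2), matrix(1, 2, 2)), "diagonal")
})

test_that("Abouheif's Cmean equals Moran's I on the row-normalized
           product-rule matrix", {
  tr <- parse_newick("((A,B),C);")
  x <- c(A = 1, B = -1, C = 0)
  A <- matrix(0, 3, 3, dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  A["A", "B"] <- A["B", "A"] <- 1 / 2
  A["A", "C"] <- A["C", "A"] <- A["B", "C"] <- A["C", "B"] <- 1 / 4
  expect_equal(abouheif_cmean(tr, x), moran_oracle(x, A / rowSums(A)),
               tolerance = 1e-12)
  expect_error(abouheif_cmean(tr, c(A = 1, B = 1, C = 1)), "zero variance")
})

test_that("Blomberg's K is exactly 1 when V is proportional to identity", {
  star <- set_unit_branch_lengths(parse_newick("(A,B,C,D,E);"))
  set.seed(2)
  for (i in 1:10)
    expect_equal(blomberg_k(star, setNames(rnorm(5), star$tip.label)), 1,
                 tolerance = 1e-12)
})

test_that("Blomberg's K matches the dense oracle and phytools", {
  tr <- unit4()
  x <- c(A = 1, B = 2, C = 4, D = 8)
  expect_equal(blomberg_k(tr, x), k_oracle(tr, x), tolerance = 1e-12)

  set.seed(4)
  tr <- simulate_yule_tree(25)
  x <- simulate_bm(tr)
  expect_equal(blomberg_k(tr, x), k_oracle(tr, x), tolerance = 1e-12)
  expect_equal(blomberg_k(tr, x),
               as.numeric(phytools::phylosig(tr, x, method = "K")),
               tolerance = 1e-6)
})

test_that("lambda = 0 profile equals the independent-normal likelihood", {
  set.seed(6)
  tr <- simulate_yule_tree(12)
  x <- simulate_bm(tr)
  vii <- diag(phylo_covariance(tr))[names(x)]
  direct <- optim(c(mean(x), 0), function(p) {
    -sum(dnorm(x, p[1], sqrt(exp(p[2]) * vii), log = TRUE))
  })
  expect_equal(lambda_logl_oracle(tr, x, 0), -direct$value,
               tolerance = 1e-5)
})

test_that("pagel_lambda matches the dense-matrix oracle", {
  set.seed(16)
  for (i in 1:5) {
    tr <- simulate_yule_tree(10)
    x <- simulate_bm(tr)
    fit <- pagel_lambda(tr, x)
    # profile log-likelihood agrees pointwise on a grid
    for (l in c(0, 0.3, 0.7, min(1, fit$lambda_max))) {
      p <- phylomethyl:::lambda_prep(tr)
      q <- drop(crossprod(p$U, x[tr$tip.label] / p$ds))
      expect_equal(phylomethyl:::lambda_profile(l, p, q)$logL,
                   lambda_logl_oracle(tr, x, l), tolerance = 1e-9)
    }
    expect_equal(fit$lambda, lambda_oracle(tr, x, fit$lambda_max),
                 tolerance = 1e-5)
  }
})

test_that("pagel_lambda agrees with phytools when searching the same range", {
  set.seed(31)
  tr <- simulate_yule_tree(40)
  x <- simulate_lambda_trait(tr, 0.7)
  fit <- pagel_lambda(tr, x)
  ref <- phytools::phylosig(tr, x, method = "lambda")
  if (ref$lambda < 1) {                   # interior optimum for both
    expect_equal(fit$lambda, ref$lambda, tolerance = 1e-4)
    expect_equal(fit$logL, ref$logL, tolerance = 1e-4)
  } else {
    expect_gte(fit$logL, ref$logL - 1e-6) # ours searched a wider range
  }
})

test_that("all four statistics are invariant to affine trait transforms", {
  set.seed(23)
  tr <- simulate_yule_tree(15)
  x <- simulate_bm(tr)
  W <- inverse_patristic_weights(tr)
  for (ab in list(c(2, 0), c(-3, 10), c(0.01, -5))) {
    y <- ab[1] * x + ab[2]
    expect_equal(morans_i(y, W), morans_i(x, W), tolerance = 1e-9)
    expect_equal(abouheif_cmean(tr, y), abouheif_cmean(tr, x),
                 tolerance = 1e-9)
    expect_equal(blomberg_k(tr, y), blomberg_k(tr, x), tolerance = 1e-9)
    expect_equal(pagel_lambda(tr, y)$lambda, pagel_lambda(tr, x)$lambda,
                 tolerance = 1e-6)
  }
})

test_that("randomization test p-values follow the +1 rule and ties count
           against rejection", {
  # observed exceeding all 999 permuted values would give (0+1)/(999+1)
  set.seed(12)
  tr <- simulate_yule_tree(20)
  x <- simulate_bm(tr, sigma2 = 4)
  r <- randomization_test(tr, x, "abouheif_Cmean", n_reps = 999, seed = 3)
  expect_gte(r$p_value, 1 / 1000)
  expect_lte(r$p_value, 1)
  expect_equal(r$p_value * 1000, round(r$p_value * 1000))
  expect_equal(r$statistic, abouheif_cmean(tr, x))
})

test_that("randomization tests are bit-reproducible for a fixed seed", {
  set.seed(19)
  tr <- simulate_yule_tree(12)
  x <- simulate_bm(tr)
  for (idx in c("morans_I", "abouheif_Cmean", "blomberg_K",
                "pagel_lambda")) {
    r1 <- randomization_test(tr, x, idx, n_reps = 99, seed = 7)
    r2 <- randomization_test(tr, x, idx, n_reps = 99, seed = 7)
    expect_identical(r1, r2)
  }
})

test_that("randomization p matches exhaustive enumeration at n = 4", {
  tr <- unit4()
  x <- c(A = 1, B = 2, C = 4, D = 8)
  W <- inverse_patristic_weights(tr)
  p_exact <- moran_exhaustive_p(x, W)
  r <- randomization_test(tr, x, "morans_I", n_reps = 20000, seed = 2)
  expect_lt(abs(r$p_value - p_exact), 0.02)
})
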