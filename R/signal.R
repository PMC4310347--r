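# Phylogenetic-signal statistics: Moran's I and Abouheif's Cmean
# (autocorrelation indices, no evolutionary model), Blomberg's K and
# Pagel's lambda (Brownian-motion based), plus the shared randomization
# test. All are invariant to affine transforms of the trait.

#' Moran's I phylogenetic autocorrelation
#'
#' With centred trait \eqn{z = x - \bar x} and proximity weights W (zero
#' diagonal, non-negative):
#' \deqn{I = \frac{n}{S_0} \frac{\sum_{i \ne j} w_{ij} z_i z_j}{\sum_i z_i^2},
#'   \qquad S_0 = \sum_{i \ne j} w_{ij}.}
#' Its expected value under random tip permutation is \eqn{-1/(n-1)};
#' values above that indicate that phylogenetically close species carry
#' similar trait values. The default weights for a tree are
#' inverse-patristic ([inverse_patristic_weights()]); any proximity
#' matrix with zero diagonal may be supplied.
#'
#' @param x named numeric trait vector (names = species labels).
#' @param weights proximity matrix with zero diagonal and non-negative
#'   entries, dimnames matching `names(x)`.
#' @return the Moran's I statistic (scalar).
#' @export
morans_i <- function(x, weights) {
  weights <- as.matrix(weights)
  n <- length(x)
  if (n < 2L) stop("need at least 2 values")
  if (!all(dim(weights) == n)) stop("weights must be ", n, "x", n)
  if (any(weights < 0)) stop("negative weights are not allowed")
  if (any(diag(weights) != 0)) stop("weights must have a zero diagonal")
  if (!is.null(names(x)) && !is.null(rownames(weights))) {
    if (!setequal(names(x), rownames(weights)))
      stop("names of 'x' and dimnames of 'weights' disagree")
    weights <- weights[names(x), names(x), drop = FALSE]
  }
  if (anyNA(x)) stop("'x' contains missing values")
  if (var(x) == 0) stop("trait has zero variance")
  z <- x - mean(x)
  s0 <- sum(weights)
  (n / s0) * drop(crossprod(z, weights %*% z)) / sum(z^2)
}

# batched Moran's I: columns of Z are centred trait vectors
morans_i_batch <- function(Z, weights, s0 = sum(weights)) {
  n <- nrow(Z)
  (n / s0) * colSums(Z * (weights %*% Z)) / colSums(Z^2)
}

#' Abouheif's Cmean
#'
#' Abouheif's test statistic for phylogenetic autocorrelation: Moran's I
#' computed with the row-normalized Abouheif proximity matrix
#' ([abouheif_proximity()]), which depends on topology only (products of
#' numbers of direct descendants along tip-to-tip paths). Robust to
#' missing branch lengths.
#'
#' @param tree a rooted `"phylo"` object.
#' @param x named numeric trait vector over the tips of `tree`.
#' @return the Cmean statistic (scalar).
#' @export
abouheif_cmean <- function(tree, x) {
  x <- align_trait(tree, x)
  W <- abouheif_proximity(tree, normalize = "row")
  morans_i(x, W)
}

#' Blomberg's K
#'
#' Ratio of the observed trait variance (around the phylogenetically
#' corrected mean) to the variance expected under Brownian motion on the
#' tree. With \eqn{V} the phylogenetic covariance matrix,
#' \eqn{\hat a = (1^T V^{-1} x)/(1^T V^{-1} 1)} the GLS mean and
#' \eqn{z = x - \hat a 1}:
#' \deqn{K = \frac{z^T z / z^T V^{-1} z}{[\mathrm{tr}(V) - n/(1^T V^{-1} 1)]/(n-1)}.}
#' K = 1 is the Brownian expectation; K < 1 means less resemblance among
#' relatives than Brownian motion predicts, K > 1 more. On a star tree
#' (V proportional to the identity) K equals 1 exactly for any
#' non-constant trait.
#'
#' @inheritParams abouheif_cmean
#' @return the K statistic (non-negative scalar).
#' @export
blomberg_k <- function(tree, x) {
  x <- align_trait(tree, x)
  if (var(x) == 0) stop("trait has zero variance")
  V <- phylo_covariance(tree)
  Vinv <- tryCatch(solve(V), error = function(e)
    stop("phylogenetic covariance is singular (zero-length branches?): ",
         conditionMessage(e), call. = FALSE))
  unname(blomberg_k_batch(cbind(unname(x)), Vinv, sum(diag(V)))[1L])
}

# batched K: columns of X are trait vectors; Vinv and tr(V) precomputed
blomberg_k_batch <- function(X, Vinv, trV) {
  n <- nrow(X)
  v1 <- Vinv %*% rep(1, n)
  s1 <- sum(v1)
  ahat <- drop(crossprod(v1, X)) / s1
  D <- X - rep(ahat, each = n)
  mse0 <- colSums(D^2)
  mse <- colSums(D * (Vinv %*% D))
  expected <- (trV - n / s1) / (n - 1)
  (mse0 / mse) / expected
}

# Shared spectral preparation for the lambda model. With D = diag(V) and
# C = D^{-1/2} V D^{-1/2} (unit diagonal), V(lambda) = D^{1/2} [I +
# lambda (C - I)] D^{1/2}, so one symmetric eigendecomposition C = U L U'
# makes every lambda evaluation O(n): quadratic forms against
# V(lambda)^{-1} become weighted sums with weights 1/(1 + lambda(L_i -
# 1)) and log|V(lambda)| = sum log D_ii + sum log(1 + lambda(L_i - 1)).
lambda_prep <- function(tree) {
  V <- phylo_covariance(tree)
  d <- diag(V)
  if (any(d <= 0)) stop("zero-depth tip: V is not positive definite")
  ds <- sqrt(d)
  C <- V / tcrossprod(ds)
  eig <- eigen(C, symmetric = TRUE)
  n <- nrow(V)
  offdiag <- C[row(C) != col(C)]
  pair_bound <- if (any(offdiag > 0)) 1 / max(offdiag) else Inf
  lmin <- min(eig$values)
  pd_bound <- if (lmin < 1) (1 - 1e-8) / (1 - lmin) else Inf
  list(n = n, ds = ds, sumlogd = sum(log(d)),
       U = eig$vectors, lam = eig$values,
       q1 = drop(crossprod(eig$vectors, 1 / ds)),
       lambda_cap = min(pair_bound, pd_bound))
}

# Profile log-likelihood of lambda given q = U' D^{-1/2} x. mu and
# sigma2 are profiled out analytically (GLS mean, ML variance).
lambda_profile <- function(lambda, prep, q) {
  g <- 1 + lambda * (prep$lam - 1)
  if (any(g <= 0)) return(list(logL = -Inf, mu = NA_real_, s2 = NA_real_))
  q1 <- prep$q1
  mu <- sum(q * q1 / g) / sum(q1^2 / g)
  r <- q - mu * q1
  s2 <- sum(r^2 / g) / prep$n
  logL <- -0.5 * (prep$n * (log(2 * pi * s2) + 1) +
                    prep$sumlogd + sum(log(g)))
  list(logL = logL, mu = mu, s2 = s2)
}

#' Maximum-likelihood estimate of Pagel's lambda
#'
#' Pagel's lambda rescales the off-diagonal entries of the phylogenetic
#' covariance matrix: \eqn{V(\lambda)} has the diagonal of V and
#' \eqn{\lambda v_{ij}} off it. lambda = 0 corresponds to phylogenetic
#' independence, lambda = 1 to Brownian motion. The Gaussian likelihood
#' is profiled analytically over the mean and rate, and the profile
#' log-likelihood is maximized over `[0, lambda_max]` by bounded scalar
#' optimization (tolerance 1e-8), with both interval endpoints checked.
#'
#' The default upper bound is the largest value keeping
#' \eqn{V(\lambda)} positive definite: the smaller of
#' \eqn{\min_{i \ne j} \sqrt{v_{ii} v_{jj}}/v_{ij}}, the exact spectral
#' positive-definiteness limit, and `cap` (1.5 by default; values above 1
#' are allowed because for non-ultrametric trees the likelihood can peak
#' slightly above unity).
#'
#' @inheritParams abouheif_cmean
#' @param lambda_max optional upper search bound; defaults as described.
#' @param cap cap applied to the automatic bound.
#' @param tol convergence tolerance of the scalar optimizer.
#' @return a list of class `"lambda_fit"`: `lambda`, `logL`, `sigma2`
#'   (ML Brownian rate at the optimum), `mu` (GLS root mean),
#'   `lambda_max`.
#' @export
pagel_lambda <- function(tree, x, lambda_max = NULL, cap = 1.5, tol = 1e-8) {
  x <- align_trait(tree, x)
  if (length(x) < 4L) stop("need at least 4 tips to estimate lambda")
  if (var(x) == 0) stop("trait has zero variance")
  prep <- lambda_prep(tree)
  if (is.null(lambda_max)) lambda_max <- min(prep$lambda_cap, cap)
  if (!is.finite(lambda_max) || lambda_max <= 0)
    stop("invalid lambda_max")
  q <- drop(crossprod(prep$U, x / prep$ds))
  fit <- lambda_ml(prep, q, lambda_max, tol)
  structure(c(fit, list(lambda_max = lambda_max)), class = "lambda_fit")
}

lambda_ml <- function(prep, q, lambda_max, tol = 1e-8) {
  f <- function(l) lambda_profile(l, prep, q)$logL
  opt <- optimize(f, c(0, lambda_max), maximum = TRUE, tol = tol)
  cand <- c(0, opt$maximum, lambda_max)
  ll <- c(f(0), opt$objective, f(lambda_max))
  best <- which.max(ll)
  prof <- lambda_profile(cand[best], prep, q)
  list(lambda = cand[best], logL = prof$logL,
       sigma2 = prof$s2, mu = prof$mu)
}

#' @export
print.lambda_fit <- function(x, ...) {
  cat("Pagel's lambda (ML)\n")
  cat(sprintf("  lambda = %.4f  (search bound %.4f)\n", x$lambda,
              x$lambda_max))
  cat(sprintf("  logL = %.4f, sigma2 = %.4g, mu = %.4g\n",
              x$logL, x$sigma2, x$mu))
  invisible(x)
}

#' Randomization test for phylogenetic signal
#'
#' Tests a signal statistic against the null of no association between
#' trait values and tip positions, by permuting trait values uniformly
#' across tips and recomputing the statistic. The one-sided p-value
#' (signal greater than null) is
#' \deqn{p = (\#\{stat_{perm} \ge stat_{obs}\} + 1)/(n_{reps} + 1),}
#' so it is never zero, and ties count against rejection (conservative).
#' Deterministic for a fixed `seed`.
#'
#' For `"pagel_lambda"` the statistic recomputed per permutation is the
#' ML estimate itself, which is the costly case; its customary replicate
#' count is therefore lower (e.g. 999) while the other three indices are
#' cheap enough for 1e5 replicates.
#'
#' @param tree a rooted `"phylo"` object (may be omitted for
#'   `"morans_I"` when `weights` is supplied).
#' @param x named numeric trait vector.
#' @param index which statistic to test.
#' @param n_reps number of random permutations (at least 99).
#' @param seed integer seed for reproducibility.
#' @param weights optional proximity matrix for `"morans_I"`; defaults
#'   to inverse-patristic weights of `tree`.
#' @return an object of class `"signal_result"`: `index`, `statistic`,
#'   `p_value`, `n_reps`, `seed`, and for lambda also `logL`, `sigma2`,
#'   `mu`.
#' @export
randomization_test <- function(tree = NULL, x,
                               index = c("morans_I", "abouheif_Cmean",
                                         "blomberg_K", "pagel_lambda"),
                               n_reps = 999, seed = NULL, weights = NULL) {
  index <- match.arg(index)
  if (n_reps < 99) stop("n_reps must be at least 99")
  if (!is.null(tree)) x <- align_trait(tree, x)
  n <- length(x)
  if (n < 3L) stop("need at least 3 tips for a randomization test")
  if (var(x) == 0) stop("trait has zero variance")
  if (!is.null(seed)) set.seed(seed)

  extras <- NULL
  if (index %in% c("morans_I", "abouheif_Cmean")) {
    W <- if (index == "abouheif_Cmean") {
      if (is.null(tree)) stop("'tree' is required for Abouheif's Cmean")
      abouheif_proximity(tree, normalize = "row")
    } else if (is.null(weights)) {
      if (is.null(tree)) stop("supply 'tree' or 'weights' for Moran's I")
      inverse_patristic_weights(tree)
    } else {
      weights
    }
    if (!is.null(names(x)) && !is.null(rownames(W)))
      W <- W[names(x), names(x), drop = FALSE]
    s0 <- sum(W)
    z <- unname(x - mean(x))
    obs <- unname(morans_i_batch(cbind(z), W, s0)[1L])
    perm <- permute_stat(z, n_reps, function(Z) morans_i_batch(Z, W, s0))
  } else if (index == "blomberg_K") {
    if (is.null(tree)) stop("'tree' is required for Blomberg's K")
    V <- phylo_covariance(tree)
    Vinv <- solve(V)
    trV <- sum(diag(V))
    obs <- blomberg_k_batch(cbind(x), Vinv, trV)[1L]
    perm <- permute_stat(x, n_reps, function(X) blomberg_k_batch(X, Vinv, trV))
  } else {
    if (is.null(tree)) stop("'tree' is required for Pagel's lambda")
    prep <- lambda_prep(tree)
    lambda_max <- min(prep$lambda_cap, 1.5)
    q <- drop(crossprod(prep$U, x / prep$ds))
    ofit <- lambda_ml(prep, q, lambda_max)
    obs <- ofit$lambda
    extras <- list(logL = ofit$logL, sigma2 = ofit$sigma2, mu = ofit$mu)
    tU <- t(prep$U)
    perm <- vapply(seq_len(n_reps), function(b) {
      xp <- x[sample.int(n)]
      lambda_ml(prep, drop(tU %*% (xp / prep$ds)), lambda_max)$lambda
    }, numeric(1))
  }
  p <- (sum(perm >= obs) + 1) / (n_reps + 1)
  structure(c(list(index = index, statistic = obs, p_value = p,
                   n_reps = as.integer(n_reps), seed = seed), extras),
            class = "signal_result")
}

# Apply 'fun' to chunks of tip-permuted copies of x (columns), returning
# the vector of permuted statistics. Chunked to bound memory at large
# replicate counts.
permute_stat <- function(x, n_reps, fun, chunk = 10000L) {
  n <- length(x)
  out <- numeric(n_reps)
  done <- 0L
  while (done < n_reps) {
    b <- min(chunk, n_reps - done)
    idx <- vapply(seq_len(b), function(i) sample.int(n), integer(n))
    out[done + seq_len(b)] <- fun(matrix(x[idx], n, b))
    done <- done + b
  }
  out
}

#' @export
print.signal_result <- function(x, ...) {
  nice <- c(morans_I = "Moran's I", abouheif_Cmean = "Abouheif's Cmean",
            blomberg_K = "Blomberg's K", pagel_lambda = "Pagel's lambda")
  cat(sprintf("%s = %.4f, randomization p = %.4g (%d reps%s)\n",
              nice[[x$index]], x$statistic, x$p_value, x$n_reps,
              if (is.null(x$seed)) "" else paste0(", seed ", x$seed)))
  invisible(x)
}
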