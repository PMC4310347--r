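# Independent oracles used to validate the package implementations.
# These deliberately take different computational routes (dense solves,
# explicit loops, exhaustive enumeration) from the code under test.

# all permutations of 1..n as columns (n small)
all_perms <- function(n) {
  if (n == 1L) return(matrix(1L))
  sub <- all_perms(n - 1L)
  out <- matrix(0L, n, n * ncol(sub))
  k <- 0L
  for (i in seq_len(n)) {
    for (j in seq_len(ncol(sub))) {
      k <- k + 1L
      rest <- seq_len(n)[-i]
      out[, k] <- c(i, rest[sub[, j]])
    }
  }
  out
}

# Moran's I by explicit double loop
moran_oracle <- function(x, W) {
  n <- length(x)
  z <- x - mean(x)
  num <- 0; s0 <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) if (i != j) {
    num <- num + W[i, j] * z[i] * z[j]
    s0 <- s0 + W[i, j]
  }
  unname((n / s0) * num / sum(z^2))
}

# Blomberg's K by scalar quadratic forms on the dense covariance
k_oracle <- function(tree, x) {
  V <- ape::vcv.phylo(tree)
  x <- x[rownames(V)]
  n <- length(x)
  one <- rep(1, n)
  Vi <- solve(V)
  ahat <- as.numeric(t(one) %*% Vi %*% x) / as.numeric(t(one) %*% Vi %*% one)
  z <- x - ahat
  mse0 <- as.numeric(t(z) %*% z) / (n - 1)
  mse <- as.numeric(t(z) %*% Vi %*% z) / (n - 1)
  expected <- (sum(diag(V)) - n / as.numeric(t(one) %*% Vi %*% one)) / (n - 1)
  (mse0 / mse) / expected
}

# lambda-model profile log-likelihood by dense solve and determinant
lambda_logl_oracle <- function(tree, x, lambda) {
  V <- ape::vcv.phylo(tree)
  x <- x[rownames(V)]
  n <- length(x)
  Vl <- lambda * V
  diag(Vl) <- diag(V)
  Vi <- solve(Vl)
  one <- rep(1, n)
  mu <- as.numeric(t(one) %*% Vi %*% x) / as.numeric(t(one) %*% Vi %*% one)
  r <- x - mu
  s2 <- as.numeric(t(r) %*% Vi %*% r) / n
  -0.5 * (n * (log(2 * pi * s2) + 1) + determinant(Vl)$modulus[1])
}

lambda_oracle <- function(tree, x, lambda_max) {
  opt <- optimize(function(l) lambda_logl_oracle(tree, x, l),
                  c(0, lambda_max), maximum = TRUE, tol = 1e-9)
  cand <- c(0, opt$maximum, lambda_max)
  ll <- vapply(cand, function(l) lambda_logl_oracle(tree, x, l), numeric(1))
  cand[which.max(ll)]
}

# Abouheif proximity via ape::nodepath (different path machinery)
abouheif_oracle <- function(tree) {
  n <- length(tree$tip.label)
  nchild <- tabulate(tree$edge[, 1L], nbins = n + tree$Nnode)
  A <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    path <- ape::nodepath(tree, i, j)
    inner <- path[path > n]               # internal nodes only
    A[i, j] <- A[j, i] <- 1 / prod(nchild[inner])
  }
  A
}

# Linear map x -> contrasts, built by probing with basis vectors.
# Under BM with unit rate, contrasts must satisfy T V T' = I.
contrast_matrix <- function(tree) {
  n <- length(tree$tip.label)
  base <- pic_contrasts(tree, setNames(rep(0, n), tree$tip.label))
  T <- matrix(0, n - 1, n)
  for (k in seq_len(n)) {
    e <- setNames(numeric(n), tree$tip.label)
    e[k] <- 1
    T[, k] <- pic_contrasts(tree, e)$contrast - base$contrast
  }
  T
}

# exhaustive one-sided permutation p for Moran's I at small n
moran_exhaustive_p <- function(x, W) {
  P <- all_perms(length(x))
  obs <- moran_oracle(x, W)
  stats <- apply(P, 2, function(id) moran_oracle(x[id], W))
  mean(stats >= obs - 1e-12)
}

# exhaustive permutation + sign-flip p for the origin regression F
origin_exhaustive_p <- function(cx, cy) {
  n <- length(cx)
  fstat <- function(cy2) {
    sxx <- sum(cx^2)
    slope <- sum(cx * cy2) / sxx
    ssr <- sum((cy2 - slope * cx)^2)
    slope^2 * sxx / (ssr / (n - 1))
  }
  obs <- fstat(cy)
  P <- all_perms(n)
  signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
  vals <- numeric(ncol(P) * nrow(signs))
  k <- 0L
  for (j in seq_len(ncol(P))) for (s in seq_len(nrow(signs))) {
    k <- k + 1L
    vals[k] <- fstat(cy[P[, j]] * signs[s, ])
  }
  mean(vals >= obs - 1e-12)
}
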