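# Correlated evolution: Felsenstein's phylogenetically independent
# contrasts, regression through the origin with a permutation test, and
# the associated diagnostics.

#' Phylogenetically independent contrasts
#'
#' Felsenstein's contrasts on a rooted binary tree with strictly positive
#' branch lengths. In one post-order pass, each internal node with child
#' values \eqn{x_i, x_j} on (adjusted) branches \eqn{b_i, b_j} yields the
#' standardized contrast \eqn{(x_i - x_j)/\sqrt{b_i + b_j}}; the node is
#' assigned the weighted value \eqn{(x_i/b_i + x_j/b_j)/(1/b_i + 1/b_j)}
#' and its own branch is lengthened by \eqn{b_i b_j/(b_i + b_j)}. A
#' binary tree with n tips gives n - 1 contrasts, mutually independent
#' with common variance under Brownian motion.
#'
#' Contrast signs are arbitrary; for reproducibility the minuend at every
#' node is the child whose descendant set contains the lexicographically
#' smallest tip label. Two traits computed on the same tree therefore
#' pair up node by node with consistent orientation.
#'
#' @param tree a binary `"phylo"` object with all branch lengths > 0
#'   (resolve polytomies first with [resolve_polytomies()]).
#' @param x named numeric trait vector, complete for all tips.
#' @return a data frame of class `"contrast_set"` with columns `node`
#'   (ape node id), `contrast` and `variance` (the expected variance
#'   \eqn{b_i + b_j}), in post-order; `nrow = Ntip - 1`.
#' @export
pic_contrasts <- function(tree, x) {
  validate_phylo(tree, require_lengths = TRUE)
  if (!tree_is_binary(tree))
    stop("tree has polytomies; run resolve_polytomies() first")
  if (any(tree$edge.length <= 0))
    stop("all branch lengths must be > 0 for contrasts")
  x <- align_trait(tree, x)
  n <- length(tree$tip.label)
  nnode <- tree$Nnode
  tp <- ape::reorder.phylo(tree, "postorder")
  val <- numeric(n + nnode)
  val[seq_len(n)] <- x
  blen <- numeric(n + nnode)
  blen[tp$edge[, 2L]] <- tp$edge.length
  minlab <- character(n + nnode)
  minlab[seq_len(n)] <- tree$tip.label

  parents <- unique(tp$edge[, 1L])          # post-order over internal nodes
  contrast <- numeric(length(parents))
  cvar <- numeric(length(parents))
  for (k in seq_along(parents)) {
    nd <- parents[k]
    ch <- tp$edge[tp$edge[, 1L] == nd, 2L]
    if (length(ch) != 2L) stop("non-binary node encountered")
    if (minlab[ch[2L]] < minlab[ch[1L]]) ch <- ch[c(2L, 1L)]
    b <- blen[ch]
    v <- b[1L] + b[2L]
    contrast[k] <- (val[ch[1L]] - val[ch[2L]]) / sqrt(v)
    cvar[k] <- v
    val[nd] <- (val[ch[1L]] / b[1L] + val[ch[2L]] / b[2L]) /
      (1 / b[1L] + 1 / b[2L])
    blen[nd] <- blen[nd] + b[1L] * b[2L] / v
    minlab[nd] <- min(minlab[ch])
  }
  out <- data.frame(node = parents, contrast = contrast, variance = cvar)
  attr(out, "trait") <- deparse1(substitute(x))
  class(out) <- c("contrast_set", "data.frame")
  out
}

#' Base-10 log transform of genome sizes
#'
#' Genome size (C-value, picograms per haploid nucleus) spans orders of
#' magnitude across species and is log10-transformed before contrasts.
#'
#' @param values positive numeric vector (named by species, typically).
#' @return `log10(values)`, names preserved.
#' @export
log10_transform <- function(values) {
  bad <- !is.na(values) & values <= 0
  if (any(bad)) {
    who <- if (!is.null(names(values))) names(values)[bad]
           else paste("element", which(bad))
    stop("non-positive values cannot be log-transformed: ",
         paste(who, collapse = ", "))
  }
  log10(values)
}

contrast_values <- function(c) {
  if (inherits(c, "contrast_set")) c$contrast else as.numeric(c)
}

#' Regression through the origin for paired contrasts
#'
#' Least-squares regression of `cy` on `cx` with no intercept, the
#' appropriate model for independent contrasts (whose signs, hence means,
#' are arbitrary):
#' \deqn{\hat\beta = \frac{\sum c_x c_y}{\sum c_x^2}, \qquad
#'   F = \frac{\hat\beta^2 \sum c_x^2}{MS_{res}} \ \text{on } (1, n-1)\ df.}
#' R-squared uses the uncentered total sum of squares
#' \eqn{\sum c_y^2} (origin model); the adjusted version is
#' \eqn{1 - (1 - R^2)\, n/(n-1)}, consistent with total df = n for a
#' model with no intercept.
#'
#' @param cx,cy paired contrasts (`"contrast_set"` or numeric vectors of
#'   equal length, n >= 3).
#' @return a list of class `"origin_fit"`: `slope`, `se`, `F`, `df`
#'   (`c(1, n-1)`), `r_squared`, `adj_r_squared`, `p_parametric`,
#'   `residuals`, `fitted`, `n`.
#' @export
origin_regression <- function(cx, cy) {
  cx <- contrast_values(cx); cy <- contrast_values(cy)
  n <- length(cx)
  if (length(cy) != n) stop("'cx' and 'cy' lengths differ")
  if (n < 3L) stop("need at least 3 contrast pairs")
  if (anyNA(cx) || anyNA(cy)) stop("contrasts contain missing values")
  sxx <- sum(cx^2)
  if (sxx == 0) stop("all x-contrasts are zero")
  slope <- sum(cx * cy) / sxx
  fitted <- slope * cx
  res <- cy - fitted
  ss_res <- sum(res^2)
  ss_tot <- sum(cy^2)
  ms_res <- ss_res / (n - 1)
  Fstat <- if (ms_res > 0) slope^2 * sxx / ms_res else Inf
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_
  structure(list(
    slope = slope,
    se = sqrt(ms_res / sxx),
    F = Fstat,
    df = c(1L, n - 1L),
    r_squared = r2,
    adj_r_squared = 1 - (1 - r2) * n / (n - 1),
    p_parametric = pf(Fstat, 1, n - 1, lower.tail = FALSE),
    residuals = res,
    fitted = fitted,
    n = n
  ), class = "origin_fit")
}

#' @export
print.origin_fit <- function(x, ...) {
  cat("Regression through the origin (independent contrasts)\n")
  cat(sprintf("  slope = %.4g +/- %.4g (SE), n = %d\n", x$slope, x$se, x$n))
  cat(sprintf("  F(%d, %d) = %.4g, parametric p = %.4g\n",
              x$df[1], x$df[2], x$F, x$p_parametric))
  cat(sprintf("  R2 = %.4f, adjusted R2 = %.4f\n",
              x$r_squared, x$adj_r_squared))
  invisible(x)
}

#' Permutation test for the through-origin regression
#'
#' Each replicate permutes the `cy` contrasts against `cx` and, by
#' default, independently flips each permuted value's sign with
#' probability 1/2 (contrast directions are arbitrary, so the null is
#' invariant to reflections); the F statistic is recomputed and
#' \eqn{p = (\#\{F_{perm} \ge F_{obs}\} + 1)/(n_{reps} + 1)}. Plain
#' permutation without sign flips is available via `sign_flip = FALSE`.
#'
#' @inheritParams origin_regression
#' @param n_reps number of permutations (at least 99).
#' @param seed integer seed for reproducibility.
#' @param sign_flip randomly flip signs of permuted contrasts?
#' @return a list of class `"origin_permutation"`: `p_value`, `F_obs`,
#'   `n_reps`, `seed`, `sign_flip`.
#' @export
origin_permutation_test <- function(cx, cy, n_reps = 999, seed = NULL,
                                    sign_flip = TRUE) {
  cx <- contrast_values(cx); cy <- contrast_values(cy)
  if (n_reps < 99) stop("n_reps must be at least 99")
  fit <- origin_regression(cx, cy)
  n <- fit$n
  sxx <- sum(cx^2)
  if (!is.null(seed)) set.seed(seed)
  perm <- numeric(n_reps)
  done <- 0L
  chunk <- 10000L
  while (done < n_reps) {
    b <- min(chunk, n_reps - done)
    idx <- vapply(seq_len(b), function(i) sample.int(n), integer(n))
    Y <- matrix(cy[idx], n, b)
    if (sign_flip)
      Y <- Y * matrix(sample(c(-1, 1), n * b, replace = TRUE), n, b)
    slopes <- drop(crossprod(Y, cx)) / sxx
    ss_res <- colSums(Y^2) - slopes^2 * sxx
    perm[done + seq_len(b)] <- slopes^2 * sxx / (ss_res / (n - 1))
    done <- done + b
  }
  p <- (sum(perm >= fit$F) + 1) / (n_reps + 1)
  structure(list(p_value = p, F_obs = fit$F, n_reps = as.integer(n_reps),
                 seed = seed, sign_flip = sign_flip),
            class = "origin_permutation")
}

#' @export
print.origin_permutation <- function(x, ...) {
  cat(sprintf(
    "Permutation test (%s): F_obs = %.4g, p = %.4g (%d reps)\n",
    if (x$sign_flip) "permute + sign-flip" else "permute only",
    x$F_obs, x$p_value, x$n_reps))
  invisible(x)
}

#' Shapiro-Wilk normality test
#'
#' Contrasts are expected to be normally distributed under Brownian
#' motion; this wraps [stats::shapiro.test()] to check that expectation
#' (and residual normality in [regression_diagnostics()]).
#'
#' @param values numeric vector, 3 <= n <= 5000, non-constant.
#' @return a list with `W` and `p_value`.
#' @export
shapiro_wilk <- function(values) {
  values <- contrast_values(values)
  if (anyNA(values)) stop("missing values")
  if (length(values) < 3L || length(values) > 5000L)
    stop("Shapiro-Wilk requires 3 <= n <= 5000")
  if (var(values) == 0) stop("constant input")
  st <- shapiro.test(values)
  list(W = unname(st$statistic), p_value = st$p.value)
}

#' Diagnostics for a through-origin contrast regression
#'
#' Descriptive checks mirroring conventional regression diagnostics,
#' adjusted for phylogeny by operating on contrasts: Shapiro-Wilk
#' normality of residuals, a residual-versus-fitted table for visual
#' linearity/homoscedasticity inspection, and a scale-location slope
#' (slope of sqrt(|standardized residual|) on fitted values) as a
#' heteroscedasticity screen. Purely descriptive; nothing is rejected
#' automatically. Exact fits (all residuals numerically zero) are
#' flagged degenerate and skip the normality test.
#'
#' @param fit an `"origin_fit"` from [origin_regression()].
#' @return a list of class `"origin_diagnostics"`: `degenerate`,
#'   `residual_normality` (`W`, `p_value`, or `NULL` if degenerate),
#'   `scale_location_slope`, `table` (data frame of fitted and
#'   residuals).
#' @export
regression_diagnostics <- function(fit) {
  if (!inherits(fit, "origin_fit")) stop("'fit' must be an origin_fit")
  res <- fit$residuals
  scale <- sqrt(mean(res^2))
  degenerate <- scale < 1e-12 * max(1, sqrt(mean(fit$fitted^2)))
  norm <- NULL
  sl_slope <- NA_real_
  if (!degenerate) {
    norm <- shapiro_wilk(res)
    sl <- lm(sqrt(abs(res / scale)) ~ fit$fitted)
    sl_slope <- unname(coef(sl)[2L])
  }
  structure(list(degenerate = degenerate,
                 residual_normality = norm,
                 scale_location_slope = sl_slope,
                 table = data.frame(fitted = fit$fitted, residual = res)),
            class = "origin_diagnostics")
}

#' @export
print.origin_diagnostics <- function(x, ...) {
  if (x$degenerate) {
    cat("Diagnostics: exact fit (all residuals ~ 0); degenerate\n")
  } else {
    cat(sprintf(
      "Residual normality: W = %.4f, p = %.4g; scale-location slope = %.4g\n",
      x$residual_normality$W, x$residual_normality$p_value,
      x$scale_location_slope))
  }
  invisible(x)
}
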