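# Tip-by-tip matrices derived from the tree: the Brownian-motion
# covariance V, patristic distances, and the proximity matrices used by
# the autocorrelation statistics. All matrices are returned with rows and
# columns in tree tip-label order (tree$tip.label), with dimnames set.

#' Phylogenetic (Brownian-motion) covariance matrix
#'
#' Entry \eqn{v_{ij}} is the total branch length shared by the root-to-tip
#' paths of tips i and j, i.e. the depth of their most recent common
#' ancestor; \eqn{v_{ii}} is the depth of tip i. Under Brownian motion
#' with rate \eqn{\sigma^2}, tip values are jointly Gaussian with
#' covariance \eqn{\sigma^2 V}.
#'
#' @param tree a `"phylo"` object with complete, non-negative branch
#'   lengths.
#' @return a symmetric positive semi-definite matrix indexed by tip label.
#' @export
phylo_covariance <- function(tree) {
  validate_phylo(tree, require_lengths = TRUE)
  V <- ape::vcv.phylo(tree)
  V[tree$tip.label, tree$tip.label, drop = FALSE]
}

#' Patristic distance matrix
#'
#' \eqn{d_{ij}} is the sum of branch lengths on the path between tips i
#' and j; it satisfies \eqn{d_{ij} = v_{ii} + v_{jj} - 2 v_{ij}} with V
#' from [phylo_covariance()].
#'
#' @inheritParams phylo_covariance
#' @return a symmetric matrix with zero diagonal, indexed by tip label.
#' @export
patristic_distances <- function(tree) {
  validate_phylo(tree, require_lengths = TRUE)
  D <- ape::cophenetic.phylo(tree)
  D[tree$tip.label, tree$tip.label, drop = FALSE]
}

#' Inverse-patristic proximity weights
#'
#' The default spatial-style weight matrix for [morans_i()]:
#' \eqn{w_{ij} = 1/d_{ij}} off the diagonal (patristic distances), zero on
#' the diagonal. Optionally row-normalized so each row sums to one.
#'
#' @inheritParams phylo_covariance
#' @param row_normalize divide each row by its sum?
#' @return a non-negative matrix with zero diagonal, indexed by tip label.
#' @export
inverse_patristic_weights <- function(tree, row_normalize = FALSE) {
  D <- patristic_distances(tree)
  if (any(D[upper.tri(D)] == 0))
    stop("patristic distance of 0 between distinct tips; ",
         "cannot form inverse-distance weights")
  W <- 1 / D
  diag(W) <- 0
  if (row_normalize) W <- W / rowSums(W)
  W
}

#' Abouheif proximity matrix
#'
#' For tips \eqn{i \neq j} the raw proximity is
#' \eqn{a_{ij} = 1 / \prod_k \mathrm{DD}(k)} where the product runs over
#' the internal nodes k on the path between i and j (the most recent
#' common ancestor included once) and \eqn{\mathrm{DD}(k)} is the number
#' of direct descendants (children) of k. The diagonal is zero. This is
#' the proximity underlying Abouheif's test of serial independence; it
#' uses topology only, so missing branch lengths are irrelevant.
#'
#' @inheritParams phylo_covariance
#' @param normalize `"row"` (default; each row divided by its sum — the
#'   form consumed by [abouheif_cmean()]), `"none"` for the raw
#'   product-rule matrix, or `"total"` to divide by the grand sum.
#' @return a non-negative matrix with zero diagonal, indexed by tip label.
#' @export
abouheif_proximity <- function(tree, normalize = c("row", "none", "total")) {
  validate_phylo(tree)
  normalize <- match.arg(normalize)
  n <- length(tree$tip.label)
  nnode <- tree$Nnode
  parent <- integer(n + nnode)
  parent[tree$edge[, 2L]] <- tree$edge[, 1L]
  nchild <- tabulate(tree$edge[, 1L], nbins = n + nnode)
  root <- n + 1L
  # ancestors of each tip, ordered parent -> root
  anc <- vector("list", n)
  for (i in seq_len(n)) {
    path <- integer(0)
    k <- parent[i]
    while (k != 0L) { path <- c(path, k); k <- parent[k] }
    anc[[i]] <- path
  }
  A <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(n - 1L)) {
    ai <- anc[[i]]
    for (j in (i + 1L):n) {
      aj <- anc[[j]]
      pos <- match(ai, aj)
      k <- which(!is.na(pos))[1L]     # first shared ancestor = MRCA
      nodes <- c(ai[seq_len(k)], aj[seq_len(pos[k] - 1L)])
      A[i, j] <- A[j, i] <- 1 / prod(nchild[nodes])
    }
  }
  switch(normalize,
         none  = A,
         row   = A / rowSums(A),
         total = A / sum(A))
}

# Align a named trait vector to the tree's tip order. Unnamed vectors of
# the right length are accepted and assumed to already be in tip order.
align_trait <- function(tree, x, what = "trait") {
  n <- length(tree$tip.label)
  if (length(x) != n)
    stop(what, " has length ", length(x), " but tree has ", n, " tips",
         call. = FALSE)
  if (!is.numeric(x)) stop(what, " must be numeric", call. = FALSE)
  if (anyNA(x)) stop(what, " contains missing values", call. = FALSE)
  if (!is.null(names(x))) {
    miss <- setdiff(tree$tip.label, names(x))
    if (length(miss))
      stop(what, " is missing species: ", paste(miss, collapse = ", "),
           call. = FALSE)
    x <- x[tree$tip.label]
  } else {
    names(x) <- tree$tip.label
  }
  x
}
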