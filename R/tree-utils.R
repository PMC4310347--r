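# Tree input, validation and preparation.
#
# All functions operate on rooted ape "phylo" objects. Tip labels are the
# join key against trait tables, so they must be unique and non-empty.

`%||%` <- function(a, b) if (is.null(a)) b else a

validate_phylo <- function(tree, require_lengths = FALSE) {
  if (!inherits(tree, "phylo"))
    stop("'tree' must be an ape \"phylo\" object", call. = FALSE)
  labs <- tree$tip.label
  if (length(labs) < 2L)
    stop("tree must have at least 2 tips", call. = FALSE)
  if (anyNA(labs) || any(!nzchar(labs)))
    stop("tip labels must be non-empty", call. = FALSE)
  if (anyDuplicated(labs))
    stop("duplicate tip labels: ",
         paste(unique(labs[duplicated(labs)]), collapse = ", "),
         call. = FALSE)
  if (require_lengths) {
    if (is.null(tree$edge.length))
      stop("tree has no branch lengths; use set_unit_branch_lengths()",
           call. = FALSE)
    if (anyNA(tree$edge.length))
      stop("tree has missing branch lengths", call. = FALSE)
    if (any(tree$edge.length < 0))
      stop("tree has negative branch lengths", call. = FALSE)
  }
  invisible(tree)
}

# strict binarity: every internal node has exactly two children (ape's
# is.binary() would accept a basal trichotomy as binary-unrooted)
tree_is_binary <- function(tree) {
  n <- length(tree$tip.label)
  kids <- tabulate(tree$edge[, 1L], nbins = n + tree$Nnode)
  all(kids[(n + 1L):(n + tree$Nnode)] == 2L)
}

#' Parse a Newick string into a phylogeny
#'
#' Thin, validating wrapper around [ape::read.tree()]. Exactly one tree
#' is expected; quoted labels are supported and square-bracket comments
#' are ignored (standard Newick dialect). Branch lengths absent from the
#' string are left absent (`edge.length` is `NULL`), never silently set
#' to zero.
#'
#' @param text a Newick string (single tree, terminated by `;`).
#' @param file alternatively, path to a Newick file containing one tree.
#' @return an object of class `"phylo"`. Query binarity with
#'   [is_binary_tree()].
#' @examples
#' tr <- parse_newick("((A:1,B:1):1,C:2);")
#' is_binary_tree(tr)
#' @seealso [write_newick()], [resolve_polytomies()]
#' @export
parse_newick <- function(text = NULL, file = NULL) {
  if (is.null(text) == is.null(file))
    stop("supply exactly one of 'text' or 'file'")
  tr <- tryCatch(
    if (is.null(file)) ape::read.tree(text = text) else ape::read.tree(file),
    error = function(e) stop("malformed Newick: ", conditionMessage(e),
                             call. = FALSE),
    warning = function(w) stop("malformed Newick: ", conditionMessage(w),
                               call. = FALSE)
  )
  if (is.null(tr)) stop("malformed Newick: no tree could be read")
  if (inherits(tr, "multiPhylo")) {
    if (length(tr) != 1L) stop("expected a single tree, found ", length(tr))
    tr <- tr[[1L]]
  }
  validate_phylo(tr)
  tr
}

#' Write a phylogeny to Newick
#'
#' @param tree a `"phylo"` object.
#' @param file optional path; if omitted the Newick string is returned.
#' @return the Newick string, invisibly when written to a file.
#' @export
write_newick <- function(tree, file = NULL) {
  validate_phylo(tree)
  if (is.null(file)) return(ape::write.tree(tree))
  ape::write.tree(tree, file = file)
  invisible(ape::write.tree(tree))
}

#' Test whether every internal node of a tree is bifurcating
#'
#' @param tree a `"phylo"` object.
#' @return `TRUE` iff every internal node has exactly two children.
#' @export
is_binary_tree <- function(tree) {
  validate_phylo(tree)
  tree_is_binary(tree)
}

#' Set all branch lengths to one
#'
#' Replaces every branch length by 1, the convention used throughout the
#' analysis when divergence times are unknown: topology then carries all
#' of the phylogenetic structure. Idempotent; topology is untouched.
#'
#' @param tree a `"phylo"` object (branch lengths may be absent).
#' @return the tree with unit branch lengths.
#' @export
set_unit_branch_lengths <- function(tree) {
  validate_phylo(tree)
  tree$edge.length <- rep(1, nrow(tree$edge))
  tree
}

#' Randomly resolve polytomies into bifurcations
#'
#' Each multifurcation is broken into a uniform-random sequence of
#' bifurcations ([ape::multi2di()] with `random = TRUE`). Newly inserted
#' branches are given length 1, consistent with the unit-branch-length
#' convention and avoiding zero-variance contrasts downstream. Because
#' inserted branches are created with length zero, any zero-length branch
#' present after resolution is set to 1; genuinely zero-length input
#' branches are therefore also promoted (such branches are degenerate for
#' every analysis in this package).
#'
#' A binary input tree is returned unchanged. For a fixed `seed` the
#' resolution is deterministic.
#'
#' @param tree a `"phylo"` object.
#' @param seed integer seed controlling the random resolution order.
#' @return a binary `"phylo"` object with the same tip set.
#' @export
resolve_polytomies <- function(tree, seed = NULL) {
  validate_phylo(tree)
  if (tree_is_binary(tree)) return(tree)
  if (!is.null(seed)) set.seed(seed)
  out <- ape::multi2di(tree, random = TRUE)
  if (!is.null(out$edge.length))
    out$edge.length[out$edge.length == 0] <- 1
  out
}

#' Prune a tree to a set of taxa
#'
#' Returns the induced subtree on `taxa`: other tips are dropped and
#' resulting degree-2 internal nodes are collapsed with their branch
#' lengths summed ([ape::keep.tip()]).
#'
#' @param tree a `"phylo"` object.
#' @param taxa character vector of at least two tip labels to keep.
#' @return the induced subtree.
#' @export
prune_to_taxa <- function(tree, taxa) {
  validate_phylo(tree)
  taxa <- unique(as.character(taxa))
  unknown <- setdiff(taxa, tree$tip.label)
  if (length(unknown))
    stop("taxa not in tree: ", paste(unknown, collapse = ", "), call. = FALSE)
  if (length(taxa) < 2L)
    stop("need at least 2 taxa to prune to", call. = FALSE)
  ape::keep.tip(tree, taxa)
}
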