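## Phylogeny I/O and phylogenetic covariance structures.
##
## Trees are represented throughout as ape "phylo" objects: rooted, with
## branch lengths in arbitrary (typically expected-substitution) units.
## Trees are used exactly as given; no ultrametricisation is applied.

#' Read and validate a rooted phylogeny from a Newick file
#'
#' Wraps [ape::read.tree()] with the validation the comparative machinery in
#' this package relies on: unique non-empty tip labels, non-negative branch
#' lengths, a single tree per file. Unlabelled internal nodes and polytomies
#' are permitted. Gzip-compressed files are handled transparently.
#'
#' @param path path to a file containing one Newick string terminated by `;`.
#' @return an object of class `phylo`.
#' @export
read_newick <- function(path) {
  con <- open_input(path)
  on.exit(close(con))
  txt <- paste(readLines(con, warn = FALSE), collapse = "")
  tr <- tryCatch(ape::read.tree(text = txt),
                 error = function(e) stopf("Newick parse failure in '%s': %s",
                                           path, conditionMessage(e)))
  if (is.null(tr)) stopf("Newick parse failure in '%s': no tree found", path)
  if (inherits(tr, "multiPhylo")) {
    if (length(tr) != 1L) stopf("'%s': expected one tree, found %d", path, length(tr))
    tr <- tr[[1L]]
  }
  validate_tree(tr, where = path)
  tr
}

#' Write a phylogeny to a Newick file
#'
#' @param tree a `phylo` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Validate a phylogeny for comparative analysis
#'
#' @param tree a `phylo` object.
#' @param where label used in error messages (e.g. a file name).
#' @param require_lengths require branch lengths to be present.
#' @return `tree`, invisibly.
#' @export
validate_tree <- function(tree, where = "tree", require_lengths = FALSE) {
  if (!inherits(tree, "phylo")) stopf("%s: not a 'phylo' object", where)
  labs <- tree$tip.label
  if (length(labs) < 2L) stopf("%s: tree must have at least 2 tips", where)
  if (any(!nzchar(labs))) stopf("%s: empty tip label", where)
  dup <- labs[duplicated(labs)]
  if (length(dup) > 0L)
    stopf("%s: duplicate tip label(s): %s", where, paste(unique(dup), collapse = ", "))
  if (!is.null(tree$edge.length)) {
    if (anyNA(tree$edge.length)) stopf("%s: missing branch length", where)
    if (any(tree$edge.length < 0))
      stopf("%s: negative branch length (edge %d)", where,
            which(tree$edge.length < 0)[1L])
  } else if (require_lengths) {
    stopf("%s: branch lengths required but absent", where)
  }
  ## exactly one root: every other node has exactly one parent
  all_nodes <- seq_len(ape::Ntip(tree) + tree$Nnode)
  tab <- tabulate(tree$edge[, 2L], nbins = max(all_nodes))
  if (any(tab[all_nodes] > 1L)) stopf("%s: node with more than one parent", where)
  roots <- setdiff(all_nodes, tree$edge[, 2L])
  if (length(roots) != 1L) stopf("%s: tree must have exactly one root", where)
  invisible(tree)
}

#' Phylogenetic variance-covariance matrix of a tree
#'
#' Entry (i, j) is the sum of branch lengths on the path from the root to the
#' most recent common ancestor of tips i and j; the diagonal holds
#' root-to-tip path lengths. This is the Brownian-motion covariance structure
#' used by the regression models in this package.
#'
#' @param tree a `phylo` object with branch lengths.
#' @return a symmetric numeric matrix with tip labels as dimnames.
#' @export
vcv_from_tree <- function(tree) {
  validate_tree(tree, require_lengths = TRUE)
  ape::vcv.phylo(tree)
}

#' Pagel's lambda transform of a phylogenetic covariance matrix
#'
#' Multiplies off-diagonal entries by `lambda`, leaving the diagonal
#' unchanged: `lambda = 1` preserves full Brownian structure, `lambda = 0`
#' removes all phylogenetic covariance.
#'
#' @param V a symmetric covariance matrix (e.g. from [vcv_from_tree()]).
#' @param lambda scalar in `[0, 1]`.
#' @return the transformed matrix.
#' @export
lambda_transform <- function(V, lambda) {
  if (!is.numeric(lambda) || length(lambda) != 1L || is.na(lambda) ||
      lambda < 0 || lambda > 1)
    stopf("lambda must be a single value in [0, 1]")
  W <- V * lambda
  diag(W) <- diag(V)
  W
}

## Patristic (tip-to-tip path length) distance matrix.
patristic_distances <- function(tree) {
  stats::cophenetic(tree)
}

## Tree height: maximum root-to-tip path length.
tree_height <- function(tree) {
  max(diag(ape::vcv.phylo(tree)))
}
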