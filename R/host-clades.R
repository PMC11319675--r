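## Detection of maximal monophyletic host clades.
##
## A host clade is an internal node all of whose subtended tips are
## host-associated with one shared host category, and which is maximal: its
## parent also subtends tips of a different category or free-living tips.

#' Find maximal monophyletic host clades on a tree
#'
#' Scans all internal nodes and reports every maximal node with at least two
#' tips whose subtended tips all share a single host category. Reported
#' clades are disjoint, and singleton host tips are not reported.
#'
#' @param tree a `phylo` object.
#' @param labels named character vector mapping every tip label to a host
#'   category, or to `"free-living"` (or `NA`) for non-host tips.
#' @return a data.frame with columns `clade_root` (internal node number),
#'   `host_category`, `n_tips` and `member_tips` (list column of tip labels).
#' @export
find_host_clades <- function(tree, labels) {
  validate_tree(tree)
  tips <- tree$tip.label
  missing <- setdiff(tips, names(labels))
  if (length(missing) > 0L)
    stopf("tip(s) without host label: %s", paste(utils::head(missing, 5L), collapse = ", "))
  lab <- as.character(labels[tips])
  lab[is.na(lab)] <- "free-living"

  ntip <- ape::Ntip(tree)
  nnode <- tree$Nnode
  n_all <- ntip + nnode
  ## node category: tips carry their label ("free-living" treated as impure);
  ## an internal node is pure iff all children are pure with the same category.
  cat_of <- character(n_all)
  cat_of[seq_len(ntip)] <- ifelse(lab == "free-living", NA_character_, lab)
  is.na(cat_of) <- !nzchar(cat_of) | is.na(cat_of)

  ## postorder over edges guarantees children before parents; visit parents
  ## in their order of first appearance in the postorder edge list
  po <- ape::reorder.phylo(tree, "postorder")
  children <- split(po$edge[, 2L], factor(po$edge[, 1L],
                                          levels = unique(po$edge[, 1L])))
  for (node in as.integer(names(children))) {
    kid_cats <- cat_of[children[[as.character(node)]]]
    u <- unique(kid_cats)
    cat_of[node] <- if (length(u) == 1L && !is.na(u)) u else NA_character_
  }

  parent <- integer(n_all)
  parent[tree$edge[, 2L]] <- tree$edge[, 1L]
  root <- setdiff(unique(tree$edge[, 1L]), tree$edge[, 2L])

  internal <- (ntip + 1L):n_all
  pure <- internal[!is.na(cat_of[internal])]
  maximal <- pure[vapply(pure, function(nd) {
    nd == root || is.na(cat_of[parent[nd]]) || cat_of[parent[nd]] != cat_of[nd]
  }, logical(1L))]
  ## same-category parents are themselves pure, so "parent pure" can only mean
  ## same category; maximality therefore reduces to parent-impure-or-root.

  tip_sets <- lapply(maximal, function(nd) tips[tip_descendants(tree, nd)])
  keep <- lengths(tip_sets) >= 2L
  data.frame(
    clade_root = maximal[keep],
    host_category = cat_of[maximal[keep]],
    n_tips = lengths(tip_sets)[keep],
    member_tips = I(tip_sets[keep]),
    stringsAsFactors = FALSE
  )
}

## Tip indices descending from an internal node (or the tip itself).
tip_descendants <- function(tree, node) {
  ntip <- ape::Ntip(tree)
  if (node <= ntip) return(node)
  po <- ape::reorder.phylo(tree, "postorder")
  ## accumulate descendant tip sets bottom-up
  desc <- vector("list", ntip + tree$Nnode)
  for (i in seq_len(ntip)) desc[[i]] <- i
  for (k in seq_len(nrow(po$edge))) {
    p <- po$edge[k, 1L]; ch <- po$edge[k, 2L]
    desc[[p]] <- c(desc[[p]], desc[[ch]])
  }
  sort(desc[[node]])
}
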