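## Louvain community detection on weighted undirected graphs.
##
## Two-phase greedy modularity optimisation: local moves of single nodes to
## neighbouring communities until no move improves modularity, then
## aggregation of communities into super-nodes, repeated until the
## aggregated level admits no further gain. Modularity at resolution gamma:
##   Q = sum_c [ Sin_c / 2m  -  gamma * (Stot_c / 2m)^2 ]
## with Sin_c the sum of A_ij over ordered pairs within c, Stot_c the sum of
## weighted degrees in c, and 2m the total of all weighted degrees.

#' Louvain partition of a similarity graph
#'
#' @param graph a `similarity_graph` (see [build_similarity_graph()]), or any
#'   list with `nodes` and an `edges` data.frame (`from`, `to`, `weight`).
#' @param resolution resolution parameter gamma scaling the degree term
#'   (default 1, plain modularity).
#' @param seed integer seed for the node-visit order (sorted ids shuffled by
#'   a seeded RNG); identical inputs and seed give identical partitions.
#' @return list of class `louvain_partition`: `membership` (named integer
#'   vector, node -> community id numbered consecutively from 1 in order of
#'   first appearance among sorted node ids), `modularity` (final Q),
#'   `n_communities`.
#' @export
louvain_partition <- function(graph, resolution = 1, seed = 1L) {
  nodes <- as.character(graph$nodes)
  n <- length(nodes)
  if (n == 0L)
    return(structure(list(membership = stats::setNames(integer(0), character(0)),
                          modularity = NaN, n_communities = 0L),
                     class = "louvain_partition"))
  edges <- graph$edges
  if (nrow(edges) > 0L) {
    ei <- match(as.character(edges$from), nodes)
    ej <- match(as.character(edges$to), nodes)
    if (anyNA(ei) || anyNA(ej)) stopf("edge endpoint not among nodes")
    if (any(ei == ej)) stopf("self-loops are not allowed in the input graph")
    ew <- as.numeric(edges$weight)
    if (any(ew <= 0)) stopf("edge weights must be positive")
  } else {
    ei <- ej <- integer(0); ew <- numeric(0)
  }

  old_seed <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(as.integer(seed))

  ## current level: nodes 1..nc with symmetric A (i, j, w both directions)
  ## and self-weights (ordered-pair diagonal contributions)
  level_nodes <- seq_len(n)
  member_of <- seq_len(n)       # original node -> current-level node
  li <- c(ei, ej); lj <- c(ej, ei); lw <- c(ew, ew)
  self_w <- numeric(n)

  repeat {
    nc <- length(level_nodes)
    deg <- self_w
    if (length(li) > 0L) {
      ds <- rowsum(lw, li)
      deg[as.integer(rownames(ds))] <- deg[as.integer(rownames(ds))] + ds[, 1L]
    }
    two_m <- sum(deg)
    comm <- seq_len(nc)
    stot <- deg
    if (two_m == 0) break

    nbr_idx <- split(seq_along(li), li)
    improved_level <- FALSE
    repeat {
      moved <- FALSE
      order_ids <- sample(nc)
      for (v in order_ids) {
        idx <- nbr_idx[[as.character(v)]]
        if (is.null(idx)) next
        c0 <- comm[v]
        ## weights from v to each neighbouring community
        l_vc <- rowsum(lw[idx], comm[lj[idx]])
        cand <- as.integer(rownames(l_vc))
        stot[c0] <- stot[c0] - deg[v]
        gain <- l_vc[, 1L] - resolution * stot[cand] * deg[v] / two_m
        gain0 <- (if (c0 %in% cand) l_vc[match(c0, cand), 1L] else 0) -
          resolution * stot[c0] * deg[v] / two_m
        best <- which.max(gain)
        if (gain[best] > gain0 + 1e-12 && cand[best] != c0) {
          comm[v] <- cand[best]
          moved <- TRUE
          improved_level <- TRUE
        }
        stot[comm[v]] <- stot[comm[v]] + deg[v]
      }
      if (!moved) break
    }
    if (!improved_level) break

    ## renumber communities and aggregate
    keep <- sort(unique(comm))
    remap <- integer(nc); remap[keep] <- seq_along(keep)
    comm <- remap[comm]
    member_of <- comm[member_of]
    ## aggregated self-weights: internal ordered-pair sums
    new_self <- numeric(length(keep))
    sw <- rowsum(self_w, comm)
    new_self[as.integer(rownames(sw))] <- sw[, 1L]
    if (length(li) > 0L) {
      ci <- comm[li]; cj <- comm[lj]
      internal <- ci == cj
      if (any(internal)) {
        isum <- rowsum(lw[internal], ci[internal])
        new_self[as.integer(rownames(isum))] <-
          new_self[as.integer(rownames(isum))] + isum[, 1L]
      }
      ext <- !internal
      if (any(ext)) {
        key <- paste(ci[ext], cj[ext])
        agg <- rowsum(lw[ext], key)
        parts <- strsplit(rownames(agg), " ", fixed = TRUE)
        li <- vapply(parts, function(p) as.integer(p[1L]), 0L)
        lj <- vapply(parts, function(p) as.integer(p[2L]), 0L)
        lw <- agg[, 1L]
      } else {
        li <- lj <- integer(0); lw <- numeric(0)
      }
    }
    self_w <- new_self
    level_nodes <- seq_along(keep)
    if (length(level_nodes) == 1L) break
  }

  ## deterministic community ids: order of first appearance over sorted nodes
  ord <- order(nodes)
  first_seen <- unique(member_of[ord])
  remap <- integer(max(member_of)); remap[first_seen] <- seq_along(first_seen)
  membership <- stats::setNames(remap[member_of], nodes)
  q <- modularity_q(graph, membership, resolution = resolution)
  structure(list(membership = membership, modularity = q,
                 n_communities = length(first_seen)),
            class = "louvain_partition")
}

#' Modularity of a partition of a weighted graph
#'
#' Direct recomputation of `Q = sum_c [Sin_c/2m - gamma (Stot_c/2m)^2]` from
#' the edge list; used both for reporting and as an internal consistency
#' check on [louvain_partition()].
#'
#' @param graph a `similarity_graph`-style list.
#' @param membership named community vector over `graph$nodes`.
#' @param resolution resolution parameter gamma.
#' @return the modularity Q (NaN for an edgeless graph).
#' @export
modularity_q <- function(graph, membership, resolution = 1) {
  nodes <- as.character(graph$nodes)
  edges <- graph$edges
  if (nrow(edges) == 0L) return(NaN)
  comm <- membership[nodes]
  ci <- comm[as.character(edges$from)]
  cj <- comm[as.character(edges$to)]
  w <- as.numeric(edges$weight)
  m <- sum(w)
  deg <- numeric(length(nodes))
  names(deg) <- nodes
  dsum <- rowsum(c(w, w), c(as.character(edges$from), as.character(edges$to)))
  deg[rownames(dsum)] <- dsum[, 1L]
  sin_c <- tapply(2 * w * (ci == cj), factor(ci, levels = unique(comm)), sum)
  sin_c[is.na(sin_c)] <- 0
  stot_c <- tapply(deg, factor(comm, levels = unique(comm)), sum)
  sum(sin_c / (2 * m) - resolution * (stot_c / (2 * m))^2)
}

#' @export
print.louvain_partition <- function(x, ...) {
  cat(sprintf("Louvain partition: %d nodes, %d communities, Q = %.4f\n",
              length(x$membership), x$n_communities, x$modularity))
  invisible(x)
}
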