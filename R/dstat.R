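## Fritz-Purvis D-statistic: phylogenetic signal for binary traits.
##
## Nodal values are estimated tips-to-root with each internal node set to
## the arithmetic mean of its children's values; the observed quantity
## d_obs is the total absolute difference contributed at each node,
## sum over internal nodes of sum_children |child - node mean| (for a
## bifurcation this equals |v_left - v_right|). d_obs is scaled between the
## mean d under random tip shuffles (expectation of D = 1, no signal) and
## the mean d under Brownian-threshold simulations at the observed
## prevalence (expectation of D = 0, Brownian clumping).

## Precomputed traversal structure reused across null replicates.
tree_index <- function(tree) {
  validate_tree(tree)
  po <- ape::reorder.phylo(tree, "postorder")
  ntip <- ape::Ntip(tree)
  list(ntip = ntip,
       n_all = ntip + tree$Nnode,
       parent = po$edge[, 1L],
       child = po$edge[, 2L],
       edge_length = po$edge.length %||% rep(1, nrow(po$edge)),
       tip_labels = tree$tip.label)
}

sum_sister_differences_idx <- function(idx, y_tips) {
  val <- numeric(idx$n_all)
  cnt <- numeric(idx$n_all)
  val[seq_len(idx$ntip)] <- y_tips
  cnt[seq_len(idx$ntip)] <- 1
  ## first pass: accumulate children sums (postorder guarantees children done)
  sums <- numeric(idx$n_all)
  ns <- numeric(idx$n_all)
  for (k in seq_along(idx$parent)) {
    p <- idx$parent[k]; ch <- idx$child[k]
    if (ns[ch] > 0) val[ch] <- sums[ch] / ns[ch]
    sums[p] <- sums[p] + val[ch]
    ns[p] <- ns[p] + 1
  }
  root <- idx$parent[length(idx$parent)]
  val[root] <- sums[root] / ns[root]
  ## second pass: absolute differences child vs parent's nodal mean
  d <- 0
  for (k in seq_along(idx$parent)) {
    p <- idx$parent[k]; ch <- idx$child[k]
    v_ch <- if (ns[ch] > 0) sums[ch] / ns[ch] else val[ch]
    d <- d + abs(v_ch - sums[p] / ns[p])
  }
  d
}

#' Sum of sister-clade differences for a binary trait
#'
#' @param tree a `phylo` object (bifurcating or with polytomies).
#' @param y binary 0/1 values, named by tip label or given in tip order.
#' @return the unscaled d value.
#' @export
sum_sister_differences <- function(tree, y) {
  idx <- tree_index(tree)
  y <- tip_values(y, idx$tip_labels)
  sum_sister_differences_idx(idx, y)
}

tip_values <- function(y, tips) {
  if (!is.null(names(y))) {
    missing <- setdiff(tips, names(y))
    if (length(missing) > 0L)
      stopf("missing tip value(s): %s", paste(utils::head(missing, 5L), collapse = ", "))
    y <- y[tips]
  } else if (length(y) != length(tips)) {
    stopf("trait vector length does not match number of tips")
  }
  y <- as.numeric(y)
  if (anyNA(y) || !all(y %in% c(0, 1))) stopf("trait values must be 0/1")
  y
}

#' Simulate a binary trait by thresholding Brownian motion on a tree
#'
#' Brownian motion is run from a root value of 0 with variance proportional
#' to branch length; continuous tip values are thresholded at the empirical
#' quantile so that exactly `round(prevalence * n)` tips score 1. Zero-length
#' branches add no variance.
#'
#' @param tree a `phylo` object with branch lengths.
#' @param prevalence target trait frequency, strictly between 0 and 1.
#' @param seed optional integer seed.
#' @return named 0/1 vector over the tips.
#' @export
simulate_brownian_threshold <- function(tree, prevalence, seed = NULL) {
  if (prevalence <= 0 || prevalence >= 1)
    stopf("prevalence must lie strictly between 0 and 1")
  if (!is.null(seed)) set.seed(as.integer(seed))
  x <- brownian_tips(tree)
  n <- length(x)
  k <- round(prevalence * n)
  k <- min(max(k, 1L), n - 1L)  # keep both states present
  out <- as.numeric(rank(x, ties.method = "first") > n - k)
  names(out) <- tree$tip.label
  out
}

brownian_tips <- function(tree) {
  pre <- ape::reorder.phylo(tree, "cladewise")
  n_all <- ape::Ntip(tree) + tree$Nnode
  x <- numeric(n_all)
  eps <- stats::rnorm(nrow(pre$edge), sd = sqrt(pre$edge.length))
  for (k in seq_len(nrow(pre$edge))) {
    x[pre$edge[k, 2L]] <- x[pre$edge[k, 1L]] + eps[k]
  }
  x[seq_len(ape::Ntip(tree))]
}

#' Fritz-Purvis D-statistic for a binary trait on a phylogeny
#'
#' Computes the observed sum of sister-clade differences and scales it
#' between its expectations under `n_null` random tip shuffles (D = 1) and
#' `n_null` Brownian-threshold simulations at the observed prevalence
#' (D = 0). `p_random` is the fraction of shuffled d values at or below the
#' observed d (evidence of phylogenetic clumping); `p_brownian` the fraction
#' of Brownian d values at or above it.
#'
#' @param tree a `phylo` object with branch lengths.
#' @param y binary trait (both states present), named by tip or in tip order.
#' @param n_null number of null replicates for each null set (default 1000).
#' @param seed integer seed; results are reproducible bit-for-bit.
#' @param trait_id optional label carried into the result.
#' @return an object of class `phylo_d` with fields `d_obs`,
#'   `d_random_mean`, `d_brownian_mean`, `D`, `p_random`, `p_brownian`,
#'   `n_null`, `seed`, `prevalence`.
#' @export
d_statistic <- function(tree, y, n_null = 1000L, seed = 1L, trait_id = NA_character_) {
  if (n_null < 100L) stopf("n_null must be at least 100")
  idx <- tree_index(tree)
  y <- tip_values(y, idx$tip_labels)
  if (length(unique(y)) < 2L) stopf("trait must have both states")
  n <- length(y)
  prevalence <- mean(y)
  d_obs <- sum_sister_differences_idx(idx, y)

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(as.integer(seed))
  d_rand <- vapply(seq_len(n_null), function(i)
    sum_sister_differences_idx(idx, sample(y)), 0)
  d_brown <- vapply(seq_len(n_null), function(i) {
    x <- brownian_tips(tree)
    k <- round(prevalence * n); k <- min(max(k, 1L), n - 1L)
    sum_sister_differences_idx(idx, as.numeric(rank(x, ties.method = "first") > n - k))
  }, 0)
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())

  D <- (d_obs - mean(d_brown)) / (mean(d_rand) - mean(d_brown))
  structure(list(
    trait_id = trait_id,
    d_obs = d_obs,
    d_random_mean = mean(d_rand),
    d_brownian_mean = mean(d_brown),
    D = D,
    p_random = mean(d_rand <= d_obs),
    p_brownian = mean(d_brown >= d_obs),
    n_null = as.integer(n_null),
    seed = as.integer(seed),
    prevalence = prevalence,
    n = n
  ), class = "phylo_d")
}

#' @export
print.phylo_d <- function(x, ...) {
  cat("Fritz-Purvis D-statistic\n")
  if (!is.na(x$trait_id)) cat(sprintf("  trait: %s\n", x$trait_id))
  cat(sprintf("  d_obs = %.4f (random mean %.4f, Brownian mean %.4f)\n",
              x$d_obs, x$d_random_mean, x$d_brownian_mean))
  cat(sprintf("  D = %.4f; p_random = %.4g; p_brownian = %.4g (n_null = %d)\n",
              x$D, x$p_random, x$p_brownian, x$n_null))
  invisible(x)
}

#' D-statistic scan over a binary trait matrix
#'
#' @param tm binary genome x trait matrix.
#' @param tree phylogeny covering the genomes.
#' @param n_null null replicates per trait.
#' @param seed global seed; per-trait seeds are derived from it.
#' @param alpha_level significance level applied to `p_random`.
#' @return data.frame: trait_id, d_obs, D, p_random, p_brownian, n_null,
#'   seed, significant.
#' @export
d_statistic_scan <- function(tm, tree, n_null = 1000L, seed = 1L,
                             alpha_level = 0.05) {
  rows <- lapply(colnames(tm), function(trait_id) {
    yv <- stats::setNames(tm[, trait_id], rownames(tm))
    res <- tryCatch(
      d_statistic(tree, yv, n_null = n_null,
                  seed = derive_seed(seed, trait_id), trait_id = trait_id),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      return(data.frame(trait_id = trait_id, d_obs = NA_real_, D = NA_real_,
                        p_random = NA_real_, p_brownian = NA_real_,
                        n_null = as.integer(n_null), seed = NA_integer_,
                        significant = NA, note = conditionMessage(res),
                        stringsAsFactors = FALSE))
    }
    data.frame(trait_id = trait_id, d_obs = res$d_obs, D = res$D,
               p_random = res$p_random, p_brownian = res$p_brownian,
               n_null = res$n_null, seed = res$seed,
               significant = res$p_random < alpha_level, note = "",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
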