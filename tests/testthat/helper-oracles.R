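# Independent oracles and fixture builders used across the test files.
# Each oracle deliberately takes a different computational route than the
# implementation it checks.

# Plain Firth-penalised logistic regression by direct numerical optimisation
# of the penalised log-likelihood (no score equations, no tree).
firth_logistic_oracle <- function(y, X) {
  objective <- function(b) {
    eta <- drop(X %*% b)
    p <- plogis(eta)
    ll <- sum(y * eta - log1p(exp(eta)))
    W <- p * (1 - p)
    ll + 0.5 * determinant(crossprod(X * W, X) / 1, logarithm = TRUE)$modulus
  }
  ## note: penalty uses X' W X with W = p(1-p), the logistic Fisher information
  opt <- optim(rep(0, ncol(X)), function(b) -objective(b), method = "BFGS",
               control = list(reltol = 1e-15, maxit = 2000))
  opt$par
}

# Dice coefficient by explicit element counting.
dice_oracle <- function(a, b) {
  a <- unique(a); b <- unique(b)
  inter <- sum(vapply(a, function(x) any(b == x), logical(1)))
  2 * inter / (length(a) + length(b))
}

# Phylogenetic covariance by per-pair MRCA path sums along node paths.
vcv_oracle <- function(tree) {
  n <- ape::Ntip(tree)
  root <- n + 1L
  parent <- integer(max(tree$edge))
  elen <- numeric(max(tree$edge))
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  elen[tree$edge[, 2]] <- tree$edge.length
  path_to_root <- function(node) {
    out <- integer(0)
    while (node != root) { out <- c(out, node); node <- parent[node] }
    out
  }
  V <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  paths <- lapply(seq_len(n), path_to_root)
  for (i in seq_len(n)) {
    for (j in i:n) {
      shared <- intersect(paths[[i]], paths[[j]])
      V[i, j] <- V[j, i] <- sum(elen[shared])
    }
  }
  V
}

# All set partitions of n items as restricted-growth membership vectors.
enumerate_partitions <- function(n) {
  out <- list()
  recurse <- function(assign, k) {
    i <- length(assign) + 1L
    if (i > n) { out[[length(out) + 1L]] <<- assign; return(invisible()) }
    for (c in seq_len(k + 1L)) recurse(c(assign, c), max(k, c))
  }
  recurse(integer(0), 0L)
  out
}

# Exhaustive maximum modularity over all partitions of a small graph.
exhaustive_max_modularity <- function(graph, resolution = 1) {
  n <- length(graph$nodes)
  stopifnot(n <= 8)
  parts <- enumerate_partitions(n)
  qs <- vapply(parts, function(p) {
    modularity_q(graph, setNames(p, graph$nodes), resolution = resolution)
  }, numeric(1))
  list(q_max = max(qs), partition = parts[[which.max(qs)]])
}

# Planted two-block weighted graph with weak inter-block edges.
make_two_block_graph <- function(n, seed) {
  set.seed(seed)
  block <- rep(1:2, length.out = n)
  nodes <- sprintf("n%02d", seq_len(n))
  from <- to <- character(0); w <- numeric(0)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    if (block[i] == block[j]) {
      if (runif(1) < 0.9) { from <- c(from, nodes[i]); to <- c(to, nodes[j]); w <- c(w, 1) }
    } else if (runif(1) < 0.3) {
      from <- c(from, nodes[i]); to <- c(to, nodes[j]); w <- c(w, 0.05)
    }
  }
  list(nodes = nodes,
       edges = data.frame(from = from, to = to, weight = w,
                          stringsAsFactors = FALSE),
       block = setNames(block, nodes))
}

# Step-expression evaluator by string substitution (definitions built
# without top-level parentheses spanning whitespace).
eval_defn_oracle <- function(expr, kos) {
  steps <- strsplit(trimws(expr), "\\s+")[[1]]
  sat <- vapply(steps, function(s) {
    s <- gsub("(K[0-9]{5})", "`\\1`", s)
    s <- gsub(",", "|", s, fixed = TRUE)
    s <- gsub("+", "&", s, fixed = TRUE)
    env <- new.env()
    for (k in unique(regmatches(expr, gregexpr("K[0-9]{5}", expr))[[1]]))
      assign(k, k %in% kos, envir = env)
    isTRUE(eval(parse(text = s), envir = env))
  }, logical(1))
  mean(sat)
}

# Random KO-definition expression over a small KO universe.
random_definition <- function(n_steps, ko_pool) {
  steps <- vapply(seq_len(n_steps), function(s) {
    k <- sample(1:4, 1)
    kos <- sample(ko_pool, k)
    if (k == 1) return(kos)
    op <- sample(c(",", "+"), 1)
    if (k >= 3 && runif(1) < 0.5) {
      paste0("(", paste(kos[1:2], collapse = ","), ")+",
             paste(kos[-(1:2)], collapse = "+"))
    } else {
      paste(kos, collapse = op)
    }
  }, character(1))
  paste(steps, collapse = " ")
}

# Small labelled tree helper.
make_star_tree <- function(n, bl = 1) {
  tr <- ape::stree(n, "star")
  tr$edge.length <- rep(bl, nrow(tr$edge))
  tr$tip.label <- sprintf("t%03d", seq_len(n))
  tr
}

minimal_bgc_records <- function(ids, domains, classes = "terpene",
                                sources = "sanntis", genome = "g1",
                                start = 10, len = 5000) {
  n <- length(ids)
  data.frame(
    bgc_id = ids, genome_id = rep_len(genome, n),
    contig_id = "c1",
    start = rep_len(start, n),
    end = rep_len(start, n) + rep_len(len, n) - 1,
    strand = "+",
    predicted_class = rep_len(classes, n),
    domains = vapply(domains, paste, "", collapse = ";"),
    source = rep_len(sources, n),
    stringsAsFactors = FALSE
  )
}
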