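test_that("sister-clade difference sums match hand recursion", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  expect_equal(sum_sister_differences(tr, c(A = 1, B = 1, C = 0, D = 0)), 1)
  expect_equal(sum_sister_differences(tr, c(A = 1, B = 0, C = 1, D = 0)), 2)
  expect_equal(sum_sister_differences(tr, c(A = 1, B = 1, C = 1, D = 1)), 0)
  ## polytomy: |child - mean| summed over all children
  poly <- ape::read.tree(text = "(A:1,B:1,C:1);")
  ## mean = 1/3; contributions 2/3 + 1/3 + 1/3 = 4/3
  expect_equal(sum_sister_differences(poly, c(A = 1, B = 0, C = 0)), 4 / 3)
  expect_error(sum_sister_differences(tr, c(A = 1, B = 0, C = 1)), "missing tip")
})

test_that("d is invariant to child swaps and to trait complementation", {
  set.seed(23)
  for (rep in 1:10) {
    tr <- ape::rtree(16)
    y <- setNames(rbinom(16, 1, 0.4), tr$tip.label)
    if (length(unique(y)) < 2) next
    d <- sum_sister_differences(tr, y)
    expect_equal(sum_sister_differences(tr, 1 - y), d)
    rot <- ape::ladderize(tr)  # reorders children at every node
    expect_equal(sum_sister_differences(rot, y), d)
  }
})

test_that("Brownian-threshold simulation hits the target prevalence exactly", {
  set.seed(2)
  tr <- ape::rphylo(40, 1, 0)
  for (prev in c(0.1, 0.3, 0.5, 0.87)) {
    y <- simulate_brownian_threshold(tr, prev, seed = 11)
    expect_equal(sum(y), round(prev * 40))
    expect_named(y)
  }
  expect_error(simulate_brownian_threshold(tr, 0), "prevalence")
  expect_error(simulate_brownian_threshold(tr, 1), "prevalence")

  ## two clades joined by long stem branches: 1s concentrate in one clade
  stem <- ape::read.tree(text = paste0(
    "((", paste(sprintf("a%d:0.1", 1:8), collapse = ","), "):10,",
    "(", paste(sprintf("b%d:0.1", 1:8), collapse = ","), "):10);"))
  conc <- replicate(40, {
    y <- simulate_brownian_threshold(stem, 0.5)
    n_a <- sum(y[sprintf("a%d", 1:8)])
    max(n_a, 8 - n_a) >= 7  # >= ~80% of the 1s within one clade
  })
  expect_gt(mean(conc), 0.5)
})

test_that("d_statistic is reproducible, complete and detects clumped traits", {
  set.seed(3)
  tr <- ape::rphylo(64, 1, 0)
  ## perfectly clumped: all 1s within one medium-sized clade
  ntip <- ape::Ntip(tr)
  clade_sizes <- vapply((ntip + 1):(ntip + tr$Nnode), function(nd)
    length(ape::extract.clade(tr, nd)$tip.label), 0L)
  node <- ((ntip + 1):(ntip + tr$Nnode))[which.min(abs(clade_sizes - 16))]
  clade_tips <- ape::extract.clade(tr, node)$tip.label
  y <- setNames(as.numeric(tr$tip.label %in% clade_tips), tr$tip.label)
  res <- d_statistic(tr, y, n_null = 200, seed = 5)
  expect_lt(res$D, 0.5)
  expect_lt(res$p_random, 0.05)
  expect_equal(res$n_null, 200L)
  expect_equal(res$prevalence, mean(y))
  ## D recomputes exactly from its components
  expect_equal(res$D, (res$d_obs - res$d_brownian_mean) /
                 (res$d_random_mean - res$d_brownian_mean))
  ## bit-reproducible under the seed, and complementation-invariant d_obs
  res2 <- d_statistic(tr, y, n_null = 200, seed = 5)
  expect_identical(res, res2)
  expect_equal(d_statistic(tr, 1 - y, n_null = 100, seed = 5)$d_obs, res$d_obs)
  expect_output(print(res), "Fritz-Purvis")
  expect_error(d_statistic(tr, setNames(rep(1, 64), tr$tip.label)), "both states")
  expect_error(d_statistic(tr, y, n_null = 10), "at least 100")
})

test_that("d_statistic_scan reports one calibrated row per trait", {
  set.seed(44)
  tr <- ape::rphylo(40, 1, 0)
  tm <- cbind(clumped = as.numeric(seq_len(40) %in% 1:10),
              random = rbinom(40, 1, 0.4))
  rownames(tm) <- tr$tip.label
  scan <- d_statistic_scan(tm, tr, n_null = 150, seed = 6)
  expect_equal(scan$trait_id, c("clumped", "random"))
  expect_true(all(scan$p_random >= 0 & scan$p_random <= 1))
  expect_true(all(scan$p_brownian >= 0 & scan$p_brownian <= 1))
  ## derived per-trait seeds make rows independent of scan order
  scan_rev <- d_statistic_scan(tm[, 2:1], tr, n_null = 150, seed = 6)
  expect_equal(scan[scan$trait_id == "random", ],
               scan_rev[scan_rev$trait_id == "random", ],
               ignore_attr = TRUE)
})
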