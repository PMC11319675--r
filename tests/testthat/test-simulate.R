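small_config <- function(seed = 1L, ...) {
  simulation_config(n_tips = 60L, n_host_clades = 3L, n_functions = 6L,
                    n_archetypes = 6L, count_shift = 0.4,
                    planted_group_prevalence = c(0.1, 0.6), seed = seed, ...)
}

test_that("Yule tree simulation is deterministic with exact tip counts", {
  tr <- simulate_tree(2, seed = 1)
  expect_equal(ape::Ntip(tr), 2)
  tr2 <- simulate_tree(25, seed = 9)
  expect_equal(ape::Ntip(tr2), 25)
  expect_equal(tr2$tip.label[1], "g0001")
  expect_true(all(tr2$edge.length > 0))
  expect_identical(ape::write.tree(simulate_tree(25, seed = 9)),
                   ape::write.tree(tr2))
  expect_false(identical(ape::write.tree(simulate_tree(25, seed = 10)),
                         ape::write.tree(tr2)))
  expect_error(simulate_tree(1), "at least 2")
})

test_that("planted host clades are recovered exactly by find_host_clades", {
  for (seed in 1:5) {
    tr <- simulate_tree(80, seed = seed)
    labels <- plant_host_clades(tr, 4, c("lichen", "cycad", "diatom", "azolla"),
                                seed = seed)
    planted <- attr(labels, "clades")
    expect_equal(nrow(planted), 4)
    found <- find_host_clades(tr, labels)
    expect_equal(nrow(found), 4)
    key <- function(df) {
      sets <- lapply(df$member_tips, sort)
      ord <- order(vapply(sets, paste, "", collapse = ","))
      paste(df$host_category[ord], vapply(sets[ord], paste, "", collapse = ","))
    }
    expect_equal(key(found), key(planted))
  }
  labels0 <- plant_host_clades(simulate_tree(20, seed = 2), 0, "lichen")
  expect_true(all(labels0 == "free-living"))
})

test_that("KO simulation plants a recoverable logistic lifestyle effect", {
  cfg <- small_config(seed = 3)
  tr <- simulate_tree(cfg$n_tips, seed = 3)
  labels <- plant_host_clades(tr, cfg$n_host_clades, cfg$host_categories, seed = 3)
  ko <- simulate_ko_table(tr, labels, cfg)
  host <- labels != "free-living"
  expect_equal(ko$effects$beta1[1], qlogis(0.9) - qlogis(0.1))
  expect_true(all(ko$effects$beta1[-1] == 0))

  ## truth table matches the analysis route exactly (noiseless construction)
  cm <- completeness_matrix(ko$kos_by_genome[tr$tip.label], ko$definitions)
  tm <- classify_traits(cm, 0.98)
  expect_equal(unname(tm), unname(ko$truth))

  ## the planted function is more prevalent in host-associated genomes
  f1 <- ko$truth[, 1]
  expect_gt(mean(f1[host]), mean(f1[!host]))
})

test_that("null traits stay balanced and strong effects are directionally consistent", {
  diffs <- numeric(10)
  for (r in 1:10) {
    cfg <- simulation_config(n_tips = 200L, n_host_clades = 6L, n_functions = 3L,
                             n_archetypes = 4L, count_shift = 0.2,
                             planted_group_prevalence = c(0.1, 0.4), seed = r)
    tr <- simulate_tree(cfg$n_tips, seed = r)
    labels <- plant_host_clades(tr, 6, cfg$host_categories, seed = r)
    ko <- simulate_ko_table(tr, labels, cfg)
    host <- labels != "free-living"
    ## a null function (beta1 = 0): prevalence difference concentrates near 0
    diffs[r] <- mean(ko$truth[host, 2]) - mean(ko$truth[!host, 2])
    ## the planted function is enriched in every replicate
    expect_gt(mean(ko$truth[host, 1]), mean(ko$truth[!host, 1]))
  }
  expect_lt(abs(mean(diffs)), 0.1)
})

test_that("BGC simulation plants separable groups, decoys and a count shift", {
  cfg <- small_config(seed = 5)
  tr <- simulate_tree(cfg$n_tips, seed = 5)
  labels <- plant_host_clades(tr, cfg$n_host_clades, cfg$host_categories, seed = 5)
  bgc <- simulate_bgc_records(tr, labels, cfg)

  ## archetype Dice separability below the edge threshold
  doms <- bgc$archetypes$domains
  for (i in 1:(length(doms) - 1)) for (j in (i + 1):length(doms))
    expect_lt(dice_similarity(doms[[i]], doms[[j]]), cfg$edge_threshold)

  ## decoys are exactly the records the filter removes
  filtered <- filter_bgcs(bgc$records, 3000, bgc$contig_lengths)
  decoy_ids <- bgc$truth$bgc_id[bgc$truth$decoy != "none"]
  expect_setequal(setdiff(bgc$records$bgc_id, filtered$bgc_id), decoy_ids)

  ## expected host total is shifted down by count_shift
  with_arch <- bgc$archetypes
  expect_equal(sum(with_arch$prevalence_free) - sum(with_arch$prevalence_host),
               cfg$count_shift)
  expect_true(all(with_arch$prevalence_host >= 0 & with_arch$prevalence_host <= 1))
})

test_that("fixture bundles are byte-identical under a seed and reload cleanly", {
  cfg <- small_config(seed = 8)
  study <- simulate_study(cfg)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_fixture_bundle(study, d1)
  write_fixture_bundle(simulate_study(small_config(seed = 8)), d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
  inputs <- read_study_inputs(d1)
  expect_s3_class(inputs$tree, "phylo")
  expect_equal(sort(inputs$metadata$genome_id), sort(study$tree$tip.label))
  expect_equal(length(inputs$definitions), cfg$n_functions)
  expect_equal(nrow(inputs$bgc_records), nrow(study$bgc$records))
  ## truth files join 1:1 with generated entities
  truth <- read_results_table(file.path(d1, "truth_bgc_groups.tsv"))
  expect_setequal(truth$bgc_id, study$bgc$records$bgc_id)
})
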