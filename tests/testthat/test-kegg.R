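test_that("definition grammar parses AND/OR/parentheses and rejects malformed input", {
  d <- parse_function_definition("K02586+K02591 K02588", "f1")
  expect_length(d$steps, 2)
  expect_equal(compute_completeness(d, c("K02586", "K02588")), 0.5)  # AND unmet
  expect_equal(compute_completeness(d, c("K02586", "K02591", "K02588")), 1)

  d2 <- parse_function_definition("K00531,K22899", "f2")
  expect_length(d2$steps, 1)
  expect_equal(compute_completeness(d2, "K22899"), 1)
  expect_equal(compute_completeness(d2, "K00531"), 1)
  expect_equal(compute_completeness(d2, character(0)), 0)

  ## precedence: '+' binds tighter than ','
  d3 <- parse_function_definition("K00001,K00002+K00003", "f3")
  expect_equal(compute_completeness(d3, "K00001"), 1)
  expect_equal(compute_completeness(d3, "K00002"), 0)
  d4 <- parse_function_definition("(K00001,K00002)+K00003", "f4")
  expect_equal(compute_completeness(d4, "K00001"), 0)
  expect_equal(compute_completeness(d4, c("K00002", "K00003")), 1)

  expect_error(parse_function_definition("K00001+", "bad"), "dangling")
  expect_error(parse_function_definition("K00001,,K00002", "bad"), "bad")
  expect_error(parse_function_definition("(K00001 K00002", "bad"), "unbalanced")
  expect_error(parse_function_definition("K1", "bad"), "malformed")
})

test_that("completeness is the step fraction and matches hand evaluation", {
  d <- parse_function_definition("K00001 K00002 K00003 K00004", "f")
  expect_equal(compute_completeness(d, c("K00001", "K00002", "K00003", "K00004")), 1)
  expect_equal(compute_completeness(d, c("K00001", "K00003")), 0.5)
  expect_equal(compute_completeness(d, character(0)), 0)
})

test_that("compute_completeness agrees with a brute-force expression evaluator", {
  set.seed(17)
  ko_pool <- sprintf("K%05d", 1:12)
  for (rep in 1:50) {
    expr <- random_definition(sample(1:5, 1), ko_pool)
    d <- parse_function_definition(expr, "rand")
    kos <- sample(ko_pool, sample(0:8, 1))
    expect_equal(compute_completeness(d, kos), eval_defn_oracle(expr, kos),
                 info = expr)
  }
})

test_that("adding KOs never decreases completeness or trait bits (monotonicity)", {
  set.seed(31)
  ko_pool <- sprintf("K%05d", 1:10)
  for (rep in 1:20) {
    d <- parse_function_definition(random_definition(sample(2:5, 1), ko_pool), "m")
    base <- sample(ko_pool, sample(0:5, 1))
    more <- union(base, sample(ko_pool, sample(1:5, 1)))
    expect_gte(compute_completeness(d, more), compute_completeness(d, base))
  }
})

test_that("trait classification is strict at the threshold and nested across presets", {
  cm <- matrix(c(1.00, 0.98, 0.60, 0.50, 0.99, 0.51), nrow = 2,
               dimnames = list(c("g1", "g2"), c("a", "b", "c")))
  tm98 <- classify_traits(cm, 0.98)
  expect_equal(unname(tm98["g1", "a"]), 1L)   # 1.00 > 0.98
  expect_equal(unname(tm98["g2", "a"]), 0L)   # 0.98 not > 0.98 (strict)
  tm50 <- classify_traits(cm, 0.50)
  expect_equal(unname(tm50["g1", "b"]), 1L)   # 0.60 > 0.50
  expect_equal(unname(tm50["g2", "b"]), 0L)   # 0.50 not > 0.50
  ## complete implies indicative, column-wise
  expect_true(all(tm50[tm98 == 1L] == 1L))
  expect_error(classify_traits(cm, 0), "threshold")
  expect_error(classify_traits(cm, 1), "threshold")
})

test_that("invariant traits are dropped with their identities reported", {
  tm <- cbind(all1 = c(1L, 1L, 1L), all0 = c(0L, 0L, 0L), var = c(1L, 0L, 1L))
  rownames(tm) <- c("g1", "g2", "g3")
  out <- drop_invariant_traits(tm)
  expect_equal(colnames(out), "var")
  expect_setequal(attr(out, "removed"), c("all1", "all0"))
  empty <- drop_invariant_traits(tm[, 0, drop = FALSE])
  expect_equal(ncol(empty), 0)
})

test_that("pathway profiles honour known-absent orthologs", {
  pw <- nitrogen_fixation_pathways()
  mo <- pw[["nif-MoFe"]]
  kos <- list(
    full_minus_anfG = setdiff(mo$required_kos, "K00531"),
    nothing = character(0),
    v_minus_vnfH = setdiff(pw[["vnf-V"]]$required_kos, "K22899")
  )
  prof_mo <- pathway_ortholog_profile(kos, "nif-MoFe", mo$required_kos,
                                      mo$known_absent)
  expect_true(prof_mo$detected[["full_minus_anfG"]])
  expect_false(prof_mo$detected[["nothing"]])
  expect_equal(unname(prof_mo$presence["full_minus_anfG", "K00531"]), 0L)

  vn <- pw[["vnf-V"]]
  prof_v <- pathway_ortholog_profile(kos, "vnf-V", vn$required_kos, vn$known_absent)
  expect_true(prof_v$detected[["v_minus_vnfH"]])
  expect_false(prof_v$detected[["nothing"]])
})

test_that("KO tables and definition files read back from disk", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("genome_id\tgene_id\tko",
               "g1\tg1_001\tK00001", "g1\tg1_002\tK00002",
               "g2\tg2_001\tK00002", "g1\tg1_003\tK00001"), path)
  kt <- read_ko_table(path)
  expect_equal(kt$g1, c("K00001", "K00002"))  # deduplicated, sorted
  expect_equal(kt$g2, "K00002")
  writeLines(c("genome_id\tgene_id\tko", "g1\tg1_001\tKX0001"), path)
  expect_error(read_ko_table(path), "malformed KO")

  defs_path <- system.file("extdata", "function_definitions.tsv",
                           package = "cyanotraits")
  defs <- read_function_definitions(defs_path)
  expect_true("nitrogen_fixation" %in% names(defs))
  expect_gte(length(defs), 10)
  cm <- completeness_matrix(kt, defs)
  expect_equal(dim(cm), c(2L, length(defs)))
  expect_true(all(cm >= 0 & cm <= 1))
})
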