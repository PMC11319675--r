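test_that("BGC filter removes short and contig-edge clusters with exact boundaries", {
  recs <- minimal_bgc_records(
    ids = c("short", "at3000", "long_interior", "edge_start", "edge_end"),
    domains = rep(list(c("PF00001", "PF00002")), 5)
  )
  recs$start <- c(5000, 5000, 5000, 1, 95001)
  recs$end <- c(5000 + 2999 - 1,      # 2999 bp: removed
                5000 + 3000 - 1,      # 3000 bp: retained (strictly-less rule)
                15000,                # interior, long: retained
                10000,                # starts at 1: removed
                100000)               # ends at contig length: removed
  contigs <- c(c1 = 100000)
  kept <- filter_bgcs(recs, 3000, contigs)
  expect_setequal(kept$bgc_id, c("at3000", "long_interior"))

  ## explicit contig_edge flags take precedence over coordinate heuristics
  recs$contig_edge <- c(FALSE, FALSE, TRUE, FALSE, FALSE)
  kept2 <- filter_bgcs(recs, 3000)
  expect_setequal(kept2$bgc_id, c("at3000", "edge_start", "edge_end"))

  recs$contig_edge <- NULL
  expect_error(filter_bgcs(recs, 3000), "contig_lengths")
})

test_that("Dice similarity matches hand counts and brute-force oracle", {
  expect_equal(dice_similarity(c("a", "b"), c("a", "b")), 1)
  expect_equal(dice_similarity(c("a", "b"), c("c", "d")), 0)
  expect_equal(dice_similarity(c("PF00001", "PF00002", "PF00003"),
                               c("PF00002", "PF00003", "PF00004")), 2 * 2 / 6)
  expect_error(dice_similarity(character(0), "a"), "empty")

  set.seed(12)
  pool <- sprintf("PF%05d", 1:30)
  for (rep in 1:200) {
    a <- sample(pool, sample(1:12, 1))
    b <- sample(pool, sample(1:12, 1))
    d <- dice_similarity(a, b)
    expect_equal(d, dice_oracle(a, b))
    expect_equal(d, dice_similarity(b, a))       # symmetry
    expect_true(d >= 0 && d <= 1)
    expect_equal(d == 1, setequal(a, b))         # identity iff equal sets
  }
})

test_that("similarity graph thresholds edges and keeps isolated nodes", {
  ## pairwise dice: (r1,r2)=0.8, (r1,r3)=0.4..., planted below/above 0.5
  recs <- minimal_bgc_records(
    ids = c("r1", "r2", "r3"),
    domains = list(c("A", "B", "C", "D", "E"),
                   c("A", "B", "C", "D", "F"),
                   c("A", "G", "H", "I", "J"))
  )
  g <- build_similarity_graph(recs, 0.5)
  expect_equal(nrow(g$edges), 1)
  expect_setequal(c(g$edges$from, g$edges$to), c("r1", "r2"))
  expect_equal(g$edges$weight, 0.8)
  expect_setequal(g$nodes, c("r1", "r2", "r3"))  # r3 isolated but present

  ## identical records, threshold 0.5 -> single edge of weight 1
  dup <- minimal_bgc_records(ids = c("x", "y"),
                             domains = rep(list(c("A", "B")), 2))
  gd <- build_similarity_graph(dup, 0.5)
  expect_equal(gd$edges$weight, 1)

  ## threshold 1 with all-distinct sets -> edgeless
  distinct <- minimal_bgc_records(ids = c("u", "v"),
                                  domains = list(c("A", "B"), c("A", "C")))
  expect_equal(nrow(build_similarity_graph(distinct, 1)$edges), 0)

  expect_error(build_similarity_graph(recs, 0), "edge_threshold")
  empty_dom <- minimal_bgc_records(ids = "e", domains = list(character(0)))
  expect_error(build_similarity_graph(empty_dom, 0.5), "empty domain set")

  ## sparse-matrix pairwise weights agree with dice_similarity
  set.seed(8)
  pool <- sprintf("PF%05d", 1:15)
  doms <- lapply(1:10, function(i) sample(pool, sample(2:8, 1)))
  recs10 <- minimal_bgc_records(ids = sprintf("b%02d", 1:10), domains = doms)
  g10 <- build_similarity_graph(recs10, 0.3)
  for (k in seq_len(nrow(g10$edges))) {
    i <- match(g10$edges$from[k], recs10$bgc_id)
    j <- match(g10$edges$to[k], recs10$bgc_id)
    expect_equal(g10$edges$weight[k], dice_similarity(doms[[i]], doms[[j]]))
  }
})

test_that("consensus class uses majority with lexicographic tie-break", {
  expect_equal(assign_consensus_class(c("terpene", "terpene", "RiPP")), "terpene")
  expect_equal(assign_consensus_class(c("NRP", "terpene")), "NRP")
  expect_equal(assign_consensus_class("NRP+polyketide"), "NRP+polyketide")
  expect_error(assign_consensus_class(character(0)), "empty")
})

test_that("group tables, annotated retention and presence matrices are consistent", {
  recs <- minimal_bgc_records(
    ids = sprintf("b%d", 1:5),
    domains = rep(list(c("A", "B")), 5),
    classes = c("terpene", "terpene", "RiPP", "NRP", "NRP"),
    sources = c("sanntis", "antismash", "sanntis", "sanntis", "sanntis"),
    genome = c("g1", "g1", "g2", "g2", "g3")
  )
  membership <- setNames(c(1L, 1L, 1L, 2L, 2L), recs$bgc_id)
  groups <- bgc_group_table(recs, membership)
  expect_equal(groups$n_members, c(3L, 2L))
  expect_equal(groups$consensus_class, c("terpene", "NRP"))
  expect_equal(groups$annotated, c(TRUE, FALSE))

  kept <- retain_annotated_groups(groups)
  expect_equal(kept$group_id, 1L)
  expect_equal(attr(kept, "n_discarded"), 1L)
  expect_equal(nrow(retain_annotated_groups(groups[0, ])), 0)

  pres <- group_presence_matrix(kept, recs, c("g1", "g2", "g3"))
  expect_equal(unname(pres[, "group_1"]), c(1L, 1L, 0L))  # presence, not count
  expect_error(group_presence_matrix(kept, recs, c("g1", "g2")), "not in genome list")
})

test_that("count tables conserve totals and report absent classes as zero", {
  recs <- minimal_bgc_records(
    ids = sprintf("b%d", 1:3),
    domains = rep(list("A"), 3),
    classes = c("terpene", "terpene", "NRP"),
    genome = c("g1", "g1", "g1")
  )
  counts <- bgc_count_table(recs, c("g1", "g2"))
  expect_equal(unname(counts["g1", "total"]), 3L)
  expect_equal(unname(counts["g1", "terpene"]), 2L)
  expect_equal(unname(counts["g1", "NRP"]), 1L)
  expect_equal(unname(counts["g2", ]), rep(0L, 3))
  ## conservation: class counts sum to the total
  expect_equal(rowSums(counts[, -1, drop = FALSE]), counts[, "total"],
               ignore_attr = TRUE)
  empty <- bgc_count_table(recs[0, ], c("g1"))
  expect_equal(sum(empty), 0)
})

test_that("GFF3-dialect BGC records load into the tabular representation", {
  path <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    paste0("ctg1\tsanntis\tBGC\t5000\t12000\t.\t+\t.\t",
           "ID=b1;genome=g1;class=terpene;domains=PF00001,PF00002;source_tool=sanntis"),
    paste0("ctg1\tantismash\tBGC\t20000\t30000\t.\t-\t.\t",
           "ID=b2;genome=g1;class=NRP;domains=PF00003;source_tool=antismash;product=nostopeptolide")
  ), path)
  recs <- read_bgc_gff3(path)
  expect_equal(recs$bgc_id, c("b1", "b2"))
  expect_equal(recs$domains, c("PF00001;PF00002", "PF00003"))
  expect_equal(recs$source, c("sanntis", "antismash"))
  expect_equal(recs$start, c(5000, 20000))
})
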