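make_meta <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    data.frame(genome_id = r[[1]], completeness = as.numeric(r[[2]]),
               contamination = as.numeric(r[[3]]), habitat = r[[4]],
               lifestyle = r[[5]],
               host_category = if (length(r) >= 6) r[[6]] else NA_character_,
               stringsAsFactors = FALSE)
  }))
}

test_that("metadata reading validates lifestyle/host-category consistency", {
  path <- withr::local_tempfile(fileext = ".tsv")
  df <- make_meta(list("g1", 95.2, 1.1, "lichen", "host-associated", "lichen"),
                  list("g2", 99.0, 0.5, "freshwater", "free-living"))
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE, na = "")
  rd <- read_genome_metadata(path)
  expect_equal(rd$genome_id, c("g1", "g2"))
  expect_equal(rd$host_category, c("lichen", NA))

  bad <- make_meta(list("g3", 95, 1, "lichen", "host-associated"))
  write.table(bad, path, sep = "\t", row.names = FALSE, quote = FALSE, na = "")
  expect_error(read_genome_metadata(path), "without host_category")

  bad2 <- df[, setdiff(names(df), "completeness")]
  write.table(bad2, path, sep = "\t", row.names = FALSE, quote = FALSE, na = "")
  expect_error(read_genome_metadata(path), "missing required column")

  bad3 <- make_meta(list("g4", 101, 1, "soil", "free-living"))
  write.table(bad3, path, sep = "\t", row.names = FALSE, quote = FALSE, na = "")
  expect_error(read_genome_metadata(path), "completeness")
})

test_that("QC filter uses strict inequalities at both boundaries", {
  meta <- validate_genome_metadata(make_meta(
    list("keep", 95, 1, "soil", "free-living"),
    list("at_comp", 90.0, 1, "soil", "free-living"),
    list("at_cont", 95, 5.0, "soil", "free-living"),
    list("low_comp", 89.9, 1, "soil", "free-living"),
    list("high_cont", 95, 5.1, "soil", "free-living"),
    list("both_edge", 90.0, 5.0, "soil", "free-living")
  ))
  kept <- qc_filter_genomes(meta)
  expect_equal(kept$genome_id, "keep")

  ## just inside both boundaries is retained
  meta2 <- validate_genome_metadata(make_meta(
    list("in1", 90.01, 4.99, "soil", "free-living")))
  expect_equal(nrow(qc_filter_genomes(meta2)), 1)
})

test_that("QC filter is idempotent and commutes with record order", {
  set.seed(3)
  meta <- validate_genome_metadata(data.frame(
    genome_id = sprintf("g%02d", 1:40),
    completeness = runif(40, 85, 100),
    contamination = runif(40, 0, 8),
    habitat = "soil", lifestyle = "free-living",
    host_category = NA_character_, stringsAsFactors = FALSE
  ))
  once <- qc_filter_genomes(meta)
  expect_identical(qc_filter_genomes(once), once)
  perm <- meta[sample(nrow(meta)), ]
  expect_setequal(qc_filter_genomes(perm)$genome_id, once$genome_id)
  ## order of surviving records preserved
  expect_identical(once$genome_id, meta$genome_id[meta$genome_id %in% once$genome_id])
})

test_that("results tables round-trip through TSV, including empty tables", {
  path <- withr::local_tempfile(fileext = ".tsv")
  df <- data.frame(trait_id = c("a", "b"), estimate = c(1.23456789, -0.5),
                   p = c(0.04, 0.9), stringsAsFactors = FALSE)
  write_results_table(df, path)
  back <- read_results_table(path)
  expect_equal(back$estimate, signif(df$estimate, 6))
  expect_equal(names(back), names(df))
  ## re-writing the re-read table reproduces the file exactly
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write_results_table(back, path2)
  expect_identical(readLines(path), readLines(path2))

  empty <- df[0, ]
  write_results_table(empty, path)
  expect_equal(readLines(path), "trait_id\testimate\tp")
  expect_equal(nrow(read_results_table(path)), 0)
})
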