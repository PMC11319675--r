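## End-to-end orchestration: QC -> traits -> BGC grouping -> enrichment ->
## phylogenetic signal, with per-stage TSV outputs, a run manifest and a
## plain-text summary. All thresholds live in the run configuration; no
## stage hard-codes a significance level.

#' Run configuration for the analysis pipeline
#'
#' @param qc_min_completeness,qc_max_contamination genome QC thresholds in
#'   percent (strict inequalities; defaults 90 and 5).
#' @param completeness_threshold completeness cut for "complete" functions
#'   (strictly greater than; default 0.98).
#' @param indicative_threshold completeness cut for "indicative" functions
#'   (default 0.5).
#' @param bgc_min_length minimum BGC length in bp (default 3000).
#' @param edge_threshold Dice edge threshold for the BGC similarity graph
#'   (default 0.5).
#' @param resolution Louvain resolution parameter (default 1).
#' @param B bootstrap replicates for the regressions (default 100).
#' @param n_null null-set size for the D-statistic (default 1000).
#' @param alpha_level significance level (default 0.05).
#' @param headline p-value driving significance flags: "boot" or "wald".
#' @param seed global seed for all stochastic stages.
#' @return a list of class `run_config`.
#' @export
run_config <- function(qc_min_completeness = 90, qc_max_contamination = 5,
                       completeness_threshold = 0.98, indicative_threshold = 0.5,
                       bgc_min_length = 3000, edge_threshold = 0.5,
                       resolution = 1, B = 100L, n_null = 1000L,
                       alpha_level = 0.05, headline = "boot", seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(qc_min_completeness >= 0, qc_min_completeness <= 100,
            qc_max_contamination >= 0, qc_max_contamination <= 100,
            completeness_threshold > 0, completeness_threshold < 1,
            indicative_threshold > 0, indicative_threshold < 1,
            bgc_min_length >= 0, edge_threshold > 0, edge_threshold <= 1,
            alpha_level > 0, alpha_level < 1, headline %in% c("boot", "wald"))
  if (is.null(seed)) stopf("seed must be set")
  structure(cfg, class = "run_config")
}

#' Read pipeline inputs from a fixture-bundle directory
#'
#' Loads the files written by [write_fixture_bundle()] (tree.nwk,
#' metadata.tsv, ko_annotations.tsv, function_definitions.tsv,
#' bgc_records.tsv, contig_lengths.tsv) into the in-memory input list
#' consumed by [run_study()].
#'
#' @param dir bundle directory.
#' @return named list of inputs, with the source paths attached as
#'   attribute `paths`.
#' @export
read_study_inputs <- function(dir) {
  pth <- function(f) {
    p <- file.path(dir, f)
    if (!file.exists(p)) stopf("missing input file: %s", p)
    p
  }
  paths <- c(tree = pth("tree.nwk"), metadata = pth("metadata.tsv"),
             ko = pth("ko_annotations.tsv"),
             definitions = pth("function_definitions.tsv"),
             bgc = pth("bgc_records.tsv"), contigs = pth("contig_lengths.tsv"))
  ko_df <- read_results_table(paths[["ko"]])
  inputs <- list(
    tree = read_newick(paths[["tree"]]),
    metadata = read_genome_metadata(paths[["metadata"]]),
    kos_by_genome = lapply(split(ko_df$ko, ko_df$genome_id),
                           function(k) sort(unique(k))),
    definitions = read_function_definitions(paths[["definitions"]]),
    bgc_records = read_bgc_table(paths[["bgc"]]),
    contig_lengths = read_contig_lengths(paths[["contigs"]])
  )
  attr(inputs, "paths") <- paths
  inputs
}

as_study_inputs <- function(x) {
  if (inherits(x, "synthetic_study")) {
    return(list(tree = x$tree, metadata = x$metadata,
                kos_by_genome = x$ko$kos_by_genome,
                definitions = x$ko$definitions,
                bgc_records = x$bgc$records,
                contig_lengths = x$bgc$contig_lengths))
  }
  required <- c("tree", "metadata", "kos_by_genome", "definitions",
                "bgc_records", "contig_lengths")
  missing <- setdiff(required, names(x))
  if (length(missing) > 0L)
    stopf("missing input element(s): %s", paste(missing, collapse = ", "))
  x
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
}

#' Run the full comparative analysis pipeline
#'
#' Stages: genome QC filter; function completeness and trait
#' classification; lifestyle enrichment scan over complete functions; BGC
#' filtering, Dice/Louvain grouping, annotated-group retention and
#' presence/count construction; lifestyle enrichment scans over BGC-group
#' presence and per-class counts; D-statistic phylogenetic-signal scan over
#' the significantly enriched groups. Writes per-stage TSVs, a manifest and
#' a summary when `outdir` is given.
#'
#' @param inputs a `synthetic_study`, the result of [read_study_inputs()],
#'   or an equivalent named list.
#' @param config a [run_config()].
#' @param outdir optional output directory.
#' @return a list of class `study_result`.
#' @export
run_study <- function(inputs, config = run_config(), outdir = NULL) {
  inputs <- as_study_inputs(inputs)
  tree <- inputs$tree

  meta_kept <- run_stage("qc", {
    validate_genome_metadata(inputs$metadata)
    qc_filter_genomes(inputs$metadata, config$qc_min_completeness,
                      config$qc_max_contamination)
  })
  genomes <- intersect(tree$tip.label, meta_kept$genome_id)
  if (length(genomes) < 3L) stopf("fewer than 3 genomes pass QC and match the tree")
  tree_kept <- run_stage("qc", ape::keep.tip(tree, genomes))
  genomes <- tree_kept$tip.label
  meta_kept <- meta_kept[match(genomes, meta_kept$genome_id), , drop = FALSE]
  lifestyle <- stats::setNames(
    factor(meta_kept$lifestyle, levels = LIFESTYLES), genomes)

  traits <- run_stage("traits", {
    kos <- inputs$kos_by_genome[genomes]
    names(kos) <- genomes
    kos <- lapply(kos, function(k) k %||% character(0))
    cm <- completeness_matrix(kos, inputs$definitions)
    list(completeness = cm,
         complete = drop_invariant_traits(
           classify_traits(cm, config$completeness_threshold)),
         indicative = drop_invariant_traits(
           classify_traits(cm, config$indicative_threshold)))
  })

  fn_enrichment <- run_stage("enrich-functions",
    enrichment_scan(traits$complete, lifestyle, tree_kept,
                    alpha_level = config$alpha_level, B = config$B,
                    seed = config$seed, headline = config$headline))

  bgc <- run_stage("bgc-group", {
    recs <- inputs$bgc_records
    recs <- recs[recs$genome_id %in% genomes, , drop = FALSE]
    filtered <- filter_bgcs(recs, config$bgc_min_length, inputs$contig_lengths)
    graph <- build_similarity_graph(filtered, config$edge_threshold)
    part <- louvain_partition(graph, resolution = config$resolution,
                              seed = config$seed)
    groups <- bgc_group_table(filtered, part$membership)
    retained <- retain_annotated_groups(groups)
    presence <- group_presence_matrix(retained, filtered, genomes)
    counts <- bgc_count_table(filtered, genomes)
    list(n_input = nrow(recs), filtered = filtered, graph = graph,
         partition = part, groups = groups, retained = retained,
         presence = drop_invariant_traits(presence), counts = counts)
  })

  group_enrichment <- run_stage("enrich-groups",
    enrichment_scan(bgc$presence, lifestyle, tree_kept,
                    alpha_level = config$alpha_level, B = config$B,
                    seed = config$seed, headline = config$headline))

  count_enrichment <- run_stage("enrich-counts",
    count_enrichment_scan(bgc$counts, lifestyle, tree_kept,
                          alpha_level = config$alpha_level, B = config$B,
                          seed = config$seed, headline = config$headline))

  dstat <- run_stage("dstat", {
    sig <- group_enrichment$trait_id[group_enrichment$significant]
    if (length(sig) > 0L) {
      d_statistic_scan(bgc$presence[, sig, drop = FALSE], tree_kept,
                       n_null = config$n_null, seed = config$seed,
                       alpha_level = config$alpha_level)
    } else {
      data.frame()
    }
  })

  host_labels <- stats::setNames(
    ifelse(is.na(meta_kept$host_category), "free-living", meta_kept$host_category),
    genomes)
  clades <- run_stage("host-clades", find_host_clades(tree_kept, host_labels))

  summary_counts <- c(
    genomes_in = nrow(inputs$metadata),
    genomes_retained = length(genomes),
    host_associated = sum(lifestyle == "host-associated"),
    host_clades = nrow(clades),
    functions_defined = length(inputs$definitions),
    functions_variable = ncol(traits$complete),
    functions_significant = sum(fn_enrichment$significant),
    bgc_records_in = bgc$n_input,
    bgc_records_filtered = nrow(bgc$filtered),
    bgc_groups = nrow(bgc$groups),
    bgc_groups_retained = nrow(bgc$retained),
    bgc_groups_variable = ncol(bgc$presence),
    bgc_groups_significant = sum(group_enrichment$significant),
    count_classes_significant = sum(count_enrichment$significant)
  )

  result <- structure(list(
    config = config, tree = tree_kept, metadata = meta_kept,
    lifestyle = lifestyle, host_clades = clades, traits = traits,
    fn_enrichment = fn_enrichment, bgc = bgc,
    group_enrichment = group_enrichment, count_enrichment = count_enrichment,
    dstat = dstat, summary_counts = summary_counts
  ), class = "study_result")

  if (!is.null(outdir)) write_study_result(result, outdir, inputs)
  result
}

write_study_result <- function(result, outdir, inputs) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, f) write_results_table(df, file.path(outdir, f))
  w(result$metadata, "genomes_retained.tsv")
  cm <- as.data.frame(result$traits$completeness)
  w(cbind(genome_id = rownames(cm), cm), "function_completeness.tsv")
  w(result$fn_enrichment, "enrichment_functions.tsv")
  groups_out <- result$bgc$groups
  groups_out$member_bgcs <- vapply(groups_out$member_bgcs, paste, "", collapse = ";")
  w(groups_out, "bgc_groups.tsv")
  pres <- as.data.frame(result$bgc$presence)
  w(cbind(genome_id = rownames(pres), pres), "bgc_group_presence.tsv")
  cnts <- as.data.frame(result$bgc$counts)
  w(cbind(genome_id = rownames(cnts), cnts), "bgc_counts.tsv")
  w(result$group_enrichment, "enrichment_bgc_groups.tsv")
  w(result$count_enrichment, "enrichment_bgc_counts.tsv")
  if (nrow(result$dstat) > 0L) w(result$dstat, "dstat.tsv")
  clades_out <- result$host_clades
  clades_out$member_tips <- vapply(clades_out$member_tips, paste, "", collapse = ";")
  w(clades_out, "host_clades.tsv")
  summary_df <- data.frame(stage = names(result$summary_counts),
                           count = unname(result$summary_counts))
  w(summary_df, "summary_counts.tsv")

  paths <- attr(inputs, "paths")
  manifest <- list(
    package = "cyanotraits",
    version = as.character(utils::packageVersion("cyanotraits")),
    config = unclass(result$config),
    seed = result$config$seed,
    inputs = if (!is.null(paths))
      as.list(tools::md5sum(paths)) else "in-memory",
    outputs = as.list(tools::md5sum(
      list.files(outdir, pattern = "\\.tsv$", full.names = TRUE)))
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(format_study_report(result), file.path(outdir, "report.txt"))
  invisible(outdir)
}

#' Render a plain-text report for a pipeline run
#'
#' @param result a `study_result`, or a results directory written by
#'   [run_study()].
#' @param html optional path; when given, a minimal HTML rendering is also
#'   written there.
#' @return character vector of report lines, invisibly printed.
#' @export
study_report <- function(result, html = NULL) {
  lines <- if (inherits(result, "study_result")) {
    format_study_report(result)
  } else if (is.character(result) && dir.exists(result)) {
    rp <- file.path(result, "report.txt")
    if (!file.exists(rp)) stopf("no report.txt under '%s'", result)
    readLines(rp)
  } else {
    stopf("expected a study_result or a results directory")
  }
  if (!is.null(html)) {
    writeLines(c("<html><body><pre>", lines, "</pre></body></html>"), html)
  }
  cat(lines, sep = "\n")
  invisible(lines)
}

format_study_report <- function(result) {
  sc <- result$summary_counts
  fmt_tab <- function(df, cols) {
    if (nrow(df) == 0L) return("  (none)")
    df <- df[order(df$p_boot %||% df$p_wald), cols, drop = FALSE]
    utils::capture.output(print(format(df, digits = 4), row.names = FALSE))
  }
  c("Comparative phylogenomics run summary",
    "=====================================",
    sprintf("%-28s %d", names(sc), sc),
    "",
    "Significant functions (lifestyle enrichment):",
    fmt_tab(result$fn_enrichment[result$fn_enrichment$significant, , drop = FALSE],
            c("trait_id", "estimate", "p_boot", "direction")),
    "",
    "Significant BGC groups (lifestyle enrichment):",
    fmt_tab(result$group_enrichment[result$group_enrichment$significant, , drop = FALSE],
            c("trait_id", "estimate", "p_boot", "direction")),
    "",
    "BGC count regressions:",
    fmt_tab(result$count_enrichment,
            c("trait_id", "estimate", "p_boot", "significant", "direction")),
    "",
    "Phylogenetic signal (D-statistic) of enriched groups:",
    if (nrow(result$dstat) > 0L)
      utils::capture.output(print(format(result$dstat[
        order(result$dstat$p_random),
        c("trait_id", "d_obs", "D", "p_random", "p_brownian")], digits = 4),
        row.names = FALSE))
    else "  (none)")
}

#' @export
print.study_result <- function(x, ...) {
  cat(format_study_report(x), sep = "\n")
  invisible(x)
}
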