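## Biosynthetic gene cluster (BGC) records, filtering and grouping support.
##
## A BGC table is a data.frame with one row per predicted cluster:
##   bgc_id, genome_id, contig_id, start, end (1-based inclusive bp), strand,
##   predicted_class (single class or '+'-joined hybrid), domains
##   (';'-separated protein-domain accessions), source (sanntis / antismash /
##   mibig), optional contig_edge (logical) and product.
## Domain composition is treated as a set.

BGC_SOURCES <- c("sanntis", "antismash", "mibig")

#' Read a BGC prediction table (TSV)
#'
#' @param path TSV with columns `bgc_id`, `genome_id`, `contig_id`, `start`,
#'   `end`, `predicted_class`, `domains` (';'-separated), `source`; optional
#'   `strand`, `contig_edge`, `product`. Gzip accepted; `#` comments ignored.
#' @return a validated BGC data.frame.
#' @export
read_bgc_table <- function(path) {
  df <- read_results_table(path)
  validate_bgc_table(df, where = path)
}

#' Read BGC records from a GFF3-dialect file
#'
#' Reads features of type `BGC`; attributes `ID`, `class`, `domains`
#' (comma-separated within the attribute), `source_tool` and optionally
#' `product` are mapped onto the tabular representation. The genome
#' identifier is taken from the `genome` attribute.
#'
#' @param path GFF3 file (optionally gzipped).
#' @return a validated BGC data.frame.
#' @export
read_bgc_gff3 <- function(path) {
  con <- open_input(path)
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(lines) == 0L)
    return(validate_bgc_table(empty_bgc_table(), where = path))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 9L)
  if (length(bad) > 0L) stopf("%s: line %d does not have 9 GFF3 columns", path, bad[1L])
  keep <- vapply(fields, function(f) f[3L] == "BGC", logical(1L))
  fields <- fields[keep]
  attr_get <- function(attrs, key) {
    m <- regmatches(attrs, regexpr(paste0("(^|;)", key, "=[^;]*"), attrs))
    if (length(m) == 0L) return(NA_character_)
    sub(paste0("^;?", key, "="), "", m)
  }
  rows <- lapply(fields, function(f) {
    a <- f[9L]
    data.frame(
      bgc_id = attr_get(a, "ID"),
      genome_id = attr_get(a, "genome"),
      contig_id = f[1L],
      start = as.numeric(f[4L]),
      end = as.numeric(f[5L]),
      strand = f[7L],
      predicted_class = attr_get(a, "class"),
      domains = gsub(",", ";", attr_get(a, "domains") %||% ""),
      source = attr_get(a, "source_tool"),
      product = attr_get(a, "product"),
      stringsAsFactors = FALSE
    )
  })
  validate_bgc_table(do.call(rbind, rows), where = path)
}

empty_bgc_table <- function() {
  data.frame(bgc_id = character(0), genome_id = character(0),
             contig_id = character(0), start = numeric(0), end = numeric(0),
             strand = character(0), predicted_class = character(0),
             domains = character(0), source = character(0),
             stringsAsFactors = FALSE)
}

#' Validate a BGC data.frame
#'
#' @param df BGC table as in [read_bgc_table()].
#' @param where label for error messages.
#' @return the validated data.frame.
#' @export
validate_bgc_table <- function(df, where = "bgc table") {
  required <- c("bgc_id", "genome_id", "contig_id", "start", "end",
                "predicted_class", "domains", "source")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L)
    stopf("%s: missing column(s): %s", where, paste(missing, collapse = ", "))
  if (!"strand" %in% names(df)) df$strand <- "."
  if (anyDuplicated(df$bgc_id)) stopf("%s: duplicate bgc_id", where)
  if (nrow(df) > 0L) {
    if (any(df$start < 1)) stopf("%s: start must be >= 1 (1-based coordinates)", where)
    if (any(df$end < df$start)) stopf("%s: end < start", where)
    bad_src <- setdiff(unique(df$source), BGC_SOURCES)
    if (length(bad_src) > 0L)
      stopf("%s: unknown source(s): %s", where, paste(bad_src, collapse = ", "))
  }
  df
}

## Domain set of each record, as a list of character vectors.
domain_sets <- function(records) {
  lapply(strsplit(as.character(records$domains), ";", fixed = TRUE),
         function(d) unique(d[nzchar(d)]))
}

bgc_length <- function(records) records$end - records$start + 1

#' Filter BGC predictions on contig position and length
#'
#' Removes clusters at contig edges and clusters shorter than
#' `min_length_bp` (strictly less than; a 3000 bp cluster is retained at the
#' default). A record is at a contig edge when its `contig_edge` flag is
#' `TRUE`, or — if the flag is absent — when `start == 1` or
#' `end == contig_length`.
#'
#' @param records BGC data.frame.
#' @param min_length_bp minimum retained length in bp (default 3000).
#' @param contig_lengths named numeric vector (contig_id -> length in bp);
#'   required when `records` has no `contig_edge` column.
#' @return the retained records, order preserved.
#' @export
filter_bgcs <- function(records, min_length_bp = 3000, contig_lengths = NULL) {
  if (nrow(records) == 0L) return(records)
  if ("contig_edge" %in% names(records) && !anyNA(records$contig_edge)) {
    edge <- as.logical(records$contig_edge)
  } else {
    if (is.null(contig_lengths))
      stopf("contig_edge flags absent: supply contig_lengths")
    missing <- setdiff(unique(records$contig_id), names(contig_lengths))
    if (length(missing) > 0L)
      stopf("missing contig length for: %s", paste(utils::head(missing, 5L), collapse = ", "))
    edge <- records$start == 1 | records$end == contig_lengths[records$contig_id]
  }
  records[!edge & bgc_length(records) >= min_length_bp, , drop = FALSE]
}

#' Read a contig-length table
#'
#' Accepts a two-column TSV (`contig_id`, `length`) or a `.fai`-style index
#' whose first two columns are sequence name and length.
#'
#' @param path input path (optionally gzipped).
#' @return named numeric vector of contig lengths.
#' @export
read_contig_lengths <- function(path) {
  con <- open_input(path)
  on.exit(close(con))
  df <- utils::read.delim(con, header = FALSE, comment.char = "#",
                          stringsAsFactors = FALSE)
  if (identical(tolower(as.character(df[1, 1])), "contig_id")) df <- df[-1, , drop = FALSE]
  stats::setNames(as.numeric(df[[2L]]), as.character(df[[1L]]))
}

#' Sorensen-Dice similarity of two domain sets
#'
#' `2 |A intersect B| / (|A| + |B|)` for non-empty sets.
#'
#' @param a,b character vectors (treated as sets).
#' @return similarity in `[0, 1]`.
#' @export
dice_similarity <- function(a, b) {
  a <- unique(a); b <- unique(b)
  if (length(a) == 0L || length(b) == 0L)
    stopf("dice_similarity: empty domain set")
  2 * length(intersect(a, b)) / (length(a) + length(b))
}

#' Build a Dice-similarity graph over BGC records
#'
#' Nodes are BGC identifiers; an undirected edge joins two records when the
#' Dice similarity of their domain sets is at least `edge_threshold`, with
#' the similarity as edge weight. Records with no qualifying edge remain as
#' isolated nodes. Intersection counts are computed with a sparse
#' record-by-domain incidence matrix, so large record sets stay fast.
#'
#' @param records BGC data.frame; every record must have a non-empty domain set.
#' @param edge_threshold minimum Dice similarity in `(0, 1]` (default 0.5).
#' @return an object of class `similarity_graph`: list with `nodes`
#'   (character) and `edges` (data.frame `from`, `to`, `weight`).
#' @export
build_similarity_graph <- function(records, edge_threshold = 0.5) {
  if (!is.numeric(edge_threshold) || length(edge_threshold) != 1L ||
      edge_threshold <= 0 || edge_threshold > 1)
    stopf("edge_threshold must lie in (0, 1]")
  ds <- domain_sets(records)
  if (any(lengths(ds) == 0L))
    stopf("record(s) with empty domain set: %s",
          paste(utils::head(records$bgc_id[lengths(ds) == 0L], 5L), collapse = ", "))
  n <- length(ds)
  nodes <- as.character(records$bgc_id)
  if (n < 2L)
    return(structure(list(nodes = nodes,
                          edges = data.frame(from = character(0), to = character(0),
                                             weight = numeric(0))),
                     class = "similarity_graph"))
  all_domains <- unique(unlist(ds))
  M <- Matrix::sparseMatrix(
    i = rep(seq_len(n), lengths(ds)),
    j = match(unlist(ds), all_domains),
    x = 1, dims = c(n, length(all_domains))
  )
  inter <- Matrix::tcrossprod(M)
  sizes <- lengths(ds)
  tri <- Matrix::which(inter > 0, arr.ind = TRUE)
  tri <- tri[tri[, 1L] < tri[, 2L], , drop = FALSE]
  if (nrow(tri) > 0L) {
    w <- 2 * inter[tri] / (sizes[tri[, 1L]] + sizes[tri[, 2L]])
    keep <- w >= edge_threshold
    edges <- data.frame(from = nodes[tri[keep, 1L]], to = nodes[tri[keep, 2L]],
                        weight = w[keep], stringsAsFactors = FALSE)
  } else {
    edges <- data.frame(from = character(0), to = character(0), weight = numeric(0))
  }
  structure(list(nodes = nodes, edges = edges), class = "similarity_graph")
}

#' Consensus BGC class of a set of member classes
#'
#' Majority predicted class; ties are broken by lexicographic order of the
#' class name. Hybrid ('+'-joined) labels count as their own class.
#'
#' @param classes character vector of member classes (non-empty).
#' @return a single class label.
#' @export
assign_consensus_class <- function(classes) {
  if (length(classes) == 0L) stopf("empty group")
  tab <- table(classes)
  cands <- names(tab)[tab == max(tab)]
  sort(cands)[1L]
}

#' Summarise a Louvain partition of BGC records into groups
#'
#' @param records BGC data.frame (the clustered records).
#' @param membership named integer vector (bgc_id -> group id), e.g. from
#'   [louvain_partition()].
#' @param annotated_sources sources that mark a group as annotated
#'   (default antismash and mibig).
#' @return data.frame with one row per group: `group_id`, `n_members`,
#'   `consensus_class`, `annotated`, `member_bgcs` (list column).
#' @export
bgc_group_table <- function(records, membership,
                            annotated_sources = c("antismash", "mibig")) {
  stopifnot(all(records$bgc_id %in% names(membership)))
  grp <- membership[as.character(records$bgc_id)]
  split_idx <- split(seq_len(nrow(records)), grp)
  out <- data.frame(
    group_id = as.integer(names(split_idx)),
    n_members = lengths(split_idx),
    consensus_class = vapply(split_idx, function(i)
      assign_consensus_class(records$predicted_class[i]), ""),
    annotated = vapply(split_idx, function(i)
      any(records$source[i] %in% annotated_sources), logical(1L)),
    stringsAsFactors = FALSE
  )
  out$member_bgcs <- I(lapply(split_idx, function(i) as.character(records$bgc_id[i])))
  rownames(out) <- NULL
  out
}

#' Retain groups containing at least one annotated prediction
#'
#' Groups with no member from an annotation-backed source (antiSMASH-style
#' predictions or reference clusters) are discarded; the number of discarded
#' groups is attached as attribute `n_discarded`.
#'
#' @param groups group table from [bgc_group_table()].
#' @return the retained rows, with attribute `n_discarded`.
#' @export
retain_annotated_groups <- function(groups) {
  out <- groups[groups$annotated, , drop = FALSE]
  attr(out, "n_discarded") <- sum(!groups$annotated)
  out
}

#' Genome-by-group presence matrix
#'
#' @param groups group table (e.g. from [retain_annotated_groups()]).
#' @param records the clustered BGC data.frame (maps bgc_id to genome_id).
#' @param genomes character vector of genome identifiers for the rows.
#' @return binary matrix, genomes x groups; 1 when the genome contributes at
#'   least one member BGC to the group.
#' @export
group_presence_matrix <- function(groups, records, genomes) {
  bad <- setdiff(unique(records$genome_id), genomes)
  if (length(bad) > 0L)
    stopf("record genome(s) not in genome list: %s",
          paste(utils::head(bad, 5L), collapse = ", "))
  m <- matrix(0L, nrow = length(genomes), ncol = nrow(groups),
              dimnames = list(genomes, paste0("group_", groups$group_id)))
  genome_of <- stats::setNames(as.character(records$genome_id),
                               as.character(records$bgc_id))
  for (k in seq_len(nrow(groups))) {
    g <- unique(genome_of[groups$member_bgcs[[k]]])
    m[g, k] <- 1L
  }
  m
}

#' Per-genome BGC count table
#'
#' Counts filtered BGC records per genome, in total and per predicted class;
#' classes absent from a genome are reported as 0.
#'
#' @param records filtered BGC data.frame.
#' @param genomes character vector of genome identifiers (rows; genomes with
#'   no BGC get all-zero rows).
#' @return integer matrix, genomes x (total + classes).
#' @export
bgc_count_table <- function(records, genomes) {
  classes <- sort(unique(as.character(records$predicted_class)))
  m <- matrix(0L, nrow = length(genomes), ncol = 1L + length(classes),
              dimnames = list(genomes, c("total", classes)))
  if (nrow(records) > 0L) {
    bad <- setdiff(unique(records$genome_id), genomes)
    if (length(bad) > 0L)
      stopf("record genome(s) not in genome list: %s",
            paste(utils::head(bad, 5L), collapse = ", "))
    tot <- table(factor(records$genome_id, levels = genomes))
    m[, "total"] <- as.integer(tot)
    for (cl in classes) {
      t_cl <- table(factor(records$genome_id[records$predicted_class == cl],
                           levels = genomes))
      m[, cl] <- as.integer(t_cl)
    }
  }
  m
}
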