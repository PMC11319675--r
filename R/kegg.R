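## KEGG-ortholog trait construction.
##
## Molecular functions are described declaratively as an ordered list of
## steps; each step is a boolean expression over KO identifiers with ','
## meaning OR (alternative orthologs), '+' meaning AND (complex subunits,
## binding tighter than ','), and parentheses for grouping. Steps are
## separated by whitespace at the top level. Completeness of a function in a
## genome is the fraction of steps whose expression is satisfied by the
## genome's KO set — the unweighted step-fraction convention.

KO_PATTERN <- "^K[0-9]{5}$"

#' Parse a multi-step molecular function definition
#'
#' @param expr definition string; steps separated by whitespace, `,` = OR,
#'   `+` = AND (higher precedence), parentheses allowed. Leaves are KO
#'   identifiers (`K` followed by five digits).
#' @param function_id identifier for the function.
#' @param name human-readable name (defaults to `function_id`).
#' @return an object of class `function_definition` with elements
#'   `function_id`, `name`, `steps` (list of parse trees) and `kos` (all KO
#'   ids mentioned).
#' @export
parse_function_definition <- function(expr, function_id, name = function_id) {
  if (!is.character(expr) || length(expr) != 1L || !nzchar(trimws(expr)))
    stopf("definition '%s': empty expression", function_id)
  step_strings <- split_top_level_steps(expr, function_id)
  steps <- lapply(step_strings, function(s) parse_step(s, function_id))
  structure(
    list(function_id = function_id, name = name, steps = steps,
         kos = sort(unique(unlist(lapply(steps, collect_kos))))),
    class = "function_definition"
  )
}

## Split a definition on whitespace outside parentheses.
split_top_level_steps <- function(expr, id) {
  chars <- strsplit(expr, "")[[1L]]
  depth <- 0L; cur <- character(0); out <- character(0)
  for (ch in chars) {
    if (ch == "(") depth <- depth + 1L
    if (ch == ")") depth <- depth - 1L
    if (depth < 0L) stopf("definition '%s': unbalanced ')'", id)
    if (depth == 0L && grepl("^\\s$", ch)) {
      if (length(cur) > 0L) { out <- c(out, paste(cur, collapse = "")); cur <- character(0) }
    } else {
      cur <- c(cur, ch)
    }
  }
  if (depth != 0L) stopf("definition '%s': unbalanced '('", id)
  if (length(cur) > 0L) out <- c(out, paste(cur, collapse = ""))
  if (length(out) == 0L) stopf("definition '%s': no steps", id)
  out
}

## Recursive-descent parser for one step.
## grammar: or_expr  := and_expr (',' and_expr)*
##          and_expr := atom ('+' atom)*
##          atom     := KO | '(' or_expr ')'
parse_step <- function(s, id) {
  toks <- tokenize_step(s, id)
  st <- new.env(parent = emptyenv()); st$toks <- toks; st$pos <- 1L
  node <- parse_or(st, id)
  if (st$pos <= length(st$toks))
    stopf("definition '%s': unexpected token '%s' at position %d in step '%s'",
          id, st$toks[st$pos], st$pos, s)
  node
}

tokenize_step <- function(s, id) {
  toks <- character(0)
  rest <- s
  while (nzchar(rest)) {
    if (grepl("^[,+()]", rest)) {
      toks <- c(toks, substr(rest, 1L, 1L))
      rest <- substr(rest, 2L, nchar(rest))
    } else {
      m <- regmatches(rest, regexpr("^K[0-9]{5}", rest))
      if (length(m) == 0L)
        stopf("definition '%s': malformed token near '%s'", id,
              substr(rest, 1L, 12L))
      toks <- c(toks, m)
      rest <- substr(rest, nchar(m) + 1L, nchar(rest))
    }
  }
  toks
}

peek <- function(st) if (st$pos <= length(st$toks)) st$toks[st$pos] else NA_character_
advance <- function(st) { st$pos <- st$pos + 1L; st$toks[st$pos - 1L] }

parse_or <- function(st, id) {
  parts <- list(parse_and(st, id))
  while (identical(peek(st), ",")) {
    advance(st)
    parts <- c(parts, list(parse_and(st, id)))
  }
  if (length(parts) == 1L) parts[[1L]] else list(op = "or", args = parts)
}

parse_and <- function(st, id) {
  parts <- list(parse_atom(st, id))
  while (identical(peek(st), "+")) {
    advance(st)
    parts <- c(parts, list(parse_atom(st, id)))
  }
  if (length(parts) == 1L) parts[[1L]] else list(op = "and", args = parts)
}

parse_atom <- function(st, id) {
  tok <- peek(st)
  if (is.na(tok))
    stopf("definition '%s': dangling operator (expression ends early)", id)
  if (tok == "(") {
    advance(st)
    node <- parse_or(st, id)
    if (!identical(peek(st), ")"))
      stopf("definition '%s': missing ')'", id)
    advance(st)
    return(node)
  }
  if (grepl(KO_PATTERN, tok)) { advance(st); return(list(op = "ko", ko = tok)) }
  stopf("definition '%s': unexpected token '%s'", id, tok)
}

collect_kos <- function(node) {
  if (identical(node$op, "ko")) return(node$ko)
  unlist(lapply(node$args, collect_kos))
}

eval_step <- function(node, kos) {
  switch(node$op,
         ko = node$ko %in% kos,
         and = all(vapply(node$args, eval_step, logical(1L), kos = kos)),
         or = any(vapply(node$args, eval_step, logical(1L), kos = kos)),
         stopf("corrupt parse tree"))
}

#' Completeness of one function given a genome's KO set
#'
#' @param defn a `function_definition`.
#' @param kos character vector of KO identifiers present in the genome.
#' @return fraction in `[0, 1]`: satisfied steps / total steps.
#' @export
compute_completeness <- function(defn, kos) {
  stopifnot(inherits(defn, "function_definition"))
  sat <- vapply(defn$steps, eval_step, logical(1L), kos = kos)
  sum(sat) / length(sat)
}

#' Read function definitions from a TSV file
#'
#' One function per line: columns `function_id`, `name`, `definition` (the
#' step expression, see [parse_function_definition()]). `#` comment lines
#' ignored.
#'
#' @param path path to the definitions file (optionally gzipped).
#' @return a named list of `function_definition` objects.
#' @export
read_function_definitions <- function(path) {
  df <- read_results_table(path)
  required <- c("function_id", "name", "definition")
  if (!all(required %in% names(df)))
    stopf("%s: definitions file needs columns %s", path, paste(required, collapse = ", "))
  if (anyDuplicated(df$function_id)) stopf("%s: duplicate function_id", path)
  defs <- Map(parse_function_definition, df$definition, df$function_id, df$name)
  names(defs) <- df$function_id
  defs
}

#' Read per-genome KO annotations
#'
#' Accepts either a KofamScan-like two/three column table (`genome_id`,
#' `gene_id`, `ko`) or a pre-aggregated two-column table (`genome_id`, `ko`).
#' Malformed KO identifiers are rejected.
#'
#' @param path path to a TSV file (optionally gzipped).
#' @return named list mapping genome_id to a sorted character vector of
#'   unique KO identifiers.
#' @export
read_ko_table <- function(path) {
  df <- read_results_table(path)
  if (!all(c("genome_id", "ko") %in% names(df)))
    stopf("%s: KO table needs columns genome_id, ko", path)
  bad <- !grepl(KO_PATTERN, df$ko)
  if (any(bad))
    stopf("%s: malformed KO identifier(s): %s", path,
          paste(utils::head(unique(df$ko[bad]), 5L), collapse = ", "))
  lapply(split(df$ko, df$genome_id), function(k) sort(unique(k)))
}

#' Completeness matrix over genomes and functions
#'
#' @param kos_by_genome named list: genome_id -> character vector of KOs.
#' @param definitions named list of `function_definition` objects.
#' @return numeric matrix (genomes x functions) of completeness fractions.
#' @export
completeness_matrix <- function(kos_by_genome, definitions) {
  stopifnot(length(definitions) > 0L)
  m <- vapply(definitions,
              function(d) vapply(kos_by_genome, function(k) compute_completeness(d, k), 0),
              numeric(length(kos_by_genome)))
  m <- matrix(m, nrow = length(kos_by_genome), ncol = length(definitions),
              dimnames = list(names(kos_by_genome), names(definitions)))
  m
}

#' Binarise a completeness matrix at a threshold
#'
#' Trait presence is completeness strictly greater than the threshold. The
#' two conventional presets are 0.98 ("complete" functions) and 0.50
#' ("indicative" functions).
#'
#' @param cm completeness matrix from [completeness_matrix()].
#' @param threshold fraction strictly between 0 and 1.
#' @return binary 0/1 matrix with the same dimnames.
#' @export
classify_traits <- function(cm, threshold = 0.98) {
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold >= 1)
    stopf("threshold must lie strictly between 0 and 1")
  (cm > threshold) + 0L
}

#' Drop trait columns invariant across genomes
#'
#' Removes columns that are all-0 or all-1; such traits carry no information
#' for enrichment testing.
#'
#' @param tm binary trait matrix.
#' @return the reduced matrix, with attribute `removed` listing dropped
#'   column names.
#' @export
drop_invariant_traits <- function(tm) {
  if (ncol(tm) == 0L || nrow(tm) == 0L) {
    attr(tm, "removed") <- character(0)
    return(tm)
  }
  cs <- colSums(tm)
  invariant <- cs == 0L | cs == nrow(tm)
  out <- tm[, !invariant, drop = FALSE]
  attr(out, "removed") <- colnames(tm)[invariant]
  out
}

#' Per-genome ortholog presence profile for a fixed pathway
#'
#' Maps presence of each required KO of a pathway across genomes and flags
#' the pathway as detected when every KO is present except those marked as
#' known-absent (orthologs systematically missing from the lineage, e.g.
#' anfG/K00531 in the Fe-Mo nitrogenase pathway and vnfH/K22899 in the
#' V-dependent pathway of cyanobacteria).
#'
#' @param kos_by_genome named list: genome_id -> KO character vector.
#' @param pathway_id pathway label.
#' @param required_kos ordered character vector of KO ids defining the pathway.
#' @param known_absent subset of `required_kos` whose absence does not
#'   prevent the detected flag.
#' @return list with `pathway_id`, `required_kos`, `known_absent`,
#'   `presence` (genomes x KOs binary matrix) and `detected` (named logical).
#' @export
pathway_ortholog_profile <- function(kos_by_genome, pathway_id, required_kos,
                                     known_absent = character(0)) {
  if (length(required_kos) == 0L) stopf("pathway '%s': empty KO list", pathway_id)
  stopifnot(all(known_absent %in% required_kos))
  presence <- t(vapply(kos_by_genome, function(k) required_kos %in% k,
                       logical(length(required_kos))))
  dimnames(presence) <- list(names(kos_by_genome), required_kos)
  must <- setdiff(required_kos, known_absent)
  detected <- if (length(must) > 0L) {
    rowSums(presence[, must, drop = FALSE]) == length(must)
  } else {
    rep(TRUE, nrow(presence))
  }
  names(detected) <- names(kos_by_genome)
  list(pathway_id = pathway_id, required_kos = required_kos,
       known_absent = known_absent, presence = presence + 0L,
       detected = detected)
}

#' Built-in nitrogen-fixation pathway KO sets
#'
#' Required orthologs of the iron-molybdenum dependent (`nif`) and
#' vanadium-dependent (`vnf`) nitrogenase pathways, with the orthologs known
#' to be systematically absent in cyanobacteria marked (`K00531` anfG for the
#' Fe-Mo pathway; `K22899` vnfH for the V pathway).
#'
#' @return named list of lists with `required_kos` and `known_absent`.
#' @export
nitrogen_fixation_pathways <- function() {
  list(
    `nif-MoFe` = list(
      ## nifH, nifD, nifK core nitrogenase + nifE, nifN, nifB cofactor
      ## biosynthesis; anfG listed but flagged known-absent
      required_kos = c("K02588", "K02586", "K02591", "K02587", "K02592",
                      "K02585", "K00531"),
      known_absent = "K00531"
    ),
    `vnf-V` = list(
      ## vnfD, vnfK, vnfG + vnfH flagged known-absent
      required_kos = c("K22896", "K22897", "K22898", "K22899"),
      known_absent = "K22899"
    )
  )
}
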