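## Synthetic study generator.
##
## Emulates the statistical structure of a phylum-scale comparative study of
## host-associated cyanobacteria at desk scale: a Yule phylogeny with
## monophyletic host-associated clades; KO annotations whose derived traits
## follow a planted logistic lifestyle effect; BGC records drawn from
## well-separated domain-set archetypes with lifestyle-dependent prevalence,
## a planted mean reduction of total BGC counts in host-associated genomes,
## annotation noise and decoy records that violate the length/edge filters.
## Every stage of the analysis pipeline can be exercised and scored against
## the emitted ground truth.

#' Default configuration for the synthetic study
#'
#' Defaults mirror the shape of a family-level host-association study:
#' 300 tips, 8 monophyletic host clades with distinct host categories, 40
#' multi-step molecular functions of which one is strongly lifestyle-linked
#' (prevalence 0.9 in host-associated vs 0.1 in free-living genomes), 30 BGC
#' archetypes of which one is similarly lifestyle-linked, and a mean
#' reduction of 4 total BGCs in host-associated genomes.
#'
#' @param n_tips number of genomes/tips.
#' @param birth_rate Yule birth rate per unit time.
#' @param n_host_clades number of planted monophyletic host clades.
#' @param host_categories host category labels assigned cyclically to clades.
#' @param qc_fail_rate fraction of genomes given failing QC statistics.
#' @param n_functions number of molecular function definitions.
#' @param planted_trait_prevalence length-2 numeric, free-living and
#'   host-associated prevalence of the planted enriched function.
#' @param phylo_signal_traits simulate null traits with Brownian-liability
#'   phylogenetic correlation instead of independent draws (default FALSE).
#' @param liability_h2 liability-scale heritability used when
#'   `phylo_signal_traits` is TRUE.
#' @param n_archetypes number of BGC domain archetypes.
#' @param planted_group_prevalence length-2 numeric, free/host prevalence of
#'   the planted enriched BGC archetype.
#' @param count_shift mean reduction of total BGC count in host-associated
#'   genomes.
#' @param domain_dropout per-domain dropout probability in emitted records.
#' @param domain_gain probability that a record gains one alien domain.
#' @param decoy_short_rate,decoy_edge_rate decoy records (too short / at a
#'   contig edge) added as a fraction of the real record count.
#' @param antismash_fraction fraction of records labelled source antismash.
#' @param edge_threshold Dice edge threshold the archetypes must be
#'   separable under.
#' @param seed integer seed (mandatory for any simulation).
#' @return a list of class `simulation_config`.
#' @export
simulation_config <- function(n_tips = 300L,
                              birth_rate = 1,
                              n_host_clades = 8L,
                              host_categories = c("lichen", "bryophyte", "cycad",
                                                  "diatom", "azolla", "haptophyte",
                                                  "fruit_tree", "macroalgae"),
                              qc_fail_rate = 0.1,
                              n_functions = 40L,
                              planted_trait_prevalence = c(0.1, 0.9),
                              phylo_signal_traits = FALSE,
                              liability_h2 = 0.5,
                              n_archetypes = 30L,
                              planted_group_prevalence = c(0.1, 0.9),
                              count_shift = 4,
                              domain_dropout = 0.05,
                              domain_gain = 0.05,
                              decoy_short_rate = 0.05,
                              decoy_edge_rate = 0.05,
                              antismash_fraction = 0.3,
                              edge_threshold = 0.5,
                              seed = 1L) {
  cfg <- as.list(environment())
  probs <- c(qc_fail_rate, planted_trait_prevalence, planted_group_prevalence,
             domain_dropout, domain_gain, decoy_short_rate, decoy_edge_rate,
             antismash_fraction, liability_h2)
  if (any(probs < 0 | probs > 1)) stopf("probabilities must lie in [0, 1]")
  if (is.null(seed)) stopf("seed must be set")
  structure(cfg, class = "simulation_config")
}

#' Simulate a Yule (pure-birth) tree
#'
#' @param n_tips number of tips (>= 2); the stopping rule yields exactly
#'   this many.
#' @param birth_rate birth rate per unit time.
#' @param seed integer seed.
#' @return a `phylo` object with tips labelled `g0001`, `g0002`, ...
#' @export
simulate_tree <- function(n_tips, birth_rate = 1, seed = 1L) {
  if (n_tips < 2L) stopf("n_tips must be at least 2")
  set.seed(as.integer(seed))
  tr <- ape::rphylo(n_tips, birth = birth_rate, death = 0)
  tr$tip.label <- sprintf("g%04d", seq_len(n_tips))
  tr
}

#' Plant monophyletic host clades on a tree
#'
#' Selects `n_host_clades` disjoint internal nodes with 2-10 tips each (by a
#' seeded shuffle of the candidates), marks all their tips host-associated
#' with one category per clade (categories assigned cyclically), and leaves
#' the remaining tips free-living. The planted labelling is recoverable by
#' [find_host_clades()] whenever adjacent clades carry distinct categories.
#'
#' @param tree a `phylo` object.
#' @param n_host_clades number of clades (0 gives all free-living tips).
#' @param host_categories category labels.
#' @param seed integer seed.
#' @param clade_size_range admissible clade tip counts (default 2-10).
#' @return named character vector over tips (`"free-living"` or a host
#'   category), with attribute `clades`: data.frame of planted clades.
#' @export
plant_host_clades <- function(tree, n_host_clades, host_categories, seed = 1L,
                              clade_size_range = c(2L, 10L)) {
  labels <- stats::setNames(rep("free-living", ape::Ntip(tree)), tree$tip.label)
  planted <- data.frame(clade_root = integer(0), host_category = character(0),
                        n_tips = integer(0), stringsAsFactors = FALSE)
  planted$member_tips <- I(list())
  if (n_host_clades == 0L) {
    attr(labels, "clades") <- planted
    return(labels)
  }
  ntip <- ape::Ntip(tree)
  internal <- (ntip + 1L):(ntip + tree$Nnode)
  tip_sets <- clade_tip_sets(tree)
  sizes <- lengths(tip_sets[internal])
  cand <- internal[sizes >= clade_size_range[1L] & sizes <= clade_size_range[2L]]
  if (length(cand) < n_host_clades)
    stopf("tree has only %d candidate clades of size %d-%d (need %d)",
          length(cand), clade_size_range[1L], clade_size_range[2L], n_host_clades)
  set.seed(as.integer(seed))
  cand <- sample(cand)
  chosen <- integer(0)
  used_tips <- integer(0)
  for (nd in cand) {
    tips_nd <- tip_sets[[nd]]
    if (length(intersect(tips_nd, used_tips)) == 0L) {
      chosen <- c(chosen, nd)
      used_tips <- c(used_tips, tips_nd)
      if (length(chosen) == n_host_clades) break
    }
  }
  if (length(chosen) < n_host_clades)
    stopf("could not place %d disjoint host clades", n_host_clades)
  cats <- rep_len(host_categories, n_host_clades)
  member_tips <- vector("list", n_host_clades)
  for (k in seq_len(n_host_clades)) {
    tips_k <- tree$tip.label[tip_sets[[chosen[k]]]]
    labels[tips_k] <- cats[k]
    member_tips[[k]] <- tips_k
  }
  planted <- data.frame(clade_root = chosen, host_category = cats,
                        n_tips = lengths(member_tips), stringsAsFactors = FALSE)
  planted$member_tips <- I(member_tips)
  attr(labels, "clades") <- planted
  labels
}

## Descendant tip indices for every node, computed in one postorder sweep.
clade_tip_sets <- function(tree) {
  ntip <- ape::Ntip(tree)
  po <- ape::reorder.phylo(tree, "postorder")
  sets <- vector("list", ntip + tree$Nnode)
  for (i in seq_len(ntip)) sets[[i]] <- i
  for (k in seq_len(nrow(po$edge))) {
    p <- po$edge[k, 1L]; ch <- po$edge[k, 2L]
    sets[[p]] <- c(sets[[p]], sets[[ch]])
  }
  sets
}

## Synthetic genome metadata consistent with the labels; a seeded fraction
## of genomes receives failing QC statistics.
simulate_metadata <- function(labels, qc_fail_rate, seed) {
  set.seed(as.integer(seed))
  n <- length(labels)
  ids <- names(labels)
  host <- labels != "free-living"
  completeness <- stats::runif(n, 92, 100)
  contamination <- stats::runif(n, 0, 4.5)
  fail <- stats::runif(n) < qc_fail_rate
  flip_comp <- stats::runif(n) < 0.5
  completeness[fail & flip_comp] <- stats::runif(sum(fail & flip_comp), 60, 90)
  contamination[fail & !flip_comp] <- stats::runif(sum(fail & !flip_comp), 5, 15)
  free_habitats <- c("freshwater", "marine", "soil")
  habitat <- ifelse(host, unname(labels),
                    rep_len(free_habitats, n))
  data.frame(
    genome_id = ids,
    completeness = round(completeness, 2),
    contamination = round(contamination, 2),
    habitat = habitat,
    lifestyle = ifelse(host, "host-associated", "free-living"),
    host_category = ifelse(host, unname(labels), NA_character_),
    stringsAsFactors = FALSE
  )
}

## Deterministic synthetic function definitions: disjoint KO pools, 3-5
## steps, steps mixing single-KO, OR and AND forms.
make_function_definitions <- function(n_functions, seed) {
  set.seed(as.integer(seed))
  ko_counter <- 50000L
  next_ko <- function() {
    ko_counter <<- ko_counter + 1L
    sprintf("K%05d", ko_counter)
  }
  defs <- vector("list", n_functions)
  exprs <- character(n_functions)
  for (f in seq_len(n_functions)) {
    n_steps <- sample(3:5, 1L)
    steps <- vapply(seq_len(n_steps), function(s) {
      form <- sample(c("single", "or", "and"), 1L)
      switch(form,
             single = next_ko(),
             or = paste(next_ko(), next_ko(), sep = ","),
             and = paste(next_ko(), next_ko(), sep = "+"))
    }, "")
    fid <- sprintf("fn%03d", f)
    exprs[f] <- paste(steps, collapse = " ")
    defs[[f]] <- parse_function_definition(exprs[f], fid,
                                           name = sprintf("synthetic function %d", f))
  }
  names(defs) <- vapply(defs, `[[`, "", "function_id")
  attr(defs, "table") <- data.frame(
    function_id = names(defs),
    name = vapply(defs, `[[`, "", "name"),
    definition = exprs,
    stringsAsFactors = FALSE
  )
  defs
}

## KOs needed to satisfy one step's expression (all leaves of the step).
step_kos <- function(defn, step) collect_kos(defn$steps[[step]])

#' Simulate per-genome KO annotations with a planted lifestyle effect
#'
#' For each function, per-genome trait presence follows
#' `logit(p) = beta0 + beta1 * host`; a present trait receives every KO of
#' the function (completeness 1), an absent trait a uniformly drawn proper
#' subset of satisfied steps (completeness strictly below 1). Function 1 is
#' the planted enriched trait; all other functions have `beta1 = 0` with
#' baseline prevalence spread over (0.15, 0.85). With
#' `phylo_signal_traits = TRUE`, null-trait draws are correlated along the
#' tree through a Brownian liability with heritability `liability_h2`.
#'
#' @param tree a `phylo` object.
#' @param labels host labels from [plant_host_clades()].
#' @param config a `simulation_config`.
#' @param definitions optional pre-built definitions (defaults to
#'   deterministic synthetic ones under the config seed).
#' @param seed integer seed.
#' @return list: `ko_table` (data.frame genome_id, gene_id, ko),
#'   `kos_by_genome` (named list), `truth` (binary genome x function matrix
#'   of planted trait presence), `effects` (per-function beta0/beta1),
#'   `definitions`.
#' @export
simulate_ko_table <- function(tree, labels, config = simulation_config(),
                              definitions = NULL, seed = config$seed) {
  defs <- definitions %||% make_function_definitions(config$n_functions, seed)
  n_fun <- length(defs)
  genomes <- tree$tip.label
  host <- as.numeric(labels[genomes] != "free-living")
  p_free <- config$planted_trait_prevalence[1L]
  p_host <- config$planted_trait_prevalence[2L]
  beta0 <- c(stats::qlogis(p_free),
             stats::qlogis(seq(0.15, 0.85, length.out = max(n_fun - 1L, 1L))))[seq_len(n_fun)]
  beta1 <- c(stats::qlogis(p_host) - stats::qlogis(p_free), rep(0, n_fun - 1L))
  set.seed(as.integer(seed) + 1L)
  truth <- matrix(0L, length(genomes), n_fun,
                  dimnames = list(genomes, names(defs)))
  kos_by_genome <- stats::setNames(vector("list", length(genomes)), genomes)
  for (f in seq_len(n_fun)) {
    p <- stats::plogis(beta0[f] + beta1[f] * host)
    if (config$phylo_signal_traits && beta1[f] == 0) {
      bm <- brownian_tips(tree)
      liab <- sqrt(config$liability_h2) * (bm - mean(bm)) / stats::sd(bm) +
        sqrt(1 - config$liability_h2) * stats::rnorm(length(genomes))
      z <- as.integer(stats::pnorm(liab) < p)
    } else {
      z <- stats::rbinom(length(genomes), 1L, p)
    }
    truth[, f] <- z
    defn <- defs[[f]]
    n_steps <- length(defn$steps)
    for (i in seq_along(genomes)) {
      if (z[i] == 1L) {
        kos_by_genome[[i]] <- c(kos_by_genome[[i]], defn$kos)
      } else {
        n_sat <- sample(0:(n_steps - 1L), 1L)
        if (n_sat > 0L) {
          sat <- sample(n_steps, n_sat)
          kos_by_genome[[i]] <- c(kos_by_genome[[i]],
                                  unlist(lapply(sat, step_kos, defn = defn)))
        }
      }
    }
  }
  kos_by_genome <- lapply(kos_by_genome, function(k) sort(unique(k %||% character(0))))
  ko_table <- do.call(rbind, lapply(genomes, function(g) {
    kos <- kos_by_genome[[g]]
    if (length(kos) == 0L) return(NULL)
    data.frame(genome_id = g,
               gene_id = sprintf("%s_%05d", g, seq_along(kos)),
               ko = kos, stringsAsFactors = FALSE)
  }))
  list(ko_table = ko_table, kos_by_genome = kos_by_genome, truth = truth,
       effects = data.frame(function_id = names(defs), beta0 = beta0,
                            beta1 = beta1, stringsAsFactors = FALSE),
       definitions = defs)
}

## Deterministic archetype construction: disjoint domain pools, classes
## assigned cyclically, free-living prevalences spread over (0.15, 0.45).
make_bgc_archetypes <- function(config, seed) {
  set.seed(as.integer(seed) + 2L)
  n <- config$n_archetypes
  classes <- c("NRP", "polyketide", "RiPP", "terpene", "alkaloid",
               "saccharide", "other", "NRP+polyketide")
  sizes <- sample(5:30, n, replace = TRUE)
  counter <- 0L
  domains <- lapply(sizes, function(s) {
    out <- sprintf("PF%05d", counter + seq_len(s))
    counter <<- counter + s
    out
  })
  p_free <- c(config$planted_group_prevalence[1L],
              seq(0.15, 0.45, length.out = n - 1L))
  ## host prevalences: planted archetype enriched; the rest scaled uniformly
  ## so the expected host total is the free total minus count_shift
  p_host <- p_free
  p_host[1L] <- config$planted_group_prevalence[2L]
  s_free_rest <- sum(p_free[-1L])
  target_rest <- s_free_rest + p_free[1L] - config$count_shift - p_host[1L]
  if (target_rest < 0) stopf("count_shift too large for archetype prevalences")
  p_host[-1L] <- p_free[-1L] * target_rest / s_free_rest
  data.frame(
    archetype_id = sprintf("arch%02d", seq_len(n)),
    class = rep_len(classes, n),
    prevalence_free = p_free,
    prevalence_host = p_host,
    size = sizes,
    domains = I(domains),
    stringsAsFactors = FALSE
  )
}

#' Simulate BGC prediction records with planted group structure
#'
#' Per genome, archetype memberships are Bernoulli draws with
#' lifestyle-dependent prevalence (the host-associated rates are scaled so
#' the expected total count drops by `count_shift`). Each membership yields
#' a record carrying the archetype's domain set under dropout/gain noise;
#' decoy records violating the length and contig-edge filters are appended;
#' a seeded fraction of records carries source `antismash`.
#'
#' @inheritParams simulate_ko_table
#' @return list: `records` (BGC data.frame), `contig_lengths` (named
#'   vector), `truth` (data.frame bgc_id, archetype_id, decoy),
#'   `archetypes` (data.frame).
#' @export
simulate_bgc_records <- function(tree, labels, config = simulation_config(),
                                 seed = config$seed) {
  archetypes <- make_bgc_archetypes(config, seed)
  ## planted separability: pairwise Dice must stay below the edge threshold
  for (a in seq_len(min(5L, nrow(archetypes) - 1L))) {
    d <- dice_similarity(archetypes$domains[[a]], archetypes$domains[[a + 1L]])
    stopifnot(d < config$edge_threshold)
  }
  genomes <- tree$tip.label
  host <- labels[genomes] != "free-living"
  set.seed(as.integer(seed) + 3L)
  alien_pool <- sprintf("PF9%04d", seq_len(500L))
  rows <- list()
  truth_rows <- list()
  counter <- 0L
  for (i in seq_along(genomes)) {
    g <- genomes[i]
    prev <- if (host[i]) archetypes$prevalence_host else archetypes$prevalence_free
    member <- which(stats::rbinom(nrow(archetypes), 1L, prev) == 1L)
    pos <- 5000
    for (a in member) {
      counter <- counter + 1L
      dom <- archetypes$domains[[a]]
      keep <- stats::runif(length(dom)) >= config$domain_dropout
      if (!any(keep)) keep[sample(length(dom), 1L)] <- TRUE
      dom <- dom[keep]
      if (stats::runif(1L) < config$domain_gain)
        dom <- c(dom, sample(alien_pool, 1L))
      len <- 3000 + 400 * length(dom)
      bgc_id <- sprintf("bgc%06d", counter)
      rows[[counter]] <- data.frame(
        bgc_id = bgc_id, genome_id = g, contig_id = paste0("ctg_", g),
        start = pos, end = pos + len - 1, strand = "+",
        predicted_class = archetypes$class[a],
        domains = paste(dom, collapse = ";"),
        source = if (stats::runif(1L) < config$antismash_fraction) "antismash" else "sanntis",
        stringsAsFactors = FALSE
      )
      truth_rows[[counter]] <- data.frame(bgc_id = bgc_id,
                                          archetype_id = archetypes$archetype_id[a],
                                          decoy = "none", stringsAsFactors = FALSE)
      pos <- pos + len + 1000
    }
  }
  n_real <- counter
  n_short <- round(config$decoy_short_rate * n_real)
  n_edge <- round(config$decoy_edge_rate * n_real)
  decoy_pool <- sprintf("PF8%04d", seq_len(200L))
  add_decoy <- function(kind) {
    counter <<- counter + 1L
    g <- genomes[1L + (counter %% length(genomes))]
    dom <- sample(decoy_pool, sample(5:10, 1L))
    if (kind == "short") {
      len <- sample(1000:2999, 1L); start <- 50000 + counter * 10000
    } else {
      len <- sample(3000:8000, 1L); start <- 1
    }
    bgc_id <- sprintf("bgc%06d", counter)
    rows[[counter]] <<- data.frame(
      bgc_id = bgc_id, genome_id = g, contig_id = paste0("ctg_", g),
      start = start, end = start + len - 1, strand = "+",
      predicted_class = "other", domains = paste(dom, collapse = ";"),
      source = "sanntis", stringsAsFactors = FALSE
    )
    truth_rows[[counter]] <<- data.frame(bgc_id = bgc_id,
                                         archetype_id = NA_character_,
                                         decoy = kind, stringsAsFactors = FALSE)
  }
  for (k in seq_len(n_short)) add_decoy("short")
  for (k in seq_len(n_edge)) add_decoy("edge")
  records <- do.call(rbind, rows)
  truth <- do.call(rbind, truth_rows)
  contig_lengths <- stats::setNames(rep(1e7, length(genomes)),
                                    paste0("ctg_", genomes))
  list(records = validate_bgc_table(records, where = "simulated records"),
       contig_lengths = contig_lengths, truth = truth, archetypes = archetypes)
}

#' Simulate a complete synthetic study
#'
#' Runs the full generator under one configuration: tree, host clades,
#' metadata, KO annotations and BGC records, with all ground truth attached.
#'
#' @param config a `simulation_config`.
#' @return list of class `synthetic_study` with elements `config`, `tree`,
#'   `labels`, `clades`, `metadata`, `ko` and `bgc` (generator outputs).
#' @export
simulate_study <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  tree <- simulate_tree(config$n_tips, config$birth_rate, config$seed)
  labels <- plant_host_clades(tree, config$n_host_clades,
                              config$host_categories, seed = config$seed)
  metadata <- simulate_metadata(labels, config$qc_fail_rate,
                                seed = config$seed + 4L)
  ko <- simulate_ko_table(tree, labels, config)
  bgc <- simulate_bgc_records(tree, labels, config)
  structure(list(config = config, tree = tree, labels = labels,
                 clades = attr(labels, "clades"), metadata = metadata,
                 ko = ko, bgc = bgc),
            class = "synthetic_study")
}

#' Write a synthetic study to disk as a fixture bundle
#'
#' Emits exactly the formats the readers consume: Newick tree, metadata TSV,
#' KO TSV, function definition TSV, BGC TSV, contig-length TSV, the ground
#' truth tables and the configuration (JSON). Deterministic under the
#' configuration seed.
#'
#' @param study a `synthetic_study` from [simulate_study()].
#' @param outdir output directory (created if absent).
#' @return named character vector of written paths, invisibly.
#' @export
write_fixture_bundle <- function(study, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    tree = file.path(outdir, "tree.nwk"),
    metadata = file.path(outdir, "metadata.tsv"),
    ko = file.path(outdir, "ko_annotations.tsv"),
    definitions = file.path(outdir, "function_definitions.tsv"),
    bgc = file.path(outdir, "bgc_records.tsv"),
    contigs = file.path(outdir, "contig_lengths.tsv"),
    truth_traits = file.path(outdir, "truth_traits.tsv"),
    truth_bgc = file.path(outdir, "truth_bgc_groups.tsv"),
    config = file.path(outdir, "config.json")
  )
  write_newick(study$tree, paths[["tree"]])
  write_results_table(study$metadata, paths[["metadata"]])
  write_results_table(study$ko$ko_table, paths[["ko"]])
  write_results_table(attr(study$ko$definitions, "table"), paths[["definitions"]])
  write_results_table(study$bgc$records, paths[["bgc"]])
  write_results_table(
    data.frame(contig_id = names(study$bgc$contig_lengths),
               length = unname(study$bgc$contig_lengths)),
    paths[["contigs"]])
  tt <- as.data.frame(study$ko$truth)
  tt <- cbind(genome_id = rownames(study$ko$truth), tt)
  write_results_table(tt, paths[["truth_traits"]])
  write_results_table(study$bgc$truth, paths[["truth_bgc"]])
  cfg <- unclass(study$config)
  jsonlite::write_json(cfg, paths[["config"]], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
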