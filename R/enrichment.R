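## Enrichment scans: one phylogenetic regression per trait or count column.
##
## Binary traits (KEGG functions at a completeness threshold, BGC-group
## presence) are tested with Firth-penalised phylogenetic logistic
## regression; per-genome BGC counts with the lambda-covariance linear
## model. The significance rule is an uncorrected p < alpha_level, matching
## common practice for these screens; a Benjamini-Hochberg column is emitted
## for transparency but does not drive the flag.

#' Scan a binary trait matrix for lifestyle enrichment
#'
#' Fits `trait ~ predictor` with [phyloglm_firth()] for every column of the
#' trait matrix. The predictor's first level is the baseline (for a
#' lifestyle factor, set levels so `free-living` comes first; positive
#' estimates then mean enrichment in the host-associated level). Traits
#' whose fit fails are flagged `converged = FALSE` and kept in the output.
#'
#' @param tm binary genome x trait matrix (pass through
#'   [drop_invariant_traits()] first).
#' @param predictor named factor/character over the genomes (two or more
#'   levels).
#' @param tree phylogeny covering the genomes.
#' @param alpha_level significance level for the flag (default 0.05).
#' @param B bootstrap replicates per trait (default 100).
#' @param seed global seed; each trait uses a seed derived from it and the
#'   trait id, so results do not depend on scan order.
#' @param headline which p-value drives the significance flag:
#'   `"boot"` (default) or `"wald"`.
#' @return data.frame with one row per trait: estimate, se, p_wald, p_boot,
#'   p_bh (Benjamini-Hochberg on the headline p), significant, direction,
#'   alpha, converged.
#' @export
enrichment_scan <- function(tm, predictor, tree, alpha_level = 0.05, B = 100L,
                            seed = 1L, headline = c("boot", "wald")) {
  headline <- match.arg(headline)
  genomes <- rownames(tm)
  pred <- prepare_predictor(predictor, genomes)
  if (length(unique(pred)) < 2L) stopf("predictor is constant")
  rows <- lapply(colnames(tm), function(trait_id) {
    dat <- data.frame(.trait = tm[, trait_id], .pred = pred,
                      row.names = genomes)
    fit <- tryCatch(
      phyloglm_firth(.trait ~ .pred, dat, tree, B = B,
                     seed = derive_seed(seed, trait_id)),
      error = function(e) e
    )
    if (inherits(fit, "error")) {
      return(data.frame(trait_id = trait_id, estimate = NA_real_, se = NA_real_,
                        p_wald = NA_real_, p_boot = NA_real_, alpha = NA_real_,
                        converged = FALSE, note = conditionMessage(fit),
                        stringsAsFactors = FALSE))
    }
    k <- 2L  # coefficient of the non-baseline predictor level
    data.frame(trait_id = trait_id,
               estimate = unname(fit$coefficients[k]),
               se = unname(fit$se[k]),
               p_wald = unname(fit$p_wald[k]),
               p_boot = unname(fit$p_boot[k]),
               alpha = fit$alpha,
               converged = fit$converged,
               note = if (fit$separation) "separation" else "",
               stringsAsFactors = FALSE)
  })
  finalize_scan(do.call(rbind, rows), alpha_level, headline)
}

#' Scan per-genome BGC counts for lifestyle enrichment
#'
#' Fits `count ~ predictor` with [phylolm_lambda()] for the total and each
#' BGC class column of a count table; estimates are on the raw count scale.
#' Degenerate columns (zero variance) are flagged and excluded from the
#' significance report but kept as rows.
#'
#' @param counts genome x (total + classes) count matrix from
#'   [bgc_count_table()].
#' @inheritParams enrichment_scan
#' @return data.frame with one row per count column: estimate, se, p_wald,
#'   p_boot, p_bh, significant, direction, lambda, converged.
#' @export
count_enrichment_scan <- function(counts, predictor, tree, alpha_level = 0.05,
                                  B = 100L, seed = 1L,
                                  headline = c("boot", "wald")) {
  headline <- match.arg(headline)
  genomes <- rownames(counts)
  pred <- prepare_predictor(predictor, genomes)
  if (length(unique(pred)) < 2L) stopf("predictor is constant")
  rows <- lapply(colnames(counts), function(cl) {
    yv <- counts[, cl]
    if (stats::var(yv) == 0) {
      return(data.frame(trait_id = cl, estimate = NA_real_, se = NA_real_,
                        p_wald = NA_real_, p_boot = NA_real_,
                        lambda = NA_real_, converged = FALSE,
                        note = "degenerate (constant counts)",
                        stringsAsFactors = FALSE))
    }
    dat <- data.frame(.count = yv, .pred = pred, row.names = genomes)
    fit <- tryCatch(
      phylolm_lambda(.count ~ .pred, dat, tree, B = B,
                     seed = derive_seed(seed, cl)),
      error = function(e) e
    )
    if (inherits(fit, "error")) {
      return(data.frame(trait_id = cl, estimate = NA_real_, se = NA_real_,
                        p_wald = NA_real_, p_boot = NA_real_,
                        lambda = NA_real_, converged = FALSE,
                        note = conditionMessage(fit), stringsAsFactors = FALSE))
    }
    k <- 2L
    data.frame(trait_id = cl,
               estimate = unname(fit$coefficients[k]),
               se = unname(fit$se[k]),
               p_wald = unname(fit$p_wald[k]),
               p_boot = unname(fit$p_boot[k]),
               lambda = fit$lambda,
               converged = TRUE,
               note = "",
               stringsAsFactors = FALSE)
  })
  finalize_scan(do.call(rbind, rows), alpha_level, headline)
}

prepare_predictor <- function(predictor, genomes) {
  if (!is.null(names(predictor))) {
    missing <- setdiff(genomes, names(predictor))
    if (length(missing) > 0L)
      stopf("predictor missing for genome(s): %s",
            paste(utils::head(missing, 5L), collapse = ", "))
    predictor <- predictor[genomes]
  } else if (length(predictor) != length(genomes)) {
    stopf("predictor length does not match genomes")
  }
  if (is.character(predictor)) predictor <- factor(predictor)
  droplevels(as.factor(predictor))
}

finalize_scan <- function(out, alpha_level, headline) {
  p_head <- if (headline == "boot") out$p_boot else out$p_wald
  ## fall back to the Wald p where the bootstrap was skipped (B = 0)
  p_head <- ifelse(is.na(p_head), out$p_wald, p_head)
  out$p_bh <- stats::p.adjust(p_head, method = "BH")
  out$significant <- !is.na(p_head) & out$converged & p_head < alpha_level
  out$direction <- ifelse(is.na(out$estimate), NA_character_,
                          ifelse(out$estimate > 0, "enriched", "depleted"))
  rownames(out) <- NULL
  out
}
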