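# Intramolecular epistasis: interaction strength of mutation pairs relative
# to the additive model, compensatory-pair classification against the
# wild-type structure, and the enrichment statistics (same-stem-loop
# membership of strong interactions; structural looseness of the
# seed-carrying stem-loop among efficient variants).

#' Interaction strength of a double mutant
#'
#' IS = ln(f_obs / f_add): the log-ratio between the measured efficiency of
#' a double mutant and its additive-model prediction. Positive IS means the
#' mutant is stronger than predicted (synergistic), negative weaker
#' (antagonistic). The standard error propagates the double-mutant
#' measurement and the three measurements behind the additive prediction
#' (two single mutants and the wild type).
#'
#' @param f_obs measured fold-change of the double mutant (> 0).
#' @param f_add additive-model predicted fold-change (> 0).
#' @param se_log_f_obs standard error of ln f_obs.
#' @param se_log_f_add standard error of ln f_add (error-propagated from the
#'   single-mutant and wild-type records).
#' @return list with `IS`, `se_IS`, `z`.
#' @export
interaction_strength <- function(f_obs, f_add, se_log_f_obs = NA,
                                 se_log_f_add = NA) {
  if (any(c(f_obs, f_add) <= 0)) stop("fold-changes must be positive")
  IS <- log(f_obs) - log(f_add)
  se <- sqrt(se_log_f_obs^2 + se_log_f_add^2)
  list(IS = IS, se_IS = se, z = IS / se)
}

# se of ln f from a record's se_S and u: d ln f / dS = -(1 - u)
se_log_f <- function(se_S, u) (1 - u) * se_S

#' Interaction table over all exact double mutants
#'
#' Builds one interaction record per double-mutation variant: only exact
#' two-mutation variants define IS (pairs observed inside higher-order
#' backgrounds are not pooled). Requires both single mutants to be trained
#' in the additive model. Significance: |z| against `z_threshold`, with
#' Benjamini-Hochberg FDR reported alongside.
#'
#' @param records data.frame from [infer_efficiencies()].
#' @param model an `additive_model`.
#' @param reference a `reference_srna`.
#' @param z_threshold |z| needed for a non-"none" sign class (default 3).
#' @return data.frame: variant_key, mut_a, mut_b, pos_a, pos_b, f_obs,
#'   f_add, IS, se_IS, z, p_bh, sign_class, compensatory, same_stem_loop.
#' @export
interaction_table <- function(records, model, reference, z_threshold = 3) {
  keep <- key_n_mutations(records$variant_key) == 2L & is.finite(records$S)
  if ("censored" %in% names(records)) keep <- keep & !records$censored %in% TRUE
  if ("clamped" %in% names(records)) keep <- keep & !records$clamped %in% TRUE
  doubles <- records[keep, , drop = FALSE]
  rows <- lapply(seq_len(nrow(doubles)), function(i) {
    key <- doubles$variant_key[i]
    v <- parse_variant_key(key, reference)
    idx <- cbind(v$pos, match(v$alt, RNA_BASES))
    if (any(model$mask[idx])) return(NULL) # untrained single mutant
    pred <- predict_additive(model, key, reference)
    u_add <- pred$u_pred
    se_add <- se_log_f(pred$se_S_add, u_add)
    se_obs <- se_log_f(doubles$se_S[i], doubles$u[i])
    ist <- interaction_strength(doubles$f[i], pred$f_pred, se_obs, se_add)
    data.frame(variant_key = key,
               mut_a = paste0(v$ref[1], v$pos[1], v$alt[1]),
               mut_b = paste0(v$ref[2], v$pos[2], v$alt[2]),
               pos_a = v$pos[1], pos_b = v$pos[2],
               f_obs = doubles$f[i], f_add = pred$f_pred,
               IS = ist$IS, se_IS = ist$se_IS, z = ist$z,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out) || nrow(out) == 0) {
    stop("no usable double-mutant records with trained single mutants")
  }
  out$p <- 2 * stats::pnorm(-abs(out$z))
  out$p_bh <- stats::p.adjust(out$p, method = "BH")
  out$sign_class <- ifelse(abs(out$z) < z_threshold, "none",
                           ifelse(out$IS > 0, "synergistic", "antagonistic"))
  out$compensatory <- vapply(seq_len(nrow(out)), function(i) {
    classify_compensatory(out$pos_a[i], substr(out$mut_a[i],
                                               nchar(out$mut_a[i]),
                                               nchar(out$mut_a[i])),
                          out$pos_b[i], substr(out$mut_b[i],
                                               nchar(out$mut_b[i]),
                                               nchar(out$mut_b[i])),
                          reference)
  }, TRUE)
  sl_a <- stem_loop_of(reference, out$pos_a)
  sl_b <- stem_loop_of(reference, out$pos_b)
  out$same_stem_loop <- !is.na(sl_a) & !is.na(sl_b) & sl_a == sl_b
  out
}

#' Is a mutation pair compensatory?
#'
#' TRUE iff the two positions are paired in the wild-type structure, each
#' mutation alone breaks that pairing, and the double mutation restores a
#' Watson-Crick pair. A single mutation that converts a WC pair into a GU
#' wobble is treated as retaining pairing (functional seeds tolerate a
#' single GU wobble), so such pairs are not compensatory. Symmetric in the
#' two mutations.
#'
#' @param pos_a,alt_a first mutation (1-based position, substituted base).
#' @param pos_b,alt_b second mutation.
#' @param reference a `reference_srna`.
#' @return logical flag.
#' @export
classify_compensatory <- function(pos_a, alt_a, pos_b, alt_b, reference) {
  if (pos_a == pos_b) stop("pair positions must be distinct")
  if (reference$pairs[pos_a] != pos_b) return(FALSE)
  # orient as (5' base, 3' base) of the wild-type pair
  if (pos_a > pos_b) {
    tmp <- pos_a; pos_a <- pos_b; pos_b <- tmp
    tmp <- alt_a; alt_a <- alt_b; alt_b <- tmp
  }
  wt_a <- reference$bases[pos_a]
  wt_b <- reference$bases[pos_b]
  breaks_a <- !can_pair_bases(alt_a, wt_b) # GU wobble counts as retained
  breaks_b <- !can_pair_bases(wt_a, alt_b)
  restores <- is_wc_pair(alt_a, alt_b)
  breaks_a && breaks_b && restores
}

#' Top-k interactions ranked by significance
#'
#' Descending |z|; deterministic tie-break by |IS| descending, then the
#' lexicographic variant key.
#'
#' @param interactions data.frame from [interaction_table()].
#' @param k number of records to return (default 150).
#' @return the top-k rows, with a `rank` column.
#' @export
top_interactions <- function(interactions, k = 150) {
  if (k > nrow(interactions)) {
    warning("k exceeds available records; returning all ", nrow(interactions))
    k <- nrow(interactions)
  }
  o <- order(-abs(interactions$z), -abs(interactions$IS),
             interactions$variant_key)
  out <- interactions[o[seq_len(k)], , drop = FALSE]
  if (k > 0) out$rank <- seq_len(k)
  out
}

#' Same-stem-loop enrichment of the strongest interactions
#'
#' 2x2 contingency of {in top-k vs not} x {both mutations inside one
#' annotated stem-loop vs not}, with the one-sided (enrichment) Fisher exact
#' test -- the hypergeometric tail.
#'
#' @param top ranked list from [top_interactions()].
#' @param all_pairs full table from [interaction_table()].
#' @param alternative "greater" (enrichment, default) or "two.sided".
#' @return list with `table` (2x2 matrix), `odds_ratio`, `p`,
#'   `frac_top` and `frac_rest` same-stem-loop fractions.
#' @export
enrichment_same_stemloop <- function(top, all_pairs,
                                     alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  in_top <- all_pairs$variant_key %in% top$variant_key
  tab <- matrix(c(sum(in_top & all_pairs$same_stem_loop),
                  sum(in_top & !all_pairs$same_stem_loop),
                  sum(!in_top & all_pairs$same_stem_loop),
                  sum(!in_top & !all_pairs$same_stem_loop)),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("top", "rest"), c("same_sl", "other")))
  ft <- stats::fisher.test(tab, alternative = alternative)
  list(table = tab, odds_ratio = unname(ft$estimate), p = ft$p.value,
       frac_top = tab[1, 1] / sum(tab[1, ]),
       frac_rest = tab[2, 1] / sum(tab[2, ]))
}

#' Fraction of loose-structure variants above an efficiency threshold
#'
#' For each threshold t: among variants with fold-change >= t, what fraction
#' carry a "loose" seed stem-loop (self-folding ddG > 0)? One-sided Fisher
#' exact p compares {f >= t vs f < t} x {loose vs tight}; the overall loose
#' fraction is the baseline the curve should revert to at low thresholds.
#'
#' @param records data.frame with `f` (fold-change efficiency).
#' @param loose_flags logical vector aligned with `records`.
#' @param thresholds fold-change grid (default: quantile-spanning grid).
#' @return list with `curve` (data.frame threshold, n_above, frac_loose, p)
#'   and `baseline` (overall loose fraction).
#' @export
loose_enrichment_curve <- function(records, loose_flags, thresholds = NULL) {
  ok <- is.finite(records$f) & !is.na(loose_flags)
  f <- records$f[ok]; loose <- loose_flags[ok]
  if (is.null(thresholds)) {
    thresholds <- stats::quantile(f, seq(0.05, 0.95, by = 0.05), names = FALSE)
  }
  if (length(thresholds) == 0) stop("empty threshold grid")
  rows <- lapply(thresholds, function(t) {
    above <- f >= t
    tab <- matrix(c(sum(above & loose), sum(above & !loose),
                    sum(!above & loose), sum(!above & !loose)), 2,
                  byrow = TRUE)
    p <- if (any(rowSums(tab) == 0)) 1
         else stats::fisher.test(tab, alternative = "greater")$p.value
    data.frame(threshold = t, n_above = sum(above),
               frac_loose = if (sum(above) > 0) mean(loose[above]) else NA_real_,
               p = p)
  })
  list(curve = do.call(rbind, rows), baseline = mean(loose))
}

#' Variants that maintain efficiency despite a devastating seed mutation
#'
#' Selects variants carrying at least one seed-region mutation whose
#' single-mutant efficiency (from the additive model's training records)
#' falls below `devastation_cutoff`, yet whose own measured efficiency is at
#' least `maintenance_cutoff`.
#'
#' @param records data.frame from [infer_efficiencies()].
#' @param model an `additive_model` (supplies single-mutant energies).
#' @param reference a `reference_srna`.
#' @param target target whose seed interval defines the seed region.
#' @param devastation_cutoff fold-change below which a single seed mutation
#'   counts as devastating.
#' @param maintenance_cutoff fold-change the variant must still reach.
#' @return subset of `records` rows (possibly empty), with a
#'   `devastating_seed_mut` column naming the mutation.
#' @export
seed_rescue_subset <- function(records, model, reference,
                               target = names(reference$targets)[1],
                               devastation_cutoff = 2,
                               maintenance_cutoff = 5) {
  if (devastation_cutoff > maintenance_cutoff) {
    stop("devastation_cutoff must not exceed maintenance_cutoff")
  }
  iv <- reference$targets[[target]]$srna_seed_interval
  # single-mutant fold-change from the additive model entries
  single_f <- function(pos, alt) {
    if (model$mask[pos, alt]) return(NA_real_)
    1 / stats::plogis(model$S_WT + model$delta_S[pos, alt])
  }
  keep <- logical(nrow(records))
  dev_mut <- character(nrow(records))
  for (i in seq_len(nrow(records))) {
    key <- records$variant_key[i]
    if (key %in% c(WT_KEY, EMPTY_VECTOR_KEY)) next
    if (!is.finite(records$f[i]) || records$f[i] < maintenance_cutoff) next
    v <- parse_variant_key(key, reference)
    in_seed <- which(v$pos >= iv[1] & v$pos <= iv[2])
    for (j in in_seed) {
      fj <- single_f(v$pos[j], v$alt[j])
      if (is.finite(fj) && fj < devastation_cutoff) {
        keep[i] <- TRUE
        dev_mut[i] <- paste0(v$ref[j], v$pos[j], v$alt[j])
        break
      }
    }
  }
  out <- records[keep, , drop = FALSE]
  out$devastating_seed_mut <- dev_mut[keep]
  out
}

#' Write an interaction table as TSV
#'
#' @param interactions data.frame from [interaction_table()].
#' @param path TSV path.
#' @return `path`, invisibly.
#' @export
write_interactions <- function(interactions, path) {
  utils::write.table(interactions, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
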