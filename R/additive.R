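# Additive position-weight energy model: the two-state energy of a
# multi-mutation variant is the wild-type energy plus independent
# per-mutation energy changes measured from single-mutant variants,
#   S_add = S_WT + sum_j dS[j, sigma_j],
# with dS = 0 at the wild-type base of each position. Full single-mutant
# coverage of an L-nt sRNA gives 3L + 1 free parameters.

#' Fit the additive model from efficiency records
#'
#' S_WT comes from the wild-type record; each dS entry is S(single mutant)
#' minus S_WT. Entries with no measured single mutant are masked; censored
#' or clamped records are excluded from training by default (their S is not
#' trusted).
#'
#' @param records data.frame from [infer_efficiencies()] (needs
#'   `variant_key`, `S`, `se_S`, `censored`).
#' @param reference a `reference_srna`.
#' @param exclude_censored drop censored single-mutant records (clamped
#'   records are kept: their S is pinned to the clamp boundary but defined).
#' @return object of class `additive_model`: `S_WT`, `se_S_WT`, `delta_S`
#'   (L x 4), `se_delta_S`, `mask` (TRUE = unavailable non-wild-type entry),
#'   `provenance` (training key per entry), `n_params`.
#' @export
fit_additive <- function(records, reference, exclude_censored = TRUE) {
  i_wt <- match(WT_KEY, records$variant_key)
  if (is.na(i_wt) || !is.finite(records$S[i_wt])) {
    stop("records lack a usable wild-type row")
  }
  S_WT <- records$S[i_wt]
  se_WT <- if ("se_S" %in% names(records)) records$se_S[i_wt] else NA_real_
  L <- reference$length
  dS <- matrix(NA_real_, L, 4, dimnames = list(NULL, RNA_BASES))
  seS <- matrix(NA_real_, L, 4, dimnames = list(NULL, RNA_BASES))
  prov <- matrix(NA_character_, L, 4, dimnames = list(NULL, RNA_BASES))
  singles <- records[key_n_mutations(records$variant_key) == 1L &
                       !records$variant_key %in% c(WT_KEY, EMPTY_VECTOR_KEY), ,
                     drop = FALSE]
  if (exclude_censored && "censored" %in% names(singles)) {
    singles <- singles[!singles$censored %in% TRUE, , drop = FALSE]
  }
  for (i in seq_len(nrow(singles))) {
    if (!is.finite(singles$S[i])) next
    v <- parse_variant_key(singles$variant_key[i], reference)
    dS[v$pos, v$alt] <- singles$S[i] - S_WT
    if ("se_S" %in% names(singles)) {
      seS[v$pos, v$alt] <- sqrt(singles$se_S[i]^2 + se_WT^2)
    }
    prov[v$pos, v$alt] <- singles$variant_key[i]
  }
  wt_idx <- cbind(seq_len(L), match(reference$bases, RNA_BASES))
  dS[wt_idx] <- 0
  mask <- is.na(dS)
  structure(
    list(S_WT = S_WT, se_S_WT = se_WT, delta_S = dS, se_delta_S = seS,
         mask = mask, provenance = prov,
         n_params = sum(!mask) - L + 1L, # trained non-WT entries + S_WT
         reference_name = reference$name, L = L),
    class = "additive_model"
  )
}

#' @export
print.additive_model <- function(x, ...) {
  cat("<additive_model> ", x$reference_name, ": ", x$n_params,
      " parameters (", sum(!x$mask) - x$L, " trained dS entries + S_WT), ",
      sum(x$mask), " masked\n", sep = "")
  invisible(x)
}

#' Number of free parameters of an additive model
#'
#' Trained non-wild-type dS entries plus the wild-type energy; 3L + 1 at
#' full single-mutant coverage.
#'
#' @param model an `additive_model`.
#' @return integer count.
#' @export
additive_n_parameters <- function(model) model$n_params

#' Predict a variant's energy and efficiency under the additive model
#'
#' Fails loudly when an unmeasured (masked) entry is required; pass
#' `impute_zero = TRUE` to score arbitrary substitution sets (e.g. homolog
#' sequences) with missing entries treated as neutral.
#'
#' @param model an `additive_model`.
#' @param v an `srna_variant`, canonical key, or list of either.
#' @param reference a `reference_srna` (to parse keys).
#' @param mode fold-change convention for `f_pred`.
#' @param impute_zero treat masked entries as dS = 0 instead of erroring.
#' @return data.frame with `variant_key`, `S_add`, `u_pred`, `f_pred`,
#'   `se_S_add` (error-propagated over the contributing measurements).
#' @export
predict_additive <- function(model, v, reference,
                             mode = c("repressed", "activated"),
                             impute_zero = FALSE) {
  mode <- match.arg(mode)
  if (inherits(v, "srna_variant")) v <- list(v)
  else if (is.character(v)) v <- as.list(v)
  rows <- lapply(v, function(vi) {
    if (is.character(vi)) vi <- parse_variant_key(vi, reference)
    S <- model$S_WT
    var_S <- if (is.finite(model$se_S_WT)) model$se_S_WT^2 else 0
    if (length(vi$pos) > 0) {
      idx <- cbind(vi$pos, match(vi$alt, RNA_BASES))
      masked <- model$mask[idx]
      if (any(masked) && !impute_zero) {
        stop("no measured single mutant for: ",
             paste0(vi$ref[masked], vi$pos[masked], vi$alt[masked],
                    collapse = ", "))
      }
      contrib <- model$delta_S[idx]
      contrib[is.na(contrib)] <- 0
      S <- S + sum(contrib)
      ses <- model$se_delta_S[idx]
      var_S <- var_S + sum(ses[is.finite(ses)]^2)
    }
    u <- stats::plogis(S)
    data.frame(variant_key = vi$key, S_add = S, u_pred = u, f_pred = 1 / u,
               se_S_add = sqrt(var_S), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Serialize / load an additive model as TSV + YAML header
#'
#' The dS matrix goes to TSV (position, wild-type base, one column per
#' base; NA = masked); S_WT and provenance go to a YAML sidecar.
#'
#' @param model an `additive_model`.
#' @param path TSV path (`<path>.meta.yaml` sidecar written alongside).
#' @return `path` / the model.
#' @export
write_additive <- function(model, path) {
  df <- data.frame(position = seq_len(model$L), model$delta_S,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  yaml::write_yaml(list(S_WT = model$S_WT, se_S_WT = model$se_S_WT,
                        reference_name = model$reference_name,
                        n_params = model$n_params),
                   paste0(path, ".meta.yaml"), precision = 15)
  invisible(path)
}

#' @rdname write_additive
#' @export
read_additive <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  meta <- yaml::read_yaml(paste0(path, ".meta.yaml"))
  dS <- as.matrix(df[RNA_BASES])
  L <- nrow(dS)
  structure(
    list(S_WT = meta$S_WT, se_S_WT = meta$se_S_WT, delta_S = dS,
         se_delta_S = matrix(NA_real_, L, 4, dimnames = list(NULL, RNA_BASES)),
         mask = is.na(dS), provenance = NULL,
         n_params = meta$n_params, reference_name = meta$reference_name,
         L = L),
    class = "additive_model"
  )
}
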