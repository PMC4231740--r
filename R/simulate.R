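# Synthetic sort-seq data generator. Emulates the statistical structure the
# downstream analysis assumes: mutagenesis-PCR libraries with ~2-3
# substitutions per variant and a transition-biased spectrum, 50-70 cells per
# variant, log-normal single-cell fluorescence, sorting into 4-6 log-evenly
# spaced gates covering ~90% of cells, and one multinomial sequencing draw
# per bin.

#' Default transition-biased substitution spectrum
#'
#' Rows are the reference base, columns the substituted base; zero diagonal,
#' rows sum to 1. Transitions (A<->G, C<->U) get `ti_weight` times the weight
#' of each transversion, emulating the strong transition preference of
#' mutagenesis PCR.
#'
#' @param ti_weight transition:transversion weight ratio (default 3).
#' @return 4x4 row-stochastic matrix with dimnames ACGU.
#' @export
substitution_spectrum <- function(ti_weight = 3) {
  m <- matrix(1, 4, 4, dimnames = list(RNA_BASES, RNA_BASES))
  diag(m) <- 0
  transitions <- rbind(c("A", "G"), c("G", "A"), c("C", "U"), c("U", "C"))
  m[transitions] <- ti_weight
  m / rowSums(m)
}

#' Simulation configuration
#'
#' Defaults are the study conditions the analysis is designed around: mean
#' 2.5 substitutions per variant, 60 cells per variant (midpoint of 50-70),
#' log-normal single-cell noise with sigma 0.4 log10 units, 6 gates covering
#' 90% of cells, and deep per-bin sequencing.
#'
#' @param n_variants library size (independent mutagenesis draws; duplicate
#'   sequences are allowed and pooled).
#' @param mutation_mean Poisson mean substitutions per variant.
#' @param spectrum 4x4 row-stochastic substitution matrix, zero diagonal.
#' @param cells_per_variant Poisson mean cells carrying each variant.
#' @param cell_noise_sigma sd of log10 single-cell fluorescence.
#' @param reads_per_bin sequencing depth per sorting bin.
#' @param n_bins number of sorting gates (4-6 by design).
#' @param coverage fraction of cells the gated range should cover.
#' @param mu_no_srna log10 mean fluorescence of the empty-vector control.
#' @param wt_fold_change wild-type fold-change efficiency (fold-repression
#'   or fold-activation depending on `mode`).
#' @param mode regulation mode of the simulated target.
#' @param control_cells clonal cells spiked in for each control row.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_variants = 1000,
                       mutation_mean = 2.5,
                       spectrum = substitution_spectrum(),
                       cells_per_variant = 60,
                       cell_noise_sigma = 0.4,
                       reads_per_bin = 50000,
                       n_bins = 6,
                       coverage = 0.9,
                       mu_no_srna = 3.5,
                       wt_fold_change = 20,
                       mode = c("repressed", "activated"),
                       control_cells = 5000) {
  mode <- match.arg(mode)
  stopifnot(n_variants > 0, mutation_mean >= 0, cells_per_variant > 0,
            cell_noise_sigma > 0, reads_per_bin > 0, wt_fold_change > 0)
  if (!all(abs(rowSums(spectrum) - 1) < 1e-9) || any(diag(spectrum) != 0)) {
    stop("spectrum rows must sum to 1 with a zero diagonal")
  }
  structure(list(n_variants = n_variants, mutation_mean = mutation_mean,
                 spectrum = spectrum, cells_per_variant = cells_per_variant,
                 cell_noise_sigma = cell_noise_sigma,
                 reads_per_bin = reads_per_bin, n_bins = n_bins,
                 coverage = coverage, mu_no_srna = mu_no_srna,
                 wt_fold_change = wt_fold_change, mode = mode,
                 control_cells = control_cells),
            class = "sim_config")
}

#' Draw a mutagenized variant library
#'
#' Each variant draws its substitution count from a Poisson law (capped at
#' the sequence length), positions uniformly without replacement, and
#' substituted bases from the spectrum row of the reference base. Duplicates
#' are allowed: real libraries are redundant.
#'
#' @param reference a `reference_srna`.
#' @param config a `sim_config`.
#' @return list of `srna_variant` objects of length `config$n_variants`.
#' @export
mutagenize <- function(reference, config) {
  L <- reference$length
  lapply(seq_len(config$n_variants), function(i) {
    k <- min(stats::rpois(1, config$mutation_mean), L)
    if (k == 0) return(variant(integer(0), character(0), reference))
    pos <- sort(sample.int(L, k))
    alt <- vapply(pos, function(p) {
      sample(RNA_BASES, 1, prob = config$spectrum[reference$bases[p], ])
    }, "")
    variant(pos, alt, reference)
  })
}

# --- ground-truth efficiency models -----------------------------------------

#' Additive ground-truth model
#'
#' Two-state energy S is the wild-type energy plus independent per-mutation
#' energy changes, with optional planted pairwise interaction terms
#' (epistasis) for recovery tests.
#'
#' @param reference a `reference_srna`.
#' @param S_WT wild-type two-state energy (logit of relative expression).
#' @param delta_S L x 4 matrix of per-mutation energy changes (0 at the
#'   wild-type base); colnames ACGU.
#' @param epistasis optional data.frame with columns `key_a`, `key_b`
#'   (single-mutation keys, e.g. "A30G") and `dS` added when both are present.
#' @return a `truth_model` of subclass `truth_additive`.
#' @export
truth_additive <- function(reference, S_WT, delta_S, epistasis = NULL) {
  stopifnot(nrow(delta_S) == reference$length, ncol(delta_S) == 4)
  colnames(delta_S) <- RNA_BASES
  for (p in seq_len(reference$length)) delta_S[p, reference$bases[p]] <- 0
  structure(list(reference = reference, S_WT = S_WT, delta_S = delta_S,
                 epistasis = epistasis),
            class = c("truth_additive", "truth_model"))
}

#' Heuristic (free-energy) ground-truth model
#'
#' Two-state energy built from the three free-energy changes the heuristic
#' model uses: self-folding of the two target-independent stem-loops and
#' seed-target hybridization. Each term enters through a saturating softplus
#' with its own weight and offset; the composition is centred so the wild
#' type maps exactly to `S_WT`. An optional bonus strengthens repression for
#' variants whose seed-carrying stem-loop is looser than the wild type.
#'
#' @param reference a `reference_srna`.
#' @param S_WT wild-type two-state energy.
#' @param weights,offsets numeric length-3 vectors (fold SL1, fold SL3,
#'   bind seed), weights > 0: destabilization raises S (weakens regulation).
#' @param target name of the target whose seed is used.
#' @param backend an `energy_backend`.
#' @param stem_loops the two stem-loops contributing fold terms.
#' @param loose_sl2_bonus subtracted from S when the seed stem-loop is loose.
#' @param sl2 name of the seed-carrying stem-loop for the bonus.
#' @return a `truth_model` of subclass `truth_heuristic`.
#' @export
truth_heuristic <- function(reference, S_WT = stats::qlogis(1 / 20),
                            weights = c(1.2, 1.5, 0.8),
                            offsets = c(1.5, 1.5, 3.0),
                            target = names(reference$targets)[1],
                            backend = energy_backend(),
                            stem_loops = c("SL1", "SL3"),
                            loose_sl2_bonus = 0, sl2 = "SL2") {
  stopifnot(length(weights) == 3, length(offsets) == 3, all(weights >= 0))
  structure(list(reference = reference, S_WT = S_WT, weights = weights,
                 offsets = offsets, target = target, backend = backend,
                 stem_loops = stem_loops, loose_sl2_bonus = loose_sl2_bonus,
                 sl2 = sl2),
            class = c("truth_heuristic", "truth_model"))
}

softplus <- function(x) ifelse(x > 30, x, log1p(exp(x)))

#' True two-state energy of a variant under a truth model
#'
#' @param model a `truth_model`.
#' @param v an `srna_variant` or canonical key.
#' @return scalar S.
#' @export
truth_S <- function(model, v) UseMethod("truth_S")

#' @export
truth_S.truth_additive <- function(model, v) {
  if (is.character(v)) v <- parse_variant_key(v, model$reference)
  S <- model$S_WT
  if (length(v$pos) > 0) {
    S <- S + sum(model$delta_S[cbind(v$pos, match(v$alt, RNA_BASES))])
  }
  ep <- model$epistasis
  if (!is.null(ep) && length(v$pos) > 0) {
    muts <- paste0(v$ref, v$pos, v$alt)
    hit <- ep$key_a %in% muts & ep$key_b %in% muts
    if (any(hit)) S <- S + sum(ep$dS[hit])
  }
  S
}

#' @export
truth_S.truth_heuristic <- function(model, v) {
  ref <- model$reference
  if (is.character(v)) v <- parse_variant_key(v, ref)
  dd <- c(
    fold_energy(ref, v, model$stem_loops[1], model$backend)$ddG,
    fold_energy(ref, v, model$stem_loops[2], model$backend)$ddG,
    binding_energy(ref, v, model$target, model$backend)$ddG
  )
  S <- model$S_WT + sum(model$weights *
                          (softplus(dd - model$offsets) - softplus(-model$offsets)))
  if (model$loose_sl2_bonus != 0) {
    if (fold_energy(ref, v, model$sl2, model$backend)$ddG > 0) {
      S <- S - model$loose_sl2_bonus
    }
  }
  S
}

#' True fold-change efficiency of a variant
#'
#' Maps the truth model's two-state energy through the logistic relation:
#' relative expression u = plogis(S), reported fold-change f = 1/u (the
#' fold-repression / fold-activation scale). The wild type maps to the
#' configured wild-type fold-change by construction.
#'
#' @param v an `srna_variant` or canonical key.
#' @param reference a `reference_srna` (consistency check).
#' @param truth_model a `truth_model`.
#' @return scalar f* > 0.
#' @export
simulate_truth <- function(v, reference, truth_model) {
  stopifnot(identical(reference$sequence, truth_model$reference$sequence))
  1 / stats::plogis(truth_S(truth_model, v))
}

truth_mu <- function(S, config) {
  u <- stats::plogis(S)
  if (config$mode == "repressed") config$mu_no_srna + log10(u)
  else config$mu_no_srna - log10(u)
}

# --- sorting + sequencing ----------------------------------------------------

#' Simulate sorting and per-bin sequencing of a variant library
#'
#' For each variant: draw its cell count, distribute cells over bins by the
#' log-normal fluorescence model (cells outside the gated range are
#' discarded), then draw one multinomial per bin over that bin's sorted
#' cells with the configured read depth. Clonal wild-type and empty-vector
#' control populations are spiked in under reserved keys.
#'
#' @param variants list of `srna_variant` (or character keys).
#' @param truths_mu numeric vector: true mean log10 fluorescence per variant
#'   entry (same length as `variants`).
#' @param gates a `sort_gates`.
#' @param config a `sim_config`.
#' @param reference a `reference_srna` (for key parsing only).
#' @return a `bin_count_table` including control rows `WT` and `NOSRNA`.
#' @export
simulate_sort_seq <- function(variants, truths_mu, gates, config, reference) {
  keys <- vapply(variants, function(v) if (is.character(v)) v else v$key, "")
  stopifnot(length(keys) == length(truths_mu))
  k <- gates$n_bins
  b <- gates$boundaries
  sigma <- config$cell_noise_sigma
  # aggregate duplicate draws of the same sequence
  mu_wt <- truths_mu[match(WT_KEY, keys)]
  if (is.na(mu_wt)) {
    mu_wt <- truth_mu(stats::qlogis(1 / config$wt_fold_change), config)
  }
  ukeys <- unique(keys)
  n_draws <- as.integer(table(factor(keys, levels = ukeys)))
  umu <- truths_mu[match(ukeys, keys)]
  # spike in controls under reserved keys
  all_keys <- c(ukeys, setdiff(c(WT_KEY, EMPTY_VECTOR_KEY), ukeys))
  all_mu <- c(umu, c(mu_wt, config$mu_no_srna)[match(
    setdiff(c(WT_KEY, EMPTY_VECTOR_KEY), ukeys), c(WT_KEY, EMPTY_VECTOR_KEY))])
  n_cells_mean <- ifelse(all_keys %in% c(WT_KEY, EMPTY_VECTOR_KEY),
                         config$control_cells,
                         config$cells_per_variant *
                           n_draws[match(all_keys, ukeys)])
  n_cells_mean[is.na(n_cells_mean)] <- config$control_cells
  nv <- length(all_keys)
  cells <- matrix(0, nrow = nv, ncol = k)
  cells_total <- 0
  for (i in seq_len(nv)) {
    n_i <- stats::rpois(1, n_cells_mean[i])
    if (n_i == 0) next
    cells_total <- cells_total + n_i
    p <- diff(stats::pnorm(b, all_mu[i], sigma))
    p_out <- 1 - sum(p)
    draw <- stats::rmultinom(1, n_i, c(p, max(p_out, 0)))
    cells[i, ] <- draw[seq_len(k)]
  }
  if (sum(cells) == 0) stop("no cells fell inside the gated range")
  reads <- matrix(0L, nrow = nv, ncol = k)
  for (bin in seq_len(k)) {
    tot <- sum(cells[, bin])
    if (tot == 0) next
    reads[, bin] <- stats::rmultinom(1, config$reads_per_bin, cells[, bin])
  }
  counts <- data.frame(variant_key = all_keys, reads,
                       stringsAsFactors = FALSE)
  names(counts) <- c("variant_key", paste0("bin", seq_len(k)))
  out <- bin_count_table(counts, gates,
                         cells_sorted = colSums(cells),
                         reads_sequenced = colSums(reads))
  attr(out, "cells_total") <- cells_total # incl. cells outside the gates
  out
}

#' End-to-end library simulation
#'
#' Mutagenizes, evaluates the truth model, chooses gates from a simulated
#' cell sample at the configured coverage, and runs the sorting +
#' sequencing simulation. Fully deterministic given the RNG state.
#'
#' @param reference a `reference_srna`.
#' @param truth_model a `truth_model`; its `S_WT` should equal
#'   `qlogis(1/config$wt_fold_change)` for the controls to line up.
#' @param config a `sim_config`.
#' @return list with `table` (a `bin_count_table`), `truth` (data.frame
#'   variant_key, S, f, mu -- one row per unique sequence incl. controls),
#'   `gates`, and the `config` used.
#' @export
simulate_library <- function(reference, truth_model, config = sim_config()) {
  vars <- mutagenize(reference, config)
  keys <- vapply(vars, `[[`, "", "key")
  ukeys <- unique(keys)
  S <- vapply(ukeys, function(kk) truth_S(truth_model, parse_variant_key(kk, reference)), 0)
  mu <- truth_mu(S, config)
  mu_all <- mu[match(keys, ukeys)]
  # gate choice: a cell-level fluorescence sample whose composition mirrors
  # the sorted population (variant cells plus the clonal control spike-ins)
  S_wt0 <- stats::qlogis(1 / config$wt_fold_change)
  pool_mu <- c(mu_all, truth_mu(S_wt0, config), config$mu_no_srna)
  pool_w <- c(rep(config$cells_per_variant, length(mu_all)),
              rep(config$control_cells, 2))
  n_samp <- 20000
  samp_mu <- sample(pool_mu, n_samp, replace = TRUE, prob = pool_w)
  cell_sample <- stats::rnorm(n_samp, mean = samp_mu,
                              sd = config$cell_noise_sigma)
  gates <- choose_gates(cell_sample, n_bins = config$n_bins,
                        coverage = config$coverage)
  tbl <- simulate_sort_seq(vars, mu_all, gates, config, reference)
  truth <- data.frame(
    variant_key = c(ukeys, setdiff(c(WT_KEY, EMPTY_VECTOR_KEY), ukeys)),
    stringsAsFactors = FALSE
  )
  S_wt <- stats::qlogis(1 / config$wt_fold_change)
  truth$S <- c(S, c(S_wt, NA)[match(setdiff(c(WT_KEY, EMPTY_VECTOR_KEY), ukeys),
                                    c(WT_KEY, EMPTY_VECTOR_KEY))])
  truth$mu <- ifelse(truth$variant_key == EMPTY_VECTOR_KEY, config$mu_no_srna,
                     truth_mu(truth$S, config))
  truth$f <- 1 / stats::plogis(truth$S)
  list(table = tbl, truth = truth, gates = gates, config = config)
}
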