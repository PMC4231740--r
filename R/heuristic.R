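# Six-parameter heuristic free-energy model: predicts the two-state energy
# of an arbitrary variant from three computed free-energy changes -- the
# self-folding of the two target-independent stem-loops (SL1, SL3) and the
# seed-target hybridization -- each entering through a saturating softplus
# with its own weight and offset:
#   S(v) = S_WT + sum_k w_k [softplus(ddG_k - b_k) - softplus(-b_k)].
# The centring makes the wild type (all ddG = 0) map exactly onto S_WT,
# leaving six free parameters {w_k, b_k}. S_WT is taken from the wild-type
# measurement, not fitted.

#' Free-energy features for a set of variants
#'
#' ddG of self-folding for the two stem-loops and ddG of seed-target
#' hybridization, relative to the wild type, plus the looseness flag of the
#' seed-carrying stem-loop. Backend calls are memoized per subsequence, so
#' libraries with shared mutations are cheap.
#'
#' @param keys character vector of canonical variant keys.
#' @param reference a `reference_srna`.
#' @param target target name whose seed is used for the binding term.
#' @param backend an `energy_backend`.
#' @param stem_loops the two fold-term stem-loops.
#' @param sl2 seed-carrying stem-loop used for the `loose` flag.
#' @return data.frame: variant_key, ddG_fold_1, ddG_fold_2, ddG_bind,
#'   ddG_fold_sl2, loose_sl2.
#' @export
variant_energies <- function(keys, reference,
                             target = names(reference$targets)[1],
                             backend = energy_backend(),
                             stem_loops = c("SL1", "SL3"), sl2 = "SL2") {
  rows <- lapply(keys, function(kk) {
    v <- parse_variant_key(kk, reference)
    f1 <- fold_energy(reference, v, stem_loops[1], backend)
    f2 <- fold_energy(reference, v, stem_loops[2], backend)
    bb <- binding_energy(reference, v, target, backend)
    fs <- fold_energy(reference, v, sl2, backend)
    data.frame(variant_key = kk, ddG_fold_1 = f1$ddG, ddG_fold_2 = f2$ddG,
               ddG_bind = bb$ddG, ddG_fold_sl2 = fs$ddG,
               loose_sl2 = fs$loose, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

heuristic_S <- function(par, S_WT, X) {
  w <- par[1:3]; b <- par[4:6]
  S_WT +
    w[1] * (softplus(X[, 1] - b[1]) - softplus(-b[1])) +
    w[2] * (softplus(X[, 2] - b[2]) - softplus(-b[2])) +
    w[3] * (softplus(X[, 3] - b[3]) - softplus(-b[3]))
}

#' Fit the six-parameter heuristic model
#'
#' Least squares on the energy scale S (the model's linear scale), fitted
#' from a random sample of records -- the point of the model is that ~150
#' measurements of arbitrary variants suffice, where the additive model
#' needs near-complete single-mutant coverage. Multi-start BFGS with a
#' deterministic restart schedule guards against local minima.
#'
#' @param records data.frame from [infer_efficiencies()] (needs
#'   `variant_key`, `S`; censored/clamped/control rows are dropped).
#' @param reference a `reference_srna`.
#' @param target target name for the binding term.
#' @param backend an `energy_backend`.
#' @param n_train number of randomly selected training records (>= 20);
#'   NULL uses all usable records.
#' @param n_restarts optimizer restarts.
#' @param energies optional precomputed [variant_energies()] table covering
#'   all record keys (avoids refolding).
#' @return object of class `heuristic_model`: `weights`, `offsets`, `S_WT`,
#'   `r2_train`, `train_keys`, plus fit metadata.
#' @export
fit_heuristic <- function(records, reference,
                          target = names(reference$targets)[1],
                          backend = energy_backend(),
                          n_train = 150, n_restarts = 8,
                          energies = NULL) {
  use <- !records$variant_key %in% c(WT_KEY, EMPTY_VECTOR_KEY) &
    is.finite(records$S)
  if ("censored" %in% names(records)) use <- use & !records$censored %in% TRUE
  pool <- records[use, , drop = FALSE]
  i_wt <- match(WT_KEY, records$variant_key)
  if (is.na(i_wt)) stop("records lack a wild-type row (S_WT anchor)")
  S_WT <- records$S[i_wt]
  if (!is.null(n_train)) {
    if (n_train < 20) stop("n_train must be >= 20 (>= 3x the parameter count)")
    if (n_train > nrow(pool)) {
      warning("n_train exceeds usable records; using all ", nrow(pool))
      n_train <- nrow(pool)
    }
    train <- pool[sample.int(nrow(pool), n_train), , drop = FALSE]
  } else {
    train <- pool
  }
  if (is.null(energies)) {
    energies <- variant_energies(train$variant_key, reference, target, backend)
  }
  X <- as.matrix(energies[match(train$variant_key, energies$variant_key),
                          c("ddG_fold_1", "ddG_fold_2", "ddG_bind")])
  y <- train$S
  sse <- function(par) {
    if (any(par[1:3] < 0)) return(1e12)
    sum((y - heuristic_S(par, S_WT, X))^2)
  }
  spread <- pmax(apply(X, 2, stats::sd), 0.1)
  slope0 <- stats::sd(y) / pmax(mean(spread), 0.1)
  starts <- list(c(rep(slope0, 3), rep(1, 3)))
  for (r in seq_len(n_restarts - 1)) {
    starts[[r + 1]] <- c(slope0 * stats::runif(3, 0.2, 3),
                         stats::runif(3, -1, 4))
  }
  fits <- lapply(starts, function(p0) {
    tryCatch(stats::optim(p0, sse, method = "BFGS",
                          control = list(maxit = 500, reltol = 1e-12)),
             error = function(e) list(value = Inf, par = p0, convergence = 1))
  })
  vals <- vapply(fits, `[[`, 0, "value")
  if (!any(is.finite(vals))) stop("heuristic optimizer failed to converge")
  best <- fits[[which.min(vals)]]
  r2 <- 1 - best$value / sum((y - mean(y))^2)
  structure(
    list(weights = best$par[1:3], offsets = best$par[4:6], S_WT = S_WT,
         target = target, backend_name = backend$name,
         r2_train = r2, n_train = nrow(train),
         train_keys = train$variant_key,
         sse = best$value, converged = best$convergence == 0),
    class = "heuristic_model"
  )
}

#' @export
print.heuristic_model <- function(x, ...) {
  cat("<heuristic_model> six parameters, backend ", x$backend_name, "\n",
      sep = "")
  cat("  weights: ", paste(signif(x$weights, 4), collapse = ", "), "\n",
      "  offsets: ", paste(signif(x$offsets, 4), collapse = ", "), "\n",
      "  training R^2 = ", round(x$r2_train, 4), " (n = ", x$n_train, ")\n",
      sep = "")
  invisible(x)
}

#' Predict two-state energies with a fitted heuristic model
#'
#' @param model a `heuristic_model`.
#' @param keys variant keys (or a precomputed energy table via `energies`).
#' @param reference a `reference_srna`.
#' @param backend an `energy_backend` (defaults to a fresh instance of the
#'   backend the model was fitted with).
#' @param energies optional precomputed [variant_energies()].
#' @return data.frame: variant_key, S_pred, u_pred, f_pred.
#' @export
predict_heuristic <- function(model, keys, reference, backend = NULL,
                              energies = NULL) {
  if (is.null(energies)) {
    if (is.null(backend)) backend <- energy_backend(model$backend_name)
    energies <- variant_energies(keys, reference, model$target, backend)
  }
  X <- as.matrix(energies[match(keys, energies$variant_key),
                          c("ddG_fold_1", "ddG_fold_2", "ddG_bind")])
  S <- heuristic_S(c(model$weights, model$offsets), model$S_WT, X)
  u <- stats::plogis(S)
  data.frame(variant_key = keys, S_pred = S, u_pred = u, f_pred = 1 / u,
             stringsAsFactors = FALSE)
}

#' Goodness of fit (R^2) of model predictions against measurements
#'
#' @param S_obs measured two-state energies.
#' @param S_pred predicted energies.
#' @return R^2 (1 - SSE/SST).
#' @export
r_squared <- function(S_obs, S_pred) {
  ok <- is.finite(S_obs) & is.finite(S_pred)
  1 - sum((S_obs[ok] - S_pred[ok])^2) / sum((S_obs[ok] - mean(S_obs[ok]))^2)
}

#' Logistic response of efficiency to a free-energy change
#'
#' Least-squares fit of log fold-change against ddG with the three-parameter
#' decaying logistic y = plateau / (1 + exp((x - midpoint)/slope)):
#' efficiency falls from a plateau toward zero as the structure (or duplex)
#' is destabilized.
#'
#' @param log_f log fold-change measurements (natural log).
#' @param energies matching ddG values (kcal/mol).
#' @return list with `midpoint`, `slope`, `plateau`, `r2`, `fitted`.
#' @export
fit_energy_response <- function(log_f, energies) {
  ok <- is.finite(log_f) & is.finite(energies)
  y <- log_f[ok]; x <- energies[ok]
  if (length(y) < 10) stop("need at least 10 paired observations")
  if (stats::sd(x) == 0) stop("degenerate energies: zero spread")
  obj <- function(p) {
    pred <- p[3] / (1 + exp((x - p[1]) / max(p[2], 1e-6)))
    sum((y - pred)^2)
  }
  starts <- list(c(stats::median(x), max(stats::sd(x) / 2, 0.1), max(y)),
                 c(stats::quantile(x, 0.25), 1, max(y)),
                 c(stats::quantile(x, 0.75), 0.5, stats::quantile(y, 0.9)))
  fits <- lapply(starts, function(p0) {
    stats::optim(p0, obj, method = "Nelder-Mead",
                 control = list(maxit = 2000, reltol = 1e-14))
  })
  best <- fits[[which.min(vapply(fits, `[[`, 0, "value"))]]
  # polish
  best <- stats::optim(best$par, obj, method = "BFGS",
                       control = list(maxit = 1000, reltol = 1e-15))
  p <- best$par
  fitted <- p[3] / (1 + exp((x - p[1]) / max(p[2], 1e-6)))
  list(midpoint = p[1], slope = p[2], plateau = p[3],
       r2 = 1 - best$value / sum((y - mean(y))^2), fitted = fitted)
}
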