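# Maximum-likelihood inference of per-variant mean fluorescence from binned
# read counts, and conversion to fold-change efficiency on the two-state
# energy scale.

#' Choose sorting gates from a fluorescence sample
#'
#' Boundaries span the central `coverage` quantile range of the sample,
#' divided into `n_bins` equal widths on the log10 scale (gates are chosen
#' evenly on a log scale over a range that includes about 90% of cells).
#'
#' @param fluorescence_sample vector of log10 fluorescence values.
#' @param n_bins number of bins; 4-6 by design (outside that a warning).
#' @param coverage central fraction of cells the gates should cover.
#' @return a `sort_gates`.
#' @export
choose_gates <- function(fluorescence_sample, n_bins = 6, coverage = 0.9) {
  stopifnot(length(fluorescence_sample) > 0, coverage > 0, coverage <= 1)
  if (n_bins < 2) stop("n_bins must be at least 2")
  if (n_bins < 4 || n_bins > 6) {
    warning("n_bins outside the designed 4-6 range")
  }
  lo <- (1 - coverage) / 2
  qs <- stats::quantile(fluorescence_sample, c(lo, 1 - lo), names = FALSE,
                        type = 7)
  if (diff(qs) <= 0) stop("degenerate fluorescence sample: zero spread")
  sort_gates(seq(qs[1], qs[2], length.out = n_bins + 1))
}

#' Bin occupancy probabilities under the log-normal cell model
#'
#' Probability that a sorted cell with mean `mu` lands in each bin,
#' conditioned on falling inside the gated range (about 10% of cells are
#' never sorted, so the likelihood conditions on sorting).
#'
#' @param mu log10 mean fluorescence.
#' @param sigma log10 sd (> 0), shared across variants.
#' @param gates a `sort_gates`.
#' @param condition condition on the gated range (divide by its mass);
#'   set FALSE for the unconditioned truncated-normal masses.
#' @return probability vector of length `gates$n_bins` (sums to 1 when
#'   conditioned).
#' @export
bin_probabilities <- function(mu, sigma, gates, condition = TRUE) {
  stopifnot(sigma > 0)
  p <- diff(stats::pnorm(gates$boundaries, mean = mu, sd = sigma))
  if (condition) {
    Z <- sum(p)
    if (Z <= 0) {
      # numerically outside the gates: put all mass in the nearest bin
      p <- numeric(gates$n_bins)
      p[if (mu < gates$boundaries[1]) 1 else gates$n_bins] <- 1
      return(p)
    }
    p <- p / Z
  }
  p
}

weighted_loglik <- function(mu, wcounts, gates, sigma) {
  p <- bin_probabilities(mu, sigma, gates)
  occupied <- wcounts > 0
  # finite floor keeps optimize() off -Inf when p underflows at extreme mu
  if (any(p[occupied] <= 0)) return(-1e12)
  sum(wcounts[occupied] * log(p[occupied]))
}

#' ML estimate of mean fluorescence from one variant's bin counts
#'
#' Maximizes the weighted multinomial log-likelihood
#' sum_b w_b n_b log p_b(mu), where the per-bin weights convert read counts
#' to estimated cell proportions (cells_sorted_b / reads_sequenced_b) and
#' p_b conditions on the cell being sorted. The standard error comes from
#' the observed information at the maximum and the confidence interval from
#' the profile likelihood. When all weighted counts fall in an extreme bin
#' the mean is not identified; the estimate is reported censored at the
#' outer gate boundary with a one-sided interval. An interior maximum that
#' falls outside the gated range is also flagged censored: such variants
#' lie beyond the assay's measurable range and their point estimates rest
#' entirely on the truncated tail of the cell distribution.
#'
#' @param counts per-bin read counts (length `gates$n_bins`).
#' @param gates a `sort_gates`.
#' @param sigma log10 cell-noise sd (shared, from clonal controls).
#' @param depth_weights per-bin weights (default 1; typically
#'   cells_sorted / reads_sequenced).
#' @param level confidence level for the interval.
#' @return list with `mu_hat`, `se_mu`, `ci` (length 2), `censored`,
#'   `n_eff` (total weighted count).
#' @export
infer_mean_fluorescence <- function(counts, gates, sigma,
                                    depth_weights = NULL, level = 0.95) {
  k <- gates$n_bins
  stopifnot(length(counts) == k, all(counts >= 0), sigma > 0)
  if (sum(counts) == 0) stop("all counts are zero")
  if (is.null(depth_weights)) depth_weights <- rep(1, k)
  w <- counts * depth_weights
  b <- gates$boundaries
  lo <- b[1] - 6 * sigma
  hi <- b[k + 1] + 6 * sigma
  crit <- stats::qchisq(level, df = 1) / 2
  occ <- which(w > 0)
  if (length(occ) == 1 && (occ == 1 || occ == k)) {
    # censored: likelihood increases monotonically toward the outer edge
    edge <- if (occ == 1) b[1] else b[k + 1]
    ll_sup <- 0 # limit of n log p as p -> 1
    f <- function(m) weighted_loglik(m, w, gates, sigma) - (ll_sup - crit)
    if (occ == 1) {
      bound <- tryCatch(stats::uniroot(f, c(edge, hi))$root, error = function(e) hi)
      ci <- c(-Inf, bound)
    } else {
      bound <- tryCatch(stats::uniroot(f, c(lo, edge))$root, error = function(e) lo)
      ci <- c(bound, Inf)
    }
    return(list(mu_hat = edge, se_mu = NA_real_, ci = ci, censored = TRUE,
                n_eff = sum(w)))
  }
  opt <- stats::optimize(function(m) weighted_loglik(m, w, gates, sigma),
                         interval = c(lo, hi), maximum = TRUE, tol = 1e-7)
  mu_hat <- opt$maximum
  ll_max <- opt$objective
  h <- 1e-3
  d2 <- (weighted_loglik(mu_hat + h, w, gates, sigma) - 2 * ll_max +
           weighted_loglik(mu_hat - h, w, gates, sigma)) / h^2
  se <- if (is.finite(d2) && d2 < 0) sqrt(-1 / d2) else NA_real_
  f <- function(m) weighted_loglik(m, w, gates, sigma) - (ll_max - crit)
  ci_lo <- tryCatch({
    if (f(lo) < 0) stats::uniroot(f, c(lo, mu_hat))$root else lo
  }, error = function(e) NA_real_)
  ci_hi <- tryCatch({
    if (f(hi) < 0) stats::uniroot(f, c(mu_hat, hi))$root else hi
  }, error = function(e) NA_real_)
  out_of_range <- mu_hat < b[1] || mu_hat > b[k + 1]
  list(mu_hat = mu_hat, se_mu = se, ci = c(ci_lo, ci_hi),
       censored = out_of_range, n_eff = sum(w))
}

#' Estimate the shared cell-noise sigma from clonal control rows
#'
#' Flow-cytometry noise is considerable even for clonal populations; sigma
#' is taken as shared across variants and estimated by joint maximum
#' likelihood over the clonal control rows, profiling out one free mean per
#' control.
#'
#' @param control_table a `bin_count_table` whose rows are clonal controls
#'   (e.g. the reserved `WT` and `NOSRNA` rows of a library table), or a
#'   full table -- rows with reserved control keys are used.
#' @param gates a `sort_gates` (defaults to the table's).
#' @return sigma (log10 units).
#' @export
estimate_sigma <- function(control_table, gates = control_table$gates) {
  cm <- count_matrix(control_table)
  keys <- rownames(cm)
  ctrl <- keys %in% c(WT_KEY, EMPTY_VECTOR_KEY)
  if (any(ctrl)) cm <- cm[ctrl, , drop = FALSE]
  dw <- control_table$cells_sorted / pmax(control_table$reads_sequenced, 1)
  dw <- dw / (1 + dw) # same two-stage sampling correction as the mean fits
  wm <- sweep(cm, 2, dw, `*`)
  occupied <- rowSums(wm > 0)
  wm <- wm[occupied >= 2, , drop = FALSE]
  if (nrow(wm) == 0) {
    stop("need at least one control row occupying >= 2 bins")
  }
  b <- gates$boundaries
  lo <- b[1] - 6; hi <- b[length(b)] + 6
  prof <- function(sigma) {
    sum(apply(wm, 1, function(w) {
      stats::optimize(function(m) weighted_loglik(m, w, gates, sigma),
                      interval = c(lo, hi), maximum = TRUE)$objective
    }))
  }
  stats::optimize(prof, interval = c(0.02, 2), maximum = TRUE, tol = 1e-5)$maximum
}

#' Fold-change efficiency and two-state energy from mean fluorescences
#'
#' The efficiency f is the fold-change in target expression: mean control
#' fluorescence over variant fluorescence for repressed targets, and the
#' reciprocal for activated targets. The relative expression u = 1/f
#' (clamped into (eps, 1-eps)) maps onto the two-state energy through the
#' logistic relation S = log(u/(1-u)), i.e. u = [1 + exp(-S)]^-1.
#'
#' @param mu_variant inferred log10 mean fluorescence of the variant.
#' @param mu_no_srna log10 mean of the empty-vector (no-sRNA) control.
#' @param mu_full_regulation optional log10 mean at full regulation (the
#'   wild-type control); when supplied a normalized efficiency `eta` in
#'   [0,1]-ish units is also reported.
#' @param mode "repressed" or "activated".
#' @param epsilon clamp width for u.
#' @return list with `f`, `u`, `S`, `clamped`, and `eta` when available.
#' @export
efficiency_from_means <- function(mu_variant, mu_no_srna,
                                  mu_full_regulation = NULL,
                                  mode = c("repressed", "activated"),
                                  epsilon = 1e-3) {
  mode <- match.arg(mode)
  stopifnot(is.finite(mu_variant), is.finite(mu_no_srna))
  lf <- if (mode == "repressed") mu_no_srna - mu_variant
        else mu_variant - mu_no_srna
  f <- 10^lf
  u_raw <- 1 / f
  u <- min(max(u_raw, epsilon), 1 - epsilon)
  clamped <- u != u_raw
  S <- log(u / (1 - u))
  out <- list(f = f, u = u, S = S, clamped = clamped)
  if (!is.null(mu_full_regulation) && is.finite(mu_full_regulation) &&
      mu_full_regulation != mu_no_srna) {
    out$eta <- (mu_no_srna - mu_variant) / (mu_no_srna - mu_full_regulation)
    if (mode == "activated") {
      out$eta <- (mu_variant - mu_no_srna) / (mu_full_regulation - mu_no_srna)
    }
  }
  out
}

#' Infer efficiency records for every variant in a bin-count table
#'
#' Table-level driver: estimates sigma from the clonal control rows (unless
#' given), converts read counts to cell proportions with per-bin depth
#' weights, runs the ML mean inference per variant, and maps means to
#' fold-change efficiency and two-state energy against the empty-vector
#' control. The delta-method standard error of S
#' (se_S = log(10) * se_mu / (1 - u)) is carried for downstream error
#' propagation.
#'
#' Read counts are a multinomial resample of the sorted cells, so the
#' per-bin weights are additionally shrunk by 1/(1 + cells/reads): the
#' quasi-multinomial correction for the two-stage (cells, then reads)
#' sampling, without which standard errors are understated at moderate
#' depth.
#'
#' @param tbl a `bin_count_table` with `WT` and `NOSRNA` control rows.
#' @param mode regulation mode of the measured target.
#' @param sigma shared cell-noise sd; estimated from controls when NULL.
#' @param epsilon clamp width for u.
#' @param level confidence level for the mu interval.
#' @return data.frame (one row per variant, controls included and flagged):
#'   variant_key, n_mut, is_control, total_reads, mu_hat, se_mu, ci_lo,
#'   ci_hi, censored, f, u, S, se_S, clamped.
#' @export
infer_efficiencies <- function(tbl, mode = c("repressed", "activated"),
                               sigma = NULL, epsilon = 1e-3, level = 0.95) {
  mode <- match.arg(mode)
  if (is.null(sigma)) sigma <- estimate_sigma(tbl)
  cm <- count_matrix(tbl)
  dw <- tbl$cells_sorted / pmax(tbl$reads_sequenced, 1)
  dw <- dw / (1 + dw) # quasi-multinomial shrinkage for read resampling
  keys <- rownames(cm)
  fits <- lapply(seq_len(nrow(cm)), function(i) {
    if (sum(cm[i, ]) == 0) {
      return(list(mu_hat = NA_real_, se_mu = NA_real_, ci = c(NA, NA),
                  censored = NA, n_eff = 0))
    }
    infer_mean_fluorescence(cm[i, ], tbl$gates, sigma, depth_weights = dw,
                            level = level)
  })
  mu_hat <- vapply(fits, `[[`, 0, "mu_hat")
  i_ctrl <- match(EMPTY_VECTOR_KEY, keys)
  i_wt <- match(WT_KEY, keys)
  if (is.na(i_ctrl)) stop("table lacks the empty-vector control row '",
                          EMPTY_VECTOR_KEY, "'")
  mu_ctrl <- mu_hat[i_ctrl]
  mu_full <- if (!is.na(i_wt)) mu_hat[i_wt] else NULL
  eff <- lapply(mu_hat, function(m) {
    if (!is.finite(m)) return(list(f = NA, u = NA, S = NA, clamped = NA))
    efficiency_from_means(m, mu_ctrl, mu_full, mode = mode, epsilon = epsilon)
  })
  u <- vapply(eff, function(e) as.numeric(e$u), 0)
  se_mu <- vapply(fits, `[[`, 0, "se_mu")
  out <- data.frame(
    variant_key = keys,
    n_mut = key_n_mutations(keys),
    is_control = keys %in% c(WT_KEY, EMPTY_VECTOR_KEY),
    total_reads = rowSums(cm),
    mu_hat = mu_hat,
    se_mu = se_mu,
    ci_lo = vapply(fits, function(x) x$ci[1], 0),
    ci_hi = vapply(fits, function(x) x$ci[2], 0),
    censored = vapply(fits, function(x) as.logical(x$censored), TRUE),
    f = vapply(eff, function(e) as.numeric(e$f), 0),
    u = u,
    S = vapply(eff, function(e) as.numeric(e$S), 0),
    se_S = log(10) * se_mu / (1 - u),
    clamped = vapply(eff, function(e) as.logical(e$clamped), TRUE),
    stringsAsFactors = FALSE
  )
  attr(out, "sigma") <- sigma
  attr(out, "mode") <- mode
  attr(out, "mu_no_srna") <- mu_ctrl
  out
}

#' Write / read an efficiency-record table as TSV
#'
#' @param records data.frame from [infer_efficiencies()].
#' @param path TSV path.
#' @return `path` / the data.frame.
#' @export
write_efficiencies <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_efficiencies
#' @export
read_efficiencies <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}
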