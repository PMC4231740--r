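test_that("gates span the central coverage quantiles evenly on the log scale", {
  set.seed(2)
  x <- runif(200000, 2, 4)
  g <- choose_gates(x, n_bins = 5, coverage = 0.9)
  # central 90% of Uniform(2,4): [2.05, 3.95] in 5 equal widths
  expect_equal(g$boundaries, seq(2.05, 3.95, length.out = 6), tolerance = 0.01)
  # coverage 1 spans the sample range exactly
  g1 <- choose_gates(x, n_bins = 4, coverage = 1)
  expect_equal(g1$boundaries[c(1, 5)], range(x))
  expect_silent(choose_gates(x, n_bins = 4))
  expect_silent(choose_gates(x, n_bins = 6))
  expect_warning(choose_gates(x, n_bins = 2), "4-6")
  expect_error(choose_gates(x, n_bins = 1), "at least 2")
  expect_error(choose_gates(rep(3, 100), n_bins = 5), "degenerate")
})

test_that("bin probabilities follow the sorted-conditioned normal model", {
  gates <- sort_gates(c(2, 2.5, 3, 3.5))
  # symmetry: mean at the middle of a symmetric gate set
  p <- bin_probabilities(2.75, 0.3, sort_gates(c(2.5, 2.75, 3)))
  expect_equal(p, c(0.5, 0.5))
  # far below all gates: mass concentrates in bin 1
  expect_gt(bin_probabilities(-2, 0.4, gates)[1], 0.999)
  # quadrature oracle: truncated-normal masses by numerical integration
  mu <- 2.5; sigma <- 0.4
  g4 <- sort_gates(c(2, 2.5, 3, 3.5))
  p <- bin_probabilities(mu, sigma, g4)
  q <- vapply(1:3, function(b) {
    integrate(function(x) dnorm(x, mu, sigma), g4$boundaries[b],
              g4$boundaries[b + 1], rel.tol = 1e-12)$value
  }, 0)
  expect_equal(p, q / sum(q), tolerance = 1e-9)
  # normalization holds across random cases
  set.seed(12)
  for (i in 1:50) {
    gg <- sort_gates(sort(runif(6, 1, 5)))
    pp <- bin_probabilities(runif(1, 0, 6), runif(1, 0.05, 1), gg)
    expect_lt(abs(sum(pp) - 1), 1e-12)
  }
})

test_that("the ML mean estimator honors its symmetry and oracle cases", {
  sigma <- 0.4
  # all counts in the interior bin of a symmetric gate set -> its midpoint
  g3 <- sort_gates(c(2, 2.5, 3, 3.5))
  fit <- infer_mean_fluorescence(c(0, 80, 0), g3, sigma)
  expect_equal(fit$mu_hat, 2.75, tolerance = 1e-4)
  expect_false(fit$censored)
  # equal counts across one interior boundary -> the boundary
  g2 <- sort_gates(c(2, 3, 4))
  fit2 <- infer_mean_fluorescence(c(50, 50), g2, sigma)
  expect_equal(fit2$mu_hat, 3, tolerance = 1e-4)
  # grid-search oracle at 1e-4 resolution
  counts <- c(10, 30, 60)
  grid <- seq(1.5, 4, by = 1e-4)
  ll <- vapply(grid, function(m) {
    p <- diff(pnorm(g3$boundaries, m, sigma))
    p <- p / sum(p)
    sum(counts * log(p))
  }, 0)
  fit3 <- infer_mean_fluorescence(counts, g3, sigma)
  expect_equal(fit3$mu_hat, grid[which.max(ll)], tolerance = 2e-4)
  expect_true(is.finite(fit3$se_mu))
  expect_true(fit3$ci[1] < fit3$mu_hat && fit3$mu_hat < fit3$ci[2])
  expect_error(infer_mean_fluorescence(c(0, 0, 0), g3, sigma), "zero")
})

test_that("extreme-bin variants are reported censored with one-sided intervals", {
  g <- sort_gates(c(2, 2.5, 3, 3.5, 4))
  lowfit <- infer_mean_fluorescence(c(40, 0, 0, 0), g, 0.4)
  expect_true(lowfit$censored)
  expect_equal(lowfit$mu_hat, 2)
  expect_equal(lowfit$ci[1], -Inf)
  expect_true(is.finite(lowfit$ci[2]))
  hifit <- infer_mean_fluorescence(c(0, 0, 0, 40), g, 0.4)
  expect_true(hifit$censored)
  expect_equal(hifit$mu_hat, 4)
  expect_equal(hifit$ci[2], Inf)
})

test_that("shifting all counts one bin upward never decreases the estimate", {
  set.seed(33)
  g <- sort_gates(seq(2, 4, length.out = 7))
  for (i in 1:25) {
    counts <- rpois(5, 15)
    up <- c(0, counts)
    down <- c(counts, 0)
    if (sum(counts) == 0) next
    m_down <- infer_mean_fluorescence(down, g, 0.4)$mu_hat
    m_up <- infer_mean_fluorescence(up, g, 0.4)$mu_hat
    expect_gte(m_up, m_down - 1e-6)
  }
})

test_that("sigma is recovered from deep clonal controls", {
  set.seed(19)
  sigma_true <- 0.35
  gates <- sort_gates(seq(2, 4, length.out = 7))
  mk_control <- function(mu, n = 1e5) {
    x <- rnorm(n, mu, sigma_true)
    counts <- vapply(1:6, function(b) {
      sum(x >= gates$boundaries[b] & x < gates$boundaries[b + 1])
    }, 0)
    as.integer(counts)
  }
  counts <- data.frame(variant_key = c("WT", "NOSRNA"),
                       rbind(mk_control(2.6), mk_control(3.4)))
  names(counts) <- c("variant_key", paste0("bin", 1:6))
  tbl <- bin_count_table(counts, gates)
  sig_hat <- estimate_sigma(tbl)
  expect_lt(abs(sig_hat - sigma_true) / sigma_true, 0.05)
  # joint fit at the shared optimum is at least as good as the parts
  one <- bin_count_table(counts[1, ], gates)
  expect_error(
    estimate_sigma(bin_count_table(
      data.frame(variant_key = "WT", bin1 = 50L, bin2 = 0L,
                 bin3 = 0L, bin4 = 0L, bin5 = 0L, bin6 = 0L), gates)),
    ">= 2 bins")
})

test_that("efficiency maps onto the two-state energy scale exactly", {
  eps <- 1e-3
  # variant at the no-sRNA control level: f = 1, u clamps to 1 - eps
  e1 <- efficiency_from_means(3.5, 3.5, mode = "repressed", epsilon = eps)
  expect_equal(e1$f, 1)
  expect_equal(e1$u, 1 - eps)
  expect_equal(e1$S, log((1 - eps) / eps))
  expect_true(e1$clamped)
  # u = 0.5 <-> S = 0 (f = 2 fold-repression)
  e2 <- efficiency_from_means(3.5 - log10(2), 3.5, mode = "repressed")
  expect_equal(e2$u, 0.5)
  expect_equal(e2$S, 0, tolerance = 1e-12)
  # 4-fold repression: u = 1/4, S = ln(1/3)
  e3 <- efficiency_from_means(3.5 - log10(4), 3.5, mode = "repressed")
  expect_equal(e3$f, 4)
  expect_equal(e3$S, log(1 / 3))
  expect_false(e3$clamped)
  # activation mirrors the convention
  e4 <- efficiency_from_means(3.8, 3.5, mode = "activated")
  expect_equal(e4$f, 10^0.3)
  # logistic closed form: f = 1/u = 1 + exp(-S)
  expect_equal(1 / (1 + exp(-e3$S)), e3$u)
})

test_that("inferred means track truth with calibrated intervals", {
  set.seed(55)
  dS <- matrix(rexp(94 * 4, 0.7), 94, 4)
  tm <- truth_additive(ryhb, qlogis(1 / 20), dS)
  sim <- simulate_library(ryhb, tm, sim_config(n_variants = 350))
  rec <- infer_efficiencies(sim$table)
  expect_lt(abs(attr(rec, "sigma") - 0.4), 0.05)
  m <- merge(rec, sim$truth, by = "variant_key")
  ok <- !m$is_control & !m$censored & is.finite(m$mu_hat)
  err <- m$mu_hat[ok] - m$mu[ok]
  expect_lt(mean(abs(err)), 0.4 / sqrt(30))
  # slope of inferred vs true mean within 5% of 1
  slope <- coef(lm(m$mu_hat[ok] ~ m$mu[ok]))[2]
  expect_lt(abs(slope - 1), 0.05)
  cov <- mean(m$ci_lo[ok] <= m$mu[ok] & m$mu[ok] <= m$ci_hi[ok])
  expect_gte(cov, 0.90)
  expect_lte(cov, 0.98)
})
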