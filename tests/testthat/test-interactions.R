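test_that("interaction strength is the log-ratio of observed to additive fold-change", {
  is0 <- interaction_strength(5, 5, 0.1, 0.1)
  expect_equal(is0$IS, 0)
  is2 <- interaction_strength(10, 5, 0.1, 0.1)
  expect_equal(is2$IS, log(2))
  expect_equal(is2$se_IS, sqrt(0.02))
  expect_equal(is2$z, log(2) / sqrt(0.02))
  expect_gt(is2$IS, 0) # stronger than predicted: synergistic
  expect_lt(interaction_strength(2, 5, 0.1, 0.1)$IS, 0) # antagonistic
  expect_error(interaction_strength(-1, 5), "positive")
})

test_that("compensatory classification follows the structure and the GU policy", {
  # SL1 pair (8, 28) is C-G in the wild type
  expect_equal(ryhb$pairs[8], 28L)
  expect_equal(ryhb$bases[c(8, 28)], c("C", "G"))
  # swap to G-C: each alone breaks, together restore WC
  expect_true(classify_compensatory(8, "G", 28, "C", ryhb))
  # symmetric in the two mutations
  expect_true(classify_compensatory(28, "C", 8, "G", ryhb))
  # two loop positions (14, 15 unpaired): never compensatory
  expect_equal(ryhb$pairs[14], 0L)
  expect_false(classify_compensatory(14, "G", 15, "G", ryhb))
  # non-partner paired positions: not compensatory
  expect_false(classify_compensatory(8, "G", 29, "A", ryhb))
  expect_error(classify_compensatory(8, "G", 8, "C", ryhb), "distinct")
})

test_that("all nine alternative pairs of a C-G stem pair match the policy table", {
  # positions 8 (C) and 28 (G); policy: a single mutation retaining a GU
  # wobble does not 'break' pairing, and the double must restore strict WC
  can_pair <- function(a, b) paste0(a, b) %in%
    c("AU", "UA", "CG", "GC", "GU", "UG")
  is_wc <- function(a, b) paste0(a, b) %in% c("AU", "UA", "CG", "GC")
  for (a in c("A", "G", "U")) {
    for (b in c("A", "C", "U")) {
      expected <- !can_pair(a, "G") && !can_pair("C", b) && is_wc(a, b)
      expect_identical(classify_compensatory(8, a, 28, b, ryhb), expected,
                       label = paste0("C8", a, "/G28", b))
    }
  }
  # spot checks implied by the policy: C8U leaves a U-G wobble -> retained
  expect_false(classify_compensatory(8, "U", 28, "A", ryhb))
})

test_that("top_interactions ranks by |z| with a deterministic tie-break", {
  df <- data.frame(
    variant_key = c("b", "a", "c", "d"),
    z = c(0, 0, 3, -4), IS = c(0.5, 0.9, 1, -1),
    stringsAsFactors = FALSE
  )
  expect_equal(nrow(top_interactions(df, 0)), 0)
  top2 <- top_interactions(df, 2)
  expect_equal(top2$variant_key, c("d", "c"))
  # all-zero z: ordered by |IS| then key
  df0 <- df; df0$z <- 0
  expect_equal(top_interactions(df0, 4)$variant_key, c("c", "d", "a", "b"))
  expect_warning(t5 <- top_interactions(df, 10), "exceeds")
  expect_equal(nrow(t5), 4)
})

test_that("Fisher enrichment matches hypergeometric enumeration", {
  top <- data.frame(variant_key = letters[1:5], stringsAsFactors = FALSE)
  all_pairs <- data.frame(
    variant_key = letters[1:10],
    same_stem_loop = c(rep(TRUE, 5), rep(FALSE, 5)),
    stringsAsFactors = FALSE
  )
  enr <- enrichment_same_stemloop(top, all_pairs)
  expect_equal(enr$table, matrix(c(5, 0, 0, 5), 2, byrow = TRUE),
               ignore_attr = TRUE)
  # [[5,0],[0,5]]: P = 1/choose(10,5) = 1/252
  expect_equal(enr$p, 1 / 252, tolerance = 1e-9)
  expect_equal(enr$frac_top, 1)
  # invariant to permuting record order
  perm <- all_pairs[sample.int(10), ]
  expect_equal(enrichment_same_stemloop(top, perm)$p, enr$p)
})

test_that("IS is calibrated on an additive truth and flags planted epistasis", {
  set.seed(91)
  dS <- matrix(rnorm(94 * 4, 0, 0.6), 94, 4,
               dimnames = list(NULL, c("A", "C", "G", "U")))
  tm <- truth_additive(ryhb, qlogis(1 / 20), dS)
  vars <- c(list(variant(integer(0), character(0), ryhb)),
            all_single_variants(ryhb),
            random_double_variants(ryhb, 600))
  sim <- simulate_variant_list(vars, ryhb, tm, sim_config(n_variants = 1))
  rec <- infer_efficiencies(sim$table)
  mod <- fit_additive(rec, ryhb)
  it <- interaction_table(rec, mod, ryhb)
  expect_gt(nrow(it), 250)
  # null calibration: |z| tail near its nominal level, IS centred at zero
  expect_lt(mean(abs(it$z) > qnorm(0.995)), 0.025)
  expect_lt(abs(mean(it$IS)), 0.05)
  # propagated errors match the empirical spread within 20%
  expect_lt(abs(sd(it$IS) / mean(it$se_IS) - 1), 0.2)
  # most measurements agree with the additive prediction within 2-fold
  expect_gt(mean(abs(it$IS) <= log(2)), 0.95)
})

test_that("planted compensatory pairs dominate the interaction ranking", {
  set.seed(92)
  dS <- matrix(rnorm(94 * 4, 0, 0.4), 94, 4,
               dimnames = list(NULL, c("A", "C", "G", "U")))
  # plant 10 compensatory pairs on annotated stem pairs: each single breaks
  # the stem (penalty), the double restores it (epistatic rescue)
  pair_rows <- do.call(rbind, lapply(ryhb$stem_loops, `[[`, "pairs"))
  sel <- pair_rows[seq_len(10), , drop = FALSE]
  planted <- list(); ep <- NULL
  for (r in seq_len(nrow(sel))) {
    i <- sel[r, 1]; j <- sel[r, 2]
    ai <- ryhb$bases[j]; aj <- ryhb$bases[i] # base swap restores WC
    dS[i, ai] <- 1.5; dS[j, aj] <- 1.5
    ka <- paste0(ryhb$bases[i], i, ai); kb <- paste0(ryhb$bases[j], j, aj)
    ep <- rbind(ep, data.frame(key_a = ka, key_b = kb, dS = -3))
    planted[[r]] <- variant(c(i, j), c(ai, aj), ryhb)
  }
  tm <- truth_additive(ryhb, qlogis(1 / 20), dS, epistasis = ep)
  vars <- c(list(variant(integer(0), character(0), ryhb)),
            all_single_variants(ryhb),
            random_double_variants(ryhb, 1000),
            planted)
  sim <- simulate_variant_list(vars, ryhb, tm, sim_config(n_variants = 1))
  rec <- infer_efficiencies(sim$table)
  mod <- fit_additive(rec, ryhb)
  it <- interaction_table(rec, mod, ryhb)
  top20 <- top_interactions(it, 20)
  planted_keys <- vapply(planted, `[[`, "", "key")
  expect_gte(sum(planted_keys %in% top20$variant_key), 9)
  # the planted pairs are classified compensatory and synergistic
  hit <- it[it$variant_key %in% planted_keys, ]
  expect_true(all(hit$compensatory))
  expect_true(all(hit$IS > 0))
})

test_that("the loose-structure enrichment curve behaves at its limits", {
  set.seed(93)
  f <- exp(rnorm(400, log(8), 0.8))
  loose <- runif(400) < 0.3
  out <- loose_enrichment_curve(data.frame(f = f), loose,
                                thresholds = c(min(f) - 1, median(f)))
  # threshold below all efficiencies: fraction equals the baseline, p = 1
  expect_equal(out$curve$frac_loose[1], out$baseline)
  expect_equal(out$curve$p[1], 1)
  expect_equal(out$curve$n_above[1], 400)
  expect_error(loose_enrichment_curve(data.frame(f = f), loose,
                                      thresholds = numeric(0)), "empty")
})

test_that("a planted looseness boost is detected and the shuffled null is quiet", {
  set.seed(94)
  n <- 600
  loose <- runif(n) < 0.3
  log_f <- rnorm(n, log(6), 0.6) + 0.5 * loose
  rec <- data.frame(f = exp(log_f))
  thr <- exp(quantile(log_f, seq(0.1, 0.9, 0.1), names = FALSE))
  out <- loose_enrichment_curve(rec, loose, thresholds = thr)
  # loose fraction climbs with the threshold and is significant at the top
  expect_gt(tail(out$curve$frac_loose, 1), out$baseline)
  expect_lt(tail(out$curve$p, 1), 0.05)
  expect_true(all(diff(out$curve$frac_loose) > -0.1))
  # permutation null: few falsely significant thresholds
  set.seed(95)
  fp <- vapply(1:100, function(i) {
    o <- loose_enrichment_curve(rec, sample(loose), thresholds = thr)
    mean(o$curve$p < 0.05)
  }, 0)
  expect_lte(mean(fp), 0.10)
})

test_that("seed rescue selects devastated-but-maintained variants only", {
  set.seed(96)
  dS <- matrix(0, 94, 4, dimnames = list(NULL, c("A", "C", "G", "U")))
  S_WT <- qlogis(1 / 20)
  # seed position 38: A38G devastating; A38C mild
  dS[38, "G"] <- 6     # single-mutant f ~ 1 (devastating)
  dS[38, "C"] <- 0.3   # mild
  rec <- data.frame(
    variant_key = c("WT", "A30G", "A38G", "A38C", "A38G;U55A", "A38C;U55A"),
    S = c(S_WT, S_WT, S_WT + 6, S_WT + 0.3, S_WT, S_WT),
    se_S = 0.1, censored = FALSE, stringsAsFactors = FALSE
  )
  rec$f <- 1 / plogis(rec$S)
  mod_rec <- rec[c(1, 2, 3, 4), ]
  mod <- fit_additive(mod_rec, ryhb)
  sub <- seed_rescue_subset(rec, mod, ryhb, "sodB",
                            devastation_cutoff = 2, maintenance_cutoff = 5)
  expect_equal(sub$variant_key, "A38G;U55A")
  expect_equal(sub$devastating_seed_mut, "A38G")
  # empty library: empty subset
  empty <- seed_rescue_subset(rec[FALSE, ], mod, ryhb, "sodB")
  expect_equal(nrow(empty), 0)
  expect_error(seed_rescue_subset(rec, mod, ryhb, "sodB",
                                  devastation_cutoff = 10,
                                  maintenance_cutoff = 5), "exceed")
})
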