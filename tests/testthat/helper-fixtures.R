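# Shared fixtures: the packaged designed reference and a minimal toy
# reference small enough to reason about by hand.

ryhb <- load_reference(packaged_reference("ryhb"))

# 20-nt toy: one 5-bp hairpin (pairs 4-19, 5-18, 6-17, 7-16, 8-15)
toy_ref <- reference_srna(
  name = "toy",
  sequence = "AAAGCACUGAAAACAGUGCU",
  structure = "...(((((......))))).",
  stem_loops = list(list(name = "SL1", start = 4, end = 19)),
  regions = list(all = c(1, 20)),
  targets = list(list(name = "t1", mode = "repressed",
                      mrna_site = "GGGCACUGUUUG",
                      srna_seed_interval = c(13, 19),
                      mrna_site_interval = c(3, 9)))
)

# deliberate library: every single mutant of a reference
all_single_variants <- function(reference) {
  out <- list()
  for (p in seq_len(reference$length)) {
    for (a in setdiff(c("A", "C", "G", "U"), reference$bases[p])) {
      out[[length(out) + 1L]] <- variant(p, a, reference)
    }
  }
  out
}

# random double mutants (positions uniform, alt bases uniform)
random_double_variants <- function(reference, n) {
  lapply(seq_len(n), function(i) {
    ps <- sort(sample.int(reference$length, 2))
    as <- vapply(ps, function(p) {
      sample(setdiff(c("A", "C", "G", "U"), reference$bases[p]), 1)
    }, "")
    variant(ps, as, reference)
  })
}

# simulate a deliberate variant list end to end under a truth model
simulate_variant_list <- function(vars, reference, truth, config,
                                  gate_sample_n = 20000) {
  keys <- vapply(vars, `[[`, "", "key")
  S <- vapply(vars, function(v) truth_S(truth, v), 0)
  mu <- config$mu_no_srna + log10(plogis(S))
  pool <- c(mu, config$mu_no_srna)
  w <- c(rep(config$cells_per_variant, length(mu)), 2 * config$control_cells)
  samp <- sample(pool, gate_sample_n, replace = TRUE, prob = w)
  gates <- choose_gates(rnorm(gate_sample_n, samp, config$cell_noise_sigma),
                        n_bins = config$n_bins, coverage = config$coverage)
  tbl <- simulate_sort_seq(vars, mu, gates, config, reference)
  list(table = tbl, gates = gates,
       truth = data.frame(variant_key = keys, S = S, mu = mu,
                          stringsAsFactors = FALSE))
}
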