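#!/usr/bin/env Rscript
# Stage 3: quantitative sequence->efficiency models.
#
# (a) Free-energy responses: logistic fits of log fold-repression against
#     stem-loop folding ddG (SL1, SL3) and seed-binding ddG, the library
#     analogues of single-feature energy analyses.
# (b) Additive position-weight model trained on the wild type + single
#     mutants, evaluated on all multi-mutant records.
# (c) Six-parameter heuristic model fitted from 150 randomly selected
#     measurements, evaluated on the rest of the library.

library(qsortseq)

set.seed(20260921)
ref <- load_reference(packaged_reference("ryhb"))
backend <- energy_backend("reference")
rec <- read_efficiencies("results/efficiencies.tsv")
# the empty-vector control is not an sRNA sequence; keep the wild type (it
# anchors the heuristic model)
usable <- rec[!rec$censored %in% TRUE & is.finite(rec$S) &
                rec$variant_key != "NOSRNA", ]

message("computing free-energy features for ", nrow(usable), " variants")
en <- variant_energies(usable$variant_key, ref, "sodB", backend)

## (a) energy responses ----------------------------------------------------
resp <- NULL
for (term in c("ddG_fold_1", "ddG_fold_2", "ddG_bind")) {
  sel <- en[[term]] != 0 & usable$variant_key != "WT"
  fit <- fit_energy_response(log(usable$f[sel]), en[[term]][sel])
  resp <- rbind(resp, data.frame(
    term = term, n = sum(sel), r2 = fit$r2, midpoint = fit$midpoint,
    slope = fit$slope, plateau = fit$plateau))
  message(sprintf("%-11s n=%4d  R^2 = %.2f  midpoint = %.2f kcal/mol",
                  term, sum(sel), fit$r2, fit$midpoint))
}
write.table(resp, "results/energy_response.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

## (b) additive model ------------------------------------------------------
mod <- fit_additive(rec, ref)
message("additive model: ", additive_n_parameters(mod), " parameters, ",
        sum(mod$mask), " masked entries")
multi <- usable[usable$n_mut >= 2, ]
predictable <- vapply(multi$variant_key, function(k) {
  v <- parse_variant_key(k, ref)
  !any(mod$mask[cbind(v$pos, match(v$alt, c("A", "C", "G", "U")))])
}, TRUE)
pred <- predict_additive(mod, multi$variant_key[predictable], ref)
r2_add <- r_squared(multi$S[predictable], pred$S_add)
message("additive prediction R^2 on ", sum(predictable),
        " multi-mutant records: ", round(r2_add, 3))
within14 <- mean(abs(log(multi$f[predictable] / pred$f_pred)) <= log(1.4))
message(round(100 * within14, 1), "% of predictions within 1.4-fold")
write_additive(mod, "results/additive_model.tsv")

## (c) heuristic model -----------------------------------------------------
hfit <- fit_heuristic(usable, ref, "sodB", backend, n_train = 150,
                      energies = en)
held <- setdiff(usable$variant_key, c(hfit$train_keys, "WT"))
hpred <- predict_heuristic(hfit, held, ref, energies = en)
r2_h <- r_squared(usable$S[match(held, usable$variant_key)], hpred$S_pred)
message("heuristic model (150 training records): train R^2 = ",
        round(hfit$r2_train, 3), ", held-out R^2 = ", round(r2_h, 3))
yaml::write_yaml(list(weights = hfit$weights, offsets = hfit$offsets,
                      S_WT = hfit$S_WT, r2_train = hfit$r2_train,
                      r2_heldout = r2_h, n_train = hfit$n_train),
                 "results/heuristic_model.yaml")
message("wrote results/energy_response.tsv, additive_model.tsv, ",
        "heuristic_model.yaml")
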