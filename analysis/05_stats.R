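#!/usr/bin/env Rscript
# Stage 5: cohort statistics.
#
# Reproduces the statistics stage on the synthetic cohort: baseline table
# with one-way ANOVA p-values, per-outcome group comparisons with pairwise
# t-tests (P1 = EM vs LM/MM, P2 = EM vs SHM, P3 = LM/MM vs SHM), the sex
# chi-square, Pearson correlations with axial length, and the
# univariate-to-multivariate regression screen for AULCSF.
# Writes results/table1.csv, results/group_comparisons.csv,
# results/correlations.csv, results/regression_*.csv.

library(myoretina)

cohort <- read.csv("results/cohort.csv")
dir.create("results", showWarnings = FALSE)

run_pipeline("results", stages = "stats", seed = 1, quiet = TRUE)

cors <- do.call(rbind, lapply(
  c("aulcsf", "cutoff_sf", "cone_density_inner", "cone_density_outer",
    "cone_spacing_inner", "ct_inner", "cvi_inner", "la_inner", "tca_inner"),
  function(v) {
    ct <- correlate(cohort, "al", v)
    data.frame(x = "al", y = v, r = ct$r, p = ct$p, n = ct$n)
  }))
write.csv(cors, "results/correlations.csv", row.names = FALSE)

gc <- compare_groups(cohort, "cone_density_inner")
message(sprintf("cone density inner: ANOVA p = %.2g; pairwise %s",
                gc$p_overall,
                paste(gc$pairwise$label, signif(gc$pairwise$p, 2),
                      sep = "=", collapse = ", ")))
message(sprintf("AL correlations: density r = %.2f, CT r = %.2f, AULCSF r = %.2f",
                cors$r[cors$y == "cone_density_inner"],
                cors$r[cors$y == "ct_inner"], cors$r[cors$y == "aulcsf"]))
rs <- regression_screen(cohort, "aulcsf",
                        c("al", "cone_density_outer", "ct_inner",
                          "cvi_inner", "is_inner"))
if (nrow(rs$final) > 0) {
  message(sprintf("final AULCSF model keeps: %s (R = %.3f)",
                  paste(rs$final$term, collapse = ", "), rs$r_model))
} else {
  message("final AULCSF model: no predictor retained at p < 0.05 ",
          "(the cohort's CSF couplings are weak, as in the study population)")
}
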