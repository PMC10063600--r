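#!/usr/bin/env Rscript
# Design-analysis numbers that depend only on printed statistics, not on any
# cohort: the z-to-d effect-size chain for the three group comparisons, the
# semipartial correlations and adjusted R2 recoverable from the regression
# table, and the sensitivity analyses for each design.
# Writes results/design_analyses.csv.

library(evaldiff)

rows <- list()
add <- function(quantity, value, note) {
  rows[[length(rows) + 1]] <<- data.frame(quantity = quantity, value = value,
                                          note = note)
}

# effect sizes from published z and group sizes
add("d_emotion_study1", effect_size_from_z(3.79, 15, 51)$d, "z=3.79, 15 vs 51")
add("d_evaluation_study1", effect_size_from_z(3.43, 15, 47)$d, "z=3.43, 15 vs 47")
add("d_evaluation_study2", effect_size_from_z(2.64, 31, 218)$d, "z=2.64, 31 vs 218")

# semipartial correlations from the regression table (R2=.082, df=290)
add("sr_crt", semipartial_from_t(2.916, 0.082, 290), "t=2.916")
add("sr_dif", semipartial_from_t(-2.360, 0.082, 290), "t=-2.360")
add("sr_eot", semipartial_from_t(-3.015, 0.082, 290), "t=-3.015")
add("adj_r2", adjusted_r2(0.082, 296, 5), "R2=.082, n=296, k=5")

# sensitivity analyses, two-tailed alpha=.05
add("detectable_r_n72", detectable_r(72)$minimal_detectable, "power .95")
add("detectable_r_n296", detectable_r(296)$minimal_detectable, "power .95")
add("detectable_d_15_47", detectable_d_wmw(15, 47)$minimal_detectable,
    "power .95, normal ARE")
add("detectable_d_31_218", detectable_d_wmw(31, 218)$minimal_detectable,
    "power .95, normal ARE")
add("detectable_f2_n296_k5", detectable_f2(296, 5, power = 0.80)$minimal_detectable,
    "power .80")

tab <- do.call(rbind, rows)
dir.create("results", showWarnings = FALSE)
write.csv(tab, "results/design_analyses.csv", row.names = FALSE)
print(tab, row.names = FALSE)
message("\nSo: the three d values and the correlation sensitivities land on ",
        "the published 1.05 / 0.967 / 0.339 and 0.4 / 0.2; the WMW ",
        "sensitivities come out at 1.094 / 0.708 under (power .95, normal ",
        "ARE) - no documented assumption reproduces the published 1.01 / ",
        "0.65 exactly, so the assumption is reported explicitly instead.")
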