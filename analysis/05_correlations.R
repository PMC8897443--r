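#!/usr/bin/env Rscript
# The prediction analyses: correlate pre- and post-DFC neural
# discriminability (mean Z_diff, SVM accuracy) of the conditioned mice with
# their learning specificity, with 1000-resample bootstrap confidence
# intervals, and test whether the pre- and post-DFC correlations differ
# (paired bootstrap over the same mice).

library(fearcortex)

report <- run_full_pipeline(cohort_config(seed = 20260925L),
                            n_resamples = 20, n_boot = 1000, seed = 303L)
write.csv(report$correlations, "results/correlations.csv", row.names = FALSE)
write.csv(report$mouse_table, "results/mouse_table.csv", row.names = FALSE)

mt <- report$mouse_table
cond <- mt[mt$group == "conditioned", ]
diff <- corr_difference_test(cond$zdiff_pre, cond$ls_retrieval1,
                             cond$zdiff_post, cond$ls_mean,
                             n_boot = 1000, seed = 304L)
write.csv(data.frame(analysis = "zdiff_pre_vs_post_prediction",
                     delta_r = diff$delta_r, ci_low = diff$ci_low,
                     ci_high = diff$ci_high, p = diff$p),
          "results/correlation_difference.csv", row.names = FALSE)

cat("Correlation analyses (conditioned mice, n = ", nrow(cond), "):\n", sep = "")
print(as.data.frame(report$correlations), digits = 3)
cat("\nPre- vs post-DFC prediction difference: delta r =",
    round(diff$delta_r, 3), " 95% CI [", round(diff$ci_low, 3), ",",
    round(diff$ci_high, 3), "], p =", round(diff$p, 3), "\n")
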