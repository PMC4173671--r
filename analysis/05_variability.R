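#!/usr/bin/env Rscript
# Step 5: population variability before and after the truncation.
#
# The synthetic twin of the observed abundance record: yearly lognormal
# abundance whose log-scale dispersion doubles at the 1976 truncation.
# The coefficient of variation (sample s.d. over mean) is computed in
# every sliding window of 3-11 years within each period; a truncated
# population shows higher CV at every window length. Writes
# results/cv_by_window.csv.

library(phenomatch)

seed <- 1L
ab <- gen_abundance(abundance_regime(split_year = 1976, sdlog_pre = 0.3,
                                     sdlog_post = 0.6),
                    n_years = 60, start_year = 1946, seed = seed)
res <- sliding_cv(ab, split_year = 1976, windows = 3:11)
utils::write.csv(res, "results/cv_by_window.csv", row.names = FALSE)

wide <- merge(res[res$period == "pre", c("w", "mean_cv")],
              res[res$period == "post", c("w", "mean_cv")],
              by = "w", suffixes = c("_pre", "_post"))
print(wide, row.names = FALSE)
cat(sprintf("post-period CV exceeds pre-period CV at every window: %s\n",
            all(wide$mean_cv_post > wide$mean_cv_pre)))
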