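#!/usr/bin/env Rscript
# Step 2: estimate spawning and zooplankton phenology year by year.
#
# Fits Gaussian curves to the weekly spawner catches (grouped multinomial
# likelihood over bin masses) and to the zooplankton counts
# (least-squares on the seasonal curve, since those are repeated point
# samples rather than partitioned counts). Peak = fitted mean; duration =
# four fitted standard deviations. Writes results/phenology.csv.

library(phenomatch)

catches <- utils::read.csv("results/data/catches.csv")
zoop <- utils::read.csv("results/data/zooplankton.csv")

spawning <- annual_phenology(catches, method = "grouped-likelihood")
spawning$event <- "spawning"
zoo_fit <- annual_phenology(zoop, method = "curve-least-squares")
zoo_fit$event <- "zooplankton"

tab <- rbind(spawning, zoo_fit)
tab <- tab[, c("year", "event", "peak_doy", "sigma_days", "duration_days",
               "flag")]
utils::write.csv(tab, "results/phenology.csv", row.names = FALSE)

ok <- tab$flag == "ok"
cat(sprintf("fitted %d year-events (%d flagged)\n", nrow(tab), sum(!ok)))
truth <- utils::read.csv("results/data/truth.csv")
sp <- spawning[order(spawning$year), ]
cat(sprintf("spawning peak RMSE vs truth: %.2f days\n",
            sqrt(mean((sp$peak_doy - truth$spawn_peak)^2))))
trend <- stats::lm(peak_doy ~ year, data = sp)
cat(sprintf("estimated spawning advance: %.2f d/yr (generated: -0.35 d/yr)\n",
            stats::coef(trend)[2]))
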