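#!/usr/bin/env Rscript
# Stage 5: longitudinal statistics. Aggregates the simulated cohort per
# visit and location, tests every later visit against baseline with paired
# t-tests (star annotations), and classifies the Pearson correlations
# between imaging metrics and subjective scores.

library(octavet)

cohort <- read_cohort_csv("results/study/cohort.csv")

agg_bvd <- aggregate_study(cohort, "bvd")
agg_vet <- aggregate_study(cohort, "vet_um")
grand <- subset(agg_bvd, location == "all")
message(sprintf("grand-mean BVD by visit: %s",
                paste(sprintf("%.1f%%", 100 * grand$mean), collapse = " -> ")))
grand_v <- subset(agg_vet, location == "all")
message(sprintf("grand-mean VET by visit: %s",
                paste(sprintf("%.0f um", grand_v$mean), collapse = " -> ")))

cmp_bvd <- compare_to_baseline(cohort, "bvd")
cmp_vet <- compare_to_baseline(cohort, "vet_um")
message("visit-4 BVD vs baseline: ",
        paste(sprintf("%s %s", cmp_bvd$location[cmp_bvd$visit == 4],
                      cmp_bvd$stars[cmp_bvd$visit == 4]), collapse = ", "))

pairs <- list(c("vhi", "vsq"), c("vsq", "bvd"), c("vhi", "bvd"),
              c("vhi", "vet_um"), c("vsq", "vet_um"))
cors <- do.call(rbind, lapply(pairs, function(p) {
  cr <- correlate_metrics(cohort, p[1], p[2])
  message(sprintf("|r(%s, %s)| = %.3f (%s)", p[1], p[2], cr$abs_r,
                  cr$strength))
  data.frame(metric_a = p[1], metric_b = p[2], r = cr$r, abs_r = cr$abs_r,
             strength = cr$strength, n = cr$n)
}))

utils::write.csv(rbind(cbind(metric = "bvd", agg_bvd),
                       cbind(metric = "vet_um", agg_vet)),
                 "results/study/aggregates.csv", row.names = FALSE)
utils::write.csv(rbind(cbind(metric = "bvd", cmp_bvd),
                       cbind(metric = "vet_um", cmp_vet)),
                 "results/study/comparisons.csv", row.names = FALSE)
utils::write.csv(cors, "results/study/correlations.csv", row.names = FALSE)
message("tables written to results/study/")
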