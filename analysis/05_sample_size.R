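#!/usr/bin/env Rscript
# Sample-size calculations: the pilot's two-mean design (8% absolute
# difference in percentage MAP-deficit, SD 9%) and the phase-III two-proportion
# design (14-day mortality 20% vs 14%, 2.5% attrition).

library(mapdeficit)

pilot <- sample_size_two_means(delta = 8, sd = 9, alpha = 0.05, power = 0.80)
cat("Pilot (two means, delta 8%, SD 9%):",
    pilot$per_group, "per group,", pilot$total, "total\n")

phase3 <- sample_size_two_proportions(p1 = 0.20, p2 = 0.14, alpha = 0.05,
                                      power = 0.80, attrition = 0.025)
cat("Phase III (two proportions, 20% vs 14%, 2.5% attrition):",
    phase3, "total\n")
cat("Without attrition:",
    sample_size_two_proportions(0.20, 0.14), "total\n")
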