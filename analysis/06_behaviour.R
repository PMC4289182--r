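#!/usr/bin/env Rscript
# Stage 6: day/night photo-behaviour analysis -- per-treatment daily
# means, F-test and Shapiro-Wilk gates, unpaired two-tailed t-tests,
# and the spectral-sensitivity verdicts.
suppressMessages(library(opsinminer))

beh <- read_behaviour_tsv("results/synthetic/behaviour.tsv")
v <- spectral_verdicts(beh)
write.table(v, "results/behaviour_stats.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

print(v[, c("treatment", "mean_day", "mean_night", "t_statistic",
            "p_value", "verdict")], row.names = FALSE)
cat("sensitive treatments:",
    paste(v$treatment[v$verdict == "sensitive"], collapse = ", "), "\n")
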