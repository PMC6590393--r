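#!/usr/bin/env Rscript
# Parameter screening: z-normalisation, multimodality index per parameter,
# and the |r| < 0.7 correlation filter ranked by multimodality. Writes
# results/selection.csv (one row per parameter with its fate).

suppressMessages(library(cytofractal))
features <- read_features_csv("results/features.csv")
z <- zscore(features)
report <- correlation_filter(z, r_threshold = 0.7)

fate <- data.frame(parameter = names(report$mmi),
                   mmi = unname(report$mmi),
                   retained = names(report$mmi) %in% report$retained)
fate <- merge(fate, report$dropped, by = "parameter", all.x = TRUE)
fate <- fate[order(-fate$mmi), ]
write.csv(fate, "results/selection.csv", row.names = FALSE)

cat(sprintf("%d of %d parameters retained at |r| < 0.7:\n",
            length(report$retained), length(report$mmi)))
print(report)
cat("\nDropped parameters and their blockers:\n")
print(report$dropped, row.names = FALSE)
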