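#!/usr/bin/env Rscript
# Stage 6: single-coverage mosaic selection — one image per tile by
# priority class (early dry season, near-nadir) with image-quality
# tiebreaks, so no tree can be counted twice.

library(drylandtrees)

catalog <- read.csv("results/inputs/image_catalog.csv")
sel <- select_mosaic(catalog)
write.csv(sel, "results/mosaic_selection.csv", row.names = FALSE)

cat(sprintf("selected %d of %d tiles (%d candidate images)\n",
            nrow(sel), length(unique(catalog$tile_id)), nrow(catalog)))
cat("priority class distribution of selected images:\n")
print(table(sel$priority_class))
cat(sprintf("%.0f%% of selections are early dry season (Nov-Jan), %.0f%% within 15 deg of nadir\n",
            100 * mean(sel$month %in% c(11, 12, 1)),
            100 * mean(abs(sel$off_nadir_deg) < 15)))
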