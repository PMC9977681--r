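#!/usr/bin/env Rscript
# Stage 1: simulate the study inputs — a rainfall-gradient landscape with
# individual tree crowns, destructive-sampling field campaigns, and a
# satellite image catalog. All downstream stages read these products.

library(drylandtrees)

out_dir <- "results/inputs"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

land <- gen_landscape(landscape_config(seed = 20260921L))
cat(sprintf("landscape: %d trees over %.0f ha along a 0-1000 mm/yr gradient\n",
            nrow(land$crowns),
            diff(land$config$extent[1:2]) * diff(land$config$extent[3:4]) / 1e4))
print(table(land$crowns$zone))

write_crowns_geojson(land$crowns, file.path(out_dir, "crowns.geojson"))
write_asc(land$field, file.path(out_dir, "rainfall.asc"))

samples <- gen_field_samples(field_sample_config(seed = 20260922L))
cat(sprintf("field campaigns: %d wood, %d foliage, %d root trees\n",
            nrow(samples$wood), nrow(samples$foliage), nrow(samples$root)))
write.csv(do.call(rbind, samples), file.path(out_dir, "field_samples.csv"),
          row.names = FALSE)

catalog <- gen_image_catalog(600, seed = 20260923L)
write.csv(catalog, file.path(out_dir, "image_catalog.csv"), row.names = FALSE)
cat(sprintf("image catalog: %d records over %d tiles\n",
            nrow(catalog), length(unique(catalog$tile_id))))
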