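#!/usr/bin/env Rscript
# Generate the synthetic open-chromatin region sets used by the
# enrichment screen: foreground regions half of which carry a planted
# palindromic SOX composite (inverted repeat, 4 bp spacer), and a large
# unplanted control set emulating a pooled-DHS background.

suppressPackageStartupMessages(library(dimerscreen))

seed <- 1
out <- "results"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

half <- consensus_to_pwm("ACAAAG", name = "SOX_ACAAAG")
cfg <- dimer_config(half, orientation = "inverted", spacer = 4)
cat("planting configuration: "); print(cfg)

sim <- simulate_region_sets(n_fg = 200, n_ctrl = 2000, length = 300,
                            config = cfg, plant_rate = 0.5, seed = seed)

write_region_set(sim$foreground, file.path(out, "foreground"))
write_region_set(sim$control, file.path(out, "control"))
write_results_tsv(sim$plants, file.path(out, "plant_records.tsv"),
                  seed = seed,
                  params = list(n_fg = 200, n_ctrl = 2000, length = 300,
                                plant_rate = 0.5, orientation = "inverted",
                                spacer = 4))
jsonlite::write_json(
  list(seed = seed, n_fg = 200, n_ctrl = 2000, length = 300,
       plant_rate = 0.5, motif = "ACAAAG", orientation = "inverted",
       spacer = 4),
  file.path(out, "simulate_regions.params.json"), auto_unbox = TRUE)

cat(sprintf("wrote %d foreground and %d control regions (%d planted)\n",
            n_regions(sim$foreground), n_regions(sim$control),
            nrow(sim$plants)))
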