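#!/usr/bin/env Rscript
# Score nascent-NPC holes on the synthetic membrane traces: enumerate gap
# candidates, apply the three acceptance criteria (< 100 nm, tapered edges,
# continuous flanks), and report per-region and mean densities for the
# control-like and depleted-like fields. Run analysis/01_simulate.R first.

suppressPackageStartupMessages(library(nedyn))
dir.create("results/holes", recursive = TRUE, showWarnings = FALSE)

objs <- read_pointlists("results/synthetic/membrane_traces.csv", units = "nm")
areas <- read.csv("results/synthetic/membrane_areas.csv")

# group chains back into their fields by label prefix
field_of <- sub("_chain[0-9]+$", "", vapply(objs, `[[`, character(1), "id"))
calls <- lapply(split(objs, field_of), function(chains_objs) {
  tr <- membrane_trace(lapply(chains_objs, `[[`, "xy"),
                       area_um2 = areas$area_um2[
                         areas$label == sub("_chain.*", "",
                                            chains_objs[[1]]$id)][1])
  lapply(detect_gaps(tr), classify_hole)
})

dens <- hole_density(calls, areas)
print(dens)
write.csv(dens$per_region, "results/holes/hole_densities.csv", row.names = FALSE)

is_ctl <- grepl("^control", dens$per_region$label)
mean_ctl <- mean(dens$per_region$density_per_um2[is_ctl])
mean_dep <- mean(dens$per_region$density_per_um2[!is_ctl])
cat(sprintf("mean density control-like: %.1f /um^2; depleted-like: %.1f /um^2 (%.1f-fold)\n",
            mean_ctl, mean_dep, mean_ctl / mean_dep))
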