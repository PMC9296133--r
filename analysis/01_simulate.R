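#!/usr/bin/env Rscript
# Generate the synthetic study inputs used by the downstream analysis
# scripts: a two-channel embryo time-lapse with known import kinetics, FRAP
# recovery series for a control-like and a depleted-like condition, traced
# sphere contours, and membrane-gap fields emulating tomogram traces of
# reforming ("control-like", many sub-100 nm holes) and depleted-like
# (few holes) nuclear envelopes.

suppressPackageStartupMessages(library(nedyn))
seed <- 20260926L
dir.create("results/synthetic", recursive = TRUE, showWarnings = FALSE)

# -- embryo time-lapse: 60 frames at 20 s, nucleus growing 2 -> 4.4 um ------
emb <- gen_embryo_timelapse(n_frames = 60, time_step_s = 20, noise_sd = 2,
                            import_start_frame = 5, seed = seed)
write_stack(emb$stack, "results/synthetic/embryo_timelapse.tif")
write.csv(emb$truth, "results/synthetic/embryo_truth.csv", row.names = FALSE)
cat(sprintf("embryo time-lapse: %d frames, true ratio plateau %.2f\n",
            nrow(emb$truth), max(emb$truth$ratio_true)))

# -- FRAP series: 8 replicates per condition ---------------------------------
# mobile fractions chosen at the two study conditions: stable outer-ring
# scaffold (A = 0.20) and destabilized scaffold (A = 0.47)
truth_A <- c(control = 0.20, depleted = 0.47)
frap <- do.call(rbind, lapply(names(truth_A), function(cond) {
  do.call(rbind, lapply(1:8, function(r) {
    cv <- gen_frap_curve(A = truth_A[[cond]], tau = 0.03, n_post = 60,
                         noise_sd = 0.05,
                         seed = seed + round(1000 * truth_A[[cond]]) + r)
    cbind(condition = cond, replicate = r, cv)
  }))
}))
write.csv(frap, "results/synthetic/frap_curves.csv", row.names = FALSE)
cat(sprintf("FRAP curves: %d rows, %d condition x replicate series\n",
            nrow(frap), length(unique(paste(frap$condition, frap$replicate)))))

# -- sphere contours for the volume analysis --------------------------------
cs <- gen_sphere_contours(radius_um = 4, z_step_um = 0.1625, n_vertices = 256,
                          jitter_um = 0.05, seed = seed)
objs <- lapply(seq_along(cs$slices), function(i)
  list(id = "pronucleus", slice = cs$z_index[i], xy = cs$slices[[i]],
       closed = TRUE))
write_pointlists(objs, "results/synthetic/pronucleus_contours.csv", units = "um")
cat(sprintf("contours: %d slices of a jittered r = 4 um sphere\n",
            length(cs$slices)))

# -- membrane-gap fields -----------------------------------------------------
# control-like: many tapered sub-100 nm gaps; depleted-like: few, mostly
# blunt or wide gaps
set.seed(seed)
fields <- list(
  control_1 = list(widths = c(45, 60, 55, 70, 80), taper = TRUE,  area = 0.10),
  control_2 = list(widths = c(50, 65, 75, 90),     taper = TRUE,  area = 0.08),
  depleted_1 = list(widths = c(60, 120),
                    taper = c(TRUE, TRUE),         area = 0.20),
  depleted_2 = list(widths = c(130, 95),
                    taper = c(FALSE, FALSE),       area = 0.18))
rows <- list()
for (lab in names(fields)) {
  f <- fields[[lab]]
  g <- gen_membrane_field(f$widths, tapered = f$taper, flank_nm = 300,
                          field_area_um2 = f$area, seed = seed + nchar(lab))
  for (ci in seq_along(g$trace$chains))
    rows[[length(rows) + 1]] <- list(id = paste0(lab, "_chain", ci), slice = 1,
                                     xy = g$trace$chains[[ci]], closed = FALSE)
  cat(sprintf("field %s: %d gaps over %.2f um^2\n", lab, length(f$widths), f$area))
}
write_pointlists(rows, "results/synthetic/membrane_traces.csv", units = "nm")
write.csv(data.frame(label = names(fields),
                     area_um2 = vapply(fields, `[[`, numeric(1), "area")),
          "results/synthetic/membrane_areas.csv", row.names = FALSE)

cat("synthetic inputs written under results/synthetic/\n")
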