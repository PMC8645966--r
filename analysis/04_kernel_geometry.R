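#!/usr/bin/env Rscript
# Geometry of the lateral connectivity kernel in position-orientation
# coordinates: hypercolumn orientation tuning, the orientation-weighted
# vector field, association-field streamlines and circular-arc fits.
#
# Runs the full analysis chain on the synthetic ground-truth bundle (so
# every recovered quantity can be compared with its generator value) and,
# if 02_train_smoke.R has produced one, also on the trained bundle.

library(lgncnn)

outdir <- "results"
dir.create(outdir, showWarnings = FALSE)

set.seed(1)
b <- make_synthetic_bundle(n_theta = 32, seed = 2)
message("Analysing the synthetic ground-truth bundle ...")
rep <- run_analysis(b, outdir = file.path(outdir, "synthetic_analysis"),
                    figures = TRUE)
print(rep)

rk <- rep$reparam[[rep$reference$parity]]
raw <- hypercolumn_profile(rk, rep$reference$index, smooth = FALSE)
expected <- b$kernel$dog(lgncnn:::orientation_diff(raw$theta_g, raw$theta_f))
message(sprintf("Mexican-hat profile vs generator: correlation %.4f",
                cor(raw$raw, expected)))
message(sprintf("association-field arcs: k in [%.3f, %.3f], grand mean distance %.4f",
                min(rep$arcs$k), max(rep$arcs$k), rep$grand_mean_distance))

trained <- file.path(outdir, "trained_bundle.rds")
if (file.exists(trained)) {
  message("Analysing the trained bundle ...")
  rep_t <- run_analysis(load_bundle(trained),
                        outdir = file.path(outdir, "trained_analysis"),
                        figures = TRUE)
  print(rep_t)
}
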