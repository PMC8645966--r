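#!/usr/bin/env Rscript
# Receptive-profile analysis of a weight bundle: LoG fit of the LGN
# filter and Gabor fits of the first-layer bank, with parity counts and
# orientation ordering. Uses the trained bundle from 02_train_smoke.R if
# present, otherwise a fully synthetic bundle with known ground truth.

library(lgncnn)

outdir <- "results"
dir.create(outdir, showWarnings = FALSE)

bundle_path <- file.path(outdir, "trained_bundle.rds")
if (file.exists(bundle_path)) {
  message("Using trained bundle: ", bundle_path)
  bundle <- load_bundle(bundle_path)
} else {
  message("No trained bundle found; using the synthetic ground-truth bundle.")
  set.seed(1)
  bundle <- make_synthetic_bundle(n_theta = 32, seed = 2)
}

lf <- fit_log(bundle$psi0)
message(sprintf("LGN filter: best-fit LoG sigma = %.3f, correlation = %.2f%% (p = %.2g)",
                lf$sigma, 100 * lf$correlation, lf$p_value))

fb <- fit_filter_bank(bundle$l1_filters)
message(sprintf("Gabor fits: mean correlation = %.2f%% over %d filters; parity: %s",
                100 * mean(fb$table$correlation), nrow(fb$table),
                paste(names(table(fb$table$parity)), table(fb$table$parity),
                      sep = "=", collapse = ", ")))

write.csv(data.frame(sigma = lf$sigma, correlation = lf$correlation,
                     p_value = lf$p_value),
          file.path(outdir, "log_fit.csv"), row.names = FALSE)
write.csv(fb$table, file.path(outdir, "gabor_fits.csv"), row.names = FALSE)

# gallery of filters ordered by orientation, with their fitted surfaces
dir.create(file.path(outdir, "figures"), showWarnings = FALSE)
perm <- order_by_orientation(fb$table$theta)
png(file.path(outdir, "figures", "filter_gallery.png"), 1200, 600)
n <- length(perm)
op <- par(mfrow = c(4, ceiling(n / 2)), mar = c(0.4, 0.4, 1.2, 0.4))
for (i in perm) {
  image(t(fb$normalized_bank[nrow(fb$normalized_bank):1, , i]),
        col = gray.colors(64), axes = FALSE,
        main = sprintf("f%d %.0f°", i, fb$table$theta[i] * 180 / pi),
        cex.main = 0.8)
}
for (i in perm) {
  image(t(fb$fits[[i]]$fitted[nrow(fb$fits[[i]]$fitted):1, ]),
        col = gray.colors(64), axes = FALSE,
        main = sprintf("fit %.2f", fb$table$correlation[i]), cex.main = 0.8)
}
par(op); dev.off()
message("Gallery written to results/figures/filter_gallery.png")
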