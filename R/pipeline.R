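# Orchestration: weight bundles, the end-to-end kernel-geometry analysis
# and the architecture-comparison experiment. CSV tables are the tested
# surface; figures are side effects.

#' Save a weight bundle with a JSON metadata sidecar
#'
#' A bundle is a named list with entries `psi0` (LGN filter matrix),
#' `l1_filters` (array `(s, s, n)`), optionally `K1` (array
#' `(D, D, n, n)`), and free-form `meta`. It is stored as a compressed
#' RDS file plus `<path>.json` recording shapes, configuration and seed
#' for provenance.
#'
#' @param bundle named list as above.
#' @param path output file path (`.rds`).
#' @return invisibly, `path`.
#' @export
save_bundle <- function(bundle, path) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  saveRDS(bundle, path, compress = "gzip")
  meta <- list(
    entries = names(bundle),
    shapes = lapply(bundle, function(x) if (is.array(x) || is.matrix(x)) dim(x) else NULL),
    meta = bundle$meta
  )
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Load a weight bundle
#' @param path path written by [save_bundle()].
#' @return the bundle list.
#' @export
load_bundle <- function(path) readRDS(path)

#' Extract a weight bundle from a trained network
#' @param net an `lgn_network`.
#' @param meta optional free-form metadata list.
#' @return bundle list with `psi0`, `l1_filters`, `K1` (if present),
#'   `meta`.
#' @export
network_bundle <- function(net, meta = list()) {
  psi0 <- get_weights(net, "l0")
  l1 <- get_weights(net, "l1")
  K1 <- get_weights(net, "K1")
  b <- list(meta = meta)
  if (!is.null(psi0)) b$psi0 <- matrix(psi0, dim(psi0)[1], dim(psi0)[2])
  if (!is.null(l1)) {
    d <- dim(l1)  # (s, s, 1, n) -> (s, s, n)
    b$l1_filters <- array(l1, c(d[1], d[2], d[4]))
  }
  if (!is.null(K1)) b$K1 <- K1
  b
}

#' Analysis configuration
#'
#' Tunable parameters of the geometric analysis, with the defaults used
#' throughout the package.
#'
#' @param min_correlation Gabor-fit retention threshold; filters below it
#'   are flagged "complex shape" and excluded from kernel geometry.
#' @param smooth_window hypercolumn-profile moving-average window
#'   (samples).
#' @param upsample spatial-projection magnification factor.
#' @param n_seeds,seed_spacing association-field seed layout (count,
#'   spacing in cells along the trans-axial segment).
#' @param step streamline integration step (cells).
#' @param max_steps streamline step cap per direction.
#' @param k_range arc-fit curvature search interval.
#' @param reference `"median"` picks the filter with the median
#'   orientation of the larger parity group as the reference; or a
#'   numeric orientation (radians) whose nearest filter is used.
#' @return object of class `analysis_config`.
#' @export
analysis_config <- function(min_correlation = 0.5, smooth_window = 5,
                            upsample = 10, n_seeds = 7, seed_spacing = 0.5,
                            step = 0.1, max_steps = 1e4,
                            k_range = c(-5, 5), reference = "median") {
  cfg <- list(min_correlation = min_correlation, smooth_window = smooth_window,
              upsample = upsample, n_seeds = n_seeds,
              seed_spacing = seed_spacing, step = step,
              max_steps = max_steps, k_range = k_range,
              reference = reference)
  class(cfg) <- "analysis_config"
  cfg
}

pick_reference <- function(rk, reference) {
  if (is.numeric(reference))
    return(which.min(abs(orientation_diff(rk$thetas, reference))))
  ord_mid <- ceiling(length(rk$thetas) / 2)
  ord_mid
}

#' Run the full geometric analysis on a weight bundle
#'
#' Executes the analysis chain: LoG fit of the LGN filter, Gabor fits of
#' the first-layer bank, parity split / sign normalization / orientation
#' ordering, re-parameterization of the lateral kernel into
#' position-orientation coordinates, hypercolumn orientation-tuning
#' profile, orientation-weighted vector field, association-field
#' streamlines and per-curve circular-arc fits. Deterministic given
#' `(bundle, cfg)`.
#'
#' @param bundle list with `psi0`, `l1_filters` and optionally `K1` (see
#'   [network_bundle()]); a missing `K1` yields a report with the kernel
#'   sections marked absent.
#' @param cfg an [analysis_config()].
#' @param outdir optional directory; when given, CSV tables (and figures
#'   if `figures = TRUE`) are written there.
#' @param figures write PNG figures? (Requires `outdir`.)
#' @return object of class `analysis_report`: list with `log_fit`
#'   (sigma, correlation, p-value), `gabor_table`, `parity_counts`,
#'   `reparam` (per-parity kernels), `profile` (hypercolumn tuning),
#'   `field`, `association` (curves), `arcs` (per-seed curvature table
#'   with the grand mean distance), `config`.
#' @export
run_analysis <- function(bundle, cfg = analysis_config(), outdir = NULL,
                         figures = FALSE) {
  stopifnot(inherits(cfg, "analysis_config"))
  for (need in c("psi0", "l1_filters"))
    if (is.null(bundle[[need]])) stop("bundle is missing entry '", need, "'")
  report <- list(config = cfg)

  lf <- fit_log(bundle$psi0)
  report$log_fit <- list(sigma = lf$sigma, correlation = lf$correlation,
                         p_value = lf$p_value, amplitude = lf$amplitude)

  fb <- fit_filter_bank(bundle$l1_filters, min_correlation = cfg$min_correlation)
  report$gabor_table <- fb$table
  report$parity_counts <- table(factor(fb$table$parity[fb$table$retained],
                                       levels = c("even", "odd")))
  report$mean_gabor_correlation <- mean(fb$table$correlation)

  if (is.null(bundle$K1)) {
    report$kernel_absent <- TRUE
  } else {
    s <- dim(bundle$l1_filters)[1]
    rep_k <- reparameterize(bundle$K1, fb$table, filter_size = s)
    report$reparam <- rep_k
    # analyse the parity group with more retained filters
    sizes <- vapply(rep_k, function(r) length(r$thetas), numeric(1))
    rk <- rep_k[[which.max(sizes)]]
    f_ref <- pick_reference(rk, cfg$reference)
    report$reference <- list(parity = rk$parity, index = f_ref,
                             theta_f = rk$thetas[f_ref])
    report$profile <- hypercolumn_profile(rk, f_ref, smooth = TRUE,
                                          window = cfg$smooth_window)
    report$projection <- project_spatial(rk, f_ref, upsample = cfg$upsample)
    report$field <- vector_field(rk, f_ref)
    report$association <- streamlines(report$field,
                                      theta_f = rk$thetas[f_ref],
                                      step = cfg$step,
                                      max_steps = cfg$max_steps,
                                      n_seeds = cfg$n_seeds,
                                      seed_spacing = cfg$seed_spacing)
    report$arcs <- fit_association_arcs(report$association,
                                        k_range = cfg$k_range)
    report$grand_mean_distance <- mean(report$arcs$mean_distance)
  }
  class(report) <- "analysis_report"
  if (!is.null(outdir)) write_report(report, outdir, figures = figures)
  report
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("Analysis report\n")
  cat(sprintf("  LGN filter: LoG sigma = %.4f, correlation = %.4f\n",
              x$log_fit$sigma, x$log_fit$correlation))
  cat(sprintf("  Gabor bank: mean correlation = %.4f (%d filters)\n",
              x$mean_gabor_correlation, nrow(x$gabor_table)))
  cat("  parity counts:", paste(names(x$parity_counts), x$parity_counts,
                                collapse = ", ", sep = " = "), "\n")
  if (isTRUE(x$kernel_absent)) {
    cat("  lateral kernel: absent (kernel sections skipped)\n")
  } else {
    cat(sprintf("  reference filter: parity %s, theta_f = %.3f rad\n",
                x$reference$parity, x$reference$theta_f))
    cat(sprintf("  association field: %d curves, grand mean arc distance = %.4g\n",
                length(x$association$curves), x$grand_mean_distance))
  }
  invisible(x)
}

#' Write the CSV tables (and optional figures) of an analysis report
#'
#' @param report an `analysis_report`.
#' @param outdir output directory.
#' @param figures also write PNG figures.
#' @return invisibly, the vector of files written.
#' @export
write_report <- function(report, outdir, figures = FALSE) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  wcsv <- function(df, name) {
    p <- file.path(outdir, name)
    utils::write.csv(df, p, row.names = FALSE)
    files <<- c(files, p)
  }
  wcsv(data.frame(sigma = report$log_fit$sigma,
                  correlation = report$log_fit$correlation,
                  p_value = report$log_fit$p_value), "log_fit.csv")
  wcsv(report$gabor_table, "gabor_fits.csv")
  if (!isTRUE(report$kernel_absent)) {
    wcsv(data.frame(theta_g = report$profile$theta_g,
                    strength = report$profile$strength,
                    raw = report$profile$raw,
                    theta_f = report$profile$theta_f),
         "hypercolumn_profile.csv")
    wcsv(report$arcs, "association_arcs.csv")
  }
  if (figures) {
    figdir <- file.path(outdir, "figures")
    dir.create(figdir, showWarnings = FALSE)
    if (!isTRUE(report$kernel_absent)) {
      p <- file.path(figdir, "association_field.png")
      grDevices::png(p, width = 700, height = 700)
      plot_association_field(report)
      grDevices::dev.off()
      files <- c(files, p)
      p <- file.path(figdir, "hypercolumn_profile.png")
      grDevices::png(p, width = 700, height = 450)
      plot(report$profile$theta_g, report$profile$strength, type = "l",
           xlab = expression(theta[g]), ylab = "connection strength",
           main = sprintf("Hypercolumn tuning around theta_f = %.2f",
                          report$profile$theta_f))
      graphics::abline(v = report$profile$theta_f, lty = 2)
      grDevices::dev.off()
      files <- c(files, p)
    }
  }
  invisible(files)
}

#' Plot the kernel projection with vector field and association curves
#'
#' Reproduces the standard layout: spatial projection of the kernel as an
#' intensity image, the orientation-weighted vector field as arrows, and
#' the association-field streamlines overlaid.
#'
#' @param report an `analysis_report` with kernel sections.
#' @export
plot_association_field <- function(report) {
  pr <- report$projection
  # image() wants x ascending and the matrix transposed to (x, y)
  graphics::image(pr$x, rev(pr$y), t(pr$map[nrow(pr$map):1, ]),
                  col = grDevices::gray(seq(1, 0, length.out = 64)),
                  xlab = "x (cells)", ylab = "y (cells)", asp = 1)
  vf <- report$field
  r <- vf$r
  idx <- which(vf$vx != 0 | vf$vy != 0, arr.ind = TRUE)
  if (nrow(idx)) {
    x0 <- idx[, 2] - r - 1; y0 <- -(idx[, 1] - r - 1)
    vx <- vf$vx[idx]; vy <- vf$vy[idx]
    sc <- 0.4 / max(sqrt(vx^2 + vy^2))
    graphics::arrows(x0, y0, x0 + sc * vx, y0 + sc * vy,
                     length = 0.04, col = "blue")
  }
  for (cv in report$association$curves)
    graphics::lines(cv[, 1], cv[, 2], col = "blue", lwd = 2)
  if (!is.null(report$arcs)) {
    for (i in seq_len(nrow(report$arcs))) {
      cv <- report$association$curves[[report$arcs$seed[i]]]
      anchor <- report$association$anchors[report$arcs$seed[i]]
      seg <- sqrt(rowSums(diff(cv)^2))
      s <- c(0, cumsum(seg)) - c(0, cumsum(seg))[anchor]
      arc <- integral_curve(report$arcs$k[i], sort(unique(s)),
                            start = c(cv[anchor, ], report$association$theta_f))
      graphics::lines(arc[, "x"], arc[, "y"], col = "red", lty = 2)
    }
  }
  invisible(NULL)
}

#' Compare classical CNN, LGN-CNN and LGN-CNN with lateral kernel
#'
#' Trains the three configurations (no LGN layer / LGN layer only / LGN
#' layer plus lateral kernel) across `n_seeds` seeds at the given
#' (typically reduced) scale and reports mean accuracy with the standard
#' error of the mean.
#'
#' @param dataset list with `x`, `y` (see [train_network()]).
#' @param base_cfg an [arch_config()] describing the shared backbone;
#'   `use_l0` / `use_lateral` are overridden per configuration.
#' @param train_cfg a [training_config()]; its seed is offset per run.
#' @param n_seeds seeds per configuration (>= 2 for a finite SEM).
#' @return data frame with one row per configuration: mean validation
#'   accuracy, SEM, and the per-seed accuracies as a comma-joined string.
#' @export
compare_architectures <- function(dataset, base_cfg, train_cfg, n_seeds = 2) {
  stopifnot(n_seeds >= 2)
  variants <- list(
    classical = list(use_l0 = FALSE, use_lateral = FALSE),
    lgn = list(use_l0 = TRUE, use_lateral = FALSE),
    lgn_lateral = list(use_l0 = TRUE, use_lateral = TRUE)
  )
  rows <- lapply(names(variants), function(nm) {
    v <- variants[[nm]]
    accs <- vapply(seq_len(n_seeds), function(si) {
      cfg <- base_cfg
      cfg$use_l0 <- v$use_l0; cfg$use_lateral <- v$use_lateral
      tc <- train_cfg; tc$seed <- train_cfg$seed + si * 1000L
      set.seed(tc$seed)
      net <- build_network(cfg)
      phases <- if (v$use_lateral)
        c("pretrain_feedforward", "joint_with_lateral") else "pretrain_feedforward"
      train_network(net, dataset, tc, phases = phases)$val_acc
    }, numeric(1))
    data.frame(config = nm, mean_acc = mean(accs),
               sem = stats::sd(accs) / sqrt(n_seeds),
               accs = paste(signif(accs, 4), collapse = ","))
  })
  do.call(rbind, rows)
}
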