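# Shared fixtures, all generated in code.

# random lateral kernel and activation with reproducible contents
random_kernel <- function(D, n, seed = 1) {
  set.seed(seed)
  array(stats::rnorm(D * D * n * n), c(D, D, n, n))
}

random_activation <- function(H, N, C, seed = 2) {
  set.seed(seed)
  array(stats::rnorm(H * H * N * C), c(H, H, N, C))
}

# activation that is zero within `margin` cells of the spatial border, so
# zero-padded kernel composition identities hold exactly
padded_activation <- function(H, N, C, margin, seed = 2) {
  h <- random_activation(H, N, C, seed)
  h[c(seq_len(margin), H - seq_len(margin) + 1), , , ] <- 0
  h[, c(seq_len(margin), H - seq_len(margin) + 1), , ] <- 0
  h
}

# a tiny architecture used across network tests
tiny_arch <- function(...) {
  arch_config(l0_size = 3, lateral_size = 3,
              conv_spec = data.frame(filters = c(3, 4), size = c(3, 3),
                                     pool_after = c(TRUE, FALSE)),
              fc_widths = c(6, 2), n_classes = 2, input_size = 8,
              dropout_final = 0, ...)
}

angdiff_deg <- function(a, b) abs(lgncnn:::orientation_diff(a, b)) * 180 / pi
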