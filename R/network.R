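#' Architecture configuration for the LGN-inspired CNN
#'
#' The reference architecture is a grayscale image classifier made of a
#' single-filter pre-processing layer (the "LGN layer", one `l0_size x
#' l0_size` filter followed by ReLU and batch normalization), a stack of
#' convolutional layers each followed by ReLU and batch normalization with
#' zero padding preserving the spatial size, max pooling after selected
#' layers, and three fully connected heads. The first convolutional layer
#' additionally carries a lateral connectivity kernel `K` of size
#' `lateral_size^2 x n x n` applied through [lateral_update()].
#'
#' Defaults reproduce the reference stack: l1 64@7x7 (pool), l2 64@5x5,
#' l3-l4 64@3x3 (pool), l5-l6 64@3x3, l7 128@3x3 (pool), l8-l10 128@3x3
#' (pool), FC 1000/200/`n_classes`, with a 13x13x64x64 lateral kernel and
#' an 11x11 LGN filter.
#'
#' @param l0_size odd side of the LGN filter.
#' @param lateral_size odd side of the lateral kernel spatial support; the
#'   displacement range is then `{-r..r}^2` with `r = (lateral_size-1)/2`.
#' @param conv_spec data frame with columns `filters`, `size`, `pool_after`
#'   describing the convolutional stack (first row is the layer carrying
#'   the lateral kernel).
#' @param fc_widths integer vector of fully connected widths; the last
#'   entry is replaced by `n_classes`.
#' @param n_classes number of output classes.
#' @param input_size spatial side of the (square, single-channel) input.
#' @param use_l0 include the LGN pre-filtering layer?
#' @param use_lateral include the lateral connectivity kernel on the first
#'   convolutional layer? (`use_l0 = FALSE, use_lateral = FALSE` is the
#'   classical-CNN baseline.)
#' @param unit_fraction scales every convolutional filter count (rounded,
#'   minimum 1); used for the architecture-comparison sweeps.
#' @param dropout_final dropout probability after the last convolutional
#'   layer.
#' @return object of class `arch_config`.
#' @export
arch_config <- function(l0_size = 11,
                        lateral_size = 13,
                        conv_spec = default_conv_spec(),
                        fc_widths = c(1000, 200, 10),
                        n_classes = 10,
                        input_size = 32,
                        use_l0 = TRUE,
                        use_lateral = TRUE,
                        unit_fraction = 1,
                        dropout_final = 0.5) {
  stopifnot(l0_size %% 2 == 1, lateral_size %% 2 == 1,
            unit_fraction > 0, unit_fraction <= 1,
            all(conv_spec$size %% 2 == 1), nrow(conv_spec) >= 1)
  conv_spec$filters <- pmax(1L, as.integer(round(conv_spec$filters * unit_fraction)))
  fc_widths[length(fc_widths)] <- n_classes
  cfg <- list(l0_size = l0_size, lateral_size = lateral_size,
              conv_spec = conv_spec, fc_widths = fc_widths,
              n_classes = n_classes, input_size = input_size,
              use_l0 = use_l0, use_lateral = use_lateral,
              unit_fraction = unit_fraction, dropout_final = dropout_final)
  class(cfg) <- "arch_config"
  cfg
}

#' Reference convolutional stack
#' @return data frame with columns `filters`, `size`, `pool_after`.
#' @export
default_conv_spec <- function() {
  data.frame(
    filters    = c(64, 64, 64, 64, 64, 64, 128, 128, 128, 128),
    size       = c(7, 5, 3, 3, 3, 3, 3, 3, 3, 3),
    pool_after = c(TRUE, FALSE, FALSE, TRUE, FALSE, FALSE, TRUE, FALSE, FALSE, TRUE)
  )
}

#' A reduced stack for desk-scale experiments
#'
#' Three convolutional layers on small inputs; same building blocks as the
#' reference stack.
#' @param filters integer vector of filter counts.
#' @export
reduced_conv_spec <- function(filters = c(12, 16, 16)) {
  data.frame(filters = filters,
             size = c(5, 3, 3)[seq_along(filters)],
             pool_after = c(TRUE, TRUE, FALSE)[seq_along(filters)])
}

he_init <- function(dims, fan_in) {
  array(stats::rnorm(prod(dims), sd = sqrt(2 / fan_in)), dims)
}

#' Initialize the lateral kernel
#'
#' Zero-mean uniform entries scaled by `1/(n * D^2)` so the initial
#' propagated activation is small relative to the feedforward one.
#' @param D odd spatial side, `n` filter count.
#' @param n number of filters.
#' @return array `(D, D, n, n)`.
#' @export
init_lateral_kernel <- function(D, n) {
  c0 <- 1 / (n * D^2)
  array(stats::runif(D * D * n * n, -c0, c0), c(D, D, n, n))
}

#' Build an LGN-CNN network
#'
#' Assembles the layer list with freshly initialized weights (He-scaled
#' Gaussians for convolutional and fully connected weights; the lateral
#' kernel via [init_lateral_kernel()]). Weight initialization draws from
#' R's RNG, so seed before calling for reproducibility.
#'
#' @param cfg an [arch_config()].
#' @return object of class `lgn_network`: list of layers plus bookkeeping.
#'   The lateral kernel starts inactive (`lateral_active = FALSE`); the
#'   two-phase [train_network()] activates it for the joint phase.
#' @export
build_network <- function(cfg) {
  stopifnot(inherits(cfg, "arch_config"))
  layers <- list()
  sz <- cfg$input_size
  ch <- 1L
  add <- function(l) layers[[length(layers) + 1]] <<- l
  if (cfg$use_l0) {
    add(list(type = "conv", W = he_init(c(cfg$l0_size, cfg$l0_size, ch, 1), cfg$l0_size^2 * ch),
             b = numeric(1), tag = "l0"))
    add(list(type = "relu"))
    add(list(type = "bn", gamma = rep(1, 1), beta = rep(0, 1),
             rm = rep(0, 1), rv = rep(1, 1), eps = 1e-5, mom = 0.1))
    ch <- 1L
  }
  for (i in seq_len(nrow(cfg$conv_spec))) {
    nf <- cfg$conv_spec$filters[i]; ks <- cfg$conv_spec$size[i]
    add(list(type = "conv", W = he_init(c(ks, ks, ch, nf), ks^2 * ch),
             b = numeric(nf), tag = paste0("l", i)))
    add(list(type = "relu"))
    add(list(type = "bn", gamma = rep(1, nf), beta = rep(0, nf),
             rm = rep(0, nf), rv = rep(1, nf), eps = 1e-5, mom = 0.1))
    ch <- nf
    if (i == 1 && cfg$use_lateral) {
      add(list(type = "lateral",
               K = init_lateral_kernel(cfg$lateral_size, nf),
               p_drop = 0.2, tag = "K1"))
    }
    if (cfg$conv_spec$pool_after[i]) {
      if (sz %% 2 != 0) stop("config error: spatial size ", sz, " not divisible by 2 at pool after l", i)
      add(list(type = "pool"))
      sz <- sz / 2
    }
  }
  add(list(type = "dropout", p = cfg$dropout_final))
  add(list(type = "flatten"))
  fin <- sz * sz * ch
  for (j in seq_along(cfg$fc_widths)) {
    fout <- cfg$fc_widths[j]
    add(list(type = "fc", W = he_init(c(fin, fout), fin), b = numeric(fout),
             act = if (j < length(cfg$fc_widths)) "relu" else "none",
             tag = paste0("FC", j)))
    fin <- fout
  }
  net <- list(layers = layers, cfg = cfg, lateral_active = FALSE,
              final_spatial = sz)
  class(net) <- "lgn_network"
  net
}

#' @export
print.lgn_network <- function(x, ...) {
  cat("LGN-CNN network:", length(x$layers), "layers;",
      "lateral", if (x$lateral_active) "active" else "inactive", "\n")
  for (l in x$layers) {
    if (l$type == "conv")
      cat(sprintf("  conv %-4s W: %s\n", l$tag %||% "", paste(dim(l$W), collapse = "x")))
    if (l$type == "lateral")
      cat(sprintf("  lateral K1: %s (dropout %.2f)\n", paste(dim(l$K), collapse = "x"), l$p_drop))
    if (l$type == "fc")
      cat(sprintf("  fc   %-4s W: %s act=%s\n", l$tag %||% "", paste(dim(l$W), collapse = "x"), l$act))
    if (l$type == "pool") cat("  maxpool 2x2\n")
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Extract a named weight array from a network
#' @param net an `lgn_network`.
#' @param tag layer tag, e.g. `"l0"`, `"l1"`, `"K1"`.
#' @return the weight array (`W` for conv/fc layers, `K` for the lateral
#'   layer), or `NULL` if absent.
#' @export
get_weights <- function(net, tag) {
  for (l in net$layers) {
    if (identical(l$tag, tag)) return(if (l$type == "lateral") l$K else l$W)
  }
  NULL
}

set_weights <- function(net, tag, value) {
  for (i in seq_along(net$layers)) {
    if (identical(net$layers[[i]]$tag, tag)) {
      if (net$layers[[i]]$type == "lateral") net$layers[[i]]$K <- value
      else net$layers[[i]]$W <- value
      return(net)
    }
  }
  stop("no layer with tag ", tag)
}

# ---- forward / backward ----------------------------------------------------

bn_stats <- function(M) {
  m <- colMeans(M)
  v <- colMeans(M^2) - m^2
  list(m = m, v = v)
}

forward_layer <- function(l, x, train, lateral_active) {
  switch(l$type,
    conv = {
      out <- conv_same(x, l$W)
      out <- sweep(out, 4, l$b, "+")
      list(out = out, cache = list(x = x))
    },
    relu = {
      out <- x * (x > 0)
      list(out = out, cache = list(mask = x > 0))
    },
    bn = {
      d <- dim(x); C <- d[4]
      M <- matrix(x, prod(d[1:3]), C)
      if (train) {
        st <- bn_stats(M)
        mu <- st$m; va <- st$v
      } else {
        mu <- l$rm; va <- l$rv
      }
      xhat <- sweep(sweep(M, 2, mu, "-"), 2, sqrt(va + l$eps), "/")
      out <- sweep(sweep(xhat, 2, l$gamma, "*"), 2, l$beta, "+")
      list(out = array(out, d),
           cache = list(xhat = xhat, mu = mu, va = va, d = d, train = train),
           stat_update = if (train) list(mu = mu, va = va) else NULL)
    },
    lateral = {
      if (!lateral_active) return(list(out = x, cache = list(skipped = TRUE)))
      K <- l$K
      mask <- NULL
      if (train && l$p_drop > 0) {
        mask <- array(stats::rbinom(length(K), 1, 1 - l$p_drop), dim(K)) / (1 - l$p_drop)
        K <- K * mask
      }
      out <- 0.5 * (x + kernel_apply(x, K))
      list(out = out, cache = list(x = x, Keff = K, mask = mask))
    },
    pool = {
      d <- dim(x)
      a <- array(x, c(2, d[1] / 2, 2, d[2] / 2, d[3], d[4]))
      m <- pmax(a[1, , 1, , , , drop = FALSE], a[2, , 1, , , , drop = FALSE],
                a[1, , 2, , , , drop = FALSE], a[2, , 2, , , , drop = FALSE])
      out <- array(m, c(d[1] / 2, d[2] / 2, d[3], d[4]))
      list(out = out, cache = list(a = a, m = m, d = d))
    },
    dropout = {
      if (!train || l$p == 0) return(list(out = x, cache = list(mask = NULL)))
      mask <- array(stats::rbinom(length(x), 1, 1 - l$p), dim(x)) / (1 - l$p)
      list(out = x * mask, cache = list(mask = mask))
    },
    flatten = {
      d <- dim(x)
      out <- t(matrix(aperm(x, c(1, 2, 4, 3)), d[1] * d[2] * d[4], d[3]))
      list(out = out, cache = list(d = d))
    },
    fc = {
      z <- sweep(x %*% l$W, 2, l$b, "+")
      out <- if (l$act == "relu") z * (z > 0) else z
      list(out = out, cache = list(x = x, z = z))
    },
    stop("unknown layer type ", l$type)
  )
}

backward_layer <- function(l, dout, cache) {
  switch(l$type,
    conv = {
      kh <- dim(l$W)[1]; kw <- dim(l$W)[2]
      list(dx = conv_same_grad_x(dout, l$W),
           grads = list(W = conv_same_grad_w(cache$x, dout, kh, kw),
                        b = colSums(matrix(dout, ncol = dim(l$W)[4]))))
    },
    relu = list(dx = dout * cache$mask, grads = NULL),
    bn = {
      d <- cache$d; C <- d[4]; m <- prod(d[1:3])
      Dm <- matrix(dout, m, C)
      dgamma <- colSums(Dm * cache$xhat)
      dbeta <- colSums(Dm)
      if (!cache$train) {
        dx <- sweep(sweep(Dm, 2, l$gamma, "*"), 2, sqrt(cache$va + l$eps), "/")
        return(list(dx = array(dx, d), grads = list(gamma = dgamma, beta = dbeta)))
      }
      dxhat <- sweep(Dm, 2, l$gamma, "*")
      inv <- 1 / sqrt(cache$va + l$eps)
      t1 <- sweep(dxhat, 2, colMeans(dxhat), "-")
      t2 <- sweep(cache$xhat, 2, colMeans(dxhat * cache$xhat), "*")
      dx <- sweep(t1 - t2, 2, inv, "*")
      list(dx = array(dx, d), grads = list(gamma = dgamma, beta = dbeta))
    },
    lateral = {
      if (isTRUE(cache$skipped)) return(list(dx = dout, grads = NULL))
      K <- cache$Keff
      D <- dim(K)[1]
      # dx: adjoint of h -> 0.5*(h + K*h); the adjoint of true convolution
      # by K is cross-correlation by K with filter indices transposed.
      Kt <- aperm(K, c(1, 2, 4, 3))
      dx <- 0.5 * (dout + conv_same(dout, Kt))
      # dK(i,j,f,g) = 0.5 * sum h(y-i, x-j, n, f) dout(y, x, n, g):
      # cross-correlation of dout against h at offsets (-i, -j).
      dK_corr <- conv_same_grad_w(cache$x, dout, D, D)   # offsets a-1-r = i'
      dK <- 0.5 * dK_corr[D:1, D:1, , , drop = FALSE]
      if (!is.null(cache$mask)) dK <- dK * cache$mask
      list(dx = dx, grads = list(K = dK))
    },
    pool = {
      d <- cache$d
      da <- array(0, c(2, d[1] / 2, 2, d[2] / 2, d[3], d[4]))
      dm <- array(dout, dim(cache$m))
      taken <- array(FALSE, dim(cache$m))
      for (s in 1:2) for (t in 1:2) {
        hit <- (cache$a[s, , t, , , , drop = FALSE] == cache$m) & !taken
        da[s, , t, , , ] <- dm * hit
        taken <- taken | hit
      }
      list(dx = array(da, d), grads = NULL)
    },
    dropout = {
      if (is.null(cache$mask)) list(dx = dout, grads = NULL)
      else list(dx = dout * cache$mask, grads = NULL)
    },
    flatten = {
      d <- cache$d
      dx <- aperm(array(t(dout), c(d[1], d[2], d[4], d[3])), c(1, 2, 4, 3))
      list(dx = dx, grads = NULL)
    },
    fc = {
      dz <- if (l$act == "relu") dout * (cache$z > 0) else dout
      list(dx = dz %*% t(l$W),
           grads = list(W = crossprod(cache$x, dz), b = colSums(dz)))
    },
    stop("unknown layer type ", l$type)
  )
}

#' Forward pass through the network
#'
#' @param net an `lgn_network`.
#' @param x input array `(H, W, N, 1)` (a matrix or `(H, W, N)` array is
#'   promoted).
#' @param train logical; training mode uses batch statistics and draws
#'   dropout masks from the RNG, evaluation mode uses running statistics
#'   and no dropout.
#' @return list with `out` (logits, `N x n_classes`) and `caches` (for
#'   [network_backward()]).
#' @export
network_forward <- function(net, x, train = FALSE) {
  if (is.matrix(x)) x <- array(x, c(dim(x), 1, 1))
  if (length(dim(x)) == 3) x <- array(x, c(dim(x), 1))
  caches <- vector("list", length(net$layers))
  stat_updates <- vector("list", length(net$layers))
  for (i in seq_along(net$layers)) {
    r <- forward_layer(net$layers[[i]], x, train, net$lateral_active)
    x <- r$out
    caches[[i]] <- r$cache
    if (!is.null(r$stat_update)) stat_updates[[i]] <- r$stat_update
  }
  list(out = x, caches = caches, stat_updates = stat_updates)
}

#' Backward pass: gradients of the loss w.r.t. all parameters
#'
#' @param net an `lgn_network`.
#' @param caches from [network_forward()] (training mode).
#' @param dlogits gradient of the loss w.r.t. the logits.
#' @return list of per-layer gradient lists (NULL for parameter-free
#'   layers).
#' @export
network_backward <- function(net, caches, dlogits) {
  grads <- vector("list", length(net$layers))
  dout <- dlogits
  for (i in rev(seq_along(net$layers))) {
    r <- backward_layer(net$layers[[i]], dout, caches[[i]])
    grads[i] <- list(r$grads)  # [[<- would drop NULL entries
    dout <- r$dx
  }
  grads
}

#' Softmax cross-entropy loss and its gradient
#' @param logits `N x k` matrix.
#' @param y integer labels in `1..k`.
#' @return list with `loss` (mean over the batch) and `dlogits`.
#' @export
softmax_xent <- function(logits, y) {
  N <- nrow(logits)
  z <- logits - apply(logits, 1, max)
  ez <- exp(z)
  p <- ez / rowSums(ez)
  idx <- cbind(seq_len(N), y)
  loss <- -mean(log(pmax(p[idx], 1e-300)))
  dl <- p
  dl[idx] <- dl[idx] - 1
  list(loss = loss, dlogits = dl / N)
}
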