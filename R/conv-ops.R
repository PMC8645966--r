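# Array convolution primitives.
#
# Activations are stored as 4-D arrays indexed (row, col, sample, channel);
# R's column-major layout then makes every kernel-offset slice a contiguous
# (H*W*N) x C matrix, so a convolution is a short sum of BLAS matrix
# products. Spatial kernels are (kh, kw, in_channels, out_channels).

#' Same-size cross-correlation of a batched activation with a filter bank
#'
#' Computes `out(y, x, n, g) = sum_{a,b,c} w(a, b, c, g) *
#' xpad(y + a - 1, x + b - 1, n, c)` with zero padding chosen so the
#' spatial size is preserved (odd kernels only). This is the feedforward
#' convolution of CNN layers (cross-correlation orientation).
#'
#' @param x array `(H, W, N, C)`.
#' @param w array `(kh, kw, C, G)` with odd `kh`, `kw`.
#' @return array `(H, W, N, G)`.
#' @keywords internal
conv_same <- function(x, w) {
  d <- dim(x); H <- d[1]; W <- d[2]; N <- d[3]; C <- d[4]
  dw <- dim(w); kh <- dw[1]; kw <- dw[2]; G <- dw[4]
  stopifnot(dw[3] == C, kh %% 2 == 1, kw %% 2 == 1)
  ph <- (kh - 1) / 2; pw <- (kw - 1) / 2
  xp <- array(0, c(H + 2 * ph, W + 2 * pw, N, C))
  xp[ph + seq_len(H), pw + seq_len(W), , ] <- x
  out <- matrix(0, H * W * N, G)
  for (a in seq_len(kh)) for (b in seq_len(kw)) {
    S <- matrix(xp[a:(a + H - 1), b:(b + W - 1), , , drop = FALSE], H * W * N, C)
    out <- out + S %*% matrix(w[a, b, , ], C, G)
  }
  array(out, c(H, W, N, G))
}

# Gradient of conv_same w.r.t. the filter bank: dw(a,b,c,g).
conv_same_grad_w <- function(x, dout, kh, kw) {
  d <- dim(x); H <- d[1]; W <- d[2]; N <- d[3]; C <- d[4]
  G <- dim(dout)[4]
  ph <- (kh - 1) / 2; pw <- (kw - 1) / 2
  xp <- array(0, c(H + 2 * ph, W + 2 * pw, N, C))
  xp[ph + seq_len(H), pw + seq_len(W), , ] <- x
  Dm <- matrix(dout, H * W * N, G)
  dw <- array(0, c(kh, kw, C, G))
  for (a in seq_len(kh)) for (b in seq_len(kw)) {
    S <- matrix(xp[a:(a + H - 1), b:(b + W - 1), , , drop = FALSE], H * W * N, C)
    dw[a, b, , ] <- crossprod(S, Dm)
  }
  dw
}

# Gradient of conv_same w.r.t. the input: conv of dout with the spatially
# flipped kernel, channels transposed.
conv_same_grad_x <- function(dout, w) {
  dw <- dim(w); kh <- dw[1]; kw <- dw[2]
  wt <- aperm(w[kh:1, kw:1, , , drop = FALSE], c(1, 2, 4, 3))
  conv_same(dout, wt)
}

#' Apply a lateral connectivity kernel to activation maps (true convolution)
#'
#' Computes `(K * h)(y, x, n, g) = sum_{i,j,f} K(i, j, f, g) *
#' h(y - i, x - j, n, f)` with zero padding at the borders, where the
#' spatial indices `(i, j)` of `K` run over displacements `-r..r`
#' (`r = (D-1)/2`). This is the propagated activation of the lateral
#' connectivity rule: `K(i, j, f, g)` is the connection strength between
#' filters `f` and `g` at spatial offset `(i, j)`.
#'
#' @param h array `(H, W, N, F)` of activations.
#' @param K array `(D, D, F, G)`, `D` odd.
#' @return array `(H, W, N, G)`.
#' @export
kernel_apply <- function(h, K) {
  D <- dim(K)[1]
  stopifnot(dim(K)[2] == D, D %% 2 == 1, dim(h)[4] == dim(K)[3])
  conv_same(h, K[D:1, D:1, , , drop = FALSE])
}

#' Lateral connectivity update rule
#'
#' The first-layer activation is diffused through the learned lateral
#' kernel and averaged with the feedforward activation:
#' `h~ = (1/2)(h + K * h)`. The operator is linear in `h`; `K == 0` gives
#' `h/2` and the identity delta kernel (`K(0,0,f,f) = 1`) gives `h` back.
#'
#' @param h array `(H, W, N, F)`; for a single map an `(H, W)` matrix or
#'   `(H, W, F)` array is promoted.
#' @param K array `(D, D, F, F)` lateral kernel.
#' @return array of the same shape as `h`.
#' @export
lateral_update <- function(h, K) {
  h4 <- promote_hwnc(h)
  if (dim(h4)[4] != dim(K)[3] || dim(K)[3] != dim(K)[4])
    stop("channel count of 'h' must match both filter indices of 'K'")
  out <- 0.5 * (h4 + kernel_apply(h4, K))
  demote_like(out, h)
}

promote_hwnc <- function(h) {
  if (length(dim(h)) == 4) return(h)
  if (is.matrix(h)) return(array(h, c(dim(h), 1, 1)))
  if (length(dim(h)) == 3) {
    d <- dim(h)
    return(array(h, c(d[1], d[2], 1, d[3])))  # (H, W, F) -> (H, W, 1, F)
  }
  stop("'h' must be a 2-, 3- or 4-dimensional array")
}

demote_like <- function(out, h) {
  if (length(dim(h)) == 4) return(out)
  if (is.matrix(h)) return(matrix(out, dim(h)[1], dim(h)[2]))
  array(out, dim(h))
}

#' Convolve two lateral kernels over space, contracting the shared filter index
#'
#' `(K1 * K2)(u, v, f, g) = sum_{a,b,m} K1(a, b, f, m) K2(u-a, v-b, m, g)`
#' on the enlarged spatial support `-2r..2r` (side `2D-1`). Composition of
#' two propagation steps through `K` is, away from the borders, a single
#' step through `K * K`.
#'
#' @param K1,K2 arrays `(D, D, n, n)`.
#' @return array `(2D-1, 2D-1, n, n)`.
#' @export
kernel_convolve <- function(K1, K2) {
  d1 <- dim(K1); d2 <- dim(K2)
  stopifnot(d1[1] == d1[2], d2[1] == d2[2], d1[4] == d2[3])
  D1 <- d1[1]; D2 <- d2[1]
  Do <- D1 + D2 - 1
  out <- array(0, c(Do, Do, d1[3], d2[4]))
  for (a in seq_len(D1)) for (b in seq_len(D1)) {
    A <- matrix(K1[a, b, , ], d1[3], d1[4])
    if (!any(A != 0)) next
    for (u in seq_len(D2)) for (v in seq_len(D2)) {
      B <- matrix(K2[u, v, , ], d2[3], d2[4])
      out[a + u - 1, b + v - 1, , ] <-
        out[a + u - 1, b + v - 1, , ] + A %*% B
    }
  }
  out
}

#' Self-replication of a lateral kernel
#'
#' Two steps of the lateral update are equivalent (in the interior, away
#' from zero-padded borders) to one step with the long-range kernel
#' `2K + K * K`, defined on the enlarged support of side `4r + 1`. This
#' self-replication builds wide-range connectivity out of the learned
#' short-range kernel.
#'
#' @param K array `(D, D, n, n)`.
#' @return array `(2D-1, 2D-1, n, n)` holding `2K + K*K` (the `2K` term is
#'   embedded at the center of the enlarged support).
#' @export
self_replicate <- function(K) {
  D <- dim(K)[1]
  stopifnot(dim(K)[2] == D, dim(K)[3] == dim(K)[4])
  out <- kernel_convolve(K, K)
  ctr <- (D - 1) / 2
  idx <- ctr + seq_len(D)
  out[idx, idx, , ] <- out[idx, idx, , ] + 2 * K
  out
}

#' Identity delta kernel
#'
#' `K(0, 0, f, f) = 1` and zero elsewhere: the neutral element of
#' [kernel_apply()].
#' @param D odd spatial side.
#' @param n number of filters.
#' @return array `(D, D, n, n)`.
#' @export
delta_kernel <- function(D, n) {
  K <- array(0, c(D, D, n, n))
  c0 <- (D + 1) / 2
  for (f in seq_len(n)) K[c0, c0, f, f] <- 1
  K
}
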