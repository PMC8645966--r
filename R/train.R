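#' Training configuration
#'
#' Two-phase protocol: all weights except the lateral kernel are first
#' pre-trained purely feedforward (the lateral step is skipped entirely in
#' this phase); the lateral kernel is then initialized randomly and the
#' whole architecture, lateral kernel included, is trained jointly, with
#' dropout on the lateral connections (a Bernoulli mask over the kernel
#' entries redrawn at every weight update). Both phases stop early when
#' validation accuracy has not improved for `patience` consecutive epochs.
#'
#' The optimizer is stochastic gradient descent with momentum and weight
#' decay; the reference study does not report optimizer hyper-parameters,
#' so these are exposed here with conventional defaults.
#'
#' @param max_epochs maximum epochs per phase.
#' @param patience early-stopping patience (epochs without validation
#'   improvement).
#' @param lr learning rate.
#' @param momentum SGD momentum coefficient.
#' @param weight_decay L2 penalty coefficient (not applied to batch-norm
#'   parameters or biases).
#' @param batch_size minibatch size.
#' @param val_fraction fraction of the dataset held out for validation.
#' @param dropout_lateral dropping probability for lateral connections in
#'   the joint phase.
#' @param seed integer seed controlling the split, shuffling, weight
#'   initialization of the lateral kernel and all dropout masks.
#' @return object of class `training_config`.
#' @export
training_config <- function(max_epochs = 800, patience = 80, lr = 0.01,
                            momentum = 0.9, weight_decay = 5e-4,
                            batch_size = 128, val_fraction = 0.1,
                            dropout_lateral = 0.2, seed = 1L) {
  stopifnot(max_epochs >= 1, patience >= 1, lr > 0,
            dropout_lateral >= 0, dropout_lateral < 1,
            val_fraction > 0, val_fraction < 1)
  cfg <- list(max_epochs = max_epochs, patience = patience, lr = lr,
              momentum = momentum, weight_decay = weight_decay,
              batch_size = batch_size, val_fraction = val_fraction,
              dropout_lateral = dropout_lateral, seed = as.integer(seed))
  class(cfg) <- "training_config"
  cfg
}

param_layers <- function(net) which(vapply(net$layers, function(l)
  l$type %in% c("conv", "fc", "bn", "lateral"), logical(1)))

layer_params <- function(l) {
  switch(l$type,
    conv = list(W = l$W, b = l$b),
    fc = list(W = l$W, b = l$b),
    bn = list(gamma = l$gamma, beta = l$beta),
    lateral = list(K = l$K))
}

assign_params <- function(l, p) {
  for (nm in names(p)) l[[nm]] <- p[[nm]]
  l
}

decay_mask <- function(l) {
  # weight decay only on multiplicative weights, not biases/BN parameters
  switch(l$type,
    conv = list(W = TRUE, b = FALSE),
    fc = list(W = TRUE, b = FALSE),
    bn = list(gamma = FALSE, beta = FALSE),
    lateral = list(K = TRUE))
}

run_phase <- function(net, xs, ys, xv, yv, cfg, phase_name) {
  n <- length(ys)
  vel <- lapply(net$layers, function(l)
    if (l$type %in% c("conv", "fc", "bn", "lateral"))
      lapply(layer_params(l), function(p) p * 0) else NULL)
  best_acc <- -Inf; since_best <- 0
  hist <- data.frame()
  for (epoch in seq_len(cfg$max_epochs)) {
    ord <- sample.int(n)
    nb <- ceiling(n / cfg$batch_size)
    tr_correct <- 0; tr_loss <- 0
    for (bi in seq_len(nb)) {
      idx <- ord[((bi - 1) * cfg$batch_size + 1):min(bi * cfg$batch_size, n)]
      xb <- xs[, , idx, , drop = FALSE]
      yb <- ys[idx]
      fw <- network_forward(net, xb, train = TRUE)
      ls <- softmax_xent(fw$out, yb)
      tr_loss <- tr_loss + ls$loss * length(idx)
      tr_correct <- tr_correct + sum(max.col(fw$out, ties.method = "first") == yb)
      grads <- network_backward(net, fw$caches, ls$dlogits)
      for (li in seq_along(net$layers)) {
        g <- grads[[li]]
        if (is.null(g)) next
        l <- net$layers[[li]]
        dm <- decay_mask(l)
        for (nm in names(g)) {
          gg <- g[[nm]]
          if (isTRUE(dm[[nm]])) gg <- gg + cfg$weight_decay * l[[nm]]
          vel[[li]][[nm]] <- cfg$momentum * vel[[li]][[nm]] - cfg$lr * gg
          net$layers[[li]][[nm]] <- l[[nm]] + vel[[li]][[nm]]
        }
        # update batch-norm running statistics
        if (l$type == "bn" && !is.null(fw$stat_updates[[li]])) {
          su <- fw$stat_updates[[li]]
          net$layers[[li]]$rm <- (1 - l$mom) * net$layers[[li]]$rm + l$mom * su$mu
          net$layers[[li]]$rv <- (1 - l$mom) * net$layers[[li]]$rv + l$mom * su$va
        }
      }
    }
    val_acc <- evaluate(net, list(x = xv, y = yv))
    hist <- rbind(hist, data.frame(phase = phase_name, epoch = epoch,
                                   train_loss = tr_loss / n,
                                   train_acc = tr_correct / n,
                                   val_acc = val_acc))
    if (val_acc > best_acc) {
      best_acc <- val_acc; since_best <- 0
    } else {
      since_best <- since_best + 1
      if (since_best >= cfg$patience) break
    }
  }
  # early stopping halts training; the network keeps the weights at stop
  # (restoring an earlier snapshot would hand downstream analyses a
  # less-trained filter whenever the small validation split is noisy)
  list(net = net, history = hist, best_val = best_acc)
}

#' Train an LGN-CNN with the two-phase protocol
#'
#' Phase 1 (`pretrain_feedforward`) trains all weights with the lateral
#' step disabled; the lateral kernel keeps its initialization untouched.
#' Phase 2 (`joint_with_lateral`) re-initializes the lateral kernel
#' randomly, activates the lateral update and trains everything jointly,
#' with Bernoulli dropout of lateral connections at each weight update.
#' Early stopping halts a phase; the network keeps the weights it had at
#' the stop (no snapshot restoration).
#'
#' All stochastic sources (split, shuffling, dropout masks, kernel
#' re-initialization) derive from `cfg$seed`, so a run is reproducible
#' from `(network, dataset, cfg)`.
#'
#' @param net an `lgn_network` from [build_network()].
#' @param dataset list with `x` (array `(H, W, N, 1)` or `(H, W, N)`) and
#'   `y` (integer labels `1..k`).
#' @param cfg a [training_config()].
#' @param phases character vector; subset of
#'   `c("pretrain_feedforward", "joint_with_lateral")` in that order.
#' @return list with `net` (trained), `history` (per-epoch data frame with
#'   phase, epoch, train loss/accuracy, validation accuracy), `psi0`
#'   (list of LGN-filter snapshots: at initialization and after each
#'   phase), and `val_acc` (best validation accuracy of the last phase).
#' @export
train_network <- function(net, dataset, cfg = training_config(),
                          phases = c("pretrain_feedforward", "joint_with_lateral")) {
  stopifnot(inherits(net, "lgn_network"), inherits(cfg, "training_config"))
  x <- dataset$x
  if (length(dim(x)) == 3) x <- array(x, c(dim(x), 1))
  y <- as.integer(dataset$y)
  if (is.null(x) || length(y) == 0) stop("empty dataset")
  if (dim(x)[3] != length(y)) stop("x / y length mismatch")
  phases <- match.arg(phases, c("pretrain_feedforward", "joint_with_lateral"),
                      several.ok = TRUE)
  set.seed(cfg$seed)
  n <- length(y)
  n_val <- max(1L, round(cfg$val_fraction * n))
  if (n_val >= n) stop("dataset too small for the requested validation split")
  vidx <- sample.int(n, n_val)
  xv <- x[, , vidx, , drop = FALSE]; yv <- y[vidx]
  xs <- x[, , -vidx, , drop = FALSE]; ys <- y[-vidx]

  psi0_snaps <- list(init = get_weights(net, "l0"))
  history <- data.frame()
  best_val <- NA_real_
  for (ph in phases) {
    if (ph == "pretrain_feedforward") {
      net$lateral_active <- FALSE
    } else {
      # fresh random lateral kernel, then joint training
      for (i in seq_along(net$layers)) {
        if (net$layers[[i]]$type == "lateral") {
          d <- dim(net$layers[[i]]$K)
          net$layers[[i]]$K <- init_lateral_kernel(d[1], d[3])
          net$layers[[i]]$p_drop <- cfg$dropout_lateral
        }
      }
      net$lateral_active <- TRUE
    }
    res <- run_phase(net, xs, ys, xv, yv, cfg, ph)
    net <- res$net
    history <- rbind(history, res$history)
    best_val <- res$best_val
    psi0_snaps[[ph]] <- get_weights(net, "l0")
  }
  list(net = net, history = history, psi0 = psi0_snaps, val_acc = best_val)
}

#' Classification accuracy on a dataset
#'
#' Fraction of correctly predicted examples (top-1), evaluated in
#' inference mode (running batch-norm statistics, no dropout).
#'
#' @param net an `lgn_network`.
#' @param dataset list with `x` and integer labels `y`.
#' @param batch_size evaluation batch size.
#' @return accuracy in `[0, 1]`.
#' @export
evaluate <- function(net, dataset, batch_size = 256) {
  x <- dataset$x
  if (length(dim(x)) == 3) x <- array(x, c(dim(x), 1))
  y <- as.integer(dataset$y)
  n <- length(y)
  if (n == 0) stop("empty dataset")
  correct <- 0
  for (start in seq(1, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1, n)
    fw <- network_forward(net, x[, , idx, , drop = FALSE], train = FALSE)
    correct <- correct + sum(max.col(fw$out, ties.method = "first") == y[idx])
  }
  correct / n
}
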