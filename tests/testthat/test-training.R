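# Small-scale training-contract tests; the longer learning smoke test
# lives in test-acceptance.R.

tiny_dataset <- function(n = 40, size = 8, sep = 3, seed = 1) {
  # trivially separable two-class set: bright vs dark mean level
  set.seed(seed)
  x <- array(rnorm(size * size * n), c(size, size, n))
  y <- rep(1:2, length.out = n)
  x[, , y == 2] <- x[, , y == 2] + sep
  list(x = x, y = y)
}

test_that("phase 1 trains feedforward weights and leaves the lateral kernel untouched", {
  ds <- tiny_dataset()
  set.seed(3)
  net <- build_network(tiny_arch())
  K_init <- get_weights(net, "K1")
  tc <- training_config(max_epochs = 2, patience = 5, batch_size = 16,
                        lr = 0.01, seed = 3)
  res <- train_network(net, ds, tc, phases = "pretrain_feedforward")
  expect_equal(get_weights(res$net, "K1"), K_init)
  expect_false(identical(get_weights(res$net, "l1"), get_weights(net, "l1")))
  expect_true(all(is.finite(unlist(lapply(res$net$layers, function(l) l$W)))))
  expect_named(res$psi0, c("init", "pretrain_feedforward"))
})

test_that("the joint phase re-initializes and updates the lateral kernel", {
  ds <- tiny_dataset()
  set.seed(4)
  net <- build_network(tiny_arch())
  K_init <- get_weights(net, "K1")
  tc <- training_config(max_epochs = 2, patience = 5, batch_size = 16,
                        lr = 0.01, seed = 4)
  res <- train_network(net, ds, tc)
  expect_false(identical(get_weights(res$net, "K1"), K_init))
  expect_true(res$net$lateral_active)
  expect_setequal(unique(res$history$phase),
                  c("pretrain_feedforward", "joint_with_lateral"))
})

test_that("training is reproducible given seed, dataset and config", {
  ds <- tiny_dataset()
  tc <- training_config(max_epochs = 2, patience = 5, batch_size = 16,
                        lr = 0.01, seed = 11)
  set.seed(5); net1 <- build_network(tiny_arch())
  set.seed(5); net2 <- build_network(tiny_arch())
  r1 <- train_network(net1, ds, tc)
  r2 <- train_network(net2, ds, tc)
  expect_identical(r1$history, r2$history)
  expect_identical(get_weights(r1$net, "l1"), get_weights(r2$net, "l1"))
})

test_that("early stopping halts a non-improving run before max_epochs", {
  ds <- tiny_dataset()
  set.seed(6)
  net <- build_network(tiny_arch())
  # zero learning rate cannot be configured (lr > 0), so use one so small
  # that validation accuracy is frozen
  tc <- training_config(max_epochs = 30, patience = 3, batch_size = 16,
                        lr = 1e-12, seed = 6)
  res <- train_network(net, ds, tc, phases = "pretrain_feedforward")
  expect_lt(nrow(res$history), 30)
})

test_that("a separable dataset is learned to high accuracy", {
  ds <- tiny_dataset(n = 60, sep = 4)
  set.seed(7)
  net <- build_network(tiny_arch())
  tc <- training_config(max_epochs = 12, patience = 12, batch_size = 16,
                        lr = 0.02, seed = 7)
  res <- train_network(net, ds, tc, phases = "pretrain_feedforward")
  expect_gt(evaluate(res$net, ds), 0.9)
})

test_that("evaluate returns chance for a constant-output network", {
  set.seed(8)
  net <- build_network(tiny_arch())
  # zero every multiplicative weight: logits identical across classes
  for (i in seq_along(net$layers)) {
    if (!is.null(net$layers[[i]]$W)) net$layers[[i]]$W[] <- 0
    if (!is.null(net$layers[[i]]$b)) net$layers[[i]]$b[] <- 0
  }
  ds <- tiny_dataset(n = 30)
  expect_equal(evaluate(net, ds), mean(ds$y == 1))
  expect_error(evaluate(net, list(x = ds$x[, , integer(0)], y = integer(0))),
               "empty")
})

test_that("training rejects an empty or mismatched dataset", {
  set.seed(9)
  net <- build_network(tiny_arch())
  tc <- training_config(max_epochs = 1, seed = 9)
  expect_error(train_network(net, list(x = NULL, y = integer(0)), tc), "empty")
  ds <- tiny_dataset(n = 4)
  tc2 <- training_config(max_epochs = 1, val_fraction = 0.9, seed = 9)
  ds$y <- ds$y[1:3]
  expect_error(train_network(net, ds, tc), "mismatch")
})
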