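test_that("the full-scale preset counts 20 convolutional layers", {
  m <- build_network(network_config("paper"), seed = 1)
  expect_equal(count_conv_layers(m), 20L)
  cfg <- network_config("paper")
  expect_equal(sum(cfg$n_layers_per_block), 20L)
  expect_equal(cfg$dilation_per_block, c(1L, 2L, 4L))
  # residual connections only between equal-shape layers
  for (i in which(!is.na(m$res_src))) {
    src <- m$res_src[i]
    expect_equal(m$units[[src]]$c_in, m$units[[i]]$c_out)
  }
})

test_that("an untrained model maps a random slice to a finite same-shape output", {
  m <- build_network(network_config("desk"), seed = 2)
  x <- array(runif(24 * 24), c(24, 24, 1))
  y <- predict_sct(m, x)
  expect_equal(dim(y), dim(x))
  expect_true(all(is.finite(y)))
  expect_true(all(y >= -1000 & y <= 1000))
})

test_that("initialisation and training are deterministic under a seed", {
  a <- build_network(network_config("desk"), seed = 5)
  b <- build_network(network_config("desk"), seed = 5)
  expect_identical(a$units[[7]]$W, b$units[[7]]$W)
  c3 <- build_network(network_config("desk"), seed = 6)
  expect_false(identical(a$units[[7]]$W, c3$units[[7]]$W))
  set.seed(1)
  sl <- array(runif(16 * 16 * 6), c(16, 16, 6))
  tgt <- sl * 2000 - 1000
  cfg <- training_config("desk", epochs = 2, seed = 9)
  f1 <- train_network(build_network(network_config("desk"), seed = 5), sl, tgt, cfg)
  f2 <- train_network(build_network(network_config("desk"), seed = 5), sl, tgt, cfg)
  expect_identical(f1$loss_trace$loss, f2$loss_trace$loss)
})

test_that("subject-level cross-validation folds are disjoint and exhaustive", {
  folds <- crossval_split(1:25, k = 5, seed = 1)
  expect_equal(length(folds), 5L)
  expect_true(all(lengths(folds) == 5L)) # 20 train / 5 validation
  expect_equal(sort(unname(unlist(folds))), 1:25)
  f2 <- crossval_split(1:10, k = 5, seed = 1)
  expect_true(all(lengths(f2) == 2L))
  expect_equal(anyDuplicated(unlist(f2)), 0L)
  expect_error(crossval_split(1:3, k = 5), "k must be")
})

test_that("invalid training configurations are rejected", {
  expect_error(training_config(lr_schedule = c(1e-3, 2e-3)), "start >= end")
  expect_error(training_config(lr_schedule = c(1e-3, 0)), "start >= end")
  expect_error(training_config(folds = 1), "folds")
  m <- build_network(network_config("desk"), seed = 1)
  expect_error(train_network(m, array(0, c(8, 8, 2)), array(0, c(8, 9, 2))),
               "co-registered")
})

test_that("the identity task is learned within 50 steps", {
  set.seed(2)
  n <- 24L
  sl <- array(0, c(24, 24, n))
  for (i in 1:n) sl[, , i] <- sctpet:::box_mean(matrix(runif(576), 24), 2)
  tgt <- sl * 2000 - 1000 # ct_to_unit(tgt) == sl
  fit <- train_network(build_network(network_config("desk"), seed = 1), sl, tgt,
                       training_config("desk", epochs = 17, seed = 1))
  tr <- fit$loss_trace
  i50 <- min(50, nrow(tr))
  expect_lt(tr$loss[i50], 0.1 * tr$loss[1])
})

test_that("CT unit mapping clips implants and inverts cleanly", {
  expect_equal(ct_to_unit(c(-1000, 0, 1000, 3000)), c(0, 0.5, 1, 1))
  expect_equal(unit_to_ct(ct_to_unit(c(-500, 250))), c(-500, 250))
})
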