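test_that("conv_forward matches the naive loop oracle", {
  set.seed(51)
  for (i in 1:30) {
    C <- sample(1:4, 1); H <- sample(2:5, 1); W <- sample(2:5, 1)
    kh <- sample(1:H, 1); kw <- sample(1:W, 1); K <- sample(1:5, 1)
    x <- array(rnorm(C * H * W), c(C, H, W))
    k <- array(rnorm(K * C * kh * kw), c(K, C, kh, kw))
    b <- rnorm(K)
    for (act in c("relu", "identity")) {
      got <- conv_forward(x, k, b, act)
      want <- oracle_conv(x, k, b, relu = act == "relu")
      expect_lt(max(abs(got - want)), 1e-6)
    }
  }
  # worked example: all-ones 3x3 input, one all-ones 2x2 kernel -> ReLU(4)
  one <- conv_forward(array(1, c(1, 3, 3)), array(1, c(1, 1, 2, 2)))
  expect_equal(as.vector(one), rep(4, 4))
  # all-zero input with zero bias stays zero under ReLU
  expect_true(all(conv_forward(array(0, c(1, 7, 20)),
                               array(rnorm(4), c(1, 1, 2, 2))) == 0))
  expect_error(conv_forward(array(1, c(1, 2, 2)),
                            array(1, c(1, 1, 3, 3))), "larger")
})

test_that("maxpool_forward matches the naive loop oracle", {
  set.seed(52)
  for (i in 1:30) {
    C <- sample(1:5, 1); H <- sample(2:7, 1); W <- sample(2:7, 1)
    x <- array(rnorm(C * H * W), c(C, H, W))
    got <- maxpool_forward(x)
    expect_lt(max(abs(got - oracle_maxpool(x))), 1e-6)
  }
  expect_equal(as.vector(maxpool_forward(array(c(0.1, 0.9, -0.5, 0.3),
                                               c(1, 2, 2)))), 0.9)
  expect_equal(dim(maxpool_forward(array(0, c(20, 6, 199)))), c(20L, 3L, 99L))
  cst <- maxpool_forward(array(3.5, c(2, 4, 4)))
  expect_true(all(cst == 3.5))
})

test_that("the layer shape chain is exactly as designed for L = 200", {
  sh <- model_shapes(mircnn_config(L = 200))
  expect_equal(sh$input, c(1L, 7L, 200L))
  expect_equal(sh$conv1, c(20L, 6L, 199L))
  expect_equal(sh$pool1, c(20L, 3L, 99L))
  expect_equal(sh$conv2, c(60L, 2L, 98L))
  expect_equal(sh$pool2, c(60L, 1L, 49L))
  expect_equal(sh$flatten, 2940L)
  expect_equal(sh$fc, 500L)
  expect_equal(sh$output, 2L)
  expect_error(mircnn_config(L = 6), "shape")
})

test_that("softmax outputs are normalised probabilities", {
  cfg <- mircnn_config(L = 40, epochs = 0)
  m <- mircnn_build(cfg, seed = 2)
  x <- array(rnorm(7 * 40 * 50), c(7, 40, 50))
  p <- predict(m, x, type = "prob")
  expect_equal(rowSums(p), rep(1, 50), tolerance = 1e-6)
  expect_true(all(p >= 0))
  cl <- predict(m, x, type = "class")
  expect_equal(as.character(cl), ifelse(p[, "miRNA"] >= 0.5, "miRNA", "other"))
})

test_that("the inference pass equals the composition of the generic ops", {
  set.seed(53)
  cfg <- mircnn_config(L = 24, epochs = 0)
  m <- mircnn_build(cfg, seed = 9)
  W <- m$weights
  x <- array(runif(7 * 24), c(7, 24, 1))
  p_cpp <- predict(m, x, type = "prob")

  k1 <- array(0, c(20, 1, 2, 2))
  for (k in 1:20) for (dr in 0:1) for (dc in 0:1)
    k1[k, 1, dr + 1, dc + 1] <- W$W1[k, 1 + dr + 2 * dc]
  a1 <- conv_forward(array(x[, , 1], c(1, 7, 24)), k1, W$b1, "relu")
  p1 <- maxpool_forward(a1)
  k2 <- array(0, c(60, 20, 2, 2))
  for (k in 1:60) for (ch in 1:20) for (dr in 0:1) for (dc in 0:1)
    k2[k, ch, dr + 1, dc + 1] <- W$W2[k, ch + 20 * (dr + 2 * dc)]
  a2 <- conv_forward(p1, k2, W$b2, "relu")
  p2 <- maxpool_forward(a2)
  fl <- as.vector(p2[, 1, ])
  h <- W$W3 %*% fl + W$b3
  o <- as.vector(W$W4 %*% h + W$b4)
  sm <- exp(o - max(o)); sm <- sm / sum(sm)
  expect_equal(as.vector(p_cpp), sm, tolerance = 1e-10)
})

test_that("with no dropout the first training batch sees the initial model", {
  set.seed(54)
  n <- 40
  x <- array(runif(7 * 30 * n), c(7, 30, n))
  y <- rep(c(0L, 1L), n / 2)
  cfg <- mircnn_config(L = 30, epochs = 1, batch_size = n,
                       dropout_retain = 1)
  m0 <- mircnn_build(cfg, seed = 4)
  p0 <- predict(m0, x, type = "prob")
  nll0 <- mean(-log(p0[cbind(seq_len(n), y + 1L)]))
  m1 <- mircnn_fit(x, y, cfg, seed = 4, model = m0)
  expect_equal(m1$training_log[1], nll0, tolerance = 1e-10)
})

test_that("training memorises a small separable set and loss trends down", {
  set.seed(55)
  n <- 50
  y <- rep(c(0L, 1L), each = n / 2)
  x <- array(rnorm(7 * 30 * n, sd = 0.1), c(7, 30, n))
  x[7, 1:10, y == 1] <- x[7, 1:10, y == 1] + 1   # class signal in coverage row
  cfg <- mircnn_config(L = 30, epochs = 30, batch_size = 16)
  m <- mircnn_fit(x, y, cfg, seed = 6)
  tl <- m$training_log
  # decreasing trend over 10-epoch windows (minor wiggles permitted)
  expect_lt(mean(tl[21:30]), mean(tl[1:10]))
  acc <- mean((predict(m, x, type = "prob")[, "miRNA"] >= 0.5) == (y == 1))
  expect_gte(acc, 0.9)
})

test_that("fits are bit-reproducible under a fixed seed", {
  set.seed(56)
  n <- 30
  x <- array(rnorm(7 * 30 * n), c(7, 30, n))
  y <- rep(c(0L, 1L), n / 2)
  cfg <- mircnn_config(L = 30, epochs = 3, batch_size = 8)
  m1 <- mircnn_fit(x, y, cfg, seed = 11)
  m2 <- mircnn_fit(x, y, cfg, seed = 11)
  expect_identical(m1$weights, m2$weights)
  expect_identical(m1$training_log, m2$training_log)
  m3 <- mircnn_fit(x, y, cfg, seed = 12)
  expect_false(identical(m3$weights, m1$weights))
})

test_that("oversampling duplicates only minority items to exact parity", {
  set.seed(57)
  y <- c(rep(0L, 750), rep(1L, 250))
  idx <- oversample_minority(y)
  expect_equal(sum(y[idx] == 1), 750L)              # 750/750 balance
  expect_equal(sum(y[idx] == 0), 750L)
  expect_true(all(seq_along(y) %in% idx))            # originals all kept
  expect_true(all(y[setdiff(idx, seq_along(y))] == 1))  # extras are minority
  expect_equal(oversample_minority(c(0L, 1L)), 1:2)  # balanced input untouched
  expect_error(oversample_minority(rep(1L, 5)), "both classes")
})

test_that("stratified folds partition samples with balanced classes", {
  set.seed(58)
  y <- c(rep(0L, 750), rep(1L, 250))
  f <- stratified_folds(y, 5L)
  expect_equal(sort(unique(f)), 1:5)
  expect_equal(as.vector(table(f)), rep(200L, 5))    # equal-sized subsets
  for (k in 1:5) expect_equal(sum(y[f == k] == 1), 50L)
})
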