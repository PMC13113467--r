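numgrad <- function(f, x, eps = 1e-6) {
  g <- array(0, dim(x) %||% length(x))
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- x[i] + eps
    xm <- x; xm[i] <- x[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

test_that("conv2d matches the naive loop oracle over strides and dilations", {
  set.seed(1)
  x <- array(rnorm(3 * 11 * 9), c(3, 11, 9))
  w <- array(rnorm(4 * 3 * 9), c(4, 3, 3, 3))
  for (st in 1:2) {
    for (dl in c(1, 2, 4)) {
      expect_equal(conv2d(x, w, stride = st, dilation = dl),
                   oracle_conv(x, w, st, dl), tolerance = 1e-12)
    }
  }
})

test_that("depthwise conv equals dense conv with diagonal kernels", {
  set.seed(2)
  C <- 4
  x <- array(rnorm(C * 8 * 8), c(C, 8, 8))
  wd <- array(rnorm(C * 5 * 3), c(C, 5, 3))
  dense <- array(0, c(C, C, 5, 3))
  for (c in 1:C) dense[c, c, , ] <- wd[c, , ]
  expect_equal(conv2d(x, wd), conv2d(x, dense), tolerance = 1e-12)
})

test_that("conv2d backward matches numeric gradients", {
  set.seed(3)
  x <- array(rnorm(2 * 6 * 5), c(2, 6, 5))
  w <- array(rnorm(3 * 2 * 9), c(3, 2, 3, 3))
  b <- rnorm(3)
  fw <- fabseg:::conv2d_forward(x, w, b, stride = 2L, dilation = 2L)
  dout <- array(rnorm(length(fw$out)), dim(fw$out))
  g <- fabseg:::conv2d_backward(dout, fw$cache)
  loss <- function(x., w., b.) sum(conv2d(x., w., b., 2L, 2L) * dout)
  expect_equal(g$dx, numgrad(function(v) loss(v, w, b), x), tolerance = 1e-5)
  expect_equal(g$dw, numgrad(function(v) loss(x, v, b), w), tolerance = 1e-5)
  expect_equal(as.numeric(g$db), as.numeric(numgrad(function(v) loss(x, w, v), b)),
               tolerance = 1e-5)
})

test_that("depthwise conv backward matches numeric gradients", {
  set.seed(4)
  x <- array(rnorm(3 * 5 * 5), c(3, 5, 5))
  w <- array(rnorm(3 * 1 * 7), c(3, 1, 7))
  fw <- fabseg:::conv2d_forward(x, w)
  dout <- array(rnorm(length(fw$out)), dim(fw$out))
  g <- fabseg:::conv2d_backward(dout, fw$cache)
  loss <- function(x., w.) sum(conv2d(x., w.) * dout)
  expect_equal(g$dx, numgrad(function(v) loss(v, w), x), tolerance = 1e-5)
  expect_equal(g$dw, numgrad(function(v) loss(x, v), w), tolerance = 1e-5)
})

test_that("layer norm normalizes channels and backpropagates exactly", {
  set.seed(5)
  x <- array(rnorm(6 * 4 * 3, sd = 3), c(6, 4, 3))
  gamma <- runif(6, 0.5, 1.5); beta <- rnorm(6)
  fw <- fabseg:::layernorm_forward(x, gamma, beta)
  xm <- fw$out; dim(xm) <- c(6, 12)
  centred <- sweep(xm, 1, beta) / gamma
  expect_equal(colMeans(centred), rep(0, 12), tolerance = 1e-10)
  dout <- array(rnorm(length(x)), dim(x))
  g <- fabseg:::layernorm_backward(dout, fw$cache)
  loss <- function(x., g., b.) {
    sum(fabseg:::layernorm_forward(x., g., b.)$out * dout)
  }
  expect_equal(g$dx, numgrad(function(v) loss(v, gamma, beta), x),
               tolerance = 1e-4)
  expect_equal(as.numeric(g$dgamma),
               as.numeric(numgrad(function(v) loss(x, v, beta), gamma)),
               tolerance = 1e-5)
})

test_that("bilinear upsampling preserves constants and has exact adjoint", {
  x <- array(2.5, c(3, 4, 5))
  up <- fabseg:::upsample_forward(x, 4L)
  expect_equal(dim(up$out), c(3L, 16L, 20L))
  expect_true(all(abs(up$out - 2.5) < 1e-12))
  set.seed(6)
  x <- array(rnorm(2 * 3 * 3), c(2, 3, 3))
  fw <- fabseg:::upsample_forward(x, 2L)
  dout <- array(rnorm(length(fw$out)), dim(fw$out))
  dx <- fabseg:::upsample_backward(dout, fw$cache)
  expect_equal(dx, numgrad(function(v)
    sum(fabseg:::upsample_forward(v, 2L)$out * dout), x), tolerance = 1e-5)
})

test_that("masked attention normalizes per query and backpropagates", {
  set.seed(7)
  n <- 10; dk <- 4; dv <- 5
  Q <- matrix(rnorm(n * dk), n); K <- matrix(rnorm(n * dk), n)
  V <- matrix(rnorm(n * dv), n)
  mask <- matrix(runif(n * n) > 0.4, n); diag(mask) <- TRUE
  fw <- fabseg:::attention_forward(Q, K, V, mask)
  expect_equal(rowSums(fw$cache$P), rep(1, n), tolerance = 1e-12)
  expect_true(all(fw$cache$P[!mask] == 0))
  dout <- matrix(rnorm(n * dv), n)
  g <- fabseg:::attention_backward(dout, fw$cache)
  loss <- function(Q., K., V.) {
    sum(fabseg:::attention_forward(Q., K., V., mask,
                                   scale = 1 / sqrt(dk))$out * dout)
  }
  expect_equal(g$dQ, numgrad(function(v) loss(v, K, V), Q), tolerance = 1e-5)
  expect_equal(g$dK, numgrad(function(v) loss(Q, v, V), K), tolerance = 1e-5)
  expect_equal(g$dV, numgrad(function(v) loss(Q, K, v), V), tolerance = 1e-5)
})
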