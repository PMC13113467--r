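test_that("receptive field follows the 2r + 1 rule", {
  expect_equal(receptive_field(3, 6), 13L)
  expect_equal(receptive_field(3, 12), 25L)
  expect_equal(receptive_field(3, 18), 37L)
  expect_equal(receptive_field(3, 24), 49L)
  expect_equal(receptive_field(3, 1), 3L)  # rate 1 = ordinary convolution
  expect_error(receptive_field(3, 0))
  expect_error(receptive_field(5, 2))
})

test_that("ASPP concatenates four branches and is linear in its kernels", {
  cfg <- aspp_config(branch_channels = 3L)
  params <- with_seed(1, fabseg:::aspp_init(2L, cfg))
  x <- array(rnorm(2 * 8 * 8), c(2, 8, 8))
  out <- aspp_forward(x, cfg, params)
  expect_equal(dim(out), c(12L, 8L, 8L))
  zero <- fabseg:::tree_map(params, function(p) p * 0)
  expect_true(all(aspp_forward(x, cfg, zero) == 0))
})

test_that("ASPP impulse supports equal the printed receptive fields", {
  for (case in list(c(6, 64), c(12, 64), c(18, 96), c(24, 128))) {
    rate <- case[1]; size <- case[2]
    cfg <- aspp_config(rates = rate, branch_channels = 1L)
    params <- list(branches = list(list(w = array(1, c(1, 1, 3, 3)),
                                        b = 0)))
    supp <- impulse_support(function(x) aspp_forward(x, cfg, params), size)
    expect_equal(supp, receptive_field(3, rate))
  }
})

test_that("atrous branches equal dense convolution with zero-inflated kernels", {
  cfg <- aspp_config(rates = c(6L, 12L), branch_channels = 2L)
  for (seed in 1:20) {
    set.seed(seed)
    x <- array(rnorm(3 * 16 * 16), c(3, 16, 16))
    params <- with_seed(seed, fabseg:::aspp_init(3L, cfg))
    out <- aspp_forward(x, cfg, params)
    for (i in seq_along(cfg$rates)) {
      r <- cfg$rates[i]
      w <- params$branches[[i]]$w
      # dilation by insertion: spread the 3x3 taps r pixels apart in a
      # dense (2r+1)x(2r+1) kernel and convolve undilated
      big <- array(0, c(2, 3, 2 * r + 1, 2 * r + 1))
      big[, , 1 + r * (0:2), 1 + r * (0:2)] <- w
      dense <- conv2d(x, big, params$branches[[i]]$b)
      expect_equal(out[(i - 1) * 2 + 1:2, , ], dense, tolerance = 1e-6)
    }
  }
})

test_that("MSCA with an all-ones attention map is the identity", {
  cfg <- msca_config(channels = 3L)
  params <- with_seed(2, fabseg:::msca_init(cfg))
  params$mix$w <- params$mix$w * 0
  params$mix$b <- rep(1, 3)
  x <- array(rnorm(3 * 10 * 10), c(3, 10, 10))
  expect_equal(msca_forward(x, cfg, params), x, tolerance = 1e-12)
})

test_that("a 1xk + kx1 strip pair equals one dense separable convolution", {
  for (seed in 1:20) {
    set.seed(seed)
    k <- sample(c(7, 11, 21), 1)
    C <- 2
    x <- array(rnorm(C * 12 * 12), c(C, 12, 12))
    v <- matrix(rnorm(C * k), C)  # 1 x k taps per channel
    u <- matrix(rnorm(C * k), C)  # k x 1 taps per channel
    w1 <- array(v, c(C, 1, k))
    w2 <- array(u, c(C, k, 1))
    strip <- conv2d(conv2d(x, w1), w2)
    dense <- array(0, c(C, k, k))
    for (c in 1:C) dense[c, , ] <- outer(u[c, ], v[c, ])
    expect_equal(strip, conv2d(x, dense), tolerance = 1e-6)
  }
})

test_that("the k = 21 strip branch has 21-pixel impulse support", {
  w1 <- array(1, c(1, 1, 21))
  w2 <- array(1, c(1, 21, 1))
  supp <- impulse_support(function(x) conv2d(conv2d(x, w1), w2), 64)
  expect_equal(supp, 21L)
})

test_that("MSCA preserves shape and validates strips", {
  cfg <- msca_config(channels = 4L, strips = c(7L, 11L))
  params <- with_seed(3, fabseg:::msca_init(cfg))
  x <- array(rnorm(4 * 9 * 7), c(4, 9, 7))
  expect_equal(dim(msca_forward(x, cfg, params)), dim(x))
  expect_error(msca_config(channels = 4L, strips = c(8L)), "odd")
  expect_error(msca_forward(array(0, c(3, 4, 4)), cfg, params), "channels")
})

test_that("bi-level routing with S = 1 equals global attention", {
  cfg <- bra_config(channels = 6L, S = 1L, topk = 1L)
  params <- with_seed(4, fabseg:::bra_init(cfg))
  x <- array(rnorm(6 * 4 * 5), c(6, 4, 5))
  out <- bra_attention(x, cfg, params)
  # dense global softmax attention oracle on the same Q/K/V
  Tm <- t(matrix(x, 6, 20))
  Q <- Tm %*% params$wq; K <- Tm %*% params$wk; V <- Tm %*% params$wv
  neigh <- rep(list(1:20), 20)
  O <- oracle_masked_attention(Q, K, V, neigh, 1 / sqrt(6))
  Y <- sweep(O %*% params$wo, 2, params$bo, `+`)
  expect_equal(out, array(t(Y), c(6, 4, 5)), tolerance = 1e-6)
})

test_that("routing confines attention to the top-k regions exactly", {
  cfg <- bra_config(channels = 4L, S = 2L, topk = 1L)
  params <- with_seed(5, fabseg:::bra_init(cfg))
  x <- array(rnorm(4 * 8 * 8), c(4, 8, 8))
  fw <- fabseg:::bra_attn_fwd(x, cfg, params)
  P <- fw$cache$heads[[1]]$P
  rid <- fabseg:::bra_region_ids(8L, 8L, 2L)
  # independent routing oracle from the cached Q/K
  Qr <- rowsum(fw$cache$Q, rid) / as.vector(table(rid))
  Kr <- rowsum(fw$cache$K, rid) / as.vector(table(rid))
  Ar <- Qr %*% t(Kr)
  routed <- apply(Ar, 1, which.max)
  for (i in 1:64) {
    allowed <- rid == routed[rid[i]]
    expect_true(all(P[i, !allowed] == 0))
    expect_equal(sum(P[i, ]), 1, tolerance = 1e-6)
  }
})

test_that("per-query attention weights sum to one on random inputs", {
  cfg <- bra_config(channels = 4L, S = 2L, topk = 2L, heads = 2L)
  for (seed in 1:5) {
    params <- with_seed(seed, fabseg:::bra_init(cfg))
    x <- array(rnorm(4 * 6 * 6), c(4, 6, 6))
    fw <- fabseg:::bra_attn_fwd(x, cfg, params)
    for (h in fw$cache$heads) {
      expect_equal(rowSums(h$P), rep(1, nrow(h$P)), tolerance = 1e-6)
    }
  }
})

test_that("the BiFormer block preserves shape, pads non-divisible grids", {
  cfg <- bra_config(channels = 4L, S = 2L, topk = 4L)
  params <- with_seed(6, fabseg:::bra_init(cfg))
  for (dims in list(c(4, 4), c(5, 7))) {
    x <- array(rnorm(4 * dims[1] * dims[2]), c(4, dims[1], dims[2]))
    expect_equal(dim(bra_forward(x, cfg, params)), dim(x))
  }
  expect_error(bra_config(channels = 4L, S = 2L, topk = 5L), "topk")
})

test_that("criss-cross attention equals the masked dense oracle on a 3x4 map", {
  cfg <- cca_config(channels = 5L, reduced = 2L)
  params <- with_seed(7, fabseg:::cca_init(cfg))
  x <- array(rnorm(5 * 3 * 4), c(5, 3, 4))
  out <- cca_forward(x, cfg, params)
  # explicit per-position oracle over the 12 positions: gather the row and
  # column of each position, softmax, aggregate, add the residual
  Tm <- t(matrix(x, 5, 12))
  Q <- sweep(Tm %*% params$wq, 2, params$bq, `+`)
  K <- sweep(Tm %*% params$wk, 2, params$bk, `+`)
  V <- sweep(Tm %*% params$wv, 2, params$bv, `+`)
  h <- rep(1:3, times = 4); w <- rep(1:4, each = 3)
  neigh <- lapply(1:12, function(i) which(h == h[i] | w == w[i]))
  expect_length(neigh[[1]], 3 + 4 - 1)
  O <- oracle_masked_attention(Q, K, V, neigh, 1 / sqrt(2))
  expect_equal(out, x + array(t(O), c(5, 3, 4)), tolerance = 1e-6)
})

test_that("criss-cross affinity rows sum to one; 1x1 maps reduce to V", {
  cfg <- cca_config(channels = 3L, reduced = 1L)
  params <- with_seed(8, fabseg:::cca_init(cfg))
  x <- array(rnorm(3 * 4 * 6), c(3, 4, 6))
  st <- fabseg:::cca_step_fwd(x, cfg, params)
  expect_equal(rowSums(st$cache$at$P), rep(1, 24), tolerance = 1e-12)

  x1 <- array(rnorm(3), c(3, 1, 1))
  out <- cca_forward(x1, cfg, params)
  v <- as.numeric(t(matrix(x1, 3, 1)) %*% params$wv + params$bv)
  expect_equal(as.numeric(out), as.numeric(x1) + v, tolerance = 1e-12)
})

test_that("two criss-cross recurrences reach every position, one does not", {
  params <- with_seed(9, fabseg:::cca_init(cca_config(channels = 2L)))
  x <- array(rnorm(2 * 5 * 5), c(2, 5, 5))
  xp <- x; xp[, 3, 4] <- xp[, 3, 4] + 0.5  # off the (1,1) criss-cross set
  one <- cca_config(channels = 2L, recurrence = 1L)
  two <- cca_config(channels = 2L, recurrence = 2L)
  d1 <- cca_forward(xp, one, params)[, 1, 1] - cca_forward(x, one, params)[, 1, 1]
  d2 <- cca_forward(xp, two, params)[, 1, 1] - cca_forward(x, two, params)[, 1, 1]
  expect_equal(d1, c(0, 0))
  expect_gt(max(abs(d2)), 1e-8)
})

test_that("block backward passes match numeric gradients", {
  numgrad_local <- function(f, x, eps = 1e-6) {
    g <- array(0, dim(x) %||% length(x))
    for (i in seq_along(x)) {
      xp <- x; xp[i] <- x[i] + eps
      xm <- x; xm[i] <- x[i] - eps
      g[i] <- (f(xp) - f(xm)) / (2 * eps)
    }
    g
  }
  set.seed(10)
  # MSCA
  mcfg <- msca_config(channels = 2L, strips = c(7L))
  mp <- with_seed(11, fabseg:::msca_init(mcfg))
  x <- array(rnorm(2 * 6 * 6), c(2, 6, 6))
  fw <- fabseg:::msca_fwd(x, mcfg, mp)
  dout <- array(rnorm(length(fw$out)), dim(fw$out))
  g <- fabseg:::msca_bwd(dout, fw$cache)
  expect_equal(g$dx, numgrad_local(function(v)
    sum(msca_forward(v, mcfg, mp) * dout), x), tolerance = 1e-5)
  # BiFormer block
  bcfg <- bra_config(channels = 4L, S = 2L, topk = 4L)
  bp <- with_seed(12, fabseg:::bra_init(bcfg))
  xb <- array(rnorm(4 * 4 * 4), c(4, 4, 4))
  fwb <- fabseg:::bra_fwd(xb, bcfg, bp)
  doutb <- array(rnorm(length(fwb$out)), dim(fwb$out))
  gb <- fabseg:::bra_bwd(doutb, fwb$cache)
  expect_equal(gb$dx, numgrad_local(function(v)
    sum(bra_forward(v, bcfg, bp) * doutb), xb), tolerance = 1e-4)
  # CCA with recurrence 2
  ccfg <- cca_config(channels = 3L, recurrence = 2L)
  cp <- with_seed(13, fabseg:::cca_init(ccfg))
  xc <- array(rnorm(3 * 4 * 3), c(3, 4, 3))
  fwc <- fabseg:::cca_fwd(xc, ccfg, cp)
  doutc <- array(rnorm(length(fwc$out)), dim(fwc$out))
  gc <- fabseg:::cca_bwd(doutc, fwc$cache)
  expect_equal(gc$dx, numgrad_local(function(v)
    sum(cca_forward(v, ccfg, cp) * doutc), xc), tolerance = 1e-5)
})
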