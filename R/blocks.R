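# The four feature-enhancement blocks of the encoder. Each block has a
# config constructor, a parameter initialiser (draws from the caller's RNG
# stream), an exported forward returning the output feature map, and an
# internal fwd/bwd pair used by the training loop.

#' Effective receptive field of a 3x3 atrous convolution
#'
#' A 3x3 kernel with dilation rate `rate` samples taps spaced `rate` pixels
#' apart, so its effective receptive field is `(2*rate + 1)` pixels per
#' side: 13 for rate 6, 25 for 12, 37 for 18, 49 for 24.
#'
#' @param kernel Kernel size; the rule is stated for 3.
#' @param rate Dilation rate (>= 1).
#' @return Side length in pixels of the effective receptive field.
#' @export
receptive_field <- function(kernel = 3L, rate) {
  assert_that(kernel == 3L, "the (2r + 1) rule applies to 3x3 kernels")
  assert_that(length(rate) == 1 && rate >= 1, "rate must be >= 1")
  as.integer(2L * rate + 1L)
}

# ---------------------------------------------------------------- ASPP ----

#' Atrous spatial pyramid pooling configuration
#'
#' Four parallel same-padded 3x3 atrous convolutions with dilation rates
#' 6, 12, 18 and 24 by default; branch outputs are concatenated along the
#' channel axis, so the block emits `length(rates) * branch_channels`
#' channels. The block itself is linear (no activation); the network applies
#' a ReLU after concatenation.
#'
#' @param rates Dilation rates, positive integers.
#' @param branch_channels Output channels per branch.
#' @param kernel Kernel size (3).
#' @return An `aspp_config` object.
#' @export
aspp_config <- function(rates = c(6L, 12L, 18L, 24L), branch_channels = 64L,
                        kernel = 3L) {
  assert_that(all(rates >= 1), "dilation rates must be positive")
  structure(list(rates = as.integer(rates),
                 branch_channels = as.integer(branch_channels),
                 kernel = as.integer(kernel)),
            class = "aspp_config")
}

aspp_init <- function(cin, cfg) {
  list(branches = lapply(cfg$rates, function(r) {
    list(w = init_conv(cfg$branch_channels, cin, cfg$kernel, cfg$kernel),
         b = init_bias(cfg$branch_channels))
  }))
}

aspp_fwd <- function(x, cfg, params) {
  d <- fm_dims(x)
  caches <- vector("list", length(cfg$rates))
  outs <- vector("list", length(cfg$rates))
  for (i in seq_along(cfg$rates)) {
    cv <- conv2d_forward(x, params$branches[[i]]$w, params$branches[[i]]$b,
                         stride = 1L, dilation = cfg$rates[i])
    outs[[i]] <- cv$out
    caches[[i]] <- cv$cache
  }
  cb <- cfg$branch_channels
  out <- array(0, c(cb * length(outs), d[2], d[3]))
  for (i in seq_along(outs)) out[(i - 1L) * cb + seq_len(cb), , ] <- outs[[i]]
  list(out = out, cache = list(convs = caches, cb = cb, d = d))
}

aspp_bwd <- function(dout, cache) {
  cb <- cache$cb
  dx <- array(0, cache$d)
  grads <- list(branches = vector("list", length(cache$convs)))
  for (i in seq_along(cache$convs)) {
    g <- conv2d_backward(dout[(i - 1L) * cb + seq_len(cb), , , drop = FALSE],
                         cache$convs[[i]])
    dx <- dx + g$dx
    grads$branches[[i]] <- list(w = g$dw, b = g$db)
  }
  list(dx = dx, grads = grads)
}

#' Atrous spatial pyramid pooling forward pass
#'
#' @param x Feature map (`C x H x W`).
#' @param cfg An [aspp_config()].
#' @param params Parameters from the block initialiser (a list of per-branch
#'   kernels and biases).
#' @return Feature map with `length(cfg$rates) * cfg$branch_channels`
#'   channels and unchanged spatial dimensions.
#' @export
aspp_forward <- function(x, cfg, params) aspp_fwd(x, cfg, params)$out

# ---------------------------------------------------------------- MSCA ----

#' Multi-scale convolutional attention configuration
#'
#' A 5x5 depthwise aggregation convolution followed by parallel strip
#' branches; each branch applies a 1xk then a kx1 depthwise convolution,
#' giving equivalent receptive fields of k x k (7, 11, 21 by default). The
#' aggregate plus the branch outputs are mixed by a 1x1 convolution into an
#' attention map that multiplies the original input elementwise.
#'
#' @param channels Channel count `d` of the input.
#' @param strips Odd strip lengths.
#' @param agg_kernel Aggregation depthwise kernel size (5).
#' @return An `msca_config` object.
#' @export
msca_config <- function(channels, strips = c(7L, 11L, 21L), agg_kernel = 5L) {
  assert_that(all(strips %% 2L == 1L), "strip lengths must be odd")
  structure(list(channels = as.integer(channels),
                 strips = as.integer(strips),
                 agg_kernel = as.integer(agg_kernel)),
            class = "msca_config")
}

msca_init <- function(cfg) {
  d <- cfg$channels
  list(
    agg = list(w = init_dwconv(d, cfg$agg_kernel, cfg$agg_kernel),
               b = init_bias(d)),
    strips = lapply(cfg$strips, function(k) {
      list(w1 = init_dwconv(d, 1L, k), b1 = init_bias(d),
           w2 = init_dwconv(d, k, 1L), b2 = init_bias(d))
    }),
    mix = list(w = init_conv(d, d, 1L, 1L, gain = 1), b = init_bias(d))
  )
}

msca_fwd <- function(x, cfg, params) {
  d <- fm_dims(x)
  assert_that(d[1] == cfg$channels, "input channels must equal cfg$channels")
  agg <- conv2d_forward(x, params$agg$w, params$agg$b)
  s <- agg$out
  strip_caches <- vector("list", length(cfg$strips))
  for (i in seq_along(cfg$strips)) {
    p <- params$strips[[i]]
    c1 <- conv2d_forward(agg$out, p$w1, p$b1)  # 1 x k
    c2 <- conv2d_forward(c1$out, p$w2, p$b2)   # k x 1
    s <- s + c2$out
    strip_caches[[i]] <- list(c1 = c1$cache, c2 = c2$cache)
  }
  mix <- conv2d_forward(s, params$mix$w, params$mix$b)
  att <- mix$out
  out <- att * x
  list(out = out,
       cache = list(agg = agg$cache, strips = strip_caches, mix = mix$cache,
                    att = att, x = x))
}

msca_bwd <- function(dout, cache) {
  datt <- dout * cache$x
  dx <- dout * cache$att
  gm <- conv2d_backward(datt, cache$mix)
  ds <- gm$dx
  dagg <- ds  # identity path of the aggregate into the sum
  grads <- list(mix = list(w = gm$dw, b = gm$db),
                strips = vector("list", length(cache$strips)))
  for (i in seq_along(cache$strips)) {
    sc <- cache$strips[[i]]
    g2 <- conv2d_backward(ds, sc$c2)
    g1 <- conv2d_backward(g2$dx, sc$c1)
    dagg <- dagg + g1$dx
    grads$strips[[i]] <- list(w1 = g1$dw, b1 = g1$db, w2 = g2$dw, b2 = g2$db)
  }
  ga <- conv2d_backward(dagg, cache$agg)
  grads$agg <- list(w = ga$dw, b = ga$db)
  dx <- dx + ga$dx
  list(dx = dx, grads = grads)
}

#' Multi-scale convolutional attention forward pass
#'
#' @param x Feature map with `cfg$channels` channels.
#' @param cfg An [msca_config()].
#' @param params Parameters from the block initialiser.
#' @return Feature map of the same shape as `x` (attention-weighted input).
#' @export
msca_forward <- function(x, cfg, params) msca_fwd(x, cfg, params)$out

# ----------------------------------------------------------- BiFormer ----

#' Bi-level routing attention block configuration
#'
#' The block applies a 3x3 depthwise convolution with a residual connection,
#' then layer norm + bi-level routing attention + residual, then layer norm
#' + MLP + residual. Inside the attention, the token grid is partitioned
#' into `S x S` regions; region-level affinity between mean-pooled region
#' queries and keys routes each query region to its `topk` most related key
#' regions, and token-level softmax attention is computed only over tokens
#' of the routed regions.
#'
#' @param channels Channel count of the input.
#' @param S Region grid size (the grid has `S^2` regions).
#' @param topk Number of routed key regions per query region
#'   (`1 <= topk <= S^2`).
#' @param heads Attention heads (must divide `channels`).
#' @param mlp_ratio Hidden width multiplier of the MLP.
#' @return A `bra_config` object.
#' @export
bra_config <- function(channels, S = 2L, topk = 4L, heads = 1L,
                       mlp_ratio = 2L) {
  assert_that(topk >= 1 && topk <= S^2, "need 1 <= topk <= S^2")
  assert_that(channels %% heads == 0, "heads must divide channels")
  structure(list(channels = as.integer(channels), S = as.integer(S),
                 topk = as.integer(topk), heads = as.integer(heads),
                 mlp_ratio = as.integer(mlp_ratio)),
            class = "bra_config")
}

bra_init <- function(cfg) {
  C <- cfg$channels
  hid <- C * cfg$mlp_ratio
  list(
    dw = list(w = init_dwconv(C, 3L, 3L), b = init_bias(C)),
    ln1 = list(gamma = rep(1, C), beta = numeric(C)),
    wq = init_linear(C, C), wk = init_linear(C, C), wv = init_linear(C, C),
    wo = init_linear(C, C), bo = init_bias(C),
    ln2 = list(gamma = rep(1, C), beta = numeric(C)),
    mlp = list(w1 = init_linear(C, hid, gain = 2), b1 = init_bias(hid),
               w2 = init_linear(hid, C), b2 = init_bias(C))
  )
}

# Region id for every token of an Hp x Wp grid split into S x S regions.
bra_region_ids <- function(Hp, Wp, S) {
  rh <- Hp %/% S; rw <- Wp %/% S
  h <- rep(seq_len(Hp), times = Wp)
  w <- rep(seq_len(Wp), each = Hp)
  rr <- (h - 1L) %/% rh + 1L
  rc <- (w - 1L) %/% rw + 1L
  (rr - 1L) * S + rc
}

# Inner bi-level routing attention on one (already normalised) feature map.
bra_attn_fwd <- function(t, cfg, params) {
  d <- fm_dims(t); C <- d[1]; H <- d[2]; W <- d[3]
  S <- cfg$S
  Hp <- ceiling(H / S) * S
  Wp <- ceiling(W / S) * S
  tp <- array(0, c(C, Hp, Wp))
  tp[, seq_len(H), seq_len(W)] <- t
  n <- Hp * Wp
  Tm <- fm_to_tokens(tp)
  valid <- as.vector(outer(seq_len(Hp) <= H, seq_len(Wp) <= W, `&`))
  Q <- Tm %*% params$wq
  K <- Tm %*% params$wk
  V <- Tm %*% params$wv
  rid <- bra_region_ids(Hp, Wp, S)
  nreg <- S^2
  # mean-pooled region queries/keys over valid tokens (routing only; the
  # top-k selection carries no gradient)
  Qr <- matrix(0, nreg, C); Kr <- matrix(0, nreg, C)
  nonempty <- logical(nreg)
  for (r in seq_len(nreg)) {
    sel <- rid == r & valid
    if (any(sel)) {
      nonempty[r] <- TRUE
      Qr[r, ] <- colMeans(Q[sel, , drop = FALSE])
      Kr[r, ] <- colMeans(K[sel, , drop = FALSE])
    }
  }
  Ar <- tcrossprod(Qr, Kr)
  Ar[, !nonempty] <- -Inf
  k_eff <- min(cfg$topk, sum(nonempty))
  allowed <- matrix(FALSE, nreg, nreg)
  for (r in seq_len(nreg)) {
    allowed[r, order(Ar[r, ], decreasing = TRUE)[seq_len(k_eff)]] <- TRUE
  }
  mask <- allowed[rid, rid, drop = FALSE] & matrix(valid, n, n, byrow = TRUE)
  if (any(!valid)) {
    # pad queries are cropped from the output; give them a self key so
    # their softmax is well defined
    idx <- which(!valid)
    mask[idx, ] <- FALSE
    mask[cbind(idx, idx)] <- TRUE
  }
  dh <- C %/% cfg$heads
  O <- matrix(0, n, C)
  head_caches <- vector("list", cfg$heads)
  for (hd in seq_len(cfg$heads)) {
    cols <- (hd - 1L) * dh + seq_len(dh)
    at <- attention_forward(Q[, cols, drop = FALSE], K[, cols, drop = FALSE],
                            V[, cols, drop = FALSE], mask,
                            scale = 1 / sqrt(dh))
    O[, cols] <- at$out
    head_caches[[hd]] <- at$cache
  }
  Y <- sweep(O %*% params$wo, 2, params$bo, `+`)
  yfm <- tokens_to_fm(Y, c(C, Hp, Wp))
  out <- yfm[, seq_len(H), seq_len(W), drop = FALSE]
  list(out = out,
       cache = list(Tm = Tm, Q = Q, K = K, V = V, O = O, heads = head_caches,
                    d = d, Hp = Hp, Wp = Wp, dh = dh, params = params))
}

bra_attn_bwd <- function(dout, cache) {
  d <- cache$d; C <- d[1]
  Hp <- cache$Hp; Wp <- cache$Wp
  dyfm <- array(0, c(C, Hp, Wp))
  dyfm[, seq_len(d[2]), seq_len(d[3])] <- dout
  dY <- fm_to_tokens(dyfm)
  dbo <- colSums(dY)
  dwo <- crossprod(cache$O, dY)
  dO <- tcrossprod(dY, cache$params$wo)
  n <- nrow(dO)
  dQ <- matrix(0, n, C); dK <- matrix(0, n, C); dV <- matrix(0, n, C)
  dh <- cache$dh
  for (hd in seq_along(cache$heads)) {
    cols <- (hd - 1L) * dh + seq_len(dh)
    g <- attention_backward(dO[, cols, drop = FALSE], cache$heads[[hd]])
    dQ[, cols] <- g$dQ; dK[, cols] <- g$dK; dV[, cols] <- g$dV
  }
  dwq <- crossprod(cache$Tm, dQ)
  dwk <- crossprod(cache$Tm, dK)
  dwv <- crossprod(cache$Tm, dV)
  dTm <- tcrossprod(dQ, cache$params$wq) + tcrossprod(dK, cache$params$wk) +
    tcrossprod(dV, cache$params$wv)
  dtp <- tokens_to_fm(dTm, c(C, Hp, Wp))
  dt <- dtp[, seq_len(d[2]), seq_len(d[3]), drop = FALSE]
  list(dx = dt, grads = list(wq = dwq, wk = dwk, wv = dwv, wo = dwo, bo = dbo))
}

#' Bi-level routing attention (inner attention only)
#'
#' Applies the routing attention of the block to a feature map directly
#' (without the depthwise convolution, layer norms, residuals or MLP).
#' Useful for inspecting the attention itself; with `S = 1` it reduces to
#' global softmax attention over all tokens.
#'
#' @param x Feature map with `cfg$channels` channels.
#' @param cfg A [bra_config()].
#' @param params Parameters from [bra_forward()]'s initialiser.
#' @return Feature map of the same shape.
#' @export
bra_attention <- function(x, cfg, params) bra_attn_fwd(x, cfg, params)$out

bra_fwd <- function(x, cfg, params) {
  d <- fm_dims(x)
  assert_that(d[1] == cfg$channels, "input channels must equal cfg$channels")
  dw <- conv2d_forward(x, params$dw$w, params$dw$b)
  x1 <- x + dw$out
  ln1 <- layernorm_forward(x1, params$ln1$gamma, params$ln1$beta)
  at <- bra_attn_fwd(ln1$out, cfg, params)
  x2 <- x1 + at$out
  ln2 <- layernorm_forward(x2, params$ln2$gamma, params$ln2$beta)
  T2 <- fm_to_tokens(ln2$out)
  h <- sweep(T2 %*% params$mlp$w1, 2, params$mlp$b1, `+`)
  ge <- gelu_forward(h)
  m <- sweep(ge$out %*% params$mlp$w2, 2, params$mlp$b2, `+`)
  out <- x2 + tokens_to_fm(m, d)
  list(out = out,
       cache = list(dw = dw$cache, ln1 = ln1$cache, at = at$cache,
                    ln2 = ln2$cache, T2 = T2, ge = ge, d = d,
                    params = params))
}

bra_bwd <- function(dout, cache) {
  d <- cache$d
  p <- cache$params
  dM <- fm_to_tokens(dout)
  db2 <- colSums(dM)
  dw2 <- crossprod(cache$ge$out, dM)
  dg <- tcrossprod(dM, p$mlp$w2)
  dhid <- gelu_backward(dg, cache$ge$cache)
  db1 <- colSums(dhid)
  dw1 <- crossprod(cache$T2, dhid)
  dT2 <- tcrossprod(dhid, p$mlp$w1)
  gl2 <- layernorm_backward(tokens_to_fm(dT2, d), cache$ln2)
  dx2 <- dout + gl2$dx
  ga <- bra_attn_bwd(dx2, cache$at)
  gl1 <- layernorm_backward(ga$dx, cache$ln1)
  dx1 <- dx2 + gl1$dx
  gdw <- conv2d_backward(dx1, cache$dw)
  dx <- dx1 + gdw$dx
  grads <- c(
    list(dw = list(w = gdw$dw, b = gdw$db),
         ln1 = list(gamma = gl1$dgamma, beta = gl1$dbeta)),
    ga$grads,
    list(ln2 = list(gamma = gl2$dgamma, beta = gl2$dbeta),
         mlp = list(w1 = dw1, b1 = db1, w2 = dw2, b2 = db2))
  )
  list(dx = dx, grads = grads)
}

#' BiFormer block forward pass
#'
#' 3x3 depthwise convolution + residual, layer norm + bi-level routing
#' attention + residual, layer norm + MLP + residual.
#'
#' @inheritParams bra_attention
#' @return Feature map of the same shape as `x`.
#' @export
bra_forward <- function(x, cfg, params) bra_fwd(x, cfg, params)$out

# --------------------------------------------------------------- CCA ----

#' Criss-cross attention configuration
#'
#' Each spatial position attends only to the `H + W - 1` positions in its
#' own row and column. Query/key projections reduce the channel count to
#' `reduced`; the value projection keeps the input width. With
#' `recurrence = 2` the criss-cross step is applied twice (shared weights),
#' which propagates information between every pair of positions.
#'
#' @param channels Input channel count.
#' @param reduced Q/K channel count (default `max(1, channels %/% 8)`).
#' @param recurrence Number of chained criss-cross steps (>= 1).
#' @param residual Add the block input to the aggregated output.
#' @return A `cca_config` object.
#' @export
cca_config <- function(channels, reduced = max(1L, channels %/% 8L),
                       recurrence = 1L, residual = TRUE) {
  assert_that(recurrence >= 1, "recurrence must be >= 1")
  structure(list(channels = as.integer(channels),
                 reduced = as.integer(reduced),
                 recurrence = as.integer(recurrence),
                 residual = isTRUE(residual)),
            class = "cca_config")
}

cca_init <- function(cfg) {
  C <- cfg$channels; Cr <- cfg$reduced
  list(wq = init_linear(C, Cr), bq = init_bias(Cr),
       wk = init_linear(C, Cr), bk = init_bias(Cr),
       wv = init_linear(C, C), bv = init_bias(C))
}

crisscross_mask <- function(H, W) {
  key <- paste0("CC", H, "x", W)
  hit <- .fabseg_op_cache[[key]]
  if (!is.null(hit)) return(hit)
  h <- rep(seq_len(H), times = W)
  w <- rep(seq_len(W), each = H)
  mask <- outer(h, h, `==`) | outer(w, w, `==`)
  .fabseg_op_cache[[key]] <- mask
  mask
}

cca_step_fwd <- function(x, cfg, params) {
  d <- fm_dims(x)
  Tm <- fm_to_tokens(x)
  Q <- sweep(Tm %*% params$wq, 2, params$bq, `+`)
  K <- sweep(Tm %*% params$wk, 2, params$bk, `+`)
  V <- sweep(Tm %*% params$wv, 2, params$bv, `+`)
  mask <- crisscross_mask(d[2], d[3])
  at <- attention_forward(Q, K, V, mask, scale = 1 / sqrt(cfg$reduced))
  agg <- tokens_to_fm(at$out, d)
  out <- if (cfg$residual) x + agg else agg
  list(out = out, cache = list(Tm = Tm, at = at$cache, d = d,
                               params = params, residual = cfg$residual))
}

cca_step_bwd <- function(dout, cache) {
  d <- cache$d
  dagg <- fm_to_tokens(dout)
  g <- attention_backward(dagg, cache$at)
  p <- cache$params
  grads <- list(
    wq = crossprod(cache$Tm, g$dQ), bq = colSums(g$dQ),
    wk = crossprod(cache$Tm, g$dK), bk = colSums(g$dK),
    wv = crossprod(cache$Tm, g$dV), bv = colSums(g$dV)
  )
  dTm <- tcrossprod(g$dQ, p$wq) + tcrossprod(g$dK, p$wk) +
    tcrossprod(g$dV, p$wv)
  dx <- tokens_to_fm(dTm, d)
  if (cache$residual) dx <- dx + dout
  list(dx = dx, grads = grads)
}

cca_fwd <- function(x, cfg, params) {
  caches <- vector("list", cfg$recurrence)
  cur <- x
  for (r in seq_len(cfg$recurrence)) {
    st <- cca_step_fwd(cur, cfg, params)
    cur <- st$out
    caches[[r]] <- st$cache
  }
  list(out = cur, cache = caches)
}

cca_bwd <- function(dout, cache) {
  grads <- NULL
  dcur <- dout
  for (r in rev(seq_along(cache))) {
    g <- cca_step_bwd(dcur, cache[[r]])
    dcur <- g$dx
    grads <- if (is.null(grads)) g$grads else
      tree_map2(grads, g$grads, `+`)
  }
  list(dx = dcur, grads = grads)
}

#' Criss-cross attention forward pass
#'
#' @param x Feature map with `cfg$channels` channels.
#' @param cfg A [cca_config()].
#' @param params Parameters from the block initialiser.
#' @return Feature map of the same shape as `x`.
#' @export
cca_forward <- function(x, cfg, params) cca_fwd(x, cfg, params)$out
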