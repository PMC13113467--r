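# Minimal neural-network primitives on C x H x W feature maps, with exact
# hand-written backward passes. Convolutions are evaluated as one matrix
# multiply per kernel tap (shift-and-accumulate), which is BLAS-bound and
# fast at the feature-map sizes this package works with. All convolutions
# use zero "same" padding: output spatial size is ceiling(input/stride).

fm_dims <- function(x) {
  d <- dim(x)
  assert_that(length(d) == 3, "feature map must be a C x H x W array")
  d
}

conv_out_len <- function(L, k, stride, dil) {
  p <- (dil * (k - 1L)) %/% 2L
  (L + 2L * p - dil * (k - 1L) - 1L) %/% stride + 1L
}

# Input coordinate sampled by kernel tap `ki` for every output position.
conv_tap_index <- function(Lo, ki, k, stride, dil) {
  p <- (dil * (k - 1L)) %/% 2L
  (seq_len(Lo) - 1L) * stride + (ki - 1L) * dil + 1L - p
}

#' 2-D convolution on a feature map
#'
#' Same-padded 2-D convolution with optional stride and dilation (atrous
#' convolution). A dense kernel of dimension `(Cout, Cin, kh, kw)` mixes
#' channels; a depthwise kernel of dimension `(C, kh, kw)` convolves each
#' channel independently. Kernel sizes must be odd.
#'
#' @param x Feature map, a numeric `C x H x W` array.
#' @param w Kernel array, `(Cout, Cin, kh, kw)` (dense) or `(C, kh, kw)`
#'   (depthwise).
#' @param b Optional bias vector (length = output channels).
#' @param stride Integer stride.
#' @param dilation Integer dilation rate; taps are spaced `dilation` pixels
#'   apart, giving a 3x3 kernel an effective receptive field of
#'   `(2*dilation + 1)` pixels per side.
#' @return Output feature map `(Cout, ceiling(H/stride), ceiling(W/stride))`.
#' @examples
#' x <- array(0, c(1, 9, 9)); x[1, 5, 5] <- 1
#' w <- array(1, c(1, 1, 3, 3))
#' y <- conv2d(x, w, dilation = 2)
#' sum(y != 0)  # 9 taps spread over a 5x5 support
#' @export
conv2d <- function(x, w, b = NULL, stride = 1L, dilation = 1L) {
  conv2d_forward(x, w, b, stride, dilation)$out
}

conv2d_forward <- function(x, w, b = NULL, stride = 1L, dilation = 1L) {
  d <- fm_dims(x); C <- d[1]; H <- d[2]; W <- d[3]
  dw <- dim(w)
  depthwise <- length(dw) == 3L
  if (depthwise) {
    assert_that(dw[1] == C, "depthwise kernel channel mismatch")
    Cout <- C; kh <- dw[2]; kw <- dw[3]
  } else {
    assert_that(length(dw) == 4L && dw[2] == C,
                sprintf("kernel expects %d input channels, feature map has %d",
                        if (length(dw) == 4L) dw[2] else -1L, C))
    Cout <- dw[1]; kh <- dw[3]; kw <- dw[4]
  }
  assert_that(kh %% 2L == 1L && kw %% 2L == 1L, "kernel sizes must be odd")
  stride <- as.integer(stride); dilation <- as.integer(dilation)
  assert_that(stride >= 1L && dilation >= 1L,
              "stride and dilation must be positive")
  Ho <- conv_out_len(H, kh, stride, dilation)
  Wo <- conv_out_len(W, kw, stride, dilation)
  xm <- x; dim(xm) <- c(C, H * W)
  out <- matrix(0, Cout, Ho * Wo)
  for (ki in seq_len(kh)) {
    hi <- conv_tap_index(Ho, ki, kh, stride, dilation)
    hv <- hi >= 1L & hi <= H
    if (!any(hv)) next
    for (kj in seq_len(kw)) {
      wi <- conv_tap_index(Wo, kj, kw, stride, dilation)
      wv <- wi >= 1L & wi <= W
      if (!any(wv)) next
      colidx <- outer(hi, (wi - 1L) * H, `+`)
      valid <- outer(hv, wv, `&`)
      xg <- matrix(0, C, Ho * Wo)
      xg[, valid] <- xm[, colidx[valid], drop = FALSE]
      if (depthwise) {
        out <- out + xg * w[, ki, kj]
      } else {
        out <- out + matrix(w[, , ki, kj], Cout, C) %*% xg
      }
    }
  }
  if (!is.null(b)) out <- out + b
  dim(out) <- c(Cout, Ho, Wo)
  list(out = out,
       cache = list(x = x, w = w, has_b = !is.null(b), stride = stride,
                    dilation = dilation, depthwise = depthwise,
                    kh = kh, kw = kw, Ho = Ho, Wo = Wo))
}

conv2d_backward <- function(dout, cache) {
  x <- cache$x; w <- cache$w
  d <- fm_dims(x); C <- d[1]; H <- d[2]; W <- d[3]
  Ho <- cache$Ho; Wo <- cache$Wo
  kh <- cache$kh; kw <- cache$kw
  stride <- cache$stride; dilation <- cache$dilation
  Cout <- if (cache$depthwise) C else dim(w)[1]
  dom <- dout; dim(dom) <- c(Cout, Ho * Wo)
  xm <- x; dim(xm) <- c(C, H * W)
  dxm <- matrix(0, C, H * W)
  dw <- array(0, dim(w))
  for (ki in seq_len(kh)) {
    hi <- conv_tap_index(Ho, ki, kh, stride, dilation)
    hv <- hi >= 1L & hi <= H
    if (!any(hv)) next
    for (kj in seq_len(kw)) {
      wi <- conv_tap_index(Wo, kj, kw, stride, dilation)
      wv <- wi >= 1L & wi <= W
      if (!any(wv)) next
      colidx <- outer(hi, (wi - 1L) * H, `+`)
      valid <- outer(hv, wv, `&`)
      vvec <- as.vector(valid)
      idx <- colidx[valid]
      xg <- matrix(0, C, Ho * Wo)
      xg[, vvec] <- xm[, idx, drop = FALSE]
      if (cache$depthwise) {
        dw[, ki, kj] <- rowSums(dom * xg)
        dxg <- dom * w[, ki, kj]
      } else {
        wtap <- matrix(w[, , ki, kj], Cout, C)
        dw[, , ki, kj] <- tcrossprod(dom, xg)
        dxg <- crossprod(wtap, dom)
      }
      # per tap the output->input column map is injective, so plain
      # indexed addition accumulates correctly
      dxm[, idx] <- dxm[, idx] + dxg[, vvec, drop = FALSE]
    }
  }
  dim(dxm) <- c(C, H, W)
  out <- list(dx = dxm, dw = dw)
  if (cache$has_b) out$db <- rowSums(dom)
  out
}

relu_forward <- function(x) {
  out <- pmax(x, 0)
  list(out = out, cache = x > 0)
}

relu_backward <- function(dout, cache) dout * cache

gelu_forward <- function(x) {
  ph <- stats::pnorm(x)
  list(out = x * ph, cache = list(x = x, ph = ph))
}

gelu_backward <- function(dout, cache) {
  dout * (cache$ph + cache$x * stats::dnorm(cache$x))
}

# Layer normalization over the channel dimension at each spatial position.
layernorm_forward <- function(x, gamma, beta, eps = 1e-5) {
  d <- dim(x)
  xm <- x; dim(xm) <- c(d[1], prod(d[-1]))
  mu <- colMeans(xm)
  xc <- sweep(xm, 2, mu)
  v <- colMeans(xc * xc)
  inv <- 1 / sqrt(v + eps)
  xhat <- sweep(xc, 2, inv, `*`)
  out <- xhat * gamma + beta
  dim(out) <- d
  list(out = out, cache = list(xhat = xhat, inv = inv, gamma = gamma, d = d))
}

layernorm_backward <- function(dout, cache) {
  d <- cache$d
  dom <- dout; dim(dom) <- c(d[1], prod(d[-1]))
  xhat <- cache$xhat
  dgamma <- rowSums(dom * xhat)
  dbeta <- rowSums(dom)
  dxhat <- dom * cache$gamma
  m1 <- colMeans(dxhat)
  m2 <- colMeans(dxhat * xhat)
  dx <- sweep(dxhat, 2, m1) - sweep(xhat, 2, m2, `*`)
  dx <- sweep(dx, 2, cache$inv, `*`)
  dim(dx) <- d
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

# --- bilinear upsampling (align-corners off) as a cached sparse operator ---

.fabseg_op_cache <- new.env(parent = emptyenv())

upsample_operator <- function(H, W, f) {
  key <- paste0("U", H, "x", W, "x", f)
  hit <- .fabseg_op_cache[[key]]
  if (!is.null(hit)) return(hit)
  lin1d <- function(L, f) {
    t <- (seq_len(L * f) - 0.5) / f + 0.5
    i0 <- floor(t)
    fr <- t - i0
    lo <- i0; hi <- i0 + 1; wlo <- 1 - fr; whi <- fr
    under <- i0 < 1; lo[under] <- 1; hi[under] <- 1; wlo[under] <- 1; whi[under] <- 0
    over <- i0 >= L; lo[over] <- L; hi[over] <- L; wlo[over] <- 1; whi[over] <- 0
    list(lo = as.integer(lo), hi = as.integer(hi), wlo = wlo, whi = whi)
  }
  ry <- lin1d(H, f); rx <- lin1d(W, f)
  Ho <- H * f; Wo <- W * f
  ho <- rep(seq_len(Ho), times = Wo)
  wo <- rep(seq_len(Wo), each = Ho)
  rowi <- seq_len(Ho * Wo)
  ii <- integer(0); jj <- integer(0); vv <- numeric(0)
  for (cy in c("lo", "hi")) {
    for (cx in c("lo", "hi")) {
      yi <- ry[[cy]][ho]
      wy <- if (cy == "lo") ry$wlo[ho] else ry$whi[ho]
      xi <- rx[[cx]][wo]
      wx <- if (cx == "lo") rx$wlo[wo] else rx$whi[wo]
      ii <- c(ii, rowi); jj <- c(jj, yi + H * (xi - 1L)); vv <- c(vv, wy * wx)
    }
  }
  U <- Matrix::sparseMatrix(i = ii, j = jj, x = vv, dims = c(Ho * Wo, H * W))
  .fabseg_op_cache[[key]] <- U
  U
}

upsample_forward <- function(x, f) {
  d <- fm_dims(x)
  U <- upsample_operator(d[2], d[3], f)
  xm <- x; dim(xm) <- c(d[1], d[2] * d[3])
  out <- as.matrix(xm %*% Matrix::t(U))
  dim(out) <- c(d[1], d[2] * f, d[3] * f)
  list(out = out, cache = list(d = d, f = f))
}

upsample_backward <- function(dout, cache) {
  d <- cache$d
  U <- upsample_operator(d[2], d[3], cache$f)
  dom <- dout; dim(dom) <- c(d[1], d[2] * d[3] * cache$f^2)
  dx <- as.matrix(dom %*% U)
  dim(dx) <- d
  dx
}

# --- masked scaled dot-product attention over token matrices ---
# Q, K: n x dk; V: n x dv; mask: n x n logical, TRUE where a query may
# attend. Every row of the mask must have at least one TRUE entry.

attention_forward <- function(Q, K, V, mask = NULL,
                              scale = 1 / sqrt(ncol(Q))) {
  L <- tcrossprod(Q, K) * scale
  if (!is.null(mask)) L[!mask] <- -Inf
  rmax <- apply(L, 1, max)
  assert_that(all(is.finite(rmax)), "attention mask leaves a query with no keys")
  P <- exp(sweep(L, 1, rmax))
  P <- P / rowSums(P)
  out <- P %*% V
  list(out = out, cache = list(P = P, Q = Q, K = K, V = V, scale = scale))
}

attention_backward <- function(dout, cache) {
  P <- cache$P
  dV <- crossprod(P, dout)
  dP <- tcrossprod(dout, cache$V)
  dL <- P * sweep(dP, 1, rowSums(dP * P))
  dQ <- (dL %*% cache$K) * cache$scale
  dK <- crossprod(dL, cache$Q) * cache$scale
  list(dQ = dQ, dK = dK, dV = dV)
}

# --- parameter initialisation (Kaiming-style, driven by the caller's RNG) ---

init_conv <- function(cout, cin, kh, kw, gain = 2) {
  sd <- sqrt(gain / (cin * kh * kw))
  array(stats::rnorm(cout * cin * kh * kw, sd = sd), c(cout, cin, kh, kw))
}

init_dwconv <- function(c, kh, kw, gain = 2) {
  sd <- sqrt(gain / (kh * kw))
  array(stats::rnorm(c * kh * kw, sd = sd), c(c, kh, kw))
}

# Token-space linear map, stored (d_in x d_out): tokens (n x d_in) %*% w.
init_linear <- function(din, dout, gain = 1) {
  matrix(stats::rnorm(din * dout, sd = sqrt(gain / din)), din, dout)
}

init_bias <- function(n) numeric(n)

# Tokens-as-rows view of a feature map and back.
fm_to_tokens <- function(x) {
  d <- fm_dims(x)
  xm <- x; dim(xm) <- c(d[1], d[2] * d[3])
  t(xm)
}

tokens_to_fm <- function(tok, d) {
  xm <- t(tok)
  dim(xm) <- d
  xm
}
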