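#' Segmentation network configuration
#'
#' The network is a DeepLabv3+-style encoder-decoder. A small residual CNN
#' backbone (output stride 16, low-level tap at stride 4) feeds a chain of
#' four feature-enhancement blocks - atrous spatial pyramid pooling,
#' multi-scale convolutional attention, a BiFormer (bi-level routing
#' attention) block, and criss-cross attention - followed by a 1x1 channel
#' compression. The decoder upsamples the high-level features by 4, adjusts
#' channels with a 1x1 convolution, concatenates reduced low-level features,
#' refines with a 3x3 convolution, upsamples by 4 again, and a final 1x1
#' convolution emits one score map per class.
#'
#' @param n_classes Number of classes including background (14 for the
#'   default 13-structure schema).
#' @param widths Backbone stage widths (stem, stride-4, stride-8, stride-16).
#' @param branch_channels Channels per ASPP branch (the enhancement chain
#'   runs at `4 * branch_channels` channels).
#' @param encoder_channels Channels after the post-chain 1x1 compression.
#' @param decoder_channels Decoder working width.
#' @param lowlevel_channels Channels of the reduced low-level features.
#' @param aspp,msca,bra,cca Optional block config overrides; by default they
#'   are derived from the widths with the standard dilation rates
#'   (6/12/18/24), strip lengths (7/11/21), region grid S = 2 with top-k = 4,
#'   and criss-cross recurrence 1.
#' @return A `network_config` object. Output stride is 16.
#' @export
network_config <- function(n_classes = 14L,
                           widths = c(32L, 64L, 128L, 256L),
                           branch_channels = 64L,
                           encoder_channels = 256L,
                           decoder_channels = 256L,
                           lowlevel_channels = 48L,
                           aspp = NULL, msca = NULL, bra = NULL, cca = NULL) {
  assert_that(length(widths) == 4 && all(widths >= 1),
              "widths must give the four backbone stage widths")
  cmid <- 4L * as.integer(branch_channels)
  aspp <- aspp %||% aspp_config(branch_channels = branch_channels)
  assert_that(length(aspp$rates) * aspp$branch_channels == cmid,
              "aspp config inconsistent with branch_channels")
  msca <- msca %||% msca_config(channels = cmid)
  bra <- bra %||% bra_config(channels = cmid)
  cca <- cca %||% cca_config(channels = cmid)
  assert_that(msca$channels == cmid,
              "channel plan broken at edge aspp->msca")
  assert_that(bra$channels == cmid,
              "channel plan broken at edge msca->biformer")
  assert_that(cca$channels == cmid,
              "channel plan broken at edge biformer->cca")
  structure(list(n_classes = as.integer(n_classes),
                 widths = as.integer(widths),
                 branch_channels = as.integer(branch_channels),
                 encoder_channels = as.integer(encoder_channels),
                 decoder_channels = as.integer(decoder_channels),
                 lowlevel_channels = as.integer(lowlevel_channels),
                 output_stride = 16L,
                 aspp = aspp, msca = msca, bra = bra, cca = cca),
            class = "network_config")
}

#' Tiny network profile for CPU-scale experiments
#'
#' Same wiring as [network_config()] with small widths, so training runs and
#' tests complete quickly on one CPU.
#'
#' @param n_classes Number of classes including background.
#' @return A `network_config`.
#' @export
tiny_network_config <- function(n_classes = 14L) {
  network_config(n_classes = n_classes,
                 widths = c(8L, 16L, 32L, 32L),
                 branch_channels = 8L,
                 encoder_channels = 32L,
                 decoder_channels = 32L,
                 lowlevel_channels = 16L)
}

#' Build a segmentation model
#'
#' Initialises all parameters (Kaiming-style for convolutions, unit/zero for
#' layer norms) deterministically from `seed`.
#'
#' @param cfg A [network_config()].
#' @param seed Integer seed; the same seed always yields bit-identical
#'   parameters.
#' @return A `seg_model` (parameter tree + config).
#' @export
build_model <- function(cfg, seed = 1L) {
  stopifnot(inherits(cfg, "network_config"))
  w <- cfg$widths
  cmid <- 4L * cfg$branch_channels
  # every conv (except the classifier) is followed by channelwise layer
  # norm, the deterministic batch-size-independent stand-in for the batch
  # norm used by DeepLab-style networks
  conv_ln <- function(cout, cin, k) {
    list(w = init_conv(cout, cin, k, k), b = init_bias(cout),
         ln = list(gamma = rep(1, cout), beta = numeric(cout)))
  }
  params <- with_seed(seed, list(
    stem = conv_ln(w[1], 1L, 3L),
    stage2 = list(down = conv_ln(w[2], w[1], 3L), res = conv_ln(w[2], w[2], 3L)),
    stage3 = list(down = conv_ln(w[3], w[2], 3L), res = conv_ln(w[3], w[3], 3L)),
    stage4 = list(down = conv_ln(w[4], w[3], 3L), res = conv_ln(w[4], w[4], 3L)),
    aspp = aspp_init(w[4], cfg$aspp),
    aspp_ln = list(gamma = rep(1, cmid), beta = numeric(cmid)),
    msca = msca_init(cfg$msca),
    bra = bra_init(cfg$bra),
    cca = cca_init(cfg$cca),
    compress = conv_ln(cfg$encoder_channels, cmid, 1L),
    dec_adjust = conv_ln(cfg$decoder_channels, cfg$encoder_channels, 1L),
    dec_low = conv_ln(cfg$lowlevel_channels, w[2], 1L),
    dec_refine = conv_ln(cfg$decoder_channels,
                         cfg$decoder_channels + cfg$lowlevel_channels, 3L),
    classifier = list(w = init_conv(cfg$n_classes, cfg$decoder_channels,
                                    1L, 1L),
                      b = init_bias(cfg$n_classes))
  ))
  structure(list(cfg = cfg, params = params, seed = as.integer(seed)),
            class = "seg_model")
}

#' @export
print.seg_model <- function(x, ...) {
  np <- length(tree_unlist(x$params))
  cat(sprintf("seg_model: %d classes, widths %s, %d parameters\n",
              x$cfg$n_classes, paste(x$cfg$widths, collapse = "/"), np))
  invisible(x)
}

# conv -> layer norm unit with its backward
convln_fwd <- function(x, p, stride = 1L, dilation = 1L) {
  cv <- conv2d_forward(x, p$w, p$b, stride = stride, dilation = dilation)
  ln <- layernorm_forward(cv$out, p$ln$gamma, p$ln$beta)
  list(out = ln$out, cache = list(cv = cv$cache, ln = ln$cache))
}

convln_bwd <- function(dout, cache) {
  gl <- layernorm_backward(dout, cache$ln)
  gc <- conv2d_backward(gl$dx, cache$cv)
  list(dx = gc$dx,
       grads = list(w = gc$dw, b = gc$db,
                    ln = list(gamma = gl$dgamma, beta = gl$dbeta)))
}

# One residual backbone stage: strided 3x3 conv + LN + ReLU, then a 3x3
# conv + LN with residual add + ReLU.
stage_fwd <- function(x, p) {
  dn <- convln_fwd(x, p$down, stride = 2L)
  a1 <- relu_forward(dn$out)
  rs <- convln_fwd(a1$out, p$res)
  a2 <- relu_forward(a1$out + rs$out)
  list(out = a2$out, cache = list(dn = dn$cache, a1 = a1$cache,
                                  rs = rs$cache, a2 = a2$cache))
}

stage_bwd <- function(dout, cache) {
  d2 <- relu_backward(dout, cache$a2)
  gr <- convln_bwd(d2, cache$rs)
  da1 <- d2 + gr$dx
  d1 <- relu_backward(da1, cache$a1)
  gd <- convln_bwd(d1, cache$dn)
  list(dx = gd$dx, grads = list(down = gd$grads, res = gr$grads))
}

model_fwd <- function(params, cfg, x) {
  st <- convln_fwd(x, params$stem, stride = 2L)
  sa <- relu_forward(st$out)
  s2 <- stage_fwd(sa$out, params$stage2)           # stride 4 (low-level tap)
  s3 <- stage_fwd(s2$out, params$stage3)           # stride 8
  s4 <- stage_fwd(s3$out, params$stage4)           # stride 16
  ap <- aspp_fwd(s4$out, cfg$aspp, params$aspp)
  al <- layernorm_forward(ap$out, params$aspp_ln$gamma, params$aspp_ln$beta)
  ar <- relu_forward(al$out)
  ms <- msca_fwd(ar$out, cfg$msca, params$msca)
  bf <- bra_fwd(ms$out, cfg$bra, params$bra)
  cc <- cca_fwd(bf$out, cfg$cca, params$cca)
  cp <- convln_fwd(cc$out, params$compress)
  cpr <- relu_forward(cp$out)
  u1 <- upsample_forward(cpr$out, 4L)
  ad <- convln_fwd(u1$out, params$dec_adjust)
  adr <- relu_forward(ad$out)
  lo <- convln_fwd(s2$out, params$dec_low)
  lor <- relu_forward(lo$out)
  dcat <- fm_dims(adr$out)
  nlow <- dim(lor$out)[1]
  cat_fm <- array(0, c(dcat[1] + nlow, dcat[2], dcat[3]))
  cat_fm[seq_len(dcat[1]), , ] <- adr$out
  cat_fm[dcat[1] + seq_len(nlow), , ] <- lor$out
  rf <- convln_fwd(cat_fm, params$dec_refine)
  rfr <- relu_forward(rf$out)
  u2 <- upsample_forward(rfr$out, 4L)
  cl <- conv2d_forward(u2$out, params$classifier$w, params$classifier$b)
  list(logits = cl$out,
       cache = list(st = st$cache, sa = sa$cache, s2 = s2$cache,
                    s3 = s3$cache, s4 = s4$cache, ap = ap$cache,
                    al = al$cache, ar = ar$cache, ms = ms$cache,
                    bf = bf$cache, cc = cc$cache, cp = cp$cache,
                    cpr = cpr$cache, u1 = u1$cache, ad = ad$cache,
                    adr = adr$cache, lo = lo$cache, lor = lor$cache,
                    ncat = dcat[1], rf = rf$cache, rfr = rfr$cache,
                    u2 = u2$cache, cl = cl$cache))
}

model_bwd <- function(dlogits, cache) {
  gcl <- conv2d_backward(dlogits, cache$cl)
  du2 <- upsample_backward(gcl$dx, cache$u2)
  drf <- relu_backward(du2, cache$rfr)
  grf <- convln_bwd(drf, cache$rf)
  ncat <- cache$ncat
  dadr <- grf$dx[seq_len(ncat), , , drop = FALSE]
  dlor <- grf$dx[-seq_len(ncat), , , drop = FALSE]
  dlo <- relu_backward(dlor, cache$lor)
  glo <- convln_bwd(dlo, cache$lo)
  dad <- relu_backward(dadr, cache$adr)
  gad <- convln_bwd(dad, cache$ad)
  du1 <- upsample_backward(gad$dx, cache$u1)
  dcp <- relu_backward(du1, cache$cpr)
  gcp <- convln_bwd(dcp, cache$cp)
  gcc <- cca_bwd(gcp$dx, cache$cc)
  gbf <- bra_bwd(gcc$dx, cache$bf)
  gms <- msca_bwd(gbf$dx, cache$ms)
  dal <- relu_backward(gms$dx, cache$ar)
  gal <- layernorm_backward(dal, cache$al)
  gap <- aspp_bwd(gal$dx, cache$ap)
  ds4 <- stage_bwd(gap$dx, cache$s4)
  ds3 <- stage_bwd(ds4$dx, cache$s3)
  ds2 <- stage_bwd(ds3$dx + glo$dx, cache$s2)
  dsa <- relu_backward(ds2$dx, cache$sa)
  gst <- convln_bwd(dsa, cache$st)
  list(grads = list(
    stem = gst$grads,
    stage2 = ds2$grads, stage3 = ds3$grads, stage4 = ds4$grads,
    aspp = gap$grads,
    aspp_ln = list(gamma = gal$dgamma, beta = gal$dbeta),
    msca = gms$grads, bra = gbf$grads, cca = gcc$grads,
    compress = gcp$grads,
    dec_adjust = gad$grads,
    dec_low = glo$grads,
    dec_refine = grf$grads,
    classifier = list(w = gcl$dw, b = gcl$db)
  ))
}

#' Forward pass: per-pixel class scores
#'
#' @param model A [build_model()] result.
#' @param image H x W numeric intensity matrix in `[0, 1]`, or a list of
#'   them.
#' @param pad Zero-pad inputs whose dimensions are not divisible by the
#'   output stride (16); the score maps are cropped back. When `FALSE`,
#'   non-divisible dimensions raise a shape error.
#' @return `n_classes x H x W` array of raw (unnormalised) scores, or a list
#'   of such arrays.
#' @export
forward <- function(model, image, pad = FALSE) {
  stopifnot(inherits(model, "seg_model"))
  if (is.list(image)) {
    return(lapply(image, function(im) forward(model, im, pad = pad)))
  }
  H <- nrow(image); W <- ncol(image)
  s <- model$cfg$output_stride
  if (H %% s != 0 || W %% s != 0) {
    if (!pad) {
      stop("input dims ", H, "x", W, " not divisible by the output stride (",
           s, "); enable pad = TRUE", call. = FALSE)
    }
    Hp <- ceiling(H / s) * s; Wp <- ceiling(W / s) * s
    xp <- matrix(0, Hp, Wp)
    xp[seq_len(H), seq_len(W)] <- image
    sc <- forward(model, xp)
    return(sc[, seq_len(H), seq_len(W), drop = FALSE])
  }
  x <- array(as.numeric(image), c(1L, H, W))
  model_fwd(model$params, model$cfg, x)$logits
}

#' Decode score maps into a label mask
#'
#' Per-pixel argmax over classes; exact ties resolve to the lowest class id.
#'
#' @param scores `n_classes x H x W` score array (finite; `NaN` raises an
#'   error).
#' @return H x W integer label mask.
#' @export
predict_mask <- function(scores) {
  d <- dim(scores)
  assert_that(length(d) == 3, "scores must be n_classes x H x W")
  assert_that(!anyNA(scores), "NaN/NA scores cannot be decoded")
  sm <- scores; dim(sm) <- c(d[1], d[2] * d[3])
  idx <- max.col(t(sm), ties.method = "first")
  mask <- matrix(as.integer(idx - 1L), d[2], d[3])
  mask
}

#' Save / load a model checkpoint
#'
#' The checkpoint is one serialized archive holding the parameter tree, the
#' network config, the label schema and the training seed.
#'
#' @param model A `seg_model`.
#' @param schema The [label_schema()] the model was trained against.
#' @param path Checkpoint path (`.rds`).
#' @param extra Optional named list stored alongside (e.g. the run log).
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(model, schema, path, extra = list()) {
  saveRDS(c(list(model = model, schema = schema), extra), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  assert_that(inherits(ck$model, "seg_model") &&
                inherits(ck$schema, "label_schema"),
              "not a model checkpoint")
  ck
}
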