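#' Compound loss configuration
#'
#' The training loss is `alpha * CE + (1 - alpha) * (1 - Dice)`: a weighted
#' sum of pixelwise cross-entropy and one minus the (soft, macro-averaged)
#' Dice coefficient. `alpha = 0.5` balances the two terms.
#'
#' @param alpha Weight of the cross-entropy term, in `[0, 1]`.
#' @param eps Dice smoothing constant (> 0); keeps the ratio defined for
#'   empty classes.
#' @param class_weights Optional per-class factors (length = number of
#'   classes incl. background) applied to the cross-entropy term.
#' @param foreground_only Average the Dice term over foreground classes only
#'   (background excluded).
#' @return A `loss_config` object.
#' @export
loss_config <- function(alpha = 0.5, eps = 1, class_weights = NULL,
                        foreground_only = TRUE) {
  assert_that(alpha >= 0 && alpha <= 1, "alpha must lie in [0, 1]")
  assert_that(eps > 0, "eps must be > 0")
  structure(list(alpha = alpha, eps = eps, class_weights = class_weights,
                 foreground_only = isTRUE(foreground_only)),
            class = "loss_config")
}

# probs (n_classes x H x W), truth (H x W integer mask) -> validated
# matrices: P (nc x N), t (N, 0-based ids)
check_probs_truth <- function(probs, truth) {
  d <- dim(probs)
  assert_that(length(d) == 3, "probs must be an n_classes x H x W array")
  assert_that(all(dim(truth) == d[2:3]),
              "probs and truth spatial shapes must match")
  P <- probs; dim(P) <- c(d[1], d[2] * d[3])
  cs <- colSums(P)
  assert_that(all(abs(cs - 1) < 1e-5),
              "probs must be normalized per pixel (channel sums = 1)")
  t <- as.integer(truth)
  assert_that(all(t >= 0 & t < d[1]), "truth ids outside probs channels")
  list(P = P, t = t, nc = d[1])
}

#' Pixelwise cross-entropy loss
#'
#' Mean over pixels of minus the log probability assigned to the true
#' class.
#'
#' @param probs `n_classes x H x W` array of per-pixel class probabilities
#'   (channel sums 1).
#' @param truth H x W integer label mask (0-based ids).
#' @param class_weights Optional per-class weights (weighted mean over
#'   pixels).
#' @return Non-negative scalar.
#' @export
cross_entropy_loss <- function(probs, truth, class_weights = NULL) {
  v <- check_probs_truth(probs, truth)
  p_true <- v$P[cbind(v$t + 1L, seq_along(v$t))]
  nll <- -log(pmax(p_true, 1e-12))
  if (is.null(class_weights)) {
    mean(nll)
  } else {
    w <- class_weights[v$t + 1L]
    sum(w * nll) / sum(w)
  }
}

# Dice class set: foreground classes present in the truth (falls back to
# all foreground classes when the truth is pure background).
dice_class_set <- function(t, nc, foreground_only) {
  ids <- if (foreground_only) seq_len(nc - 1L) else (seq_len(nc) - 1L)
  present <- ids[ids %in% t]
  if (!length(present)) present <- ids
  present
}

#' Soft Dice coefficient
#'
#' Per-class soft Dice `(2 * sum(p*y) + eps) / (sum(p) + sum(y) + eps)`,
#' macro-averaged over the foreground classes present in the truth. With
#' hard (one-hot) probabilities and `eps -> 0` this is exactly
#' `2|A n B| / (|A| + |B|)` per class.
#'
#' @inheritParams cross_entropy_loss
#' @param cfg A [loss_config()].
#' @return Scalar in `[0, 1]`.
#' @export
soft_dice <- function(probs, truth, cfg = loss_config()) {
  v <- check_probs_truth(probs, truth)
  set <- dice_class_set(v$t, v$nc, cfg$foreground_only)
  d <- vapply(set, function(c) {
    p <- v$P[c + 1L, ]
    y <- as.numeric(v$t == c)
    (2 * sum(p * y) + cfg$eps) / (sum(p) + sum(y) + cfg$eps)
  }, numeric(1))
  mean(d)
}

#' Compound cross-entropy / Dice loss
#'
#' `alpha * CE + (1 - alpha) * (1 - Dice)`; at `alpha = 1` it equals
#' [cross_entropy_loss()], at `alpha = 0` it equals `1 - soft_dice()`.
#'
#' @inheritParams soft_dice
#' @return Non-negative scalar.
#' @export
cedice_loss <- function(probs, truth, cfg = loss_config()) {
  ce <- cross_entropy_loss(probs, truth, cfg$class_weights)
  dc <- soft_dice(probs, truth, cfg)
  cfg$alpha * ce + (1 - cfg$alpha) * (1 - dc)
}

# ---- internal logits-based path used by the training loop ----------------

softmax_channels <- function(z) {
  d <- dim(z)
  zm <- z; dim(zm) <- c(d[1], d[2] * d[3])
  mx <- apply(zm, 2, max)
  e <- exp(sweep(zm, 2, mx))
  p <- sweep(e, 2, colSums(e), `/`)
  dim(p) <- d
  p
}

# Loss value and gradient w.r.t. logits for one image.
cedice_loss_grad <- function(logits, truth, cfg) {
  d <- dim(logits)
  nc <- d[1]; N <- d[2] * d[3]
  P <- softmax_channels(logits)
  dim(P) <- c(nc, N)
  t <- as.integer(truth)
  Y <- matrix(0, nc, N)
  Y[cbind(t + 1L, seq_len(N))] <- 1

  p_true <- P[cbind(t + 1L, seq_len(N))]
  if (is.null(cfg$class_weights)) {
    ce <- mean(-log(pmax(p_true, 1e-12)))
    dz_ce <- (P - Y) / N
  } else {
    w <- cfg$class_weights[t + 1L]
    sw <- sum(w)
    ce <- sum(w * -log(pmax(p_true, 1e-12))) / sw
    dz_ce <- sweep(P - Y, 2, w, `*`) / sw
  }

  set <- dice_class_set(t, nc, cfg$foreground_only)
  G <- matrix(0, nc, N)  # dLdice/dP
  dsum <- 0
  for (c in set) {
    p <- P[c + 1L, ]
    y <- Y[c + 1L, ]
    num <- 2 * sum(p * y) + cfg$eps
    den <- sum(p) + sum(y) + cfg$eps
    dsum <- dsum + num / den
    # d(1 - mean D)/dp = -(1/|set|) * (2y*den - num)/den^2
    G[c + 1L, ] <- -(2 * y * den - num) / (den^2 * length(set))
  }
  dice <- dsum / length(set)
  # chain through the channel softmax: dz = P * (G - colsum(G * P))
  dz_dice <- P * sweep(G, 2, colSums(G * P))

  dz <- cfg$alpha * dz_ce + (1 - cfg$alpha) * dz_dice
  dim(dz) <- d
  list(loss = cfg$alpha * ce + (1 - cfg$alpha) * (1 - dice),
       ce = ce, dice = dice, dlogits = dz)
}
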