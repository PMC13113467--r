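#' Training configuration
#'
#' Defaults follow common practice for DeepLab-family segmentation training:
#' SGD with momentum 0.9 and weight decay 1e-4, initial learning rate 0.01
#' decayed by per-epoch cosine annealing over 120 epochs, random horizontal
#' flip (with left/right kidney label swap), rotation within +/-15 degrees
#' and scaling in 0.8-1.2.
#'
#' @param epochs Training epochs (>= 1).
#' @param lr Initial learning rate (> 0).
#' @param momentum SGD momentum.
#' @param weight_decay L2 weight decay.
#' @param batch_size Images per SGD step.
#' @param flip Random horizontal flip (p = 0.5).
#' @param rotate Max absolute rotation in degrees (0 disables).
#' @param scale Scale range `c(min, max)` (`c(1, 1)` disables).
#' @param lateral_swap Swap LK/RK labels on horizontal flip.
#' @param loss A [loss_config()].
#' @param seed Integer seed for init, shuffling and augmentation.
#' @param val_every Validate every this many epochs.
#' @param warmup Linear learning-rate warmup epochs before the cosine phase
#'   (0 = pure cosine schedule).
#' @param class_balance When the loss has no explicit class weights, derive
#'   median-frequency balancing weights from the training masks (rare
#'   structures get proportionally larger cross-entropy weight).
#' @return A `train_config` object.
#' @export
train_config <- function(epochs = 120L, lr = 0.01, momentum = 0.9,
                         weight_decay = 1e-4, batch_size = 8L, flip = TRUE,
                         rotate = 15, scale = c(0.8, 1.2),
                         lateral_swap = TRUE, loss = loss_config(),
                         seed = 1L, val_every = 1L, warmup = 0L,
                         class_balance = TRUE) {
  assert_that(lr > 0, "lr must be > 0")
  assert_that(epochs >= 1, "epochs must be >= 1")
  structure(list(epochs = as.integer(epochs), lr = lr, momentum = momentum,
                 weight_decay = weight_decay,
                 batch_size = as.integer(batch_size), flip = isTRUE(flip),
                 rotate = rotate, scale = scale,
                 lateral_swap = isTRUE(lateral_swap), loss = loss,
                 seed = as.integer(seed), val_every = as.integer(val_every),
                 warmup = as.integer(warmup),
                 class_balance = isTRUE(class_balance)),
            class = "train_config")
}

#' Cosine annealing learning rate
#'
#' `lr(epoch) = lr0 * (1 + cos(pi * epoch / epochs)) / 2`: starts at the
#' initial rate and anneals to 0 at the final epoch. With a nonzero
#' `cfg$warmup`, the first `warmup` epochs ramp linearly from
#' `lr0 / warmup` to `lr0` before the cosine phase.
#'
#' @param epoch 0-based epoch index, `0 <= epoch <= epochs`.
#' @param cfg A [train_config()] (fields `lr`, `epochs`, `warmup`).
#' @return Learning rate scalar.
#' @export
cosine_lr <- function(epoch, cfg) {
  assert_that(all(epoch >= 0 & epoch <= cfg$epochs),
              "epoch out of [0, epochs]")
  warmup <- cfg$warmup %||% 0L
  ifelse(epoch < warmup,
         cfg$lr * (epoch + 1) / warmup,
         cfg$lr * 0.5 * (1 + cos(pi * epoch / cfg$epochs)))
}

#' Horizontal flip of an image/mask pair
#'
#' Mirrors columns. With `lateral_swap`, the left-kidney and right-kidney
#' ids are exchanged so the flipped mask stays anatomically consistent.
#' Applying the flip twice restores both inputs exactly.
#'
#' @param image H x W intensity matrix.
#' @param mask H x W integer label mask.
#' @param schema A [label_schema()].
#' @param lateral_swap Swap LK/RK ids.
#' @return List with flipped `image` and `mask`.
#' @export
flip_horizontal <- function(image, mask, schema = label_schema(),
                            lateral_swap = TRUE) {
  image <- image[, rev(seq_len(ncol(image))), drop = FALSE]
  mask <- mask[, rev(seq_len(ncol(mask))), drop = FALSE]
  if (lateral_swap && all(c("LK", "RK") %in% names(schema$classes))) {
    lk <- schema_id(schema, "LK"); rk <- schema_id(schema, "RK")
    is_lk <- mask == lk
    mask[mask == rk] <- lk
    mask[is_lk] <- rk
  }
  list(image = image, mask = mask)
}

# Rotate by `angle` degrees and scale by `s` about the image centre;
# bilinear for the image, nearest for the mask; zero fill outside.
warp_pair <- function(image, mask, angle, s) {
  H <- nrow(image); W <- ncol(image)
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  a <- -angle * pi / 180
  tr <- rep(seq_len(H), times = W) - cy
  tc <- rep(seq_len(W), each = H) - cx
  sr <- (cos(a) * tr - sin(a) * tc) / s + cy
  sc <- (sin(a) * tr + cos(a) * tc) / s + cx
  r0 <- floor(sr); c0 <- floor(sc)
  fr <- sr - r0; fc <- sc - c0
  gather <- function(r, c) {
    ok <- r >= 1 & r <= H & c >= 1 & c <= W
    v <- numeric(length(r))
    v[ok] <- image[cbind(r[ok], c[ok])]
    v
  }
  img <- (1 - fr) * (1 - fc) * gather(r0, c0) +
    (1 - fr) * fc * gather(r0, c0 + 1) +
    fr * (1 - fc) * gather(r0 + 1, c0) +
    fr * fc * gather(r0 + 1, c0 + 1)
  rn <- round(sr); cn <- round(sc)
  okm <- rn >= 1 & rn <= H & cn >= 1 & cn <= W
  m <- integer(length(rn))
  m[okm] <- mask[cbind(rn[okm], cn[okm])]
  list(image = matrix(img, H, W), mask = matrix(m, H, W))
}

#' Random geometric augmentation of an image/mask pair
#'
#' Applies the same random flip/rotation/scale to the image (bilinear) and
#' mask (nearest neighbour). With every switch off this is the identity.
#'
#' @param image,mask Paired H x W arrays.
#' @param cfg A [train_config()] (fields `flip`, `rotate`, `scale`,
#'   `lateral_swap`).
#' @param seed Integer seed.
#' @param schema A [label_schema()] (for the laterality swap).
#' @return List with augmented `image` and `mask`.
#' @export
augment <- function(image, mask, cfg, seed, schema = label_schema()) {
  assert_that(all(dim(image) == dim(mask)), "image/mask shape mismatch")
  with_seed(seed, {
    if (cfg$flip && stats::runif(1) < 0.5) {
      fl <- flip_horizontal(image, mask, schema, cfg$lateral_swap)
      image <- fl$image; mask <- fl$mask
    }
    angle <- if (cfg$rotate > 0) stats::runif(1, -cfg$rotate, cfg$rotate) else 0
    s <- if (!isTRUE(all.equal(cfg$scale, c(1, 1)))) {
      stats::runif(1, cfg$scale[1], cfg$scale[2])
    } else 1
    if (angle != 0 || s != 1) {
      wp <- warp_pair(image, mask, angle, s)
      image <- wp$image; mask <- wp$mask
    }
    list(image = image, mask = mask)
  })
}

# Load the (image, truth-mask) pairs of a record set into memory.
load_records <- function(records, schema) {
  lapply(seq_len(nrow(records)), function(i) {
    rec <- records[i, ]
    img <- read_image_png(rec$image)
    msk <- if (!is.na(rec$mask) && nzchar(rec$mask)) {
      read_mask_png(rec$mask)
    } else {
      rasterize_annotation(read_annotation(rec$annotation, schema), schema)
    }
    list(image = img, mask = msk)
  })
}

#' Median-frequency class-balancing weights
#'
#' For every class present in the masks, `weight = median(freq) / freq`
#' (clipped to `[0.05, 20]`); absent classes get weight 1. Rare structures
#' therefore contribute to the cross-entropy term in proportion to the
#' median-frequency class rather than their tiny pixel share.
#'
#' @param masks List of integer label masks.
#' @param n_classes Number of classes including background.
#' @return Numeric weight vector of length `n_classes`.
#' @export
median_frequency_weights <- function(masks, n_classes) {
  freq <- table(factor(unlist(lapply(masks, as.integer)),
                       levels = 0:(n_classes - 1L)))
  freq <- as.numeric(freq) / sum(freq)
  w <- rep(1, n_classes)
  present <- freq > 0
  w[present] <- stats::median(freq[present]) / freq[present]
  pmin(pmax(w, 0.05), 20)
}

sgd_update <- function(params, grads, velocity, lr, momentum, weight_decay) {
  velocity <- tree_map2(velocity,
                        tree_map2(grads, params,
                                  function(g, p) g + weight_decay * p),
                        function(v, g) momentum * v - lr * g)
  list(params = tree_map2(params, velocity, `+`), velocity = velocity)
}

# Macro mIoU / mDice of a model on in-memory pairs (validation monitor).
quick_val_metrics <- function(params, cfg, pairs, schema) {
  preds <- lapply(pairs, function(pr) {
    x <- array(as.numeric(pr$image), c(1L, nrow(pr$image), ncol(pr$image)))
    predict_mask(model_fwd(params, cfg, x)$logits)
  })
  counts <- pool_confusion(lapply(seq_along(pairs), function(i) {
    confusion_counts(preds[[i]], pairs[[i]]$mask, schema)
  }))
  pcm <- per_class_metrics(counts)
  fg <- pcm$id >= 1 & pcm$evaluable
  if (!any(fg)) return(c(mIoU = NA_real_, mDice = NA_real_))
  c(mIoU = mean(pcm$IoU[fg]), mDice = mean(pcm$Dice[fg]))
}

#' Train a segmentation model
#'
#' SGD with momentum and weight decay on the compound cross-entropy/Dice
#' loss; the learning rate follows [cosine_lr()] per epoch; augmentation per
#' `cfg`; the checkpoint with the best validation mIoU is retained (the
#' final model when there is no validation partition). Fully deterministic
#' under `cfg$seed`.
#'
#' @param cfg A [train_config()].
#' @param split A [make_split()] assignment (partitions `train` and
#'   optionally `val` are used).
#' @param net_cfg A [network_config()].
#' @param out_dir Optional directory for the checkpoint (`checkpoint.rds`)
#'   and run log (`runlog.csv`).
#' @param schema A [label_schema()]; must have `net_cfg$n_classes - 1`
#'   foreground classes.
#' @return List with `model` (best checkpoint), `final_model`, `runlog`
#'   (data frame: epoch, lr, loss, val_mIoU, val_mDice), `best_epoch`.
#' @export
train <- function(cfg, split, net_cfg, out_dir = NULL,
                  schema = label_schema()) {
  stopifnot(inherits(cfg, "train_config"), inherits(net_cfg, "network_config"))
  assert_that(schema$n + 1L == net_cfg$n_classes,
              "schema size does not match the network class count")
  train_rec <- partition_records(split, "train")
  assert_that(nrow(train_rec) > 0, "empty training partition")
  val_rec <- partition_records(split, "val")
  train_pairs <- load_records(train_rec, schema)
  val_pairs <- if (nrow(val_rec) > 0) load_records(val_rec, schema) else list()

  if (is.null(cfg$loss$class_weights) && isTRUE(cfg$class_balance)) {
    cfg$loss$class_weights <- median_frequency_weights(
      lapply(train_pairs, `[[`, "mask"), net_cfg$n_classes)
  }

  model <- build_model(net_cfg, cfg$seed)
  params <- model$params
  velocity <- tree_map(params, function(p) p * 0)
  n <- length(train_pairs)
  log_rows <- vector("list", cfg$epochs)
  best <- list(score = -Inf, params = params, epoch = 0L)
  aug_on <- cfg$flip || cfg$rotate > 0 || !isTRUE(all.equal(cfg$scale, c(1, 1)))

  with_seed(cfg$seed, {
    for (epoch in seq_len(cfg$epochs)) {
      lr <- cosine_lr(epoch - 1L, cfg)
      order <- sample.int(n)
      ep_loss <- 0; n_batches <- 0L
      for (start in seq(1, n, by = cfg$batch_size)) {
        idx <- order[start:min(start + cfg$batch_size - 1L, n)]
        gsum <- NULL; bloss <- 0
        for (i in idx) {
          pr <- train_pairs[[i]]
          if (aug_on) {
            pr <- augment(pr$image, pr$mask, cfg,
                          seed = sample.int(.Machine$integer.max, 1),
                          schema = schema)
          }
          x <- array(as.numeric(pr$image),
                     c(1L, nrow(pr$image), ncol(pr$image)))
          fw <- model_fwd(params, net_cfg, x)
          lg <- cedice_loss_grad(fw$logits, pr$mask, cfg$loss)
          if (!is.finite(lg$loss)) {
            stop(sprintf(
              "non-finite loss at epoch %d (lr %.5f): ce=%.4g dice=%.4g",
              epoch, lr, lg$ce, lg$dice), call. = FALSE)
          }
          bloss <- bloss + lg$loss
          g <- model_bwd(lg$dlogits, fw$cache)$grads
          gsum <- if (is.null(gsum)) g else tree_map2(gsum, g, `+`)
        }
        gmean <- tree_map(gsum, function(g) g / length(idx))
        up <- sgd_update(params, gmean, velocity, lr, cfg$momentum,
                         cfg$weight_decay)
        params <- up$params; velocity <- up$velocity
        ep_loss <- ep_loss + bloss / length(idx)
        n_batches <- n_batches + 1L
      }
      vm <- c(mIoU = NA_real_, mDice = NA_real_)
      if (length(val_pairs) && epoch %% cfg$val_every == 0L) {
        vm <- quick_val_metrics(params, net_cfg, val_pairs, schema)
        if (!is.na(vm["mIoU"]) && vm["mIoU"] > best$score) {
          best <- list(score = vm[["mIoU"]], params = params, epoch = epoch)
        }
      }
      log_rows[[epoch]] <- data.frame(
        epoch = epoch, lr = lr, loss = ep_loss / n_batches,
        val_mIoU = vm[["mIoU"]], val_mDice = vm[["mDice"]])
      message(sprintf("epoch %3d  lr %.5f  loss %.4f  val mIoU %s",
                      epoch, lr, ep_loss / n_batches,
                      ifelse(is.na(vm[["mIoU"]]), "-",
                             sprintf("%.3f", vm[["mIoU"]]))))
    }
  })

  runlog <- do.call(rbind, log_rows)
  final_model <- structure(list(cfg = net_cfg, params = params,
                                seed = cfg$seed), class = "seg_model")
  best_model <- if (best$epoch > 0L) {
    structure(list(cfg = net_cfg, params = best$params, seed = cfg$seed),
              class = "seg_model")
  } else final_model
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    save_checkpoint(best_model, schema, file.path(out_dir, "checkpoint.rds"),
                    extra = list(runlog = runlog))
    utils::write.csv(runlog, file.path(out_dir, "runlog.csv"),
                     row.names = FALSE)
  }
  list(model = best_model, final_model = final_model, runlog = runlog,
       best_epoch = best$epoch)
}

#' Evaluate a model on a record set
#'
#' Runs the model on every record and computes the pooled-count
#' [metric_report()] against the ground-truth masks. Deterministic: two
#' evaluations of the same checkpoint on the same data yield identical
#' reports.
#'
#' @param model A `seg_model` or a checkpoint path / list from
#'   [load_checkpoint()].
#' @param records A [dataset_index()] subset (non-empty).
#' @param schema A [label_schema()]; must match the model's class count.
#' @return A [metric_report()].
#' @export
evaluate <- function(model, records, schema = label_schema()) {
  if (is.character(model)) model <- load_checkpoint(model)
  if (is.list(model) && !inherits(model, "seg_model")) {
    schema <- model$schema %||% schema
    model <- model$model
  }
  stopifnot(inherits(model, "seg_model"))
  assert_that(schema$n + 1L == model$cfg$n_classes,
              "schema does not match the checkpoint class count")
  assert_that(nrow(records) > 0, "empty evaluation partition")
  pairs <- load_records(records, schema)
  preds <- lapply(pairs, function(pr) {
    predict_mask(forward(model, pr$image))
  })
  truths <- lapply(pairs, `[[`, "mask")
  metric_report(preds, truths, schema)
}

#' Cross-validated training
#'
#' Trains one model per fold (fold f is the validation/evaluation set, the
#' rest train) and averages the macro metrics arithmetically across folds.
#'
#' @param cfg A [train_config()].
#' @param folds A [make_cv_folds()] assignment.
#' @param net_cfg A [network_config()].
#' @param schema A [label_schema()].
#' @return List with `fold_reports` (per-fold [metric_report()]s) and
#'   `summary` (data frame of per-fold and mean macro metrics).
#' @export
cross_validate <- function(cfg, folds, net_cfg, schema = label_schema()) {
  assert_that("fold" %in% names(folds), "folds must come from make_cv_folds")
  ks <- sort(unique(folds$fold))
  assert_that(length(ks) >= 2, "need at least two folds")
  reports <- vector("list", length(ks))
  for (f in seq_along(ks)) {
    asg <- folds
    asg$partition <- ifelse(asg$fold == ks[f], "val", "train")
    class(asg) <- c("split_assignment", "data.frame")
    fit <- train(cfg, asg, net_cfg, schema = schema)
    reports[[f]] <- evaluate(fit$model, partition_records(asg, "val"), schema)
  }
  macro <- function(rep) unlist(rep[rep$class == "mean",
                                    c("IoU", "Dice", "PA", "ASD")])
  per_fold <- do.call(rbind, lapply(reports, macro))
  summary <- data.frame(fold = c(ks, NA),
                        rbind(per_fold, colMeans(per_fold)))
  summary$fold <- c(as.character(ks), "mean")
  list(fold_reports = reports, summary = summary)
}
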