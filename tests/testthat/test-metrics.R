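test_that("confusion counts match hand-enumerated pixels", {
  sch <- label_schema(c("A", "B"))
  # 4x4 toy: class 1 has TP = 2, FP = 1, FN = 1, TN = 12
  truth <- matrix(0L, 4, 4); truth[1, 1] <- 1L; truth[1, 2] <- 1L
  truth[2, 1] <- 1L
  pred <- truth; pred[2, 1] <- 0L; pred[3, 3] <- 1L
  cc <- confusion_counts(pred, truth, sch)
  i <- which(cc$ids == 1L)
  expect_equal(cc$tp[i], 2); expect_equal(cc$fp[i], 1)
  expect_equal(cc$fn[i], 1); expect_equal(cc$tn[i], 12)
  # partition identities: every pixel has exactly one true class, and the
  # one-vs-rest counts of every class tile the image
  expect_equal(sum(cc$tp + cc$fn), 16)
  expect_true(all(cc$tp + cc$fp + cc$fn + cc$tn == 16))
})

test_that("each pixel has one true class: sum over classes of TP + FN = N", {
  sch <- label_schema()
  set.seed(31)
  truth <- matrix(sample(0:13, 64, TRUE), 8, 8)
  pred <- matrix(sample(0:13, 64, TRUE), 8, 8)
  cc <- confusion_counts(pred, truth, sch)
  expect_equal(sum(cc$tp + cc$fn), 64)
  expect_error(confusion_counts(matrix(0L, 2, 2), truth, sch), "mismatch")
})

test_that("per-class metrics follow their closed forms", {
  sch <- label_schema(c("A"))
  truth <- matrix(0L, 4, 4); truth[1, 1:3] <- 1L
  pred <- matrix(0L, 4, 4); pred[1, 1:2] <- 1L; pred[2, 4] <- 1L
  # TP = 2, FP = 1, FN = 1
  pcm <- per_class_metrics(confusion_counts(pred, truth, sch))
  row <- pcm[pcm$class == "A", ]
  expect_equal(row$IoU, 0.5)
  expect_equal(row$Dice, 2 / 3)
  expect_equal(row$PA, 14 / 16)
  perfect <- per_class_metrics(confusion_counts(truth, truth, sch))
  expect_true(all(perfect$PA == 1 & perfect$Dice == 1 & perfect$IoU == 1))
})

test_that("Dice = 2 IoU / (1 + IoU) on 100 random mask pairs", {
  sch <- label_schema(c("A", "B", "C"))
  set.seed(32)
  for (rep in 1:100) {
    truth <- matrix(sample(0:3, 49, TRUE), 7, 7)
    pred <- matrix(sample(0:3, 49, TRUE), 7, 7)
    pcm <- per_class_metrics(confusion_counts(pred, truth, sch))
    ok <- pcm$evaluable
    expect_equal(pcm$Dice[ok], 2 * pcm$IoU[ok] / (1 + pcm$IoU[ok]),
                 tolerance = 1e-9)
    expect_true(all(pcm$Dice[ok] >= 0 & pcm$Dice[ok] <= 1))
    expect_true(all(pcm$IoU[ok] >= 0 & pcm$IoU[ok] <= 1))
  }
})

test_that("unevaluable classes are flagged, not thrown", {
  sch <- label_schema(c("A", "B"))
  truth <- matrix(0L, 3, 3); truth[1, 1] <- 1L
  pred <- truth
  pcm <- per_class_metrics(confusion_counts(pred, truth, sch))
  expect_false(pcm$evaluable[pcm$class == "B"])
  expect_true(is.na(pcm$IoU[pcm$class == "B"]))
})

test_that("surface distance is zero on identical masks and exact on fixtures", {
  m <- matrix(0L, 9, 9); m[3:5, 3:6] <- 1L
  expect_equal(surface_distance(m, m, 1L), 0)
  # two single-pixel masks three pixels apart on one row
  a <- matrix(0L, 7, 9); a[4, 2] <- 1L
  b <- matrix(0L, 7, 9); b[4, 5] <- 1L
  expect_equal(surface_distance(a, b, 1L), 3)
  expect_equal(surface_distance(b, a, 1L), 3)  # symmetric
  # absent from truth -> unevaluable; empty prediction -> image diagonal
  expect_true(is.na(surface_distance(a, matrix(0L, 7, 9), 1L)))
  expect_equal(surface_distance(matrix(0L, 7, 9), b, 1L), sqrt(49 + 81))
})

test_that("surface distance agrees with a brute-force all-pairs oracle", {
  set.seed(33)
  for (rep in 1:5) {
    a <- matrix(as.integer(matrix(rbinom(100, 1, 0.3), 10)), 10)
    b <- matrix(as.integer(matrix(rbinom(100, 1, 0.3), 10)), 10)
    if (sum(a) == 0 || sum(b) == 0) next
    # oracle: explicit double loop over boundary pixels
    bnd <- function(m) {
      out <- NULL
      for (r in 1:10) for (c in 1:10) {
        if (m[r, c] == 1) {
          nb <- c(if (r > 1) m[r - 1, c] else 0, if (r < 10) m[r + 1, c] else 0,
                  if (c > 1) m[r, c - 1] else 0, if (c < 10) m[r, c + 1] else 0)
          if (any(nb == 0)) out <- rbind(out, c(r, c))
        }
      }
      out
    }
    ba <- bnd(a); bb <- bnd(b)
    total <- 0
    for (i in seq_len(nrow(ba))) {
      total <- total + min(sqrt((ba[i, 1] - bb[, 1])^2 + (ba[i, 2] - bb[, 2])^2))
    }
    for (i in seq_len(nrow(bb))) {
      total <- total + min(sqrt((bb[i, 1] - ba[, 1])^2 + (bb[i, 2] - ba[, 2])^2))
    }
    expect_equal(surface_distance(a, b, 1L), total / (nrow(ba) + nrow(bb)),
                 tolerance = 1e-9)
  }
})

test_that("surface distance is translation invariant and ~linear under x2", {
  base <- matrix(0L, 12, 12); base[3:5, 3:5] <- 1L
  other <- matrix(0L, 12, 12); other[6:9, 5:8] <- 1L
  d <- surface_distance(base, other, 1L)
  shift <- function(m, dr, dc) {
    out <- matrix(0L, nrow(m), ncol(m))
    out[(1:3) + 2 + dr, (1:3) + 2 + dc] <- 1L
    out
  }
  d2 <- surface_distance(shift(base, 2, 1),
                         {o <- matrix(0L, 12, 12); o[8:11, 6:9] <- 1L; o}, 1L)
  expect_equal(d, d2, tolerance = 1e-9)
  up <- function(m) {
    big <- matrix(0L, 24, 24)
    for (r in 1:12) for (c in 1:12) {
      if (m[r, c] == 1) big[(2 * r - 1):(2 * r), (2 * c - 1):(2 * c)] <- 1L
    }
    big
  }
  dup <- surface_distance(up(base), up(other), 1L)
  expect_gte(dup, 2 * d - 2)
  expect_lte(dup, 2 * d + 2)
})

test_that("macro aggregation averages evaluable classes only", {
  expect_equal(aggregate_macro(c(0.4, 0.6)), 0.5)
  expect_equal(aggregate_macro(c(0.4, NA, 0.8), c(TRUE, FALSE, TRUE)), 0.6)
  expect_error(aggregate_macro(c(NA_real_, NA_real_)), "no evaluable")
})

test_that("metric report macro means match a hand-computed fixture", {
  sch <- label_schema(c("A", "B", "C"))
  truth <- matrix(0L, 6, 6)
  truth[1:2, 1:3] <- 1L   # A: 6 px
  truth[5:6, 5:6] <- 2L   # B: 4 px
  pred <- truth
  pred[1, 1] <- 0L        # A: FN 1
  pred[3, 1] <- 1L        # A: FP 1
  rep <- metric_report(pred, truth, sch)
  # hand-computed: A TP5 FP1 FN1 -> IoU 5/7; B perfect -> 1; C unevaluable
  expect_equal(rep$IoU[rep$class == "A"], 5 / 7)
  expect_equal(rep$IoU[rep$class == "B"], 1)
  expect_false(rep$evaluable[rep$class == "C"])
  expect_equal(rep$IoU[rep$class == "mean"], (5 / 7 + 1) / 2)
  expect_equal(rep$Dice[rep$class == "mean"], (10 / 12 + 1) / 2)
  expect_equal(rep$ASD[rep$class == "B"], 0)
})

test_that("pooled counts equal the sum of per-image counts", {
  sch <- label_schema(c("A", "B"))
  set.seed(34)
  preds <- lapply(1:4, function(i) matrix(sample(0:2, 25, TRUE), 5, 5))
  truths <- lapply(1:4, function(i) matrix(sample(0:2, 25, TRUE), 5, 5))
  pooled <- pool_confusion(mapply(confusion_counts, preds, truths,
                                  MoreArgs = list(schema = sch),
                                  SIMPLIFY = FALSE))
  big_pred <- do.call(rbind, preds)
  big_truth <- do.call(rbind, truths)
  direct <- confusion_counts(big_pred, big_truth, sch)
  expect_equal(pooled$tp, direct$tp)
  expect_equal(pooled$fp, direct$fp)
  expect_equal(pooled$fn, direct$fn)
  expect_equal(pooled$n_pixels, direct$n_pixels)
})
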