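make_annotation <- function(size = 512, ma = NULL, hm = NULL, ex = NULL) {
  z <- matrix(0, size, size)
  set_px <- function(m, px) {
    if (!is.null(px)) m[px] <- 1
    m
  }
  lesion_annotation(microaneurysm = set_px(z, ma), haemorrhage = set_px(z, hm),
                    exudate = set_px(z, ex))
}

test_that("lesion_annotation builds the union mask", {
  ann <- make_annotation(64, ma = cbind(3, 4), ex = cbind(10, 12))
  expect_equal(sum(ann$any_lesion), 2)
  expect_equal(ann$any_lesion[3, 4], 1)
  expect_equal(ann$any_lesion[10, 12], 1)
  expect_equal(sum(ann$haemorrhage), 0)
})

test_that("patch_lesion_labels flags windows containing a single pixel", {
  ann <- make_annotation(512, hm = cbind(100, 100))
  pos <- grid_positions(512, 64, 0.875)   # stride 8
  y <- patch_lesion_labels(pos, 64, ann, "haemorrhage")
  # oracle: windows whose span contains (100, 100) on both axes
  contains <- function(o) o <= 100 & o + 63 >= 100
  expect_equal(sum(y), sum(contains(pos$row) & contains(pos$col)))
  expect_equal(which(y == 1),
               which(contains(pos$row) & contains(pos$col)))

  expect_true(all(patch_lesion_labels(pos, 64, make_annotation(512),
                                      "any_lesion") == 0))
  full <- lesion_annotation(exudate = matrix(1, 512, 512))
  expect_true(all(patch_lesion_labels(pos, 64, full, "exudate") == 1))
})

test_that("patch_level_eval follows the attention weights", {
  ann <- make_annotation(512, hm = cbind(100, 100))
  pos <- grid_positions(512, 64, 0.75)
  y <- patch_lesion_labels(pos, 64, ann, "any_lesion")

  # constant attention is uninformative
  rec <- tibble::tibble(row = pos$row, col = pos$col,
                        alpha = rep(1 / nrow(pos), nrow(pos)))
  attr(rec, "d") <- 64
  out <- patch_level_eval(rec, ann, "any_lesion")
  expect_equal(out$auc, 0.5)
  expect_equal(out$auprc, mean(y))
  expect_equal(out$n_pos + out$n_neg, nrow(pos))

  # attention proportional to the label is perfect
  set.seed(21)
  rec2 <- rec
  rec2$alpha <- y + runif(nrow(pos), 0, 1e-6)
  rec2$alpha <- rec2$alpha / sum(rec2$alpha)
  attr(rec2, "d") <- 64
  out2 <- patch_level_eval(rec2, ann, "any_lesion")
  expect_equal(out2$auc, 1)

  # AUC is invariant to strictly monotone transforms of alpha
  rec3 <- rec2
  rec3$alpha <- exp(3 * rec2$alpha)
  attr(rec3, "d") <- 64
  expect_equal(patch_level_eval(rec3, ann, "any_lesion")$auc, out2$auc)
})

test_that("pixel_level_eval scores pixels by covering-window attention", {
  # two disjoint windows; the whole high-attention window is lesion, so
  # every positive pixel outscores every negative pixel
  rec <- tibble::tibble(row = c(1, 101), col = c(1, 101),
                        alpha = c(0.9, 0.1))
  attr(rec, "d") <- 50
  full1 <- matrix(0, 200, 200); full1[1:50, 1:50] <- 1
  ann <- lesion_annotation(exudate = full1)
  out <- pixel_level_eval(rec, ann, "exudate", size = 200)
  expect_equal(out$auc, 1)
  expect_equal(out$n_pos, 50^2)
  expect_equal(out$n_neg, 50^2)

  # lesion completely outside every window: no prediction exists
  ann2 <- make_annotation(200, ex = cbind(190, 190))
  expect_error(pixel_level_eval(rec, ann2, "exudate", size = 200),
               class = "retinamil_no_positives")
})

test_that("pixel_level_eval matches a naive per-pixel accumulation oracle", {
  set.seed(22)
  pos <- grid_positions(96, 32, 0.5)
  a <- runif(nrow(pos)); a <- a / sum(a)
  rec <- tibble::tibble(row = pos$row, col = pos$col, alpha = a)
  attr(rec, "d") <- 32
  mask <- matrix(rbinom(96 * 96, 1, 0.02), 96, 96)
  ann <- lesion_annotation(haemorrhage = mask)

  # oracle score map: mean alpha over covering windows, two plain loops
  acc <- matrix(0, 96, 96); cov <- matrix(0, 96, 96)
  for (k in seq_len(nrow(pos))) {
    rr <- pos$row[k]:(pos$row[k] + 31); cc <- pos$col[k]:(pos$col[k] + 31)
    acc[rr, cc] <- acc[rr, cc] + a[k]
    cov[rr, cc] <- cov[rr, cc] + 1
  }
  sc <- acc / pmax(cov, 1)
  covd <- cov > 0
  out <- pixel_level_eval(rec, ann, "haemorrhage", size = 96)
  expect_equal(out$auc, roc_auc(sc[covd], mask[covd] > 0), tolerance = 1e-12)
  expect_equal(out$auprc, auprc(sc[covd], mask[covd] > 0), tolerance = 1e-12)

  # the max rule is also available
  outm <- pixel_level_eval(rec, ann, "haemorrhage", size = 96, rule = "max")
  expect_true(is.finite(outm$auc))
})

test_that("area_fraction_regression recovers exact linear relations", {
  # five windows with hand-built lesion fractions
  size <- 64; d <- 16
  pos <- tibble::tibble(row = c(1, 1, 17, 33, 49), col = c(1, 17, 33, 1, 49))
  mask <- matrix(0, size, size)
  fracs <- c(0, 0.25, 0.5, 0.125, 1)
  for (k in seq_along(fracs)) {
    npix <- fracs[k] * d^2
    if (npix == 0) next
    rr <- pos$row[k]; cc <- pos$col[k]
    cells <- arrayInd(seq_len(npix), c(d, d))
    mask[cbind(rr + cells[, 1] - 1, cc + cells[, 2] - 1)] <- 1
  }
  ann <- lesion_annotation(exudate = mask)
  alpha <- 0.1 + 0.6 * fracs
  rec <- tibble::tibble(row = pos$row, col = pos$col, alpha = alpha)
  attr(rec, "d") <- d
  fit <- area_fraction_regression(rec, ann, "exudate")
  expect_equal(fit$slope, 0.6, tolerance = 1e-9)
  expect_equal(fit$intercept, 0.1, tolerance = 1e-9)
  expect_equal(fit$r, 1, tolerance = 1e-9)

  # closed-form normal equations on a noisy case
  set.seed(23)
  alpha2 <- 0.1 + 0.6 * fracs + rnorm(5, 0, 0.05)
  rec2 <- rec; rec2$alpha <- alpha2
  attr(rec2, "d") <- d
  fit2 <- area_fraction_regression(rec2, ann, "exudate")
  xb <- mean(fracs); yb <- mean(alpha2)
  slope_cf <- sum((fracs - xb) * (alpha2 - yb)) / sum((fracs - xb)^2)
  expect_equal(fit2$slope, slope_cf, tolerance = 1e-9)
  expect_equal(fit2$intercept, yb - slope_cf * xb, tolerance = 1e-9)

  # constant fractions cannot be fit
  rec3 <- rec
  attr(rec3, "d") <- d
  expect_error(area_fraction_regression(rec3, make_annotation(size),
                                        "exudate"),
               class = "retinamil_degenerate_fit")
})
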