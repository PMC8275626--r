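test_that("attention_weights matches the two-loop oracle and normalises", {
  set.seed(10)
  for (i in 1:20) {
    K <- sample(2:20, 1); M <- 16; L <- 8
    H <- matrix(rnorm(K * M), K, M)
    V <- matrix(rnorm(L * M), L, M)
    w <- rnorm(L)
    a <- attention_weights(H, V, w)
    expect_equal(sum(a), 1, tolerance = 1e-12)
    expect_true(all(a >= 0))
    expect_equal(a, attention_oracle(H, V, w), tolerance = 1e-8)
  }
})

test_that("identical features give exactly uniform attention", {
  H <- matrix(rep(rnorm(16), each = 7), 7, 16)
  a <- attention_weights(H, matrix(rnorm(8 * 16), 8, 16), rnorm(8))
  expect_equal(a, rep(1 / 7, 7))
})

test_that("attention matches the closed-form two-instance case", {
  # h = (0, 10), V = [[1]], w = [1]: logits (tanh 0, tanh 10) ~ (0, 1)
  a <- attention_weights(matrix(c(0, 10), 2, 1), matrix(1, 1, 1), 1)
  expect_equal(a, c(exp(0), exp(tanh(10))) / (exp(0) + exp(tanh(10))),
               tolerance = 1e-12)
  expect_equal(a, c(0.2689, 0.7311), tolerance = 1e-3)
})

test_that("attention is invariant to a constant logit shift", {
  set.seed(2)
  H <- matrix(rnorm(5 * 4), 5, 4)
  V <- matrix(rnorm(3 * 4), 3, 4)
  w <- rnorm(3)
  e <- tanh(H %*% t(V))
  logits <- drop(e %*% w)
  ref <- exp(logits) / sum(exp(logits))
  shifted <- exp(logits + 7) / sum(exp(logits + 7))
  expect_equal(attention_weights(H, V, w), shifted, tolerance = 1e-12)
  expect_equal(ref, shifted, tolerance = 1e-12)
})

test_that("pool is the attention-weighted feature sum", {
  set.seed(3)
  H <- matrix(rnorm(6 * 5), 6, 5)
  a <- rep(0, 6); a[3] <- 1
  expect_equal(pool(H, a), H[3, ])
  expect_equal(pool(H, rep(1 / 6, 6)), colMeans(H))
  aw <- runif(6); aw <- aw / sum(aw)
  manual <- rep(0, 5)
  for (k in 1:6) manual <- manual + aw[k] * H[k, ]
  expect_equal(pool(H, aw), manual, tolerance = 1e-8)
  expect_error(pool(H, aw[1:3]), class = "retinamil_shape_mismatch")
})

test_that("bce_loss has the textbook closed forms", {
  expect_lt(bce_loss(1 - 1e-7, 1), 1e-6)
  expect_equal(bce_loss(0.5, 0), log(2))
  expect_equal(bce_loss(0.5, 1), log(2))
  expect_equal(bce_loss(0.9, 0), -log(0.1))
  expect_gte(bce_loss(0.99, 0), 0)
})

test_that("encode_patches is per-instance and equivariant", {
  cfg <- tiny_config()
  m <- mil_model(cfg)
  bag <- random_bag(5, cfg$d, seed = 4)
  bag$patches[, , , 3] <- bag$patches[, , , 1]   # duplicate instance
  H <- encode_patches(bag, m)
  expect_equal(dim(H), c(5, cfg$M))
  expect_true(all(is.finite(H)))
  expect_equal(H[1, ], H[3, ])

  perm <- c(4, 1, 5, 2, 3)
  bagp <- bag
  bagp$patches <- bag$patches[, , , perm, drop = FALSE]
  expect_equal(encode_patches(bagp, m), H[perm, ], tolerance = 1e-12)

  # chunking must not change results
  expect_equal(encode_patches(bag, m, chunk = 2), H, tolerance = 1e-12)
})

test_that("predict_bag is permutation invariant and handles K = 1", {
  cfg <- tiny_config()
  m <- mil_model(cfg)
  bag <- random_bag(8, cfg$d, seed = 5)
  p0 <- predict_bag(bag, m)
  for (i in 1:5) {
    perm <- sample(8)
    bagp <- bag
    bagp$patches <- bag$patches[, , , perm, drop = FALSE]
    bagp$origins <- bag$origins[perm, ]
    pp <- predict_bag(bagp, m)
    expect_lt(abs(pp$probability - p0$probability), 1e-6)
    expect_equal(pp$attention$alpha, p0$attention$alpha[perm],
                 tolerance = 1e-9)
  }
  one <- random_bag(1, cfg$d, seed = 6)
  p1 <- predict_bag(one, m)
  expect_equal(p1$attention$alpha, 1)
  expect_equal(sum(p0$attention$alpha), 1, tolerance = 1e-6)
})

test_that("analytic gradients agree with finite differences", {
  set.seed(7)
  cfg <- tiny_config(M = 8, L = 4, d = 32, K = 3)
  m <- mil_model(cfg)
  patches <- array(runif(32 * 32 * 3 * 3), c(32, 32, 3, 3))
  lg <- retinamil:::loss_and_grads(patches, 1, m$params)
  loss_at <- function(p) retinamil:::loss_and_grads(patches, 1, p)$loss
  h <- 1e-5
  for (nm in names(m$params)) {
    for (rep in 1:2) {
      i <- sample(length(m$params[[nm]]), 1)
      p1 <- m$params; p1[[nm]][i] <- p1[[nm]][i] + h
      p2 <- m$params; p2[[nm]][i] <- p2[[nm]][i] - h
      num <- (loss_at(p1) - loss_at(p2)) / (2 * h)
      expect_lt(abs(lg$grads[[nm]][i] - num), 1e-4 * max(1, abs(num)))
    }
  }
})

test_that("augment with zero ranges is the identity", {
  set.seed(8)
  img <- toy_disk_image(128, c(64, 64), 50)
  mask <- toy_disk_mask(128, c(64, 64), 50)
  cfg <- augment_config(shift = 0, scale = c(1, 1), rotate = 0, flip = FALSE,
                        brightness = 0, contrast = 0, hue = 0, saturation = 0)
  out <- augment(img, mask, cfg)
  expect_equal(out$image, img, tolerance = 1e-12)
  expect_equal(out$mask, mask)
})

test_that("augment flips image and mask in lockstep", {
  set.seed(9)
  img <- array(runif(64 * 64 * 3), c(64, 64, 3))
  mask <- matrix(rbinom(64 * 64, 1, 0.5), 64, 64)
  img <- img * as.vector(mask)
  cfg <- augment_config(shift = 0, scale = c(1, 1), rotate = 0, flip = TRUE,
                        brightness = 0, contrast = 0, hue = 0, saturation = 0)
  # draw until the flip branch triggers; flipped output mirrors columns
  repeat {
    st <- .Random.seed
    out <- augment(img, mask, cfg)
    if (!isTRUE(all.equal(out$mask, mask))) break
  }
  expect_equal(out$mask, mask[, 64:1])
  expect_equal(out$image, img[, 64:1, ], tolerance = 1e-12)
})

test_that("rotation by theta then -theta approximately restores the image", {
  img <- toy_disk_image(128, c(64, 64), 40)
  mask <- toy_disk_mask(128, c(64, 64), 40)
  rot <- function(im, mk, ang) {
    A <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2, 2)
    ctr <- c(64.5, 64.5)
    retinamil:::warp_affine_cpp(im, mk, A, as.numeric(ctr - A %*% ctr))
  }
  f <- rot(img, mask, 0.4)
  b <- rot(f$image, f$mask, -0.4)
  inner <- toy_disk_mask(128, c(64, 64), 30) == 1
  expect_lt(mean(abs(b$image[, , 1][inner] - img[, , 1][inner])), 0.02)
})

test_that("training is seeded-deterministic and lr = 0 leaves params fixed", {
  set.seed(123)
  samples <- generate_samples(8, 0.5, seed = 77,
                              synth_config(size = 256, clip_prob = 0))
  prep <- lapply(samples$sample, function(s) {
    preprocess(s$image, preprocess_config(out_size = 256))
  })
  tbl <- tibble::tibble(pp = prep, label = samples$label)
  cfg <- mil_config(M = 8, L = 4, d = 64, K = 6, epochs = 2, seed = 5,
                    val_overlap = 0, lr = 3e-4)
  m1 <- suppressWarnings(train(tbl[1:5, ], tbl[6:8, ], cfg, verbose = FALSE))
  m2 <- suppressWarnings(train(tbl[1:5, ], tbl[6:8, ], cfg, verbose = FALSE))
  expect_equal(m1$log$loss, m2$log$loss, tolerance = 1e-12)
  expect_equal(m1$params, m2$params, tolerance = 1e-12)
  expect_equal(nrow(m1$log), 2)
  expect_true(all(is.finite(m1$log$val_auc)))

  cfg0 <- cfg; cfg0$lr <- 0
  m0 <- suppressWarnings(train(tbl[1:5, ], tbl[6:8, ], cfg0, verbose = FALSE))
  init <- mil_model(cfg0)
  expect_equal(m0$params, init$params, tolerance = 1e-12)

  expect_s3_class(tidy(m1), "tbl_df")
  g <- glance(m1)
  expect_equal(g$epochs, 2)
})

test_that("ensemble_predict averages member probabilities", {
  cfg <- tiny_config()
  models <- lapply(1:3, function(s) {
    c2 <- cfg; c2$seed <- s
    mil_model(c2)
  })
  img <- toy_disk_image(256, c(128, 128), 110)
  mask <- toy_disk_mask(256, c(128, 128), 110)
  pp <- structure(list(image = img * as.vector(mask), mask = mask),
                  class = "fundus_pp")
  e <- ensemble_predict(models, pp, overlap = 0.5)
  singles <- vapply(models, function(m) {
    retinamil:::predict_grid(pp$image, pp$mask, m, 0.5)$probability
  }, numeric(1))
  expect_equal(e, mean(singles), tolerance = 1e-12)
  expect_equal(ensemble_predict(models[c(1, 1, 1)], pp, overlap = 0.5),
               singles[1], tolerance = 1e-12)
})
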