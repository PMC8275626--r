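test_that("detect_disk recovers a planted full circle to within 2 px", {
  img <- toy_disk_image(512, c(256, 256), 200)
  g <- detect_disk(img)
  expect_lt(abs(g$center_row - 256), 2)
  expect_lt(abs(g$center_col - 256), 2)
  expect_lt(abs(g$radius - 200), 2)
})

test_that("detect_disk fails cleanly on an edgeless image", {
  expect_error(detect_disk(array(0, c(256, 256, 3))),
               class = "retinamil_disk_not_found")
  expect_error(detect_disk(array(0.5, c(256, 256, 3))),
               class = "retinamil_disk_not_found")
})

test_that("detect_disk handles a vertically clipped disk", {
  # 20% of the disk height above the frame
  r <- 200
  img <- toy_disk_image(512, c(1 + r * (1 - 2 * 0.2), 256), r)
  g <- detect_disk(img)
  expect_lt(abs(g$radius - r) / r, 0.05)
})

test_that("pad_partial_disk pads exactly the deficit and translates geometry", {
  img <- toy_disk_image(512, c(256, 256), 200)
  g <- disk_geometry(256, 256, 200)
  out <- pad_partial_disk(img, g)
  expect_identical(dim(out$image), dim(img))
  expect_equal(out$geometry$center_row, 256)

  # clipped at the top by 30 rows: center_row - radius = 1 - 30
  gc <- disk_geometry(171, 256, 200)
  imgc <- toy_disk_image(512, c(171, 256), 200)
  outc <- pad_partial_disk(imgc, gc)
  expect_equal(dim(outc$image)[1], 512 + 30)
  expect_equal(outc$geometry$center_row - outc$geometry$radius, 1)
  expect_true(all(outc$image[1:30, , ] == 0))

  # clipped top and bottom: both pads applied and the disk square fits
  gb <- disk_geometry(256, 256, 300)
  imgb <- toy_disk_image(512, c(256, 256), 300)
  outb <- pad_partial_disk(imgb, gb)
  expect_gt(outb$pad_top, 0)
  expect_gt(outb$pad_bottom, 0)
  expect_equal(dim(outb$image)[1], 512 + outb$pad_top + outb$pad_bottom)
  expect_gte(outb$geometry$center_row - outb$geometry$radius, 1)
  expect_lte(outb$geometry$center_row + outb$geometry$radius,
             dim(outb$image)[1])
})

test_that("crop_and_resize centres the disk and preserves aspect", {
  img <- toy_disk_image(1024, c(512, 512), 400)
  out <- crop_and_resize(img, disk_geometry(512, 512, 400), out_size = 512)
  expect_identical(dim(out$image), c(512L, 512L, 3L))
  expect_equal(out$geometry$radius, 256)
  # disk fills the frame: bright pixels reach near the borders on the
  # centre row/column, and the fitted disk is circular (no distortion)
  mid <- out$image[256, , 1] > 0.1
  expect_lt(min(which(mid)), 6)
  expect_gt(max(which(mid)), 507)

  # rectangular input: circle must remain circular
  rimg <- toy_disk_image(1440, c(480, 720), 300)[1:960, , , drop = FALSE]
  outr <- crop_and_resize(rimg, disk_geometry(480, 720, 300), out_size = 512)
  m <- outr$image[, , 1] > 0.1
  rows <- range(which(rowSums(m) > 0)); cols <- range(which(colSums(m) > 0))
  h <- diff(rows); w <- diff(cols)
  expect_lt(abs(h - w) / max(h, w), 0.05)
})

test_that("crop_and_resize rejects geometries far outside the frame", {
  img <- toy_disk_image(256, c(128, 128), 100)
  expect_error(crop_and_resize(img, disk_geometry(128, 20, 120)),
               class = "retinamil_crop_out_of_bounds")
})

test_that("subtract_local_average is a biased high-pass", {
  const <- array(0.37, c(64, 64, 3))
  out <- subtract_local_average(const, sigma = 5, amount = 4, bias = 0.5)
  expect_equal(max(abs(out - 0.5)), 0, tolerance = 1e-6)

  # a dark delta on a constant background is amplified about 'a' times
  # (delta small enough that the amplified value stays inside [0, 1])
  img <- array(0.6, c(128, 128, 3))
  img[64, 64, ] <- 0.55
  out <- subtract_local_average(img, sigma = 10, amount = 3, bias = 0.5)
  # blur of a single-pixel delta is negligible at the centre
  expect_equal(out[64, 64, 1] - 0.5, 3 * (0.55 - 0.6), tolerance = 0.01)

  # sigma -> 0 limit: image minus itself
  out0 <- subtract_local_average(img, sigma = 0, amount = 4, bias = 0.5)
  expect_true(all(out0 == 0.5))
})

test_that("apply_boundary_mask zeroes outside the shrunken disk", {
  img <- toy_disk_image(512, c(256, 256), 256, value = c(1, 1, 1))
  g <- disk_geometry(256, 256, 256)
  full <- apply_boundary_mask(img, g, shrink = 1)
  expect_equal(sum(full$mask), sum(toy_disk_mask(512, c(256, 256), 256)))

  out <- apply_boundary_mask(img, g, shrink = 0.95)
  expect_lt(abs(sum(out$mask) - pi * (0.95 * 256)^2) / (pi * (0.95 * 256)^2),
            0.01)
  # a pixel at 0.96 r is outside the shrunken mask
  p <- round(c(256 + 0.96 * 256, 256))
  expect_equal(out$mask[p[1], p[2]], 0)
  expect_equal(out$image[p[1], p[2], 1], 0)
  # masking is idempotent
  again <- apply_boundary_mask(out$image, g, shrink = 0.95)
  expect_identical(again$image, out$image)
})

test_that("preprocess composes deterministically and satisfies invariants", {
  set.seed(42)
  s <- generate_sample(TRUE)
  pp1 <- preprocess(s$image)
  pp2 <- preprocess(s$image)
  expect_identical(pp1$image, pp2$image)
  expect_identical(dim(pp1$image), c(512L, 512L, 3L))
  expect_identical(dim(pp1$mask), c(512L, 512L))
  expect_true(all(pp1$image[pp1$mask == 0] == 0))
  expect_setequal(unique(as.vector(pp1$mask)), c(0, 1))
})

test_that("preprocess of a clipped disk yields a full shrunken-disk mask", {
  set.seed(43)
  cfg <- synth_config(clip_prob = 1)
  s <- generate_sample(FALSE, cfg)
  pp <- preprocess(s$image)
  # mask must be (close to) the full shrunken disk indicator: the padded
  # zero region is outside the shrunken radius after the 2r crop
  expected <- toy_disk_mask(512, c(256.5, 256.5), 0.95 * pp$geometry$radius)
  expect_lt(mean(abs(pp$mask - expected)), 0.01)
})

test_that("detected radius tracks planted radius across scales", {
  set.seed(99)
  for (case in list(c(512, 110), c(512, 200), c(1024, 320))) {
    size <- case[1]; r <- case[2]
    img <- toy_disk_image(size, c(size / 2, size / 2), r)
    g <- detect_disk(img)
    expect_lt(abs(g$radius - r) / r, 0.05)
  }
})
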