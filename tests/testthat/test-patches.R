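test_that("grid_positions reproduces the printed window counts", {
  expect_equal(nrow(grid_positions(512, 64, 0.5)), 225)
  expect_equal(nrow(grid_positions(512, 64, 0.75)), 841)
  expect_equal(nrow(grid_positions(512, 64, 0.875)), 3249)
  expect_equal(as.data.frame(grid_positions(64, 64, 0.5)),
               data.frame(row = 1, col = 1))
})

test_that("grid_positions is row-major with the rounded stride", {
  g <- grid_positions(200, 50, 0.6)   # stride = 20
  expect_equal(unique(diff(unique(g$row))), 20)
  expect_equal(g$col[1:3], c(1, 21, 41))
  expect_equal(g$row[1:3], c(1, 1, 1))
  expect_true(all(g$row + 50 - 1 <= 200))
})

test_that("grid_positions validates its configuration", {
  expect_error(grid_positions(512, 64, 1), class = "retinamil_invalid_config")
  expect_error(grid_positions(512, 64, -0.1),
               class = "retinamil_invalid_config")
  expect_error(grid_positions(32, 64, 0.5),
               class = "retinamil_invalid_config")
  expect_error(grid_positions(512, 64, 0.999),
               class = "retinamil_invalid_config")
})

test_that("retina_fraction counts window mask content", {
  mask <- matrix(1, 128, 128)
  expect_equal(retina_fraction(mask, c(10, 10), 32), 1)
  expect_equal(retina_fraction(0 * mask, c(10, 10), 32), 0)
  # straight vertical edge through the window centre
  half <- matrix(0, 128, 128); half[, 1:64] <- 1
  d <- 32
  fr <- retina_fraction(half, c(20, 64 - d / 2 + 1), d)
  expect_lt(abs(fr - 0.5), 1 / d)
})

test_that("filter_positions matches a brute-force window count oracle", {
  mask <- toy_disk_mask(512, c(256, 256), 243)
  pos <- grid_positions(512, 64, 0.75)
  kept <- filter_positions(pos, mask, 64, 0.5)
  # oracle: count mask pixels per window directly
  keep_oracle <- vapply(seq_len(nrow(pos)), function(i) {
    r <- pos$row[i]; c <- pos$col[i]
    sum(mask[r:(r + 63), c:(c + 63)]) >= 0.5 * 64^2
  }, logical(1))
  expect_equal(nrow(kept), sum(keep_oracle))
  expect_equal(kept$row, pos$row[keep_oracle])
  expect_equal(kept$col, pos$col[keep_oracle])

  expect_equal(nrow(filter_positions(pos, matrix(1, 512, 512), 64)), nrow(pos))
  expect_error(filter_positions(pos, matrix(0, 512, 512), 64),
               class = "retinamil_empty_bag")
})

test_that("raising the retina threshold never increases survivors", {
  mask <- toy_disk_mask(256, c(128, 128), 100)
  pos <- grid_positions(256, 32, 0.5)
  counts <- vapply(c(0.1, 0.3, 0.5, 0.7, 0.9), function(f) {
    tryCatch(nrow(filter_positions(pos, mask, 32, f)),
             retinamil_empty_bag = function(e) 0L)
  }, integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("sample_random_positions is seeded, valid and uniform", {
  mask <- toy_disk_mask(256, c(128, 128), 100)
  p1 <- sample_random_positions(mask, 32, 20, seed = 11)
  p2 <- sample_random_positions(mask, 32, 20, seed = 11)
  expect_identical(p1, p2)

  # every sampled origin passes the test-time filter (policy agreement)
  fr <- vapply(seq_len(nrow(p1)), function(i) {
    retina_fraction(mask, c(p1$row[i], p1$col[i]), 32)
  }, numeric(1))
  expect_true(all(fr >= 0.5))

  # a mask leaving exactly one valid origin returns it
  one <- matrix(0, 64, 64); one[17:48, 17:48] <- 1
  p <- sample_random_positions(one, 32, 1, min_retina_fraction = 1)
  expect_equal(as.data.frame(p), data.frame(row = 17, col = 17))

  expect_error(sample_random_positions(matrix(0, 64, 64), 32, 5),
               class = "retinamil_empty_bag")

  # uniformity over the valid origin set (chi-square over coarse bins)
  big <- sample_random_positions(mask, 32, 10000, seed = 3)
  # recompute the valid set with the same filter
  S <- retinamil:::sat(mask)
  nr <- 256 - 32 + 1
  W <- S[33:257, 33:257] - S[1:nr, 33:257] - S[33:257, 1:nr] + S[1:nr, 1:nr]
  valid <- which(W / 32^2 >= 0.5, arr.ind = TRUE)
  bin <- function(rc) pmin((rc - 1) %/% 45, 4)
  expected_tab <- table(bin(valid[, 1]) * 5 + bin(valid[, 2]))
  got_tab <- table(factor(bin(big$row) * 5 + bin(big$col),
                          levels = names(expected_tab)))
  test <- suppressWarnings(
    stats::chisq.test(as.vector(got_tab), p = as.vector(expected_tab) /
                        sum(expected_tab))
  )
  expect_gt(test$p.value, 0.01)
})

test_that("extract_bag copies exact windows", {
  ramp <- array(seq(0, 1, length.out = 128 * 128 * 3), c(128, 128, 3))
  bag <- extract_bag(ramp, tibble::tibble(row = 1, col = 1), 32)
  expect_equal(bag$patches[, , , 1], ramp[1:32, 1:32, ])

  # overlapping windows agree on shared pixels
  pos <- tibble::tibble(row = c(1, 17), col = c(1, 1))
  b2 <- extract_bag(ramp, pos, 32)
  expect_equal(b2$patches[17:32, , , 1], b2$patches[1:16, , , 2])

  # a non-overlapping tiling reassembles the image
  pos <- grid_positions(128, 32, 0)
  b3 <- extract_bag(ramp, pos, 32)
  rebuilt <- array(0, dim(ramp))
  for (k in seq_len(nrow(pos))) {
    r <- pos$row[k]; c <- pos$col[k]
    rebuilt[r:(r + 31), c:(c + 31), ] <- b3$patches[, , , k]
  }
  expect_identical(rebuilt, ramp)
})
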