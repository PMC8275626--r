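#' Regular grid of patch origins
#'
#' Origins of `d x d` windows on a regular grid with overlap ratio `t`
#' (adjacent windows share a fraction `t` of their edge). The stride is
#' `round(d * (1 - t))` and windows are placed at `1 + i * stride` for
#' `i = 0 .. floor((size - d) / stride)` on both axes, in row-major order.
#' For a 512 frame with `d = 64` this yields 225 windows at `t = 0.5`,
#' 841 at `t = 0.75` and 3249 at `t = 0.875`.
#'
#' @param size Image edge in pixels.
#' @param d Patch edge in pixels.
#' @param t Overlap ratio in `[0, 1)`.
#' @return A tibble with columns `row`, `col` (1-based window origins).
#' @export
grid_positions <- function(size, d, t) {
  if (!is.numeric(t) || t < 0 || t >= 1) {
    stop_retinamil("invalid_config", "overlap ratio t must be in [0, 1)")
  }
  if (d > size || d < 1) {
    stop_retinamil("invalid_config", "patch size d must be in [1, size]")
  }
  stride <- round(d * (1 - t))
  if (stride < 1) {
    stop_retinamil("invalid_config", "overlap too large: stride < 1 px")
  }
  org <- 1 + stride * (0:floor((size - d) / stride))
  tibble(row = rep(org, each = length(org)), col = rep(org, length(org)))
}

# Summed-area table; S has an extra leading row/column of zeros so that
# the sum over rows r..r+d-1, cols c..c+d-1 is
# S[r+d, c+d] - S[r, c+d] - S[r+d, c] + S[r, c].
sat <- function(mask) {
  sat_cpp(mask * 1)
}

window_sums <- function(S, rows, cols, d) {
  S[cbind(rows + d, cols + d)] - S[cbind(rows, cols + d)] -
    S[cbind(rows + d, cols)] + S[cbind(rows, cols)]
}

#' Retina content of a patch window
#'
#' Fraction of retina-mask pixels inside the `d x d` window with the given
#' origin.
#'
#' @param mask 0/1 retina mask matrix.
#' @param origin Length-2 vector or one-row data frame `(row, col)`.
#' @param d Patch edge in pixels.
#' @return A fraction in `[0, 1]`.
#' @export
retina_fraction <- function(mask, origin, d) {
  if (is.data.frame(origin)) origin <- c(origin$row[1], origin$col[1])
  r <- origin[1]; c <- origin[2]
  stopifnot(r >= 1, c >= 1, r + d - 1 <= nrow(mask), c + d - 1 <= ncol(mask))
  sum(mask[r:(r + d - 1), c:(c + d - 1)] > 0) / d^2
}

retina_fractions <- function(mask, positions, d) {
  S <- sat(mask > 0)
  window_sums(S, positions$row, positions$col, d) / d^2
}

#' Filter patch positions by retina content
#'
#' Keeps the windows whose retina content is at least
#' `min_retina_fraction`, preserving order. Patches lying mostly on the
#' dark background carry no signal and are discarded.
#'
#' @param positions Tibble with `row`, `col` origins.
#' @param mask 0/1 retina mask.
#' @param d Patch edge in pixels.
#' @param min_retina_fraction Minimum retina fraction (default 0.5).
#' @return The surviving positions tibble.
#' @export
filter_positions <- function(positions, mask, d, min_retina_fraction = 0.5) {
  if (nrow(positions) == 0) {
    stop_retinamil("empty_bag", "no candidate positions")
  }
  keep <- retina_fractions(mask, positions, d) >= min_retina_fraction
  if (!any(keep)) {
    stop_retinamil("empty_bag", "no window passes the retina-content filter")
  }
  positions[keep, ]
}

#' Randomly sample valid patch origins (training policy)
#'
#' Draws `K` origins uniformly from the pool of all pixel-resolution
#' window origins whose retina content passes the filter — without
#' replacement while the pool allows, with replacement otherwise.
#'
#' @inheritParams filter_positions
#' @param K Bag size.
#' @param seed Optional seed for reproducible draws; `NULL` uses (and
#'   advances) the session RNG.
#' @return A tibble with `K` rows (`row`, `col`).
#' @export
sample_random_positions <- function(mask, d, K, min_retina_fraction = 0.5,
                                    seed = NULL) {
  h <- nrow(mask); w <- ncol(mask)
  nr <- h - d + 1; nc <- w - d + 1
  if (nr < 1 || nc < 1) stop_retinamil("invalid_config", "d exceeds mask size")
  S <- sat(mask > 0)
  # window sums for every origin, as an nr x nc matrix
  W <- S[(d + 1):(h + 1), (d + 1):(w + 1)] - S[1:nr, (d + 1):(w + 1)] -
    S[(d + 1):(h + 1), 1:nc] + S[1:nr, 1:nc]
  valid <- which(W / d^2 >= min_retina_fraction)
  if (length(valid) == 0) {
    stop_retinamil("empty_bag", "no valid window origin in mask")
  }
  idx <- with_seed(seed, {
    if (length(valid) >= K) valid[sample.int(length(valid), K)]
    else valid[sample.int(length(valid), K, replace = TRUE)]
  })
  tibble(row = (idx - 1) %% nr + 1, col = (idx - 1) %/% nr + 1)
}

#' Extract a bag of patches
#'
#' Copies the `d x d` windows at the given origins out of the image.
#'
#' @param image `H x W x 3` array.
#' @param positions Tibble with `row`, `col` origins.
#' @param d Patch edge in pixels.
#' @return An object of class `patch_bag`: list with `patches`
#'   (`d x d x 3 x K` array), `origins` (the positions tibble) and `d`.
#' @export
extract_bag <- function(image, positions, d) {
  K <- nrow(positions)
  if (K == 0) stop_retinamil("empty_bag", "no positions to extract")
  stopifnot(all(positions$row >= 1), all(positions$col >= 1),
            all(positions$row + d - 1 <= dim(image)[1]),
            all(positions$col + d - 1 <= dim(image)[2]))
  arr <- extract_windows_cpp(image, as.integer(positions$row),
                             as.integer(positions$col), as.integer(d))
  structure(list(patches = arr, origins = as_tibble(positions[, c("row", "col")]),
                 d = d),
            class = "patch_bag")
}

#' @export
print.patch_bag <- function(x, ...) {
  cat(sprintf("<patch_bag> %d patches of %dx%d px\n",
              dim(x$patches)[4], x$d, x$d))
  invisible(x)
}
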