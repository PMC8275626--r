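#' Disk geometry
#'
#' Location and size of the circular retina disk in an image, in 1-based
#' pixel coordinates (`row` = first array index).
#'
#' @param center_row,center_col Disk centre (pixels, may be fractional).
#' @param radius Disk radius in pixels; must be positive.
#' @return An object of class `disk_geometry`.
#' @export
disk_geometry <- function(center_row, center_col, radius) {
  stopifnot(is.numeric(radius), radius > 0)
  structure(
    list(center_row = as.numeric(center_row),
         center_col = as.numeric(center_col),
         radius = as.numeric(radius)),
    class = "disk_geometry"
  )
}

#' @export
print.disk_geometry <- function(x, ...) {
  cat(sprintf("<disk_geometry> center (%.1f, %.1f), radius %.1f px\n",
              x$center_row, x$center_col, x$radius))
  invisible(x)
}

#' Preprocessing configuration
#'
#' Tunable constants of the fundus normalisation pipeline.
#'
#' @param out_size Output frame edge in pixels.
#' @param shrink Retina-mask shrink factor: the outer `1 - shrink` fraction
#'   of the disk is zeroed to suppress boundary artefacts of the local-mean
#'   filter.
#' @param crop_edge_factor Crop square edge as a multiple of the disk
#'   radius. The default 2 crops the `2r x 2r` bounding square so the whole
#'   disk inscribes the output frame.
#' @param graham_amount,graham_bias Gain `a` and offset of the local colour
#'   average subtraction `clip(a * (I - blur(I)) + bias)`.
#' @param graham_sigma Gaussian blur radius of the local average, in output
#'   pixels; `NULL` means `out_size / 30`.
#' @param radius_range Hough search range for the disk radius, as fractions
#'   of `min(H, W)`.
#' @param score_threshold Minimum normalised Hough score (edge inliers per
#'   in-frame circumference pixel) below which detection fails.
#' @return A list of configuration values.
#' @export
preprocess_config <- function(out_size = 512, shrink = 0.95,
                              crop_edge_factor = 2,
                              graham_amount = 4, graham_bias = 0.5,
                              graham_sigma = NULL,
                              radius_range = c(0.2, 0.6),
                              score_threshold = 0.2) {
  if (is.null(graham_sigma)) graham_sigma <- out_size / 30
  list(out_size = out_size, shrink = shrink,
       crop_edge_factor = crop_edge_factor,
       graham_amount = graham_amount, graham_bias = graham_bias,
       graham_sigma = graham_sigma, radius_range = radius_range,
       score_threshold = score_threshold)
}

# Least-squares (Kasa) circle fit through points (r_i, c_i).
circle_fit <- function(r, c) {
  A <- cbind(2 * r, 2 * c, 1)
  b <- r^2 + c^2
  sol <- tryCatch(solve(crossprod(A), crossprod(A, b)),
                  error = function(e) NULL)
  if (is.null(sol)) return(NULL)
  cr <- sol[1]; cc <- sol[2]
  rad2 <- sol[3] + cr^2 + cc^2
  if (rad2 <= 0) return(NULL)
  list(center_row = cr, center_col = cc, radius = sqrt(rad2))
}

#' Locate the circular retina disk
#'
#' Circle detection via a gradient-direction Hough transform on an edge map
#' of the green channel, followed by a least-squares circle refinement on
#' the edge inliers. Detection runs on a copy downsampled so its long side
#' is at most `max_side` pixels; the returned geometry is in the original
#' resolution.
#'
#' @param image `H x W x 3` numeric array in `[0, 1]`.
#' @param config See [preprocess_config()].
#' @param max_side Maximum long side, in pixels, of the detection copy.
#' @return A [disk_geometry()].
#' @export
detect_disk <- function(image, config = preprocess_config(), max_side = 512) {
  stopifnot(length(dim(image)) == 3L, dim(image)[3] == 3L)
  h0 <- dim(image)[1]; w0 <- dim(image)[2]
  scale <- min(1, max_side / max(h0, w0))
  g <- image[, , 2]
  if (scale < 1) {
    g <- unclass(EBImage::resize(g, w = round(h0 * scale),
                                 h = round(w0 * scale)))
  }
  h <- nrow(g); w <- ncol(g)
  g <- unclass(EBImage::gblur(g, sigma = 1.5))

  # central-difference gradients
  gr <- matrix(0, h, w); gc <- matrix(0, h, w)
  gr[2:(h - 1), ] <- (g[3:h, ] - g[1:(h - 2), ]) / 2
  gc[, 2:(w - 1)] <- (g[, 3:w] - g[, 1:(w - 2)]) / 2
  mag <- sqrt(gr^2 + gc^2)
  if (max(mag) < 1e-4) {
    stop_retinamil("disk_not_found", "no edges found: image has no gradient")
  }
  thr <- max(quantile(mag, 0.98), 0.01)
  idx <- which(mag >= thr)
  if (length(idx) > 25000) idx <- idx[order(mag[idx], decreasing = TRUE)[1:25000]]
  er <- ((idx - 1) %% h)         # 0-based rows
  ec <- ((idx - 1) %/% h)
  m <- mag[idx]
  ur <- gr[idx] / m; uc <- gc[idx] / m

  radii <- seq(config$radius_range[1] * min(h, w),
               config$radius_range[2] * min(h, w), by = 2)
  peak <- hough_vote_cpp(er, ec, ur, uc, radii, h, w)
  if (!is.finite(peak$score)) {
    stop_retinamil("disk_not_found", "Hough accumulator empty")
  }

  # refine on inlier edges (coordinates back to 1-based)
  cr <- peak$center_row + 1; cc <- peak$center_col + 1; rad <- peak$radius
  for (band in c(max(4, 0.06 * rad), max(2.5, 0.03 * rad))) {
    dd <- sqrt((er + 1 - cr)^2 + (ec + 1 - cc)^2)
    keep <- abs(dd - rad) < band
    if (sum(keep) < 10) break
    fit <- circle_fit(er[keep] + 1, ec[keep] + 1)
    if (is.null(fit)) break
    cr <- fit$center_row; cc <- fit$center_col; rad <- fit$radius
  }

  # score with the refined circle: inliers per in-frame circumference pixel
  dd <- sqrt((er + 1 - cr)^2 + (ec + 1 - cc)^2)
  th <- seq(0, 2 * pi, length.out = 145)[-145]
  pr <- cr + rad * sin(th); pc <- cc + rad * cos(th)
  frac_in <- mean(pr >= 1 & pr <= h & pc >= 1 & pc <= w)
  arc <- max(2 * pi * rad * frac_in, 1)
  score <- sum(abs(dd - rad) < 2.5) / arc
  if (score < config$score_threshold) {
    stop_retinamil("disk_not_found",
                   sprintf("Hough score %.3f below threshold %.3f",
                           score, config$score_threshold))
  }

  if (scale < 1) {
    cr <- (cr - 0.5) / scale + 0.5
    cc <- (cc - 0.5) / scale + 0.5
    rad <- rad / scale
  }
  disk_geometry(cr, cc, rad)
}

#' Zero-pad a vertically clipped disk
#'
#' Fundus cameras often clip the top and bottom of the retina disk. Before
#' cropping, zero rows are prepended/appended so that the full disk square
#' fits in the frame; the geometry is translated accordingly. Images whose
#' disk already fits are returned unchanged.
#'
#' @param image `H x W x 3` array.
#' @param geometry A [disk_geometry()].
#' @return A list with elements `image` and `geometry`.
#' @export
pad_partial_disk <- function(image, geometry) {
  h <- dim(image)[1]
  pad_top <- max(0, ceiling(geometry$radius - geometry$center_row + 1))
  pad_bot <- max(0, ceiling(geometry$center_row + geometry$radius - h))
  if (pad_top == 0 && pad_bot == 0) {
    return(list(image = image, geometry = geometry, pad_top = 0, pad_bottom = 0))
  }
  out <- array(0, c(h + pad_top + pad_bot, dim(image)[2], dim(image)[3]))
  out[(pad_top + 1):(pad_top + h), , ] <- image
  list(image = out,
       geometry = disk_geometry(geometry$center_row + pad_top,
                                geometry$center_col, geometry$radius),
       pad_top = pad_top, pad_bottom = pad_bot)
}

#' Crop the disk square and resize to the output frame
#'
#' Crops the square of edge `crop_edge_factor * radius` centred on the disk
#' and resizes it (bilinear) to `out_size x out_size`, so the disk centre
#' maps to the frame centre. A deficit of up to 2 px per side (detection
#' rounding) is tolerated by zero-padding; anything larger raises an error
#' since it indicates a bad geometry.
#'
#' @inheritParams pad_partial_disk
#' @param out_size Output edge in pixels.
#' @param crop_edge_factor Crop edge as a multiple of the radius.
#' @return A list with the resized `image`, the output-frame `geometry`, and
#'   the crop window `crop = c(r0, c0, side)` in input coordinates.
#' @export
crop_and_resize <- function(image, geometry, out_size = 512,
                            crop_edge_factor = 2) {
  side <- round(crop_edge_factor * geometry$radius)
  r0 <- round(geometry$center_row - side / 2)
  c0 <- round(geometry$center_col - side / 2)
  h <- dim(image)[1]; w <- dim(image)[2]
  deficit <- max(1 - r0, 1 - c0, r0 + side - 1 - h, c0 + side - 1 - w, 0)
  if (deficit > 2) {
    stop_retinamil("crop_out_of_bounds",
                   sprintf("crop square exceeds image bounds by %d px", deficit))
  }
  crop <- array(0, c(side, side, dim(image)[3]))
  rs <- max(1, r0):min(h, r0 + side - 1)
  cs <- max(1, c0):min(w, c0 + side - 1)
  crop[rs - r0 + 1, cs - c0 + 1, ] <- image[rs, cs, , drop = FALSE]
  out <- unclass(EBImage::resize(crop, w = out_size, h = out_size))
  list(image = out,
       geometry = disk_geometry((out_size + 1) / 2, (out_size + 1) / 2,
                                geometry$radius * out_size / side),
       crop = c(r0 = r0, c0 = c0, side = side))
}

#' Subtract the local colour average
#'
#' High-pass illumination normalisation: `clip(a * (I - blur(I)) + bias)`,
#' which removes slowly varying colour/illumination and amplifies local
#' structure (vessels, lesions) by the gain `a`.
#'
#' @param image `H x W x 3` array in `[0, 1]`.
#' @param sigma Gaussian blur radius in pixels.
#' @param amount Gain `a`.
#' @param bias Output offset (mid-gray by default).
#' @return Array of the same shape, clipped to `[0, 1]`.
#' @export
subtract_local_average <- function(image, sigma, amount = 4, bias = 0.5) {
  if (sigma <= 0) {
    return(array(bias, dim(image)))
  }
  blur <- unclass(EBImage::gblur(image, sigma = sigma))
  pmin(pmax(amount * (image - blur) + bias, 0), 1)
}

#' Apply the shrunken retina boundary mask
#'
#' Zeroes all pixels outside `shrink * radius` of the disk centre and
#' returns the binary retina mask of the shrunken disk interior.
#'
#' @inheritParams pad_partial_disk
#' @param shrink Radius shrink factor (default keeps the inner 95%).
#' @return A list with the masked `image` and the 0/1 `mask` matrix.
#' @export
apply_boundary_mask <- function(image, geometry, shrink = 0.95) {
  h <- dim(image)[1]; w <- dim(image)[2]
  d2 <- outer((seq_len(h) - geometry$center_row)^2,
              (seq_len(w) - geometry$center_col)^2, `+`)
  mask <- (d2 <= (shrink * geometry$radius)^2) * 1
  out <- image * as.vector(mask)  # recycles over channels
  list(image = out, mask = mask)
}

#' Preprocess a raw fundus image
#'
#' Full normalisation pipeline: disk detection (Hough), zero-padding of
#' vertically clipped disks, crop of the disk square, resize to the common
#' frame, local colour average subtraction, and boundary masking. The
#' result carries the binary retina mask, the output-frame disk geometry and
#' the raw-to-output frame transform (see [warp_to_frame()]).
#'
#' @param image `H x W x 3` array, or a path readable by [read_fundus()].
#' @param config See [preprocess_config()].
#' @return An object of class `fundus_pp` with elements `image`
#'   (`out_size x out_size x 3`), `mask` (0/1 matrix), `geometry`
#'   ([disk_geometry()] in output coordinates) and `frame` (transform
#'   record).
#' @export
preprocess <- function(image, config = preprocess_config()) {
  if (is.character(image)) image <- read_fundus(image)
  raw_dim <- dim(image)
  geometry <- detect_disk(image, config)
  padded <- pad_partial_disk(image, geometry)
  cropped <- crop_and_resize(padded$image, padded$geometry,
                             out_size = config$out_size,
                             crop_edge_factor = config$crop_edge_factor)
  norm <- subtract_local_average(cropped$image, sigma = config$graham_sigma,
                                 amount = config$graham_amount,
                                 bias = config$graham_bias)
  masked <- apply_boundary_mask(norm, cropped$geometry, shrink = config$shrink)
  structure(
    list(image = masked$image, mask = masked$mask,
         geometry = cropped$geometry,
         frame = list(raw_dim = raw_dim, pad_top = padded$pad_top,
                      pad_bottom = padded$pad_bottom, crop = cropped$crop,
                      out_size = config$out_size),
         config = config),
    class = "fundus_pp"
  )
}

#' @export
print.fundus_pp <- function(x, ...) {
  cat(sprintf("<fundus_pp> %dx%d frame, retina radius %.1f px, %d mask px\n",
              dim(x$image)[1], dim(x$image)[2], x$geometry$radius,
              sum(x$mask)))
  invisible(x)
}

#' Map a raw-frame mask into the preprocessed frame
#'
#' Applies the same pad / crop / resize chain that produced a preprocessed
#' image to a binary mask in raw-image coordinates (e.g. a pixel-level
#' lesion annotation), using nearest-neighbour resampling.
#'
#' @param mask Binary matrix in the raw image frame.
#' @param pp A `fundus_pp` object.
#' @return A 0/1 matrix in the `out_size` frame.
#' @export
warp_to_frame <- function(mask, pp) {
  fr <- pp$frame
  stopifnot(all(dim(mask) == fr$raw_dim[1:2]))
  m <- mask * 1
  if (fr$pad_top > 0 || fr$pad_bottom > 0) {
    m <- rbind(matrix(0, fr$pad_top, ncol(m)), m,
               matrix(0, fr$pad_bottom, ncol(m)))
  }
  side <- fr$crop["side"]; r0 <- fr$crop["r0"]; c0 <- fr$crop["c0"]
  crop <- matrix(0, side, side)
  rs <- max(1, r0):min(nrow(m), r0 + side - 1)
  cs <- max(1, c0):min(ncol(m), c0 + side - 1)
  crop[rs - r0 + 1, cs - c0 + 1] <- m[rs, cs]
  out <- unclass(EBImage::resize(crop, w = fr$out_size, h = fr$out_size,
                                 filter = "none"))
  (out > 0.5) * 1
}
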