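as_attention_record <- function(record) {
  if (inherits(record, "mil_prediction")) {
    return(list(origins = record$attention[, c("row", "col")],
                alpha = record$attention$alpha, d = record$d))
  }
  stopifnot(is.data.frame(record),
            all(c("row", "col", "alpha") %in% names(record)))
  d <- attr(record, "d")
  if (is.null(d)) stop_retinamil("invalid_config",
                                 "attention record needs a 'd' attribute")
  list(origins = record[, c("row", "col")], alpha = record$alpha, d = d)
}

#' Accumulate attention weights into an image-sized accumulator
#'
#' Iterates the patches of an attention record and adds each patch's weight
#' to every pixel its window covers; also counts the number of windows
#' covering each pixel. With a full in-bounds grid and weights summing
#' to 1, the accumulator total equals `d^2` (each weight is spread over
#' `d^2` pixels).
#'
#' @param record A `mil_prediction` or a tibble with `row`, `col`, `alpha`
#'   and a `d` attribute.
#' @param size Output image edge in pixels.
#' @return A list with `accumulator` (numeric matrix) and `coverage`
#'   (integer matrix).
#' @export
accumulate_attention <- function(record, size = 512) {
  rec <- as_attention_record(record)
  stopifnot(all(rec$origins$row >= 1), all(rec$origins$col >= 1),
            all(rec$origins$row + rec$d - 1 <= size),
            all(rec$origins$col + rec$d - 1 <= size))
  res <- accumulate_windows_cpp(matrix(0, size, size),
                                matrix(0L, size, size),
                                as.integer(rec$origins$row),
                                as.integer(rec$origins$col),
                                rec$alpha, as.integer(rec$d))
  list(accumulator = res$acc, coverage = res$cov)
}

#' Min-max normalise an accumulator into a heatmap
#'
#' Linearly maps the accumulator to `[0, 1]`. A constant accumulator is
#' degenerate (no contrast to display) and maps to all zeros.
#'
#' @param accumulator Numeric matrix from [accumulate_attention()].
#' @param coverage Optional coverage matrix, carried along for evaluation.
#' @param overlap_t Overlap ratio used to build the record (metadata).
#' @return An object of class `retinamil_heatmap` with elements `values`,
#'   `coverage`, `overlap_t`.
#' @export
normalize_heatmap <- function(accumulator, coverage = NULL, overlap_t = NA) {
  rng <- range(accumulator)
  values <- if (rng[2] > rng[1]) {
    (accumulator - rng[1]) / (rng[2] - rng[1])
  } else {
    accumulator * 0
  }
  structure(list(values = values, coverage = coverage, overlap_t = overlap_t),
            class = "retinamil_heatmap")
}

#' Build an attention heatmap from a prediction
#'
#' Convenience composition of [accumulate_attention()] and
#' [normalize_heatmap()].
#'
#' @param record A `mil_prediction` (ideally from a high-overlap grid,
#'   e.g. `t = 0.875`, for fine granularity).
#' @param size Image edge in pixels.
#' @param overlap_t Overlap metadata stored on the result.
#' @return A `retinamil_heatmap`.
#' @export
attention_heatmap <- function(record, size = 512, overlap_t = NA) {
  acc <- accumulate_attention(record, size)
  normalize_heatmap(acc$accumulator, acc$coverage, overlap_t)
}

#' @export
print.retinamil_heatmap <- function(x, ...) {
  cat(sprintf("<retinamil_heatmap> %dx%d, %d covered px\n",
              nrow(x$values), ncol(x$values),
              if (is.null(x$coverage)) NA_integer_ else sum(x$coverage > 0)))
  invisible(x)
}

#' Render a colour overlay of a heatmap on an image
#'
#' Alpha-blends a colour-mapped heatmap over the (dimmed) preprocessed
#' image; where the heatmap is zero the output is simply the dimmed input.
#'
#' @param image `S x S x 3` array.
#' @param heatmap A `retinamil_heatmap` (or matrix in `[0, 1]`).
#' @param colormap Palette name passed to [grDevices::hcl.colors()].
#' @param alpha Maximum blend weight of the heatmap colour.
#' @param dim_factor Brightness factor applied to the underlying image.
#' @param file Optional PNG path to write the overlay to.
#' @return The blended `S x S x 3` array, invisibly if `file` is given.
#' @export
render_overlay <- function(image, heatmap, colormap = "Inferno",
                           alpha = 0.6, dim_factor = 0.6, file = NULL) {
  hv <- if (inherits(heatmap, "retinamil_heatmap")) heatmap$values else heatmap
  if (!all(dim(hv) == dim(image)[1:2])) {
    stop_retinamil("shape_mismatch", "heatmap and image sizes differ")
  }
  pal <- grDevices::hcl.colors(256, colormap)
  rgbmat <- grDevices::col2rgb(pal) / 255
  idx <- pmin(pmax(floor(hv * 255) + 1, 1), 256)
  w <- alpha * hv
  out <- array(0, dim(image))
  for (ch in 1:3) {
    colch <- matrix(rgbmat[ch, idx], nrow(hv), ncol(hv))
    out[, , ch] <- (1 - w) * dim_factor * image[, , ch] + w * colch
  }
  out <- pmin(pmax(out, 0), 1)
  if (!is.null(file)) {
    write_image(out, file)
    return(invisible(out))
  }
  out
}

#' Plot a heatmap with ggplot2
#'
#' @param object A `retinamil_heatmap`.
#' @param ... Unused.
#' @return A `ggplot` object.
#' @method autoplot retinamil_heatmap
#' @export
autoplot.retinamil_heatmap <- function(object, ...) {
  df <- tibble(
    row = rep(seq_len(nrow(object$values)), times = ncol(object$values)),
    col = rep(seq_len(ncol(object$values)), each = nrow(object$values)),
    attention = as.vector(object$values)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$attention)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(option = "inferno") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL, fill = "attention") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
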