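lesion_classes <- c("microaneurysm", "haemorrhage", "exudate")

#' Pixel-level lesion annotation
#'
#' Binary per-class lesion masks aligned to one image frame, plus their
#' union (`any_lesion`). Soft and hard exudates are a single `exudate`
#' class.
#'
#' @param microaneurysm,haemorrhage,exudate 0/1 matrices of equal size
#'   (missing classes default to empty masks).
#' @return An object of class `lesion_annotation`: a named list of 0/1
#'   matrices including `any_lesion`.
#' @export
lesion_annotation <- function(microaneurysm = NULL, haemorrhage = NULL,
                              exudate = NULL) {
  masks <- list(microaneurysm = microaneurysm, haemorrhage = haemorrhage,
                exudate = exudate)
  given <- purrr::compact(masks)
  stopifnot(length(given) > 0)
  dm <- dim(given[[1]])
  masks <- lapply(masks, function(m) {
    if (is.null(m)) matrix(0, dm[1], dm[2]) else {
      stopifnot(all(dim(m) == dm)); (m > 0) * 1
    }
  })
  masks$any_lesion <- (masks$microaneurysm + masks$haemorrhage +
                         masks$exudate > 0) * 1
  structure(masks, class = "lesion_annotation")
}

#' @export
print.lesion_annotation <- function(x, ...) {
  px <- vapply(unclass(x), sum, numeric(1))
  cat("<lesion_annotation>",
      paste(sprintf("%s: %d px", names(px), as.integer(px)), collapse = ", "),
      "\n")
  invisible(x)
}

# Warp every class mask of a raw-frame annotation into a preprocessed frame.
warp_annotation <- function(annotation, pp) {
  lesion_annotation(
    microaneurysm = warp_to_frame(annotation$microaneurysm, pp),
    haemorrhage = warp_to_frame(annotation$haemorrhage, pp),
    exudate = warp_to_frame(annotation$exudate, pp)
  )
}

#' Patch-level lesion labels
#'
#' A window is positive for a lesion class when it contains at least one
#' annotated pixel of that class — even a single pixel counts.
#'
#' @param positions Tibble with `row`, `col` window origins.
#' @param d Patch edge in pixels.
#' @param annotation A [lesion_annotation()].
#' @param class_name One of `"microaneurysm"`, `"haemorrhage"`,
#'   `"exudate"`, `"any_lesion"`.
#' @return Integer 0/1 vector aligned to `positions`.
#' @export
patch_lesion_labels <- function(positions, d, annotation,
                                class_name = "any_lesion") {
  mask <- annotation[[match.arg(class_name, c(lesion_classes, "any_lesion"))]]
  S <- sat(mask > 0)
  as.integer(window_sums(S, positions$row, positions$col, d) > 0)
}

#' Patch-level lesion prediction from attention weights
#'
#' Scores each patch by its attention weight and evaluates it as a binary
#' predictor of lesion presence in that patch (ROC AUC and AUPRC). Use a
#' high-overlap grid record (`t = 0.875`) to enrich the patch pool.
#'
#' @param record A `mil_prediction` (or attention tibble with a `d`
#'   attribute).
#' @param annotation A [lesion_annotation()] in the same frame.
#' @param class_name Lesion class to predict.
#' @return One-row tibble: `class`, `auc`, `auprc`, `n_pos`, `n_neg`.
#' @export
patch_level_eval <- function(record, annotation, class_name = "any_lesion") {
  rec <- as_attention_record(record)
  y <- patch_lesion_labels(rec$origins, rec$d, annotation, class_name)
  tibble(class = class_name,
         auc = roc_auc(rec$alpha, y),
         auprc = auprc(rec$alpha, y),
         n_pos = sum(y == 1), n_neg = sum(y == 0))
}

# Per-pixel attention score map: mean (or max) patch weight over the
# windows covering each pixel; pixels covered by no window get NA.
pixel_score_map <- function(record, size, rule = c("mean", "max")) {
  rule <- match.arg(rule)
  rec <- as_attention_record(record)
  if (rule == "mean") {
    acc <- accumulate_attention(record, size)
    score <- acc$accumulator / pmax(acc$coverage, 1)
    score[acc$coverage == 0] <- NA_real_
    return(score)
  }
  score <- matrix(-Inf, size, size)
  for (k in seq_along(rec$alpha)) {
    r <- rec$origins$row[k]; c <- rec$origins$col[k]
    rr <- r:(r + rec$d - 1); cc <- c:(c + rec$d - 1)
    score[rr, cc] <- pmax(score[rr, cc], rec$alpha[k])
  }
  score[!is.finite(score)] <- NA_real_
  score
}

#' Pixel-level lesion prediction from attention weights
#'
#' Extrapolates the patch-level attention weights to the pixel level: every
#' pixel inherits the mean (default) or max attention weight of the windows
#' covering it, and this per-pixel score is evaluated against the
#' pixel-level class mask. Pixels covered by no window carry no prediction
#' and are excluded.
#'
#' @inheritParams patch_level_eval
#' @param size Image edge in pixels.
#' @param rule Per-pixel combination rule over overlapping windows.
#' @return One-row tibble: `class`, `auc`, `auprc`, `n_pos`, `n_neg`.
#' @export
pixel_level_eval <- function(record, annotation, class_name = "any_lesion",
                             size = 512, rule = c("mean", "max")) {
  mask <- annotation[[match.arg(class_name, c(lesion_classes, "any_lesion"))]]
  stopifnot(all(dim(mask) == c(size, size)))
  score <- pixel_score_map(record, size, rule)
  covered <- !is.na(score)
  y <- (mask > 0)[covered]
  if (sum(y) == 0) {
    stop_retinamil("no_positives", "no annotated lesion pixel is covered")
  }
  s <- score[covered]
  tibble(class = class_name, auc = roc_auc(s, y), auprc = auprc(s, y),
         n_pos = sum(y), n_neg = sum(!y))
}

#' Attention versus lesion-area-fraction regression
#'
#' Ordinary least squares of the per-patch attention weight on the fraction
#' of the patch area covered by lesions, with the Pearson correlation. A
#' positive slope means the model attends more to patches with larger
#' lesion load.
#'
#' @inheritParams patch_level_eval
#' @return One-row tibble: `slope`, `intercept`, `r`, `n`.
#' @export
area_fraction_regression <- function(record, annotation,
                                     class_name = "any_lesion") {
  rec <- as_attention_record(record)
  if (length(rec$alpha) < 2) {
    stop_retinamil("invalid_config", "need at least 2 patches")
  }
  mask <- annotation[[match.arg(class_name, c(lesion_classes, "any_lesion"))]]
  S <- sat(mask > 0)
  frac <- window_sums(S, rec$origins$row, rec$origins$col, rec$d) / rec$d^2
  if (stats::var(frac) == 0) {
    stop_retinamil("degenerate_fit", "lesion area fraction has zero variance")
  }
  fit <- lm(alpha ~ frac, data = data.frame(alpha = rec$alpha, frac = frac))
  tibble(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
         r = cor(rec$alpha, frac), n = length(frac))
}
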