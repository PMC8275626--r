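#' Augmentation configuration
#'
#' Ranges of the label-preserving transforms applied to each training image
#' before patch sampling. Geometric transforms (shift, flip, scale,
#' rotation) move image and retina mask in lockstep; photometric jitter
#' (brightness, contrast, hue, saturation) touches the image only. All
#' ranges are symmetric around identity; setting every range to zero (and
#' `flip = FALSE`) disables augmentation.
#'
#' @param shift Maximum translation as a fraction of the frame edge.
#' @param scale Multiplicative scale range, e.g. `c(0.9, 1.1)`.
#' @param rotate Maximum rotation in degrees.
#' @param flip Allow random horizontal flips.
#' @param brightness,contrast,saturation Maximum relative jitter.
#' @param hue Maximum hue rotation as a fraction of a full revolution.
#' @return A list of augmentation ranges.
#' @export
augment_config <- function(shift = 0.1, scale = c(0.9, 1.1), rotate = 180,
                           flip = TRUE, brightness = 0.2, contrast = 0.2,
                           hue = 0.05, saturation = 0.2) {
  as.list(environment())
}

# Rotation of RGB about the gray axis by angle th (radians): a cheap,
# standard hue-shift approximation that stays in linear RGB.
hue_rotation_matrix <- function(th) {
  ct <- cos(th); st <- sin(th)
  m <- 1 / 3
  a <- ct + (1 - ct) * m
  b <- m * (1 - ct) - sqrt(m) * st
  cc <- m * (1 - ct) + sqrt(m) * st
  matrix(c(a, b, cc, cc, a, b, b, cc, a), 3, 3)
}

#' Randomly augment a preprocessed image and its retina mask
#'
#' Draws one random transform from the configured ranges using the session
#' RNG. The geometric part is a single affine warp about the frame centre
#' (bilinear for the image, nearest-neighbour for the mask); pixels outside
#' the warped mask are re-zeroed so the mask/zero invariant of
#' preprocessed images is preserved.
#'
#' @param image `S x S x 3` preprocessed image.
#' @param mask 0/1 retina mask.
#' @param config See [augment_config()].
#' @return A list with transformed `image` and `mask`.
#' @export
augment <- function(image, mask, config = augment_config()) {
  h <- dim(image)[1]; w <- dim(image)[2]
  do_flip <- isTRUE(config$flip) && runif(1) < 0.5
  ang <- runif(1, -config$rotate, config$rotate) * pi / 180
  sc <- runif(1, config$scale[1], config$scale[2])
  dr <- runif(1, -config$shift, config$shift) * h
  dc <- runif(1, -config$shift, config$shift) * w

  if (do_flip) {
    image <- image[, w:1, , drop = FALSE]
    mask <- mask[, w:1, drop = FALSE]
  }

  identity_geom <- abs(ang) < 1e-12 && abs(sc - 1) < 1e-12 &&
    abs(dr) < 1e-12 && abs(dc) < 1e-12
  if (!identity_geom) {
    A <- sc * matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2, 2)
    ctr <- c((h + 1) / 2, (w + 1) / 2)
    off <- ctr + c(dr, dc) - A %*% ctr
    warped <- warp_affine_cpp(image, mask * 1, A, as.numeric(off))
    image <- warped$image
    mask <- (warped$mask > 0.5) * 1
  }

  br <- runif(1, -config$brightness, config$brightness)
  cj <- runif(1, -config$contrast, config$contrast)
  sj <- runif(1, -config$saturation, config$saturation)
  hj <- runif(1, -config$hue, config$hue) * 2 * pi
  image <- photometric_cpp(image, mask, br, cj, sj, hue_rotation_matrix(hj))
  list(image = image, mask = mask)
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0)
}

adam_step <- function(params, grads, state, lr, beta1, beta2, eps) {
  state$t <- state$t + 1
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

# Normalise a training-set entry to a light-weight packed record.
pack_item <- function(pp, label) {
  if (inherits(pp, "fundus_pp_packed")) {
    pp$label <- label
    return(pp)
  }
  stopifnot(inherits(pp, "fundus_pp"))
  structure(list(image = pack_array(pp$image), mask = pack_array(pp$mask),
                 dim = dim(pp$image), label = label),
            class = "fundus_pp_packed")
}

unpack_item <- function(it) {
  img <- unpack_array(it$image)
  msk <- unpack_array(it$mask)
  list(image = img, mask = (msk > 0.5) * 1, label = it$label)
}

#' Train the attention-MIL classifier
#'
#' One Adam step per image per epoch: the image is augmented, `K` random
#' valid patch origins are drawn (the random-bag training policy), and the
#' binary cross-entropy loss of the bag prediction is backpropagated
#' through the classifier, the attention module and the encoder. After
#' every epoch the model is scored on the validation set (grid bags at
#' `val_overlap`) and the parameters with the highest validation ROC AUC
#' are kept as the returned checkpoint.
#'
#' Images are stored internally at 8-bit precision to bound memory on
#' large synthetic sets.
#'
#' @param data Training set: a data frame with a list-column `pp` of
#'   `fundus_pp` objects and a numeric 0/1 column `label`.
#' @param val_data Validation set in the same format.
#' @param config See [mil_config()]; `config$seed` seeds initialisation,
#'   augmentation and patch sampling, making runs reproducible.
#' @param verbose Print one line per epoch.
#' @return A trained `mil_model` whose `params` are the best-validation
#'   checkpoint; the per-epoch training log is in `$log`.
#' @export
train <- function(data, val_data, config = mil_config(), verbose = TRUE) {
  stopifnot(is.data.frame(data), all(c("pp", "label") %in% names(data)))
  model <- mil_model(config)
  items <- purrr::map2(data$pp, data$label, pack_item)
  val_items <- purrr::map2(val_data$pp, val_data$label, pack_item)
  val_labels <- as.numeric(val_data$label)

  params <- model$params
  state <- adam_init(params)
  best <- list(epoch = NA_integer_, val_auc = -Inf, params = params)
  best_va <- -Inf
  val_tol <- if (is.null(config$val_tol)) 0.02 else config$val_tol
  log <- vector("list", config$epochs)

  with_seed(config$seed + 1L, {
    for (ep in seq_len(config$epochs)) {
      ord <- sample(length(items))
      losses <- numeric(length(ord))
      n_skipped <- 0L
      for (i in seq_along(ord)) {
        it <- unpack_item(items[[ord[i]]])
        aug <- augment(it$image, it$mask, config$augment)
        bag_pos <- tryCatch(
          sample_random_positions(aug$mask, config$d, config$K,
                                  config$min_retina_fraction),
          retinamil_empty_bag = function(e) NULL
        )
        if (is.null(bag_pos)) {
          n_skipped <- n_skipped + 1L
          next
        }
        bag <- extract_bag(aug$image, bag_pos, config$d)
        lg <- loss_and_grads(bag$patches, it$label, params)
        losses[i] <- lg$loss
        upd <- adam_step(params, lg$grads, state, config$lr,
                         config$beta1, config$beta2, config$adam_eps)
        params <- upd$params
        state <- upd$state
      }
      if (n_skipped > 0) {
        warning(sprintf("epoch %d: %d image(s) skipped (empty bag)",
                        ep, n_skipped))
      }
      model$params <- params
      val_scores <- vapply(val_items, function(vi) {
        v <- unpack_item(vi)
        predict_grid(v$image, v$mask, model, config$val_overlap)$probability
      }, numeric(1))
      va <- roc_auc(val_scores, val_labels)
      log[[ep]] <- tibble(epoch = ep, loss = mean(losses), val_auc = va)
      if (verbose) {
        message(sprintf("epoch %3d  loss %.4f  val AUC %.4f", ep,
                        mean(losses), va))
      }
      # keep the latest epoch whose validation AUC is within val_tol of the
      # best seen: among statistically indistinguishable epochs, prefer the
      # more trained model
      best_va <- max(best_va, va)
      if (va >= best_va - val_tol) {
        best <- list(epoch = ep, val_auc = va, params = params)
      }
    }
  })

  model$params <- best$params
  model$log <- dplyr::bind_rows(log)
  model$best <- list(epoch = best$epoch, val_auc = best$val_auc)
  model
}

# Grid-policy prediction on an image + mask (internal building block).
predict_grid <- function(image, mask, model, overlap) {
  cfg <- model$config
  pos <- grid_positions(dim(image)[1], cfg$d, overlap)
  pos <- filter_positions(pos, mask, cfg$d, cfg$min_retina_fraction)
  predict_bag(extract_bag(image, pos, cfg$d), model)
}

#' Predict rDR probability for a preprocessed image
#'
#' Test-time policy: exhaustive grid bag at the configured overlap,
#' filtered by retina content.
#'
#' @param object A trained `mil_model`.
#' @param pp A `fundus_pp` object.
#' @param overlap Grid overlap ratio; defaults to the model's
#'   `test_overlap`.
#' @param ... Unused.
#' @return A `mil_prediction`.
#' @export
predict.mil_model <- function(object, pp, overlap = NULL, ...) {
  if (is.null(overlap)) overlap <- object$config$test_overlap
  predict_grid(pp$image, pp$mask, object, overlap)
}

#' Ensemble prediction
#'
#' Mean probability of several trained models (e.g. different seeds) on the
#' same test-time grid bag.
#'
#' @param models List of trained `mil_model` objects sharing `d`.
#' @param pp A `fundus_pp` object.
#' @param overlap Grid overlap ratio; default from the first model.
#' @return A single probability.
#' @export
ensemble_predict <- function(models, pp, overlap = NULL) {
  stopifnot(length(models) >= 1)
  cfg <- models[[1]]$config
  if (is.null(overlap)) overlap <- cfg$test_overlap
  pos <- grid_positions(dim(pp$image)[1], cfg$d, overlap)
  pos <- filter_positions(pos, pp$mask, cfg$d, cfg$min_retina_fraction)
  bag <- extract_bag(pp$image, pos, cfg$d)
  mean(vapply(models, function(m) predict_bag(bag, m)$probability,
              numeric(1)))
}

#' Tidy and summarise trained models
#'
#' `tidy()` returns the per-epoch training log (epoch, mean training loss,
#' validation ROC AUC); `glance()` returns a one-row summary. For a
#' `mil_prediction`, `tidy()` returns the per-patch attention record.
#'
#' @param x A `mil_model` or `mil_prediction`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy mil_model
#' @export
tidy.mil_model <- function(x, ...) x$log

#' @rdname tidy.mil_model
#' @method glance mil_model
#' @export
glance.mil_model <- function(x, ...) {
  tibble(epochs = nrow(x$log), best_epoch = x$best$epoch,
         best_val_auc = x$best$val_auc,
         n_params = sum(vapply(x$params, length, 1L)))
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
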