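#' Model configuration
#'
#' Hyperparameters of the attention-MIL classifier and its training loop.
#'
#' @param M Patch feature dimension.
#' @param L Attention hidden dimension.
#' @param d Patch edge in pixels.
#' @param K Training bag size (random patches per image per step).
#' @param lr Adam base learning rate.
#' @param epochs Training epochs.
#' @param seed RNG seed for initialisation, sampling and augmentation.
#' @param min_retina_fraction Patch retina-content filter threshold.
#' @param test_overlap Grid overlap ratio used for test-time bags.
#' @param val_overlap Grid overlap ratio used for the per-epoch validation
#'   pass during training (coarser than `test_overlap` to keep model
#'   selection cheap).
#' @param val_tol Checkpoint-selection tolerance: the returned checkpoint
#'   is the latest epoch whose validation ROC AUC is within `val_tol` of
#'   the best epoch's. On validation sets of a few hundred images the AUC
#'   estimate has standard error of this order, and among statistically
#'   indistinguishable epochs the later (more trained) model has the more
#'   mature attention.
#' @param beta1,beta2,adam_eps Adam moment decay rates and stabiliser.
#' @param augment Augmentation ranges, see [augment_config()].
#' @param encoder_kind Patch encoder; `"compact_cnn"` is the four-block
#'   convolutional encoder shipped with the package.
#' @return A list of configuration values.
#' @export
mil_config <- function(M = 128, L = 32, d = 64, K = 50, lr = 3e-4,
                       epochs = 60, seed = 1, min_retina_fraction = 0.5,
                       test_overlap = 0.75, val_overlap = 0.5,
                       val_tol = 0.02,
                       beta1 = 0.9, beta2 = 0.999, adam_eps = 1e-8,
                       augment = augment_config(),
                       encoder_kind = "compact_cnn") {
  stopifnot(M > 0, L > 0, K > 0, epochs > 0)
  encoder_kind <- match.arg(encoder_kind, c("compact_cnn"))
  as.list(environment())
}

# Encoder channel plan: 3 -> 8 -> 16 -> 32 -> 64, then 64 -> M linear.
encoder_channels <- c(3L, 8L, 16L, 32L, 64L)

# He-normal initialisation of all model parameters (encoder + attention +
# classifier) as a flat named list of matrices/vectors. Each conv block
# carries a per-channel normalisation scale g (init 1) and shift b (init 0).
init_params <- function(config) {
  ch <- encoder_channels
  p <- list()
  for (l in 1:4) {
    fan_in <- ch[l] * 9
    p[[paste0("W", l)]] <- matrix(rnorm(fan_in * ch[l + 1], 0,
                                        sqrt(2 / fan_in)),
                                  fan_in, ch[l + 1])
    p[[paste0("g", l)]] <- matrix(1, 1, ch[l + 1])
    p[[paste0("b", l)]] <- matrix(0, 1, ch[l + 1])
  }
  p$Wf <- matrix(rnorm(ch[5] * config$M, 0, sqrt(2 / ch[5])), ch[5], config$M)
  p$bf <- matrix(0, 1, config$M)
  p$V <- matrix(rnorm(config$L * config$M, 0, sqrt(1 / config$M)),
                config$L, config$M)
  p$w <- matrix(rnorm(config$L, 0, sqrt(1 / config$L)), config$L, 1)
  p$u <- matrix(rnorm(config$M, 0, sqrt(1 / config$M)), config$M, 1)
  p$b0 <- matrix(0, 1, 1)
  p
}

#' Create an untrained attention-MIL model
#'
#' @param config See [mil_config()]. The `seed` entry determines the
#'   parameter initialisation.
#' @return An object of class `mil_model`.
#' @export
mil_model <- function(config = mil_config()) {
  params <- with_seed(config$seed, init_params(config))
  structure(list(params = params, config = config,
                 log = tibble(epoch = integer(), loss = numeric(),
                              val_auc = numeric()),
                 best = list(epoch = NA_integer_, val_auc = NA_real_)),
            class = "mil_model")
}

#' @export
print.mil_model <- function(x, ...) {
  np <- sum(vapply(x$params, length, 1L))
  cat(sprintf("<mil_model> %s encoder, M=%d L=%d, %d parameters\n",
              x$config$encoder_kind, x$config$M, x$config$L, np))
  if (nrow(x$log) > 0) {
    cat(sprintf("  trained %d epochs; best val AUC %.3f at epoch %d\n",
                max(x$log$epoch), x$best$val_auc, x$best$epoch))
  }
  invisible(x)
}

#' Encode a bag of patches into per-patch features
#'
#' Applies the encoder function phi independently to every patch, giving
#' the `K x M` feature matrix `H`. Large bags are processed in chunks to
#' bound memory.
#'
#' @param bag A `patch_bag` (see [extract_bag()]).
#' @param model A `mil_model`.
#' @param chunk Maximum patches per forward pass.
#' @return A `K x M` numeric matrix.
#' @export
encode_patches <- function(bag, model, chunk = 256) {
  arr <- bag$patches
  K <- dim(arr)[4]
  if (dim(arr)[1] != model$config$d || dim(arr)[2] != model$config$d) {
    stop_retinamil("shape_mismatch",
                   sprintf("patches are %dx%d but model expects %dx%d",
                           dim(arr)[1], dim(arr)[2],
                           model$config$d, model$config$d))
  }
  out <- matrix(0, K, model$config$M)
  for (start in seq(1, K, by = chunk)) {
    end <- min(start + chunk - 1, K)
    sub <- arr[, , , start:end, drop = FALSE]
    out[start:end, ] <- cnn_forward_cpp(sub, model$params)$H
  }
  out
}

#' Additive attention weights over a feature bag
#'
#' Computes `alpha_k = softmax_k( w' tanh(V h_k) )`: a learned convex
#' weighting of the patch features. The tanh bounds the logits, so no
#' overflow path exists; the softmax is computed with the usual max shift.
#'
#' @param H `K x M` feature matrix.
#' @param V `L x M` attention matrix.
#' @param w Length-`L` attention vector.
#' @return A length-`K` vector of non-negative weights summing to 1.
#' @export
attention_weights <- function(H, V, w) {
  e <- tanh(H %*% t(V))          # K x L
  logits <- drop(e %*% as.matrix(w))
  a <- exp(logits - max(logits))
  a / sum(a)
}

#' Attention pooling
#'
#' Pools the feature bag into a single embedding `z = sum_k alpha_k h_k`.
#' Being a weighted sum, the pooling is invariant to any joint permutation
#' of `(H, alpha)` — the sum-decomposition contract that makes the whole
#' classifier a set function over patches.
#'
#' @param H `K x M` feature matrix.
#' @param alpha Length-`K` weight vector.
#' @return A length-`M` embedding vector.
#' @export
pool <- function(H, alpha) {
  if (length(alpha) != nrow(H)) {
    stop_retinamil("shape_mismatch", "length(alpha) must equal nrow(H)")
  }
  drop(crossprod(H, alpha))
}

#' Binary cross-entropy loss
#'
#' `-(y log p + (1 - y) log(1 - p))` with `p` clamped to
#' `[eps, 1 - eps]`.
#'
#' @param p Predicted probability (vectorised).
#' @param y Binary label (0/1).
#' @param eps Clamp value.
#' @return Non-negative loss value(s).
#' @export
bce_loss <- function(p, y, eps = 1e-7) {
  p <- pmin(pmax(p, eps), 1 - eps)
  -(y * log(p) + (1 - y) * log(1 - p))
}

# Attention + classifier head forward pass on a feature matrix.
head_forward <- function(H, params) {
  e <- tanh(H %*% t(params$V))                   # K x L
  logits <- drop(e %*% params$w)
  a <- exp(logits - max(logits)); a <- a / sum(a)
  z <- drop(crossprod(H, a))                     # M
  score <- sum(z * params$u) + params$b0[1]
  list(e = e, alpha = a, z = z, p = plogis(score))
}

# Loss and full-parameter gradients for one (bag, label) pair; a single
# fused C++ call so no activation cache crosses the R boundary.
loss_and_grads <- function(patches, y, params, eps = 1e-7) {
  mil_step_cpp(patches, y, params, eps)
}

#' Predict the rDR probability for one bag
#'
#' Runs the encoder, the additive attention pooling and the single-layer
#' classifier `rho` on a bag of patches. The output probability is a
#' permutation-invariant function of the bag.
#'
#' @param bag A `patch_bag`.
#' @param model A `mil_model`.
#' @return An object of class `mil_prediction`: `probability`, the pooled
#'   embedding `z`, and `attention` — a tibble with `row`, `col`, `alpha`
#'   aligned to the bag's patch origins.
#' @export
predict_bag <- function(bag, model) {
  if (dim(bag$patches)[4] == 0) stop_retinamil("empty_bag", "empty bag")
  H <- encode_patches(bag, model)
  hd <- head_forward(H, model$params)
  structure(
    list(probability = hd$p, z = hd$z,
         attention = tibble(row = bag$origins$row, col = bag$origins$col,
                            alpha = hd$alpha),
         d = bag$d),
    class = "mil_prediction"
  )
}

#' @export
print.mil_prediction <- function(x, ...) {
  cat(sprintf("<mil_prediction> p(rDR) = %.4f over %d patches\n",
              x$probability, nrow(x$attention)))
  invisible(x)
}

#' @rdname tidy.mil_model
#' @method tidy mil_prediction
#' @export
tidy.mil_prediction <- function(x, ...) x$attention
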