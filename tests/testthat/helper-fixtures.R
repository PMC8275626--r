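# Fixtures are built in code; nothing is read from disk.

# A clean bright disk on black background, optionally shifted so that part
# of it is clipped by the frame.
toy_disk_image <- function(size = 512, center = c(size / 2, size / 2),
                           radius = 200, value = c(0.8, 0.5, 0.3)) {
  D <- sqrt(outer((seq_len(size) - center[1])^2,
                  (seq_len(size) - center[2])^2, `+`))
  inside <- D <= radius
  img <- array(0, c(size, size, 3))
  for (ch in 1:3) img[, , ch] <- value[ch] * inside
  img
}

# Circular 0/1 mask.
toy_disk_mask <- function(size, center, radius) {
  D2 <- outer((seq_len(size) - center[1])^2,
              (seq_len(size) - center[2])^2, `+`)
  (D2 <= radius^2) * 1
}

# Small model + random bag helpers for the MIL math tests.
tiny_config <- function(M = 16, L = 8, d = 32, K = 6, seed = 1) {
  mil_config(M = M, L = L, d = d, K = K, seed = seed)
}

random_bag <- function(K, d, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  org <- tibble::tibble(row = sample(1:(256 - d), K, replace = TRUE),
                        col = sample(1:(256 - d), K, replace = TRUE))
  structure(list(patches = array(runif(d * d * 3 * K), c(d, d, 3, K)),
                 origins = org, d = d),
            class = "patch_bag")
}

# Brute-force two-loop softmax attention (independent of the package path).
attention_oracle <- function(H, V, w) {
  K <- nrow(H)
  logits <- numeric(K)
  for (k in 1:K) {
    hk <- H[k, ]
    a <- numeric(length(w))
    for (l in seq_along(w)) a[l] <- tanh(sum(V[l, ] * hk))
    logits[k] <- sum(w * a)
  }
  ex <- exp(logits)
  ex / sum(ex)
}

# O(n^2) pairwise ROC AUC oracle (ties count 1/2).
roc_auc_oracle <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# Step-integration average-precision oracle: walk thresholds at each
# distinct score, accumulate precision * recall increment.
auprc_oracle <- function(scores, labels) {
  npos <- sum(labels == 1)
  thr <- sort(unique(scores), decreasing = TRUE)
  ap <- 0; prev_rec <- 0
  for (th in thr) {
    sel <- scores >= th
    tp <- sum(labels[sel] == 1)
    prec <- tp / sum(sel)
    rec <- tp / npos
    ap <- ap + (rec - prev_rec) * prec
    prev_rec <- rec
  }
  ap
}

# Exhaustive threshold-sweep operating point oracle.
operating_point_oracle <- function(scores, labels, constraint, level = 0.9) {
  thr <- c(sort(unique(scores)), Inf)
  best <- NULL
  for (th in thr) {
    pred <- scores >= th
    sens <- sum(pred & labels == 1) / sum(labels == 1)
    spec <- sum(!pred & labels == 0) / sum(labels == 0)
    ok <- if (constraint == "high_sens") sens > level else spec > level
    if (!ok) next
    free <- if (constraint == "high_sens") spec else sens
    if (is.null(best) || free > best$free + 1e-12) {
      best <- list(threshold = th, sensitivity = sens, specificity = spec,
                   free = free)
    }
  }
  best
}

# The shared desk-scale experiment used by the end-to-end acceptance
# checks: one training run serves both the classification and the
# localization assertions. Memoised across test blocks.
desk_cache <- new.env(parent = emptyenv())
get_desk_experiment <- function() {
  if (is.null(desk_cache$res)) {
    desk_cache$res <- desk_experiment(seed = 20240501, n = 500, n_val = 100,
                                      prevalence = 0.5, epochs = 14,
                                      n_loc_positives = 20, verbose = FALSE)
  }
  desk_cache$res
}
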