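#' Preprocess a synthetic sample
#'
#' Runs the full preprocessing pipeline on a synthetic sample's raw image
#' and warps its lesion annotation into the output frame.
#'
#' @param sample A `synthetic_sample`.
#' @param config See [preprocess_config()].
#' @return A list with `pp` (`fundus_pp`), `annotation`
#'   ([lesion_annotation()] in the preprocessed frame) and `label`.
#' @export
preprocess_sample <- function(sample, config = preprocess_config()) {
  pp <- preprocess(sample$image, config)
  list(pp = pp, annotation = warp_annotation(sample$annotation, pp),
       label = sample$label)
}

#' Desk-scale end-to-end experiment
#'
#' The package's reference experiment on synthetic data: generate a seeded
#' dataset, preprocess it, train the compact attention-MIL model on a
#' subject-disjoint split, and evaluate both the classifier (ROC AUC and
#' operating points on the held-out split, grid bags at `t = 0.75`) and
#' the attention-as-lesion-detector protocol on held-out positives (grid
#' bags at `t = 0.875`: pooled patch-level AUC/AUPRC per lesion class, and
#' the per-image attention-versus-lesion-area regression).
#'
#' @param seed Seed for data generation and training.
#' @param n Total number of synthetic images.
#' @param n_val Held-out images (last subjects of the dataset).
#' @param prevalence Referable prevalence of the generator.
#' @param epochs Training epochs (validation-checkpointed).
#' @param n_loc_positives Held-out positives used for the localization
#'   protocol.
#' @param config Model configuration; see [mil_config()].
#' @param synth Generator configuration; see [synth_config()].
#' @param verbose Print progress.
#' @return A list: `model`, `classification` (one-row tibble),
#'   `patch_level` (per-class pooled tibble), `area_regression` (per-image
#'   tibble), `val_scores` tibble, and counts of discarded images.
#' @export
desk_experiment <- function(seed = 1, n = 500, n_val = 100,
                            prevalence = 0.5, epochs = 14,
                            n_loc_positives = 20,
                            config = NULL, synth = synth_config(),
                            verbose = TRUE) {
  if (is.null(config)) {
    config <- mil_config(epochs = epochs, seed = seed)
  } else {
    config$epochs <- epochs
    config$seed <- seed
  }

  if (verbose) message("generating + preprocessing ", n, " synthetic images")
  # per-sample seeds so generation can stream one image at a time
  draws <- with_seed(seed, list(
    intended = rbinom(n, 1, prevalence),
    seeds = sample.int(.Machine$integer.max - 1L, n)
  ))
  subject_ids <- rep(seq_len(ceiling(n / 2)), each = 2)[seq_len(n)]
  # subject-disjoint split: the last subjects are held out
  val_subj <- rev(unique(subject_ids))[seq_len(ceiling(n_val / 2))]

  n_discarded <- 0L
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    s <- with_seed(draws$seeds[i],
                   generate_sample(draws$intended[i] == 1, synth))
    keep_ann <- subject_ids[i] %in% val_subj
    rows[[i]] <- tryCatch({
      pp <- preprocess(s$image)
      ann <- if (keep_ann) {
        lapply(unclass(warp_annotation(s$annotation, pp)), pack_array)
      }
      list(pp = pack_item(pp, s$label), annotation = ann,
           label = s$label, subject_id = subject_ids[i])
    }, retinamil_disk_not_found = function(e) NULL)
    if (is.null(rows[[i]])) n_discarded <- n_discarded + 1L
    rm(s)
  }
  rows <- purrr::compact(rows)
  labels <- vapply(rows, function(r) r$label, integer(1))
  subjects <- vapply(rows, function(r) r$subject_id, integer(1))
  is_val <- subjects %in% val_subj

  # hand train() the packed items directly to avoid an unpack/re-pack copy
  train_tbl <- tibble(pp = lapply(rows[!is_val], function(r) r$pp),
                      label = labels[!is_val])
  val_rows <- rows[is_val]
  val_tbl <- tibble(pp = lapply(val_rows, function(r) r$pp),
                    label = labels[is_val])

  if (verbose) {
    message(sprintf("training on %d images (%d val, %d discarded)",
                    nrow(train_tbl), nrow(val_tbl), n_discarded))
  }
  model <- train(train_tbl, val_tbl, config, verbose = verbose)

  if (verbose) message("evaluating classification (grid t = ",
                       config$test_overlap, ")")
  val_scores <- tibble(
    score = vapply(val_rows, function(r) {
      it <- unpack_item(r$pp)
      predict_grid(it$image, it$mask, model, config$test_overlap)$probability
    }, numeric(1)),
    label = labels[is_val],
    subject_id = subjects[is_val]
  )
  classification <- classification_report(val_scores)

  if (verbose) message("evaluating attention localization (grid t = 0.875)")
  pos_idx <- which(val_scores$label == 1)[seq_len(min(n_loc_positives,
                                                      sum(val_scores$label)))]
  alpha_all <- list(); labels_by_class <- list()
  area_rows <- list()
  for (j in seq_along(pos_idx)) {
    r <- val_rows[[pos_idx[j]]]
    it <- unpack_item(r$pp)
    pred <- predict_grid(it$image, it$mask, model, 0.875)
    ann <- lesion_annotation(
      microaneurysm = unpack_array(r$annotation$microaneurysm) > 0.5,
      haemorrhage = unpack_array(r$annotation$haemorrhage) > 0.5,
      exudate = unpack_array(r$annotation$exudate) > 0.5
    )
    rec <- as_attention_record(pred)
    alpha_all[[j]] <- rec$alpha
    labels_by_class[[j]] <- lapply(c(lesion_classes, "any_lesion"),
                                   function(cl) patch_lesion_labels(
                                     rec$origins, rec$d, ann, cl))
    area_rows[[j]] <- tryCatch(
      area_fraction_regression(pred, ann, "any_lesion"),
      retinamil_degenerate_fit = function(e) NULL
    )
  }
  alpha_pooled <- unlist(alpha_all)
  patch_level <- purrr::map_dfr(seq_along(c(lesion_classes, "any_lesion")),
    function(ci) {
      cl <- c(lesion_classes, "any_lesion")[ci]
      y <- unlist(lapply(labels_by_class, `[[`, ci))
      if (length(unique(y)) < 2) {
        return(tibble(class = cl, auc = NA_real_, auprc = NA_real_,
                      n_pos = sum(y == 1), n_neg = sum(y == 0)))
      }
      tibble(class = cl, auc = roc_auc(alpha_pooled, y),
             auprc = auprc(alpha_pooled, y),
             n_pos = sum(y == 1), n_neg = sum(y == 0))
    })
  area_regression <- dplyr::bind_rows(purrr::compact(area_rows))

  list(model = model, classification = classification,
       patch_level = patch_level, area_regression = area_regression,
       val_scores = val_scores, n_discarded = n_discarded,
       n_train = nrow(train_tbl), n_val = nrow(val_tbl))
}
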