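#' Synthetic fundus generator configuration
#'
#' Parameters of the seeded generator used in place of real fundus
#' datasets: disk geometry and appearance, vessel count, per-class lesion
#' rates for positive images, and lesion contrast (which controls task
#' difficulty).
#'
#' @param size Raw image edge in pixels (>= 256).
#' @param radius_range Disk radius as a fraction of `size`.
#' @param clip_prob Probability that the disk is vertically clipped by
#'   10-30% of its height, as in fundus cameras with a cropped field.
#' @param n_vessels Number of dark curvilinear vessel strokes.
#' @param ma_mean,hm_mean,ex_mean Poisson means of the microaneurysm,
#'   haemorrhage and exudate counts in positive images.
#' @param distractor_prob Probability that a negative image carries 1-4
#'   microaneurysms (below the positivity threshold), so negatives are not
#'   trivially clean.
#' @param ma_strength,hm_strength,ex_strength Lesion contrast ranges.
#' @return A list of generator parameters.
#' @export
synth_config <- function(size = 512, radius_range = c(0.35, 0.45),
                         clip_prob = 0.15, n_vessels = 8,
                         ma_mean = 8, hm_mean = 2.5, ex_mean = 2.5,
                         distractor_prob = 0.15,
                         ma_strength = c(0.55, 0.75),
                         hm_strength = c(0.5, 0.7),
                         ex_strength = c(0.65, 0.85)) {
  stopifnot(size >= 256)
  as.list(environment())
}

# Smooth low-frequency field in [-1, 1]-ish range, for illumination
# variation: coarse white noise upsampled bilinearly.
low_freq_field <- function(size, cells = 8) {
  coarse <- matrix(rnorm(cells^2), cells, cells)
  unclass(EBImage::resize(coarse, w = size, h = size))
}

#' Generate a synthetic retina disk image
#'
#' Draws a bright orange-red circular disk on a dark background with radial
#' illumination falloff, low-frequency illumination noise, fine pixel
#' noise and dark curvilinear vessel strokes. With probability `clip_prob`
#' the disk is placed so that 10-30% of its height falls outside the
#' frame (vertical clipping). Uses the session RNG.
#'
#' @param config See [synth_config()].
#' @return A list with `image` (`size x size x 3`) and the ground-truth
#'   `geometry` ([disk_geometry()]).
#' @export
generate_disk <- function(config = synth_config()) {
  size <- config$size
  r <- runif(1, config$radius_range[1], config$radius_range[2]) * size
  cc <- size / 2 + runif(1, -0.02, 0.02) * size
  if (runif(1) < config$clip_prob) {
    f <- runif(1, 0.1, 0.3)
    cr <- if (runif(1) < 0.5) 1 + r * (1 - 2 * f) else size - r * (1 - 2 * f)
  } else {
    cr <- size / 2 + runif(1, -0.02, 0.02) * size
  }
  geometry <- disk_geometry(cr, cc, r)

  D <- sqrt(outer((seq_len(size) - cr)^2, (seq_len(size) - cc)^2, `+`))
  inside <- D <= r
  shade <- (1 - 0.35 * pmin(D / r, 1)^2) * inside
  base <- c(0.80, 0.47, 0.26) * runif(3, 0.92, 1.08)
  lf1 <- low_freq_field(size)
  lf2 <- low_freq_field(size)
  wts <- runif(3, -1, 1)
  img <- array(0, c(size, size, 3))
  for (ch in 1:3) {
    chan <- base[ch] * shade * (1 + 0.08 * lf1 + 0.05 * wts[ch] * lf2) +
      rnorm(size^2, 0, 0.012) * inside
    img[, , ch] <- pmin(pmax(chan, 0), 1)
  }

  # vessels: quadratic Bezier strokes from near the centre outwards
  pts <- matrix(0, size, size)
  for (v in seq_len(config$n_vessels)) {
    a0 <- runif(1, 0, 2 * pi); a2 <- a0 + runif(1, -0.9, 0.9)
    p0 <- c(cr, cc) + runif(1, 0, 0.25 * r) * c(sin(a0), cos(a0))
    p2 <- c(cr, cc) + runif(1, 0.55, 0.92) * r * c(sin(a2), cos(a2))
    mid <- (p0 + p2) / 2
    perp <- c(-(p2 - p0)[2], (p2 - p0)[1])
    perp <- perp / max(sqrt(sum(perp^2)), 1e-9)
    p1 <- mid + runif(1, -0.25, 0.25) * r * perp
    tt <- seq(0, 1, length.out = 350)
    bez <- outer((1 - tt)^2, p0) + outer(2 * tt * (1 - tt), p1) +
      outer(tt^2, p2)
    ri <- round(bez[, 1]); ci <- round(bez[, 2])
    ok <- ri >= 1 & ri <= size & ci >= 1 & ci <= size
    pts[cbind(ri[ok], ci[ok])] <- 1
  }
  prof <- pmin(unclass(EBImage::gblur(pts, sigma = 1.3)) * 5, 1) * inside
  img <- img * (1 - 0.35 * as.vector(prof))

  list(image = img, geometry = geometry)
}

# Uniform point inside the disk (margin keeps lesions off the rim and
# inside the frame).
sample_in_disk <- function(geometry, size, margin = 0.8) {
  repeat {
    a <- runif(1, 0, 2 * pi)
    rad <- sqrt(runif(1)) * margin * geometry$radius
    p <- c(geometry$center_row + rad * sin(a),
           geometry$center_col + rad * cos(a))
    if (all(p >= 14 & p <= size - 13)) return(p)
  }
}

stamp_disc <- function(mask, center, radius, size) {
  ir <- max(1, floor(center[1] - radius)):min(size, ceiling(center[1] + radius))
  ic <- max(1, floor(center[2] - radius)):min(size, ceiling(center[2] + radius))
  sub <- outer((ir - center[1])^2, (ic - center[2])^2, `+`) <= radius^2
  mask[ir, ic] <- mask[ir, ic] | sub
  attr(mask, "bb") <- range_union(attr(mask, "bb"),
                                  c(min(ir), max(ir), min(ic), max(ic)))
  mask
}

range_union <- function(a, b) {
  if (is.null(a)) return(b)
  c(min(a[1], b[1]), max(a[2], b[2]), min(a[3], b[3]), max(a[4], b[4]))
}

#' Plant lesions on a synthetic disk image
#'
#' Adds the three DR lesion classes with exact pixel masks: small dark
#' dots (microaneurysms, radius 1-3 px), larger irregular dark blobs
#' (haemorrhages, radius 4-12 px) and bright yellow blobs (exudates,
#' radius 3-10 px). For `positive = TRUE` the per-class counts are Poisson
#' draws (redrawn until they satisfy the positivity rule); negatives get
#' no lesions except, occasionally, a few sub-threshold microaneurysm
#' distractors. The image label follows the moderate-or-worse rule:
#' positive iff at least one haemorrhage or exudate is present, or at
#' least 5 microaneurysms.
#'
#' @param image,geometry Output of [generate_disk()].
#' @param positive Whether to draw a lesion load intended to be referable.
#' @param config See [synth_config()].
#' @return An object of class `synthetic_sample`: `image`, `geometry`,
#'   `annotation` ([lesion_annotation()] in the raw frame), `label` and a
#'   `provenance` record of the drawn counts.
#' @export
plant_lesions <- function(image, geometry, positive,
                          config = synth_config()) {
  size <- dim(image)[1]
  if (positive) {
    # Referable images present in clinically distinct ways; no single
    # lesion class is a sufficient marker of positivity. Draw one of four
    # presentations: haemorrhage-dominant, exudate-dominant, mixed, or
    # microaneurysm-driven (>= 5 MAs with few or no blobs).
    type <- sample(c("hm", "ex", "mixed", "ma"), 1,
                   prob = c(0.35, 0.25, 0.2, 0.2))
    if (type == "hm") {
      n_hm <- 1L + rpois(1, config$hm_mean - 1)
      n_ex <- rpois(1, 0.3)
      n_ma <- rpois(1, config$ma_mean)
    } else if (type == "ex") {
      n_ex <- 1L + rpois(1, config$ex_mean - 1)
      n_hm <- rpois(1, 0.5)
      n_ma <- rpois(1, 0.75 * config$ma_mean)
    } else if (type == "mixed") {
      n_hm <- 1L + rpois(1, config$hm_mean - 1.5)
      n_ex <- 1L + rpois(1, config$ex_mean - 1.5)
      n_ma <- rpois(1, config$ma_mean)
    } else {
      n_ma <- 5L + rpois(1, 6)
      n_hm <- rpois(1, 0.3)
      n_ex <- rpois(1, 0.2)
    }
  } else {
    n_ma <- if (runif(1) < config$distractor_prob) sample(1:4, 1) else 0L
    n_hm <- 0L; n_ex <- 0L
  }

  masks <- list(microaneurysm = matrix(FALSE, size, size),
                haemorrhage = matrix(FALSE, size, size),
                exudate = matrix(FALSE, size, size))
  target <- c(1.0, 0.93, 0.45)   # exudate colour

  for (i in seq_len(n_ma)) {
    p <- sample_in_disk(geometry, size)
    rl <- runif(1, 1.5, 3)
    m <- stamp_disc(matrix(FALSE, size, size), p, rl, size)
    s <- runif(1, config$ma_strength[1], config$ma_strength[2])
    bb <- attr(m, "bb")
    rr <- bb[1]:bb[2]; cseq <- bb[3]:bb[4]
    f <- 1 - s * m[rr, cseq]
    for (ch in 1:3) image[rr, cseq, ch] <- image[rr, cseq, ch] * f
    masks$microaneurysm <- masks$microaneurysm | m
  }
  for (i in seq_len(n_hm)) {
    p <- sample_in_disk(geometry, size)
    rb <- runif(1, 4, 12)
    m <- matrix(FALSE, size, size)
    for (l in seq_len(sample(3:6, 1))) {
      ctr <- p + runif(2, -0.45, 0.45) * rb
      m <- stamp_disc(m, ctr, runif(1, 0.45, 0.85) * rb, size)
    }
    s <- runif(1, config$hm_strength[1], config$hm_strength[2])
    bb <- attr(m, "bb")
    rr <- bb[1]:bb[2]; cseq <- bb[3]:bb[4]
    f <- 1 - s * m[rr, cseq]
    for (ch in 1:3) image[rr, cseq, ch] <- image[rr, cseq, ch] * f
    masks$haemorrhage <- masks$haemorrhage | m
  }
  for (i in seq_len(n_ex)) {
    p <- sample_in_disk(geometry, size)
    rb <- runif(1, 3, 10)
    m <- stamp_disc(matrix(FALSE, size, size), p, rb, size)
    if (runif(1) < 0.5) {
      m <- stamp_disc(m, p + runif(2, -0.5, 0.5) * rb,
                      runif(1, 0.4, 0.8) * rb, size)
    }
    s <- runif(1, config$ex_strength[1], config$ex_strength[2])
    bb <- attr(m, "bb")
    rr <- bb[1]:bb[2]; cseq <- bb[3]:bb[4]
    sub <- m[rr, cseq]
    for (ch in 1:3) {
      win <- image[rr, cseq, ch]
      win[sub] <- win[sub] * (1 - s) + target[ch] * s
      image[rr, cseq, ch] <- win
    }
    masks$exudate <- masks$exudate | m
  }

  # restrict annotations (and lesions) to the disk interior
  D <- sqrt(outer((seq_len(size) - geometry$center_row)^2,
                  (seq_len(size) - geometry$center_col)^2, `+`))
  inside <- D <= geometry$radius
  masks <- lapply(masks, function(m) m & inside)
  image <- image * as.vector(inside)

  label <- as.integer(n_hm + n_ex >= 1 || n_ma >= 5)
  structure(
    list(image = pmin(pmax(image, 0), 1), geometry = geometry,
         annotation = lesion_annotation(microaneurysm = masks$microaneurysm,
                                        haemorrhage = masks$haemorrhage,
                                        exudate = masks$exudate),
         label = label,
         provenance = list(n_ma = n_ma, n_hm = n_hm, n_ex = n_ex,
                           config = config)),
    class = "synthetic_sample"
  )
}

#' @export
print.synthetic_sample <- function(x, ...) {
  cat(sprintf(
    "<synthetic_sample> label %d (MA %d, HM %d, EX %d), radius %.0f px\n",
    x$label, x$provenance$n_ma, x$provenance$n_hm, x$provenance$n_ex,
    x$geometry$radius))
  invisible(x)
}

#' Generate one synthetic fundus sample
#'
#' @inheritParams plant_lesions
#' @param config See [synth_config()].
#' @return A `synthetic_sample`.
#' @export
generate_sample <- function(positive, config = synth_config()) {
  disk <- generate_disk(config)
  plant_lesions(disk$image, disk$geometry, positive, config)
}

#' Generate a seeded synthetic dataset in memory
#'
#' Draws `n` samples with referable prevalence `prevalence`; consecutive
#' image pairs share a synthetic subject id (two eyes per subject) to
#' exercise per-subject evaluation.
#'
#' @param n Number of images.
#' @param prevalence Target fraction of referable (label 1) images.
#' @param seed RNG seed; the same seed reproduces the dataset exactly.
#' @param config See [synth_config()].
#' @return A tibble with list-column `sample` plus `label`, `subject_id`.
#' @export
generate_samples <- function(n, prevalence = 0.5, seed = 1,
                             config = synth_config()) {
  stopifnot(n >= 2, prevalence > 0, prevalence < 1)
  with_seed(seed, {
    intended <- rbinom(n, 1, prevalence)
    samples <- lapply(intended, function(p) generate_sample(p == 1, config))
    tibble(sample = samples,
           label = vapply(samples, function(s) s$label, integer(1)),
           subject_id = rep(seq_len(ceiling(n / 2)), each = 2)[seq_len(n)])
  })
}

#' Generate a synthetic dataset on disk
#'
#' Writes images and per-class lesion masks as PNG plus a `manifest.csv`
#' (`path`, `label`, `subject_id` and mask paths).
#'
#' @inheritParams generate_samples
#' @param out_dir Output directory (created if needed).
#' @return The manifest tibble, invisibly written to
#'   `file.path(out_dir, "manifest.csv")`.
#' @export
generate_dataset <- function(n, prevalence = 0.5, seed = 1, out_dir,
                             config = synth_config()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dat <- generate_samples(n, prevalence, seed, config)
  rows <- purrr::imap(dat$sample, function(s, i) {
    stem <- sprintf("img_%04d", i)
    path <- file.path(out_dir, paste0(stem, ".png"))
    write_image(s$image, path)
    mp <- vapply(lesion_classes, function(cl) {
      p <- file.path(out_dir, sprintf("%s_mask_%s.png", stem, cl))
      write_image(s$annotation[[cl]] * 1, p)
      p
    }, character(1))
    tibble(path = path, label = s$label, subject_id = dat$subject_id[i],
           mask_microaneurysm = mp[1], mask_haemorrhage = mp[2],
           mask_exudate = mp[3])
  })
  manifest <- dplyr::bind_rows(rows)
  write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  manifest
}

#' Load a dataset manifest
#'
#' @param path Path to a `manifest.csv` written by [generate_dataset()]
#'   (or any CSV with at least `path` and `label` columns).
#' @return A tibble.
#' @export
load_manifest <- function(path) {
  as_tibble(read.csv(path, stringsAsFactors = FALSE))
}
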