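# Seeded generators standing in for the unavailable clinical image
# database: two-class textured images (smooth background vs irregular
# dark blobs) and transaction databases with planted class rules.

#' Texture image specification
#'
#' Describes one class of synthetic CT-like slices.  Normal slices are
#' smoothed low-contrast Gaussian noise around a base intensity; abnormal
#' slices add dark, rough, irregularly-edged blobs (random-walk-dilated
#' masks) whose intensity drop and internal roughness scale with
#' `blob_contrast`.  With `blob_contrast = 0` the two classes are
#' statistically indistinguishable.
#'
#' @param label `"normal"` or `"abnormal"`.
#' @param size Image side length in pixels.
#' @param base_intensity Background mean gray level (0-255 scale).
#' @param noise_sd Background noise standard deviation before smoothing.
#' @param blob_count Number of blobs per abnormal image.
#' @param blob_size Random-walk steps per blob (controls blob area).
#' @param blob_contrast Mean intensity drop inside a blob; also scales the
#'   extra in-blob roughness (sd = blob_contrast / 4).
#' @param smoothing Box-blur radius applied to the background (0 = none).
#' @param seed Integer seed; identical spec + seed gives identical images.
#' @return List of class `texture_spec`.
#' @export
texture_spec <- function(label = c("normal", "abnormal"), size = 32L,
                         base_intensity = 120, noise_sd = 12,
                         blob_count = 3L, blob_size = 60L,
                         blob_contrast = 80, smoothing = 1L, seed = 1L) {
  label <- match.arg(label)
  stopifnot(size >= 8L, noise_sd >= 0, blob_count >= 0L, blob_size >= 1L,
            blob_contrast >= 0, smoothing >= 0L)
  structure(list(label = label, size = as.integer(size),
                 base_intensity = base_intensity, noise_sd = noise_sd,
                 blob_count = as.integer(blob_count),
                 blob_size = as.integer(blob_size),
                 blob_contrast = blob_contrast,
                 smoothing = as.integer(smoothing), seed = as.integer(seed)),
            class = "texture_spec")
}

box_blur <- function(m, radius) {
  if (radius <= 0L) return(m)
  k <- 2L * radius + 1L
  nr <- nrow(m); nc <- ncol(m)
  # separable box filter with edge replication
  pad_idx <- function(n) pmin(pmax(seq(1L - radius, n + radius), 1L), n)
  mp <- m[pad_idx(nr), ]
  rows <- sapply(seq_len(nr), function(i) colMeans(mp[i:(i + k - 1L), ,
                                                      drop = FALSE]))
  m2 <- t(rows)
  mp2 <- m2[, pad_idx(nc)]
  cols <- sapply(seq_len(nc), function(j) rowMeans(mp2[, j:(j + k - 1L),
                                                       drop = FALSE]))
  cols
}

blob_mask <- function(size, steps) {
  mask <- matrix(FALSE, size, size)
  r <- sample.int(size, 1L); c <- sample.int(size, 1L)
  for (s in seq_len(steps)) {
    mask[r, c] <- TRUE
    mv <- sample.int(4L, 1L)
    if (mv == 1L) r <- min(size, r + 1L)
    else if (mv == 2L) r <- max(1L, r - 1L)
    else if (mv == 3L) c <- min(size, c + 1L)
    else c <- max(1L, c - 1L)
  }
  # one dilation pass (3x3) thickens the walk into an irregular patch
  idx <- which(mask, arr.ind = TRUE)
  for (dr in -1:1) for (dc in -1:1) {
    rr <- pmin(pmax(idx[, 1] + dr, 1L), size)
    cc <- pmin(pmax(idx[, 2] + dc, 1L), size)
    mask[cbind(rr, cc)] <- TRUE
  }
  mask
}

gen_one_image <- function(spec) {
  base <- matrix(stats::rnorm(spec$size^2, spec$base_intensity,
                              spec$noise_sd),
                 spec$size, spec$size)
  img <- box_blur(base, spec$smoothing)
  if (spec$label == "abnormal" && spec$blob_count > 0L) {
    for (b in seq_len(spec$blob_count)) {
      mask <- blob_mask(spec$size, spec$blob_size)
      nin <- sum(mask)
      img[mask] <- img[mask] - spec$blob_contrast +
        stats::rnorm(nin, 0, spec$blob_contrast / 4)
    }
  }
  img <- round(pmin(pmax(img, 0), 255))
  storage.mode(img) <- "integer"
  img
}

#' Generate a batch of synthetic textured images
#'
#' @param spec A [texture_spec()].
#' @param count Number of images (>= 1).
#' @return List with `images` (list of integer matrices) and `labels`
#'   (character vector, all `spec$label`).
#' @export
gen_texture_images <- function(spec, count) {
  stopifnot(inherits(spec, "texture_spec"), count >= 1L)
  images <- with_seed(spec$seed, lapply(seq_len(count),
                                        function(i) gen_one_image(spec)))
  list(images = images, labels = rep(spec$label, count))
}

#' Planted-rule transaction database specification
#'
#' Each planted rule `antecedent -> class` is realized on its own block of
#' transactions: `round(n * support / confidence)` transactions carry the
#' antecedent items, and each of those carries the rule's class with
#' probability `confidence` (otherwise a uniformly drawn other class).
#' Transactions outside every block get a uniform class.  Independent
#' noise items `N1..Nk` are sprinkled into every transaction with
#' probability `noise_rate`.
#'
#' @param n Number of transactions.
#' @param rules List of lists with elements `antecedent` (character
#'   items), `class` (a `Class=` item), `confidence` in (0, 1],
#'   `support` in (0, 1) with `support * n >= 1`.
#' @param classes All class items (default the union of rule classes).
#' @param n_noise_items Number of independent noise items.
#' @param noise_rate Per-transaction inclusion probability of each noise
#'   item, in `[0, 1)`.
#' @param seed Integer seed.
#' @return List of class `planted_rule_spec`.
#' @export
planted_rule_spec <- function(n, rules, classes = NULL,
                              n_noise_items = 6L, noise_rate = 0.1,
                              seed = 1L) {
  stopifnot(n >= 1L, is.list(rules), length(rules) >= 1L,
            noise_rate >= 0, noise_rate < 1, n_noise_items >= 0L)
  for (r in rules) {
    stopifnot(length(r$antecedent) >= 1L, length(r$class) == 1L,
              r$confidence > 0, r$confidence <= 1,
              r$support > 0, r$support * n >= 1)
  }
  block <- vapply(rules, function(r) round(n * r$support / r$confidence),
                  numeric(1))
  if (sum(block) > n) {
    stop("planted_rule_spec: requested supports/confidences need ",
         sum(block), " transactions but n = ", n)
  }
  if (is.null(classes)) {
    classes <- sort(unique(vapply(rules, `[[`, character(1), "class")),
                    method = "radix")
  }
  if (length(classes) < 2L) {
    stop("planted_rule_spec: need at least two class items")
  }
  structure(list(n = as.integer(n), rules = rules, classes = classes,
                 n_noise_items = as.integer(n_noise_items),
                 noise_rate = noise_rate, seed = as.integer(seed)),
            class = "planted_rule_spec")
}

#' Generate a transaction database with planted class rules
#'
#' @param spec A [planted_rule_spec()].
#' @return A [transaction_db()]; attribute `blocks` gives each rule's
#'   transaction indices.
#' @export
gen_transactions <- function(spec) {
  stopifnot(inherits(spec, "planted_rule_spec"))
  noise_items <- if (spec$n_noise_items > 0L) {
    sprintf("N%d=1", seq_len(spec$n_noise_items))
  } else character(0)
  with_seed(spec$seed, {
    tx <- vector("list", spec$n)
    pos <- 0L
    blocks <- list()
    for (k in seq_along(spec$rules)) {
      r <- spec$rules[[k]]
      m <- round(spec$n * r$support / r$confidence)
      idx <- pos + seq_len(m)
      pos <- pos + m
      blocks[[k]] <- idx
      for (i in idx) {
        cl <- if (stats::runif(1) <= r$confidence) r$class else {
          others <- setdiff(spec$classes, r$class)
          others[sample.int(length(others), 1L)]
        }
        tx[[i]] <- c(r$antecedent, cl)
      }
    }
    if (pos < spec$n) {
      for (i in (pos + 1L):spec$n) {
        tx[[i]] <- spec$classes[sample.int(length(spec$classes), 1L)]
      }
    }
    if (length(noise_items) > 0L && spec$noise_rate > 0) {
      for (i in seq_len(spec$n)) {
        hit <- stats::runif(length(noise_items)) < spec$noise_rate
        if (any(hit)) tx[[i]] <- c(tx[[i]], noise_items[hit])
      }
    }
    db <- transaction_db(tx)
    attr(db, "blocks") <- blocks
    db
  })
}

#' End-to-end labeled dataset from synthetic images
#'
#' Runs the image half of the screening pipeline on generated images:
#' texture features per image, a simulated prediagnosis bit, median-split
#' discretization, and the generator's class label as ground truth.  The
#' prediagnosis PD emulates a radiologist's first read from the image
#' itself: PD = 1 when the image's GLCM contrast exceeds the cohort
#' median, flipped with probability `pd_noise` — so PD carries signal
#' exactly when the image classes differ texturally.
#'
#' @param specs List of [texture_spec()]s (one per class).
#' @param counts Integer vector, images per spec.
#' @param params A [glcm_params()].
#' @param thresholds Passed to [discretize_features()].
#' @param pd_noise Flip probability of the simulated prediagnosis.
#' @param seed Seed for the PD simulation.
#' @return A `binary_table` with columns PN, PD, H..M, Class
#'   (Class = 1 for abnormal, 0 for normal); attribute `features` holds
#'   the continuous feature records.
#' @export
gen_labeled_dataset <- function(specs, counts, params = glcm_params(),
                                thresholds = "median-split",
                                pd_noise = 0.1, seed = 1L) {
  stopifnot(is.list(specs), length(specs) == length(counts),
            all(counts >= 1L))
  images <- list(); labels <- character(0)
  for (k in seq_along(specs)) {
    g <- gen_texture_images(specs[[k]], counts[k])
    images <- c(images, g$images)
    labels <- c(labels, g$labels)
  }
  feats <- t(vapply(images, extract_image_features, numeric(6),
                    params = params))
  records <- as.data.frame(feats)
  records$PN <- seq_len(nrow(records))
  med_contrast <- stats::median(records$contrast)
  pd_raw <- as.integer(records$contrast > med_contrast)
  pd <- with_seed(seed, {
    flip <- stats::runif(length(pd_raw)) < pd_noise
    as.integer(xor(pd_raw == 1L, flip))
  })
  records$PD <- pd
  records$Class <- as.integer(labels == "abnormal")
  out <- discretize_features(records, thresholds = thresholds)
  attr(out, "features") <- records
  out
}
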