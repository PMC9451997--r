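# Gray-level cooccurrence matrices and the six texture features used to
# characterize CT-like slices: energy, contrast, entropy, mean, local
# stability (inverse difference moment) and correlation.

#' GLCM parameters
#'
#' @param levels Quantization target L >= 2; gray levels become 0..L-1.
#' @param distance Pixel offset distance d >= 1.
#' @param angles Subset of `c(0, 45, 90, 135)` (degrees).
#' @param counting `"paper"` counts each unordered adjacent pair once,
#'   mirrored off-diagonal (so a single (1,1) pair gives M(1,1) = 1 and two
#'   (1,2) pairs give M(1,2) = M(2,1) = 2); `"ordered-symmetric"` is the
#'   conventional add-transpose matrix (the same pair counted in both
#'   directions, diagonal included).
#' @return List of class `glcm_params`.
#' @export
glcm_params <- function(levels = 16L, distance = 1L,
                        angles = c(0, 45, 90, 135),
                        counting = c("paper", "ordered-symmetric")) {
  counting <- match.arg(counting)
  stopifnot(levels >= 2L, distance >= 1L, length(angles) >= 1L,
            all(angles %in% c(0, 45, 90, 135)))
  structure(list(levels = as.integer(levels),
                 distance = as.integer(distance),
                 angles = angles, counting = counting),
            class = "glcm_params")
}

# (row, col) offset per angle, row 0 at the top of the image
angle_offset <- function(angle, d) {
  switch(as.character(angle),
         "0"   = c(0L, d),
         "45"  = c(-d, d),
         "90"  = c(-d, 0L),
         "135" = c(-d, -d),
         stop("unsupported angle: ", angle))
}

check_gray_image <- function(img) {
  stopifnot(is.matrix(img), length(img) > 0L, is.numeric(img),
            !anyNA(img), all(img >= 0), all(img == round(img)))
}

#' Quantize gray levels
#'
#' Uniform binning of the observed integer range `[min, max]` into L bins:
#' `floor((v - min) * L / (max - min + 1))`.  A constant image maps to
#' level 0; an 8-bit full-range image with L = 256 maps to itself.
#'
#' @param img Integer matrix of non-negative gray levels.
#' @param levels Target number of levels L >= 2.
#' @return Integer matrix with values in `[0, L - 1]`.
#' @export
quantize_image <- function(img, levels) {
  check_gray_image(img)
  stopifnot(levels >= 2L)
  vmin <- min(img); vmax <- max(img)
  if (vmax == vmin) {
    return(matrix(0L, nrow(img), ncol(img)))
  }
  q <- floor((img - vmin) * levels / (vmax - vmin + 1))
  storage.mode(q) <- "integer"
  q
}

#' Compute a gray-level cooccurrence matrix for one angle
#'
#' Counts gray-level pairs at the offset implied by `(distance, angle)`.
#' Under the `"paper"` convention each unordered adjacent pair {a, b}
#' increments both M(a, b) and M(b, a) by 1 when a != b and M(a, a) by 1
#' when a = b; under `"ordered-symmetric"` the scan direction and its
#' reverse are both counted (diagonal entries get 2 per pair).  Either
#' way the matrix is symmetric.
#'
#' @param img Quantized integer matrix with values in `[0, levels - 1]`.
#' @param params A [glcm_params()].
#' @param angle One angle in degrees (0, 45, 90 or 135).
#' @return Object of class `glcm`: `counts` (L x L integer matrix),
#'   `normalized` (NULL until [normalize_glcm()]), `levels`, `distance`,
#'   `angle`, `counting`, `n_pairs` (valid offset positions).
#' @export
compute_glcm <- function(img, params, angle = params$angles[1]) {
  check_gray_image(img)
  stopifnot(inherits(params, "glcm_params"))
  L <- params$levels
  if (max(img) >= L) stop("image has levels >= ", L, "; quantize first")
  off <- angle_offset(angle, params$distance)
  nr <- nrow(img); nc <- ncol(img)
  rows <- seq_len(nr)
  cols <- seq_len(nc)
  rows <- rows[rows + off[1] >= 1L & rows + off[1] <= nr]
  cols <- cols[cols + off[2] >= 1L & cols + off[2] <= nc]
  if (length(rows) == 0L || length(cols) == 0L) {
    stop("offset (d = ", params$distance, ", angle = ", angle,
         ") exceeds the image extent")
  }
  a <- img[rows, cols, drop = FALSE]
  b <- img[rows + off[1], cols + off[2], drop = FALSE]
  raw <- matrix(tabulate(as.vector(a) * L + as.vector(b) + 1L, nbins = L * L),
                nrow = L, ncol = L, byrow = TRUE)
  counts <- if (params$counting == "paper") {
    raw + t(raw) - diag(diag(raw), nrow = L)
  } else {
    raw + t(raw)
  }
  structure(list(counts = counts, normalized = NULL, levels = L,
                 distance = params$distance, angle = angle,
                 counting = params$counting,
                 n_pairs = length(a)),
            class = "glcm")
}

#' Normalize a GLCM to a probability matrix
#'
#' @param m A `glcm` (or a raw counts matrix).
#' @return The `glcm` with `normalized = counts / sum(counts)` filled in
#'   (or the normalized matrix when a plain matrix was given).
#' @export
normalize_glcm <- function(m) {
  if (is.matrix(m)) {
    total <- sum(m)
    if (total <= 0) stop("normalize_glcm: zero pair count")
    return(m / total)
  }
  stopifnot(inherits(m, "glcm"))
  total <- sum(m$counts)
  if (total <= 0) stop("normalize_glcm: zero pair count")
  m$normalized <- m$counts / total
  m
}

#' Six texture features of a normalized GLCM
#'
#' With p(i, j) the normalized matrix over levels i, j = 0..L-1 and
#' marginal means/sds mu_i, mu_j, sigma_i, sigma_j:
#' energy = sum p^2; contrast = sum (i-j)^2 p;
#' entropy = -sum p log2 p (0 log 0 = 0); mean = sum i p_i (row marginal);
#' local_stability = sum p / (1 + (i-j)^2) (inverse difference moment);
#' correlation = sum (i - mu_i)(j - mu_j) p / (sigma_i sigma_j).
#'
#' @param m A normalized `glcm` (see [normalize_glcm()]) or a probability
#'   matrix summing to 1.
#' @param degenerate_correlation What to do when sigma_i * sigma_j = 0:
#'   `"error"` (default) or `"zero"` (flag the value as 0).
#' @return Named numeric vector: energy, contrast, entropy, mean,
#'   local_stability, correlation.
#' @export
compute_features <- function(m, degenerate_correlation = c("error", "zero")) {
  degenerate_correlation <- match.arg(degenerate_correlation)
  p <- if (inherits(m, "glcm")) m$normalized else m
  if (is.null(p)) stop("compute_features: GLCM is not normalized")
  stopifnot(is.matrix(p), nrow(p) == ncol(p))
  if (abs(sum(p) - 1) > 1e-8) {
    stop("compute_features: input does not sum to 1; normalize first")
  }
  L <- nrow(p)
  lv <- seq_len(L) - 1
  i_mat <- matrix(lv, L, L)        # row index i
  j_mat <- t(i_mat)                # col index j
  diff2 <- (i_mat - j_mat)^2
  energy <- sum(p^2)
  contrast <- sum(diff2 * p)
  entropy <- -sum(ifelse(p > 0, p * log2(p), 0))
  p_i <- rowSums(p)
  p_j <- colSums(p)
  mean_i <- sum(lv * p_i)
  mu_j <- sum(lv * p_j)
  local_stability <- sum(p / (1 + diff2))
  var_i <- sum((lv - mean_i)^2 * p_i)
  var_j <- sum((lv - mu_j)^2 * p_j)
  denom <- sqrt(var_i * var_j)
  correlation <- if (denom == 0) {
    if (degenerate_correlation == "error") {
      stop("compute_features: correlation undefined (zero marginal variance)")
    }
    0
  } else {
    sum((i_mat - mean_i) * (j_mat - mu_j) * p) / denom
  }
  c(energy = energy, contrast = contrast, entropy = entropy,
    mean = mean_i, local_stability = local_stability,
    correlation = correlation)
}

#' Quantize, compute per-angle GLCMs and average the texture features
#'
#' The full single-image feature path: uniform quantization to
#' `params$levels`, one normalized GLCM per requested angle, features per
#' angle, then the arithmetic mean across angles as a rotation-robust
#' summary.
#'
#' @param img Integer gray-level matrix (any range; quantized internally).
#' @param params A [glcm_params()].
#' @param degenerate_correlation Passed to [compute_features()]; defaults
#'   to `"zero"` here so near-constant images flow through batch feature
#'   extraction.
#' @param crop Optional central-crop fraction in (0, 1]; 1 = no crop.
#' @param median_filter If TRUE, apply a 3x3 median filter before
#'   quantization (simple speckle suppression hook).
#' @return Named numeric vector of the six features.
#' @export
extract_image_features <- function(img, params = glcm_params(),
                                   degenerate_correlation = "zero",
                                   crop = 1, median_filter = FALSE) {
  check_gray_image(img)
  if (crop < 1) {
    nr <- nrow(img); nc <- ncol(img)
    kr <- max(2L, round(nr * crop)); kc <- max(2L, round(nc * crop))
    r0 <- floor((nr - kr) / 2); c0 <- floor((nc - kc) / 2)
    img <- img[(r0 + 1):(r0 + kr), (c0 + 1):(c0 + kc), drop = FALSE]
  }
  if (isTRUE(median_filter)) img <- median_filter3(img)
  q <- quantize_image(img, params$levels)
  feats <- vapply(params$angles, function(a) {
    g <- normalize_glcm(compute_glcm(q, params, a))
    compute_features(g, degenerate_correlation = degenerate_correlation)
  }, numeric(6))
  rowMeans(feats)
}

# 3x3 median filter with edge replication; tiny preprocessing hook.
median_filter3 <- function(img) {
  nr <- nrow(img); nc <- ncol(img)
  pad <- img[c(1, seq_len(nr), nr), c(1, seq_len(nc), nc)]
  stack <- array(NA_real_, dim = c(nr, nc, 9))
  k <- 0L
  for (dr in 0:2) for (dc in 0:2) {
    k <- k + 1L
    stack[, , k] <- pad[dr + seq_len(nr), dc + seq_len(nc)]
  }
  out <- apply(stack, c(1, 2), stats::median)
  storage.mode(out) <- "integer"
  out
}
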