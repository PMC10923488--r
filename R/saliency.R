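# Occlusion saliency for any classifier satisfying the probability-vector
# contract, ensemble averaging, and coverage-threshold matching against a
# reference attention map.

#' Occlusion configuration
#'
#' @param box Occlusion box side length in pixels (default 20).
#' @param stride Offset between box positions per axis (default 10).
#' @param fill Value written into an occluded box (default 0, i.e. the raw
#'   zero of the image scale).
#' @return An object of class `occlusion_config`.
#' @export
occlusion_config <- function(box = 20L, stride = 10L, fill = 0) {
  box <- as.integer(box); stride <- as.integer(stride)
  if (stride < 1L || stride > box)
    stop("need 1 <= stride <= box")
  structure(list(box = box, stride = stride, fill = fill),
            class = "occlusion_config")
}

#' Construct a classifier object
#'
#' The only interface the saliency stage needs: an ordered label set and a
#' deterministic `predict` function mapping an image grid to a probability
#' vector over those labels (nonnegative, summing to 1 within 1e-6).
#'
#' @param labels Character vector of label names.
#' @param predict Function `(image) -> named numeric vector` of probabilities.
#' @param input_shape Optional `c(H, W)` the classifier expects; images of a
#'   different size are nearest-neighbour resized before prediction and the
#'   saliency grid is mapped back to the source resolution.
#' @return An object of class `gaze_classifier`.
#' @export
classifier_contract <- function(labels, predict, input_shape = NULL) {
  stopifnot(is.character(labels), length(labels) >= 2L, is.function(predict))
  structure(list(labels = labels, predict = predict,
                 input_shape = input_shape),
            class = "gaze_classifier")
}

predict_probs <- function(clf, image) {
  p <- clf$predict(image)
  if (length(p) != length(clf$labels))
    stop("classifier returned ", length(p), " probabilities for ",
         length(clf$labels), " labels")
  if (any(p < -1e-12) || abs(sum(p) - 1) > 1e-6)
    stop("classifier output is not a probability vector (sum = ", sum(p), ")")
  names(p) <- clf$labels
  p
}

# Nearest-neighbour resize of a matrix (or H x W x C array) by index
# remapping; pixel-center sampling.
nn_resize <- function(g, shape) {
  H2 <- shape[1]; W2 <- shape[2]
  if (length(dim(g)) == 3L) {
    out <- array(0, c(H2, W2, dim(g)[3]))
    for (ch in seq_len(dim(g)[3])) out[, , ch] <- nn_resize(g[, , ch], shape)
    return(out)
  }
  if (nrow(g) == H2 && ncol(g) == W2) return(g)
  ri <- pmin(nrow(g), floor((seq_len(H2) - 0.5) * nrow(g) / H2) + 1L)
  ci <- pmin(ncol(g), floor((seq_len(W2) - 0.5) * ncol(g) / W2) + 1L)
  g[ri, ci, drop = FALSE]
}

occlude <- function(image, r0, c0, box, fill) {
  rows <- (r0 + 1L):(r0 + box); cols <- (c0 + 1L):(c0 + box)
  if (length(dim(image)) == 3L) image[rows, cols, ] <- fill
  else image[rows, cols] <- fill
  image
}

#' Occlusion saliency map
#'
#' Slides a `box x box` occluder over the image at `stride`-spaced offsets
#' (boxes fully inside the image only), sets the covered pixels to
#' `cfg$fill`, and records the drop in the classifier's probability for
#' `target`, clipped at zero so only positive contributions count. Per-pixel
#' saliency is the mean drop over all boxes covering that pixel; pixels no
#' box reaches are 0.
#'
#' The classifier's probability for `target` on the intact image must exceed
#' 1e-4 (below that the saliency map is unreliable and the call errors); a
#' warning is issued below 1e-2.
#'
#' @param image Numeric matrix (H x W) or array (H x W x C).
#' @param clf A [classifier_contract()].
#' @param target Label name the saliency is computed for.
#' @param cfg An [occlusion_config()].
#' @param image_id Identifier stored on the result.
#' @return An object of class `saliency_map` with fields `grid`, `image_id`,
#'   `target_label`, `box`, `stride`.
#' @export
occlusion_saliency <- function(image, clf, target,
                               cfg = occlusion_config(), image_id = "IMG") {
  if (!target %in% clf$labels) stop("unknown target label: ", target)
  src_shape <- dim(image)[1:2]
  work <- image
  if (!is.null(clf$input_shape) &&
      !identical(as.integer(src_shape), as.integer(clf$input_shape)))
    work <- nn_resize(image, clf$input_shape)
  H <- dim(work)[1]; W <- dim(work)[2]
  if (cfg$box > min(H, W)) stop("occlusion box larger than image")
  p0 <- predict_probs(clf, work)[[target]]
  if (p0 <= 1e-4)
    stop("target probability ", signif(p0, 3),
         " is too close to zero; the saliency map would be unreliable")
  if (p0 < 1e-2)
    warning("target probability ", signif(p0, 3),
            " is low; saliency may be unreliable")
  acc <- matrix(0, H, W)
  cnt <- matrix(0L, H, W)
  for (r0 in seq(0L, H - cfg$box, by = cfg$stride)) {
    for (c0 in seq(0L, W - cfg$box, by = cfg$stride)) {
      p <- predict_probs(clf, occlude(work, r0, c0, cfg$box, cfg$fill))[[target]]
      drop <- max(0, p0 - p)
      rows <- (r0 + 1L):(r0 + cfg$box); cols <- (c0 + 1L):(c0 + cfg$box)
      acc[rows, cols] <- acc[rows, cols] + drop
      cnt[rows, cols] <- cnt[rows, cols] + 1L
    }
  }
  sal <- acc / pmax(cnt, 1L)
  if (!identical(dim(sal), as.integer(src_shape)))
    sal <- nn_resize(sal, src_shape)
  structure(list(grid = intensity_grid(sal), image_id = image_id,
                 target_label = target, box = cfg$box, stride = cfg$stride),
            class = "saliency_map")
}

#' @export
print.saliency_map <- function(x, ...) {
  cat(sprintf("<saliency_map image=%s target=%s box=%d stride=%d %dx%d>\n",
              x$image_id, x$target_label, x$box, x$stride,
              nrow(x$grid), ncol(x$grid)))
  invisible(x)
}

#' Average saliency maps from an ensemble of models
#'
#' @param maps Nonempty list of `saliency_map`s sharing image, target and
#'   shape (the study default is 5, one per cross-validation fold).
#' @return A `saliency_map` with the pixel-wise mean grid.
#' @export
ensemble_saliency <- function(maps) {
  if (length(maps) == 0L) stop("cannot average an empty ensemble")
  tgt <- unique(vapply(maps, function(m) m$target_label, character(1)))
  iid <- unique(vapply(maps, function(m) m$image_id, character(1)))
  if (length(tgt) != 1L) stop("ensemble members target different labels")
  if (length(iid) != 1L) stop("ensemble members cover different images")
  acc <- matrix(0, nrow(maps[[1L]]$grid), ncol(maps[[1L]]$grid))
  for (m in maps) {
    check_same_shape(acc, m$grid)
    acc <- acc + unclass(m$grid)
  }
  out <- maps[[1L]]
  out$grid <- intensity_grid(acc / length(maps))
  out
}

# Rank-selection cutoff: the smallest cutoff whose retained nonzero in-mask
# count is closest to round(target_fraction * area). Ties between keeping or
# dropping pixels tied at the cutoff go to the sparser map.
coverage_cutoff <- function(g, mask, target_fraction) {
  vals <- g[mask$mask]
  pos <- vals[vals > 0]
  if (length(pos) == 0L)
    stop("map has no nonzero pixel inside the face mask")
  k <- round(target_fraction * mask$area)
  uv <- sort(unique(pos), decreasing = TRUE)
  cnt <- cumsum(tabulate(match(pos, uv), nbins = length(uv)))
  # candidate cutoffs: each distinct value (keep >= uv[i]) plus "above max"
  cand_t <- c(uv[1] * (1 + 1e-12), uv)
  cand_n <- c(0L, cnt)
  err <- abs(cand_n - k)
  best <- which(err == min(err))
  best <- best[which.min(cand_n[best])]   # prefer fewer pixels on ties
  cand_t[best]
}

#' Coverage-threshold a map against a face mask
#'
#' Chooses the cutoff so that the count of nonzero pixels inside the mask is
#' as close as possible to `round(target_fraction * mask area)` (rank
#' selection on the sorted in-mask values, equivalent to a grid search over
#' cutoffs). Pixels at or above the cutoff keep their original magnitudes;
#' pixels below it, and all pixels outside the mask, are set to 0.
#'
#' @param map An intensity grid (matrix), `attention_map` or `saliency_map`.
#' @param mask A [face_mask()] of the same shape.
#' @param target_fraction Desired nonzero fraction of the mask area, in
#'   (0, 1].
#' @return An `intensity_grid` (or the input object with its grid replaced).
#' @export
coverage_threshold <- function(map, mask, target_fraction) {
  if (target_fraction <= 0 || target_fraction > 1)
    stop("`target_fraction` must be in (0, 1]")
  g <- unclass(as_grid(map))
  check_same_shape(g, mask$mask)
  t <- coverage_cutoff(g, mask, target_fraction)
  out <- g
  out[!mask$mask] <- 0
  out[out < t] <- 0
  out <- intensity_grid(out)
  if (is.list(map)) { map$grid <- out; return(map) }
  out
}

#' Match a saliency map's coverage to a reference attention map
#'
#' Coverage-thresholds the saliency map so its nonzero in-mask pixel count is
#' approximately equal to the reference's (the reference must already be
#' noise-thresholded). This equalises the number of "active" pixels the two
#' maps contribute to IoU and KL.
#'
#' @param saliency A `saliency_map`.
#' @param reference A noise-thresholded `attention_map`.
#' @param mask A [face_mask()].
#' @return The coverage-matched `saliency_map`.
#' @export
match_coverage <- function(saliency, reference, mask) {
  rg <- unclass(as_grid(reference))
  n_ref <- sum(rg[mask$mask] > 0)
  if (n_ref == 0L)
    stop("reference map has no nonzero pixel inside the face mask")
  coverage_threshold(saliency, mask, n_ref / mask$area)
}

#' Toy prototype classifier
#'
#' A deterministic, desk-scale classifier fulfilling the probability
#' contract: each label has a prototype grid, and prediction is a softmax
#' over the negative mean-squared distance between the image and each
#' prototype, divided by `temperature`. Because prototypes can be built to
#' differ only inside known regions, the truly salient region is known
#' analytically, which is what the test suite exploits.
#'
#' @param prototypes Named list of numeric matrices, one per label, all the
#'   same shape.
#' @param temperature Softmax temperature on the MSE scale (default 0.01);
#'   smaller values sharpen the probabilities.
#' @return A [classifier_contract()] whose `input_shape` is the prototype
#'   shape.
#' @export
prototype_classifier <- function(prototypes, temperature = 0.01) {
  stopifnot(is.list(prototypes), length(prototypes) >= 2L,
            !is.null(names(prototypes)), temperature > 0)
  shp <- dim(prototypes[[1L]])
  P <- vapply(prototypes, function(p) {
    stopifnot(identical(dim(p), shp))
    as.vector(p)
  }, numeric(prod(shp)))
  labels <- names(prototypes)
  predict <- function(image) {
    v <- as.vector(image)
    if (length(v) != nrow(P))
      stop("image shape does not match prototype shape")
    mse <- colMeans((P - v)^2)
    s <- -mse / temperature
    e <- exp(s - max(s))
    e / sum(e)
  }
  classifier_contract(labels, predict, input_shape = shp)
}
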