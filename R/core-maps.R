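# Attention-map preprocessing: fixation rendering, averaging, common-attention
# subtraction, box-filter smoothing, noise thresholding.

#' Render an attention map from fixation events
#'
#' Each fixation deposits a radially decaying kernel (truncated Gaussian with
#' sigma = radius / 2, support limited to `radius` pixels) centred at its
#' pixel, scaled by the fixation duration in milliseconds. Deposits sum, so
#' total map mass is proportional to total fixation time wherever kernels are
#' not clipped by the frame border. This emulates the intensity-accumulating
#' render of screen-based eye trackers at a configurable radius.
#'
#' @param fixations Data frame with columns `participant_id`, `image_id`,
#'   `x`, `y` (0-based pixel coordinates), `onset_ms`, `duration_ms`. All rows
#'   must share one participant and one image. An empty frame yields an
#'   all-zero map.
#' @param shape Integer vector `c(H, W)`.
#' @param radius Kernel support radius in pixels (default 25).
#' @param participant_id,group,image_id Metadata overrides; defaults come from
#'   the fixation table (`group` defaults to `"clinician"` when absent).
#' @return An `attention_map` at stage `"raw"`.
#' @export
render_from_fixations <- function(fixations, shape, radius = 25,
                                  participant_id = NULL, group = NULL,
                                  image_id = NULL) {
  stopifnot(length(shape) == 2L, all(shape >= 1), radius > 0)
  H <- as.integer(shape[1]); W <- as.integer(shape[2])
  if (nrow(fixations) > 0L) {
    pid <- unique(fixations$participant_id)
    iid <- unique(fixations$image_id)
    if (length(pid) != 1L || length(iid) != 1L)
      stop("fixations must share a single participant and image")
    if (is.null(participant_id)) participant_id <- pid
    if (is.null(image_id)) image_id <- iid
    if (is.null(group) && !is.null(fixations$group))
      group <- unique(fixations$group)[1L]
    bad <- fixations$x < 0 | fixations$x >= W |
           fixations$y < 0 | fixations$y >= H
    if (any(bad))
      stop("fixation outside grid at row(s) ",
           paste(utils::head(which(bad), 5L), collapse = ", "),
           " (x must be in [0, ", W - 1, "], y in [0, ", H - 1, "])")
    if (any(fixations$duration_ms <= 0))
      stop("fixation durations must be positive")
  }
  if (is.null(participant_id)) participant_id <- "UNKNOWN"
  if (is.null(group)) group <- "clinician"
  if (is.null(image_id)) image_id <- "UNKNOWN"

  out <- matrix(0, H, W)
  if (nrow(fixations) > 0L) {
    r <- ceiling(radius)
    off <- -r:r
    d2 <- outer(off^2, off^2, "+")
    sigma <- radius / 2
    kern <- exp(-d2 / (2 * sigma^2))
    kern[sqrt(d2) > radius] <- 0
    for (i in seq_len(nrow(fixations))) {
      cx <- as.integer(round(fixations$x[i])) + 1L  # 1-based column
      cy <- as.integer(round(fixations$y[i])) + 1L  # 1-based row
      rows <- max(1L, cy - r):min(H, cy + r)
      cols <- max(1L, cx - r):min(W, cx + r)
      krows <- rows - cy + r + 1L
      kcols <- cols - cx + r + 1L
      out[rows, cols] <- out[rows, cols] +
        fixations$duration_ms[i] * kern[krows, kcols, drop = FALSE]
    }
  }
  attention_map(out, participant_id, group, image_id, stage = "raw")
}

#' Average attention maps pixel-wise
#'
#' @param maps Nonempty list of `attention_map`s sharing shape and image.
#' @return An `attention_map` with `participant_id = "GROUP_AVG"` at the
#'   furthest stage any input has reached.
#' @export
average_maps <- function(maps) {
  if (length(maps) == 0L) stop("cannot average an empty list of maps")
  g1 <- as_grid(maps[[1L]])
  iid <- unique(vapply(maps, function(m) m$image_id, character(1)))
  if (length(iid) != 1L)
    stop("maps span multiple images: ", paste(iid, collapse = ", "))
  acc <- matrix(0, nrow(g1), ncol(g1))
  for (m in maps) {
    g <- as_grid(m)
    check_same_shape(acc, g)
    acc <- acc + g
  }
  stage <- STAGES[max(vapply(maps, function(m) stage_index(m$stage), 1L))]
  attention_map(acc / length(maps), "GROUP_AVG", maps[[1L]]$group, iid,
                stage = stage)
}

#' Common-attention map of a group
#'
#' Pixel-wise mean over every participant-by-image map of one group, across
#' all images. This captures the group's generic face-viewing bias (eyes,
#' nose, mouth) which is later subtracted from each individual map to expose
#' condition-specific attention.
#'
#' @param maps Nonempty list of `attention_map`s from one group (any images).
#' @return An `attention_map` with `image_id = "COMMON"`,
#'   `participant_id = "GROUP_AVG"`.
#' @export
common_attention <- function(maps) {
  if (length(maps) == 0L) stop("cannot average an empty list of maps")
  grp <- unique(vapply(maps, function(m) m$group, character(1)))
  if (length(grp) != 1L)
    stop("common attention must be built from a single group, got: ",
         paste(grp, collapse = ", "))
  g1 <- as_grid(maps[[1L]])
  acc <- matrix(0, nrow(g1), ncol(g1))
  for (m in maps) {
    g <- as_grid(m)
    check_same_shape(acc, g)
    acc <- acc + g
  }
  attention_map(acc / length(maps), "GROUP_AVG", grp, "COMMON", stage = "raw")
}

#' Subtract a group's common attention from a map
#'
#' Pixel-wise difference, clipped at zero so the nonnegativity invariant is
#' preserved immediately rather than deferred.
#'
#' @param map An `attention_map`.
#' @param common The group's common-attention map (same shape and group).
#' @return The map at stage `"common_subtracted"`.
#' @export
subtract_common <- function(map, common) {
  check_same_shape(as_grid(map), as_grid(common))
  if (!identical(map$group, common$group))
    stop("group mismatch: map is ", map$group, ", common is ", common$group)
  d <- unclass(as_grid(map)) - unclass(as_grid(common))
  d[d < 0] <- 0
  out <- map
  out$grid <- intensity_grid(d)
  advance_stage(out, "common_subtracted")
}

box_filter <- function(g, kernel) {
  # Uniform box mean with shrink-to-valid edge handling, via summed-area
  # tables; windows at borders average over fewer cells.
  H <- nrow(g); W <- ncol(g); r <- (kernel - 1L) %/% 2L
  S <- matrix(0, H + 1L, W + 1L)
  S[-1L, -1L] <- apply(apply(g, 2L, cumsum), 1L, cumsum) |> t()
  r1 <- pmax(seq_len(H) - r, 1L); r2 <- pmin(seq_len(H) + r, H)
  c1 <- pmax(seq_len(W) - r, 1L); c2 <- pmin(seq_len(W) + r, W)
  sums <- S[r2 + 1L, c2 + 1L] - S[r1, c2 + 1L] - S[r2 + 1L, c1] + S[r1, c1]
  counts <- outer(r2 - r1 + 1L, c2 - c1 + 1L)
  sums / counts
}

#' Smooth a map with a uniform box filter
#'
#' Applies a kernel x kernel box mean (edge windows shrink to the valid
#' region) and then rescales globally so the maximum equals the pre-smoothing
#' maximum. The rescale implements intensity boosting deterministically:
#' smoothing spreads peaks, the rescale restores their height, so mid-range
#' attention becomes more visible without changing where the peak is.
#'
#' @param map An `attention_map`.
#' @param kernel Odd positive kernel width in pixels (default 15).
#' @return The map at stage `"smoothed"`.
#' @export
smooth_map <- function(map, kernel = 15) {
  if (kernel < 1 || kernel %% 2 == 0)
    stop("`kernel` must be a positive odd integer")
  g <- unclass(as_grid(map))
  pre_max <- max(g)
  out <- if (kernel == 1L) g else box_filter(g, as.integer(kernel))
  post_max <- max(out)
  if (post_max > 0) out <- out * (pre_max / post_max)
  res <- map
  res$grid <- intensity_grid(out)
  advance_stage(res, "smoothed")
}

resolve_cutoff <- function(g, spec, mask = NULL) {
  switch(spec$mode,
    absolute = spec$value,
    fraction_of_max = spec$value * max(g),
    coverage_fraction = {
      if (is.null(mask))
        stop("coverage_fraction thresholding requires a `face_mask`")
      coverage_cutoff(g, mask, spec$value)
    })
}

#' Apply a noise threshold to an attention map
#'
#' Pixels strictly below the resolved cutoff are set to 0; surviving pixels
#' keep their original values. With `coverage_fraction` mode the cutoff is
#' chosen by rank selection against the face mask (see
#' [coverage_threshold()]) and out-of-mask pixels are zeroed, matching the
#' saliency-side coverage semantics.
#'
#' @param map An `attention_map`.
#' @param spec A [threshold_spec()].
#' @param mask A [face_mask()], required for `coverage_fraction` mode.
#' @param level `"low"` or `"high"`; selects the stage the map advances to.
#' @return The map at stage `"thresholded_low"` or `"thresholded_high"`.
#' @export
apply_noise_threshold <- function(map, spec, mask = NULL,
                                  level = c("low", "high")) {
  level <- match.arg(level)
  g <- unclass(as_grid(map))
  if (spec$mode == "coverage_fraction") {
    if (is.null(mask))
      stop("coverage_fraction thresholding requires a `face_mask`")
    out <- unclass(coverage_threshold(g, mask, spec$value))
  } else {
    t <- resolve_cutoff(g, spec, mask)
    out <- g
    out[out < t] <- 0
  }
  res <- map
  res$grid <- intensity_grid(out)
  advance_stage(res, paste0("thresholded_", level))
}
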