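# Coordinate convention, used everywhere in the package: grids are numeric
# matrices with H rows and W columns, origin at the top-left, 0-based pixel
# coordinates with x = column and y = row, pixel-center semantics.
# Pixel (x, y) is grid[y + 1, x + 1].

STAGES <- c("raw", "common_subtracted", "smoothed", "thresholded_low",
            "thresholded_high")

#' Create an intensity grid
#'
#' An intensity grid is the universal 2D nonnegative map used for both gaze
#' attention and classifier saliency. Negative entries are clipped to zero at
#' creation so that nonnegativity is a global invariant.
#'
#' @param values Numeric matrix (H x W). Negatives are clipped to 0.
#' @return A numeric matrix of class `intensity_grid`.
#' @export
intensity_grid <- function(values) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (nrow(values) < 1L || ncol(values) < 1L)
    stop("grid must have positive dimensions")
  values[values < 0] <- 0
  structure(values, class = c("intensity_grid", class(values)))
}

as_grid <- function(x) {
  if (inherits(x, "attention_map") || inherits(x, "saliency_map")) return(x$grid)
  if (is.matrix(x)) return(x)
  stop("cannot interpret object of class ", paste(class(x), collapse = "/"),
       " as an intensity grid")
}

#' Create a face-region mask
#'
#' @param mask Logical matrix (H x W); `TRUE` marks face pixels.
#' @return An object of class `face_mask` with fields `mask` and `area`.
#' @export
face_mask <- function(mask) {
  if (is.numeric(mask)) mask <- mask > 0
  if (!is.matrix(mask) || !is.logical(mask))
    stop("`mask` must be a logical matrix")
  area <- sum(mask)
  if (area == 0L) stop("face mask must contain at least one TRUE pixel")
  structure(list(mask = mask, area = area), class = "face_mask")
}

#' Create an attention map
#'
#' Wraps an intensity grid with study metadata. The preprocessing `stage`
#' only ever moves forward through
#' raw -> common_subtracted -> smoothed -> thresholded_low -> thresholded_high.
#'
#' @param grid Numeric matrix of gaze intensity (negatives clipped).
#' @param participant_id Participant identifier, or `"GROUP_AVG"`.
#' @param group `"clinician"` or `"nonclinician"`.
#' @param image_id Stimulus image identifier, or `"COMMON"`.
#' @param stage One of "raw", "common_subtracted", "smoothed",
#'   "thresholded_low", "thresholded_high".
#' @return An object of class `attention_map`.
#' @export
attention_map <- function(grid, participant_id, group, image_id,
                          stage = "raw") {
  group <- match.arg(group, c("clinician", "nonclinician"))
  stage <- match.arg(stage, STAGES)
  structure(list(grid = intensity_grid(unclass(grid)),
                 participant_id = as.character(participant_id),
                 group = group,
                 image_id = as.character(image_id),
                 stage = stage),
            class = "attention_map")
}

stage_index <- function(stage) match(stage, STAGES)

advance_stage <- function(map, new_stage) {
  if (stage_index(new_stage) < stage_index(map$stage))
    stop("stage transition ", map$stage, " -> ", new_stage,
         " moves backwards; stages only advance")
  map$stage <- new_stage
  map
}

#' Specify a threshold
#'
#' @param mode `"absolute"` (cutoff in intensity units), `"fraction_of_max"`
#'   (cutoff = value x map maximum), or `"coverage_fraction"` (cutoff chosen
#'   so the nonzero in-mask pixel count matches value x mask area).
#' @param value Nonnegative real; at most 1 for the two relative modes.
#' @return An object of class `threshold_spec`.
#' @export
threshold_spec <- function(mode = c("absolute", "fraction_of_max",
                                    "coverage_fraction"),
                           value) {
  mode <- match.arg(mode)
  if (!is.numeric(value) || length(value) != 1L || value < 0)
    stop("`value` must be a single nonnegative number")
  if (mode != "absolute" && value > 1)
    stop("`value` must be <= 1 for mode ", mode)
  structure(list(mode = mode, value = value), class = "threshold_spec")
}

#' @export
print.attention_map <- function(x, ...) {
  cat(sprintf("<attention_map %s/%s image=%s stage=%s %dx%d max=%.4g>\n",
              x$group, x$participant_id, x$image_id, x$stage,
              nrow(x$grid), ncol(x$grid), max(x$grid)))
  invisible(x)
}

#' @export
print.face_mask <- function(x, ...) {
  cat(sprintf("<face_mask %dx%d area=%d (%.1f%% of frame)>\n",
              nrow(x$mask), ncol(x$mask), x$area,
              100 * x$area / length(x$mask)))
  invisible(x)
}

check_same_shape <- function(a, b) {
  if (!identical(dim(a), dim(b)))
    stop("grid shapes differ: ", paste(dim(a), collapse = "x"), " vs ",
         paste(dim(b), collapse = "x"))
  invisible(TRUE)
}
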