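# Pairwise map comparison (IoU, symmetric KL), participant-level bootstrap
# standard deviations, and AOI fixation metrics.

#' Intersection-over-Union of two maps
#'
#' Both maps are binarized (nonzero pixels become 1) and the ratio
#' |A intersect B| / |A union B| is returned; it lies in [0, 1] and is high
#' when the two maps mark overlapping regions.
#'
#' @param a,b Intensity grids (matrices), `attention_map`s or
#'   `saliency_map`s of equal shape.
#' @return A number in [0, 1], or `NA_real_` when both maps are entirely
#'   zero (the comparison is undefined, never 0 or 1).
#' @export
map_iou <- function(a, b) {
  ga <- unclass(as_grid(a)) > 0
  gb <- unclass(as_grid(b)) > 0
  check_same_shape(ga, gb)
  uni <- sum(ga | gb)
  if (uni == 0L) return(NA_real_)
  sum(ga & gb) / uni
}

#' Symmetric Kullback-Leibler divergence between two maps
#'
#' Both maps are restricted to the union of their nonzero supports
#' (optionally intersected with a face mask), smoothed by adding `eps` to
#' every pixel of that support, rescaled to sum to 1, and compared with
#' 0.5 * (KL(p||q) + KL(q||p)) in nats. Zero means identical distributions;
#' the value grows without bound as the maps diverge.
#'
#' @param a,b Intensity grids (matrices) or map objects of equal shape, each
#'   with at least one nonzero pixel.
#' @param eps Smoothing constant; default `1e-9` times the mean nonzero value
#'   of the two maps. Must be positive unless the supports are identical.
#' @param mask Optional [face_mask()] restricting the analysis support.
#' @return Nonnegative divergence in nats.
#' @export
symmetric_kl <- function(a, b, eps = NULL, mask = NULL) {
  ga <- unclass(as_grid(a)); gb <- unclass(as_grid(b))
  check_same_shape(ga, gb)
  support <- (ga > 0) | (gb > 0)
  if (!is.null(mask)) support <- support & mask$mask
  if (sum(ga[support]) == 0 || sum(gb[support]) == 0)
    stop("each map needs at least one nonzero pixel on the analysis support")
  pa <- ga[support]; pb <- gb[support]
  if (is.null(eps)) eps <- 1e-9 * mean(c(pa[pa > 0], pb[pb > 0]))
  if (eps <= 0) {
    if (!identical(pa > 0, pb > 0))
      stop("eps must be positive when the supports differ (KL is infinite)")
    eps <- 0
  }
  p <- pa + eps; p <- p / sum(p)
  q <- pb + eps; q <- q / sum(q)
  ok <- p > 0 & q > 0  # with eps = 0 and identical supports both vanish together
  0.5 * (sum(p[ok] * log(p[ok] / q[ok])) + sum(q[ok] * log(q[ok] / p[ok])))
}

#' Bootstrap standard deviation of a map-comparison metric
#'
#' Resamples participants (the independent unit) with replacement, rebuilds
#' the group-level map from each resample via the `prep` closure (typically
#' subtract-common, average, smooth, threshold), computes the metric against
#' a fixed second map, and returns the sample standard deviation over the
#' `B` replicate values. Replicates where the metric is undefined (e.g. an
#' all-zero rebuilt map) are dropped with a warning.
#'
#' @param participant_maps List (length >= 2) of per-participant
#'   `attention_map`s or grids.
#' @param other Fixed grid or map compared against.
#' @param metric `"iou"` or `"kl"`.
#' @param prep Function mapping a list of participant maps to a single grid
#'   or map. Default: plain [average_maps()].
#' @param B Number of bootstrap replicates (default 1000, minimum 100).
#' @param seed Integer seed; the result is deterministic given the seed and
#'   the global RNG state is restored on exit.
#' @param eps,mask Passed to [symmetric_kl()] when `metric = "kl"`.
#' @return The bootstrap standard deviation (single number).
#' @export
bootstrap_sd <- function(participant_maps, other, metric = c("iou", "kl"),
                         prep = average_maps, B = 1000L, seed = 1L,
                         eps = NULL, mask = NULL) {
  metric <- match.arg(metric)
  n <- length(participant_maps)
  if (n < 2L) stop("bootstrap needs at least 2 participants")
  if (B < 100L) stop("B must be at least 100")
  other_g <- unclass(as_grid(other))
  metric_fun <- if (metric == "iou") {
    function(g) map_iou(g, other_g)
  } else {
    function(g) symmetric_kl(g, other_g, eps = eps, mask = mask)
  }
  vals <- with_seed(seed, {
    idx <- matrix(sample.int(n, n * B, replace = TRUE), nrow = B)
    apply(idx, 1L, function(ii) {
      g <- prep(participant_maps[ii])
      tryCatch(metric_fun(unclass(as_grid(g))), error = function(e) NA_real_)
    })
  })
  vals[is.nan(vals)] <- NA_real_
  n_bad <- sum(is.na(vals))
  if (n_bad > 0L)
    warning(n_bad, " of ", B, " bootstrap replicates had an undefined ",
            metric, " and were dropped")
  stats::sd(vals[!is.na(vals)])
}

# Run code with a private RNG stream, restoring the caller's state.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

# Deterministic substream seeds below 2^31: a small integer hash so that
# stream i of a study never changes when more streams are added. The final
# avalanche rounds (LCG multiply + xorshift) matter: near-identical key
# tuples must land on uncorrelated RNG states, otherwise the first draws of
# sibling substreams are visibly dependent.
mix_seed <- function(seed, ...) {
  m <- 2147483647
  h <- as.numeric(seed) %% m
  for (k in list(...)) {          # list(), not c(): no type coercion
    if (is.character(k)) {
      v <- 0
      for (u in utf8ToInt(k)) v <- (v * 131 + u) %% m
      k <- v
    }
    h <- (h * 48271 + as.numeric(k) + 1) %% m
  }
  # final scramble through the generator itself; a purely arithmetic hash
  # here leaves the first draws of sibling substreams correlated
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has_seed) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(h))
  sample.int(m, 1L)
}

#' Define an area of interest
#'
#' @param image_id Image the AOI belongs to.
#' @param name Feature label (e.g. `"eyebrows"`).
#' @param polygon Two-column matrix of (x, y) vertices, at least 3.
#' @return An object of class `aoi_region`.
#' @export
aoi_region <- function(image_id, name, polygon) {
  polygon <- as.matrix(polygon)
  if (nrow(polygon) < 3L || ncol(polygon) != 2L)
    stop("polygon needs at least 3 (x, y) vertices")
  structure(list(image_id = image_id, name = name, polygon = polygon),
            class = "aoi_region")
}

# Ray casting with points on an edge (or vertex) counted as inside.
point_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  xs <- poly[, 1]; ys <- poly[, 2]
  vapply(seq_along(px), function(i) {
    x <- px[i]; y <- py[i]
    inside <- FALSE
    j <- n
    for (k in seq_len(n)) {
      x1 <- xs[j]; y1 <- ys[j]; x2 <- xs[k]; y2 <- ys[k]
      # on-edge test: collinear and within the segment's bounding box
      cross <- (x2 - x1) * (y - y1) - (y2 - y1) * (x - x1)
      if (abs(cross) < 1e-9 &&
          x >= min(x1, x2) - 1e-9 && x <= max(x1, x2) + 1e-9 &&
          y >= min(y1, y2) - 1e-9 && y <= max(y1, y2) + 1e-9)
        return(TRUE)
      if ((y1 > y) != (y2 > y) &&
          x < x1 + (y - y1) * (x2 - x1) / (y2 - y1))
        inside <- !inside
      j <- k
    }
    inside
  }, logical(1))
}

#' AOI fixation metrics
#'
#' For each area of interest, sums the durations of fixations whose position
#' falls inside the polygon (boundary counts as inside) and records the
#' onset of the earliest such fixation.
#'
#' @param fixations Data frame of fixation events sorted by `onset_ms`.
#' @param aois List of [aoi_region()]s.
#' @return Data frame with columns `participant_id`, `aoi`,
#'   `duration_of_fixation_ms`, `time_to_first_whole_fixation_ms` (`NA` when
#'   no fixation hit the AOI, in which case the duration is 0).
#' @export
aoi_metrics <- function(fixations, aois) {
  if (nrow(fixations) > 0 && is.unsorted(fixations$onset_ms))
    fixations <- fixations[order(fixations$onset_ms), ]
  pid <- if (nrow(fixations) > 0) unique(fixations$participant_id)[1] else NA_character_
  rows <- lapply(aois, function(a) {
    hit <- if (nrow(fixations) == 0) logical(0) else
      point_in_polygon(fixations$x, fixations$y, a$polygon)
    data.frame(
      participant_id = pid,
      aoi = a$name,
      duration_of_fixation_ms = sum(fixations$duration_ms[hit]),
      time_to_first_whole_fixation_ms =
        if (any(hit)) fixations$onset_ms[which(hit)[1L]] else NA_real_,
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
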