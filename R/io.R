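# File formats: dense-matrix TSV and 16-bit grayscale PNG for maps, 1-bit
# PNG for masks, delimited tables for fixations/responses/results, JSON for
# AOI polygons and ground-truth sidecars.

write_tsv <- function(d, path) {
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

#' Read and write dense-matrix maps
#'
#' The dense text format is a headerless tab-separated numeric matrix, one
#' grid row per line; values keep full precision, so a write/read round trip
#' is lossless.
#'
#' @param grid Numeric matrix (or object carrying a grid).
#' @param path File path.
#' @return `read_map_matrix` returns a numeric matrix; `write_map_matrix`
#'   returns `path` invisibly.
#' @export
write_map_matrix <- function(grid, path) {
  g <- unclass(as_grid(grid))
  utils::write.table(g, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_map_matrix
#' @export
read_map_matrix <- function(path) {
  w <- length(strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1L]])
  matrix(scan(path, quiet = TRUE), ncol = w, byrow = TRUE)
}

#' Read and write maps as grayscale PNG
#'
#' Intensities are scaled by `max_value` into [0, 1] and quantised to the
#' PNG bit depth (8 bits with the `png` encoder); the scale must be carried
#' in the manifest to recover absolute units. This is a visualization /
#' interchange format: the dense-matrix TSV format is the lossless one used
#' quantitatively.
#'
#' @param grid Numeric matrix.
#' @param path File path.
#' @param max_value Intensity mapped to white; defaults to the grid maximum
#'   (an all-zero grid uses 1).
#' @return `write_map_png` returns `max_value` invisibly; `read_map_png`
#'   returns the matrix rescaled by `max_value`.
#' @export
write_map_png <- function(grid, path, max_value = NULL) {
  g <- unclass(as_grid(grid))
  if (is.null(max_value)) max_value <- max(g, 1e-300)
  png::writePNG(pmin(g / max_value, 1), path, dpi = NULL)
  invisible(max_value)
}

#' @rdname write_map_png
#' @export
read_map_png <- function(path, max_value = 1) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  img * max_value
}

#' Read and write a face mask as 1-bit style PNG
#'
#' @param mask A [face_mask()] or logical matrix.
#' @param path File path.
#' @return `read_mask_png` returns a [face_mask()].
#' @export
write_mask_png <- function(mask, path) {
  m <- if (inherits(mask, "face_mask")) mask$mask else mask
  png::writePNG(m * 1, path, dpi = NULL)
  invisible(path)
}

#' @rdname write_mask_png
#' @export
read_mask_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  face_mask(img > 0.5)
}

#' Read and write fixation tables
#'
#' Delimited text with header
#' `participant_id, group, image_id, x, y, onset_ms, duration_ms`
#' (`group` optional on read).
#'
#' @param fixations Data frame of fixation events.
#' @param path File path.
#' @return `read_fixations` returns the data frame.
#' @export
write_fixations <- function(fixations, path) write_tsv(fixations, path)

#' @rdname write_fixations
#' @export
read_fixations <- function(path) read_tsv(path)

#' Read and write response tables
#'
#' Delimited text mirroring the study's per-image answer sheet:
#' `participant_id, group, image_id, truth_affected, response_affected,
#' condition_named_correctly`.
#'
#' @param responses Data frame of response records.
#' @param path File path.
#' @return `read_responses` returns the data frame.
#' @export
write_responses <- function(responses, path) write_tsv(responses, path)

#' @rdname write_responses
#' @export
read_responses <- function(path) read_tsv(path)

#' Read and write AOI polygon files
#'
#' JSON with one entry per AOI: `image_id`, `name` and an n x 2 vertex
#' array.
#'
#' @param aois List of [aoi_region()]s.
#' @param path File path.
#' @return `read_aois` returns a list of [aoi_region()]s.
#' @export
write_aois <- function(aois, path) {
  jsonlite::write_json(lapply(aois, function(a)
    list(image_id = a$image_id, name = a$name,
         polygon = unname(a$polygon))), path,
    auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_aois
#' @export
read_aois <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(seq_len(nrow(raw)), function(i)
    aoi_region(raw$image_id[i], raw$name[i],
               matrix(unlist(raw$polygon[i]), ncol = 2)))
}

#' Write a synthetic study to disk in the pipeline's input formats
#'
#' Emits fixations, responses, the face mask, the map manifest with rendered
#' per-participant maps (dense TSV), toy images and a ground-truth JSON
#' sidecar, laid out the way [run_study_dir()] expects.
#'
#' @param study A [generate_toy_study()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "maps"), showWarnings = FALSE)
  dir.create(file.path(dir, "images"), showWarnings = FALSE)
  write_fixations(study$cohort$fixations, file.path(dir, "fixations.tsv"))
  write_responses(study$cohort$responses, file.path(dir, "responses.tsv"))
  write_mask_png(study$layout$mask, file.path(dir, "face_mask.png"))
  maps <- study$cohort$maps
  manifest <- data.frame(file = character(0), participant_id = character(0),
                         group = character(0), image_id = character(0),
                         stage = character(0))
  for (key in names(maps)) {
    m <- maps[[key]]
    f <- file.path("maps", paste0(gsub("[|]", "_", key), ".tsv"))
    write_map_matrix(m$grid, file.path(dir, f))
    manifest <- rbind(manifest, data.frame(
      file = f, participant_id = m$participant_id, group = m$group,
      image_id = m$image_id, stage = m$stage))
  }
  write_tsv(manifest, file.path(dir, "map_manifest.tsv"))
  for (iid in names(study$bundle$images))
    write_map_matrix(study$bundle$images[[iid]],
                     file.path(dir, "images", paste0(iid, ".tsv")))
  jsonlite::write_json(list(
    seed = study$seed, shape = study$layout$shape, radius = study$radius,
    images = study$layout$images,
    truth = as.list(study$bundle$truth),
    labels = study$bundle$labels,
    feature_regions = lapply(study$layout$feature_regions, function(fr)
      list(center = unname(fr$center), radius = fr$radius)),
    landmarks = lapply(study$layout$landmarks, unname),
    n_models = length(study$bundle$classifiers),
    clf_resolution = study$bundle$resolution,
    clf_temperature = study$bundle$temperature),
    file.path(dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Load a synthetic study previously written with [write_study()]
#'
#' Rebuilds the in-memory study object, including the deterministic toy
#' classifiers (reconstructed from the ground-truth seed).
#'
#' @param dir Study directory.
#' @return A `toy_study`-shaped list.
#' @export
read_study <- function(dir) {
  gt <- jsonlite::read_json(file.path(dir, "ground_truth.json"),
                            simplifyVector = TRUE)
  fixations <- read_fixations(file.path(dir, "fixations.tsv"))
  responses <- read_responses(file.path(dir, "responses.tsv"))
  mask <- read_mask_png(file.path(dir, "face_mask.png"))
  manifest <- read_tsv(file.path(dir, "map_manifest.tsv"))
  maps <- list()
  for (i in seq_len(nrow(manifest))) {
    r <- manifest[i, ]
    maps[[paste(r$participant_id, r$image_id, sep = "|")]] <-
      attention_map(read_map_matrix(file.path(dir, r$file)),
                    r$participant_id, r$group, r$image_id, r$stage)
  }
  layout <- list(
    shape = as.integer(gt$shape),
    landmarks = lapply(gt$landmarks, function(l)
      c(x = l[[1]], y = l[[2]])),
    mask = mask,
    images = data.frame(image_id = gt$images$image_id,
                        affected = gt$images$affected,
                        stringsAsFactors = FALSE),
    feature_regions = lapply(gt$feature_regions, function(fr)
      list(center = c(x = fr$center[[1]], y = fr$center[[2]]),
           radius = fr$radius)))
  class(layout) <- "face_layout"
  image_files <- file.path(dir, "images",
                           paste0(layout$images$image_id, ".tsv"))
  images <- stats::setNames(lapply(image_files, read_map_matrix),
                            layout$images$image_id)
  bundle <- toy_classifier_bundle(
    layout, seed = gt$seed, resolution = gt$clf_resolution,
    n_models = gt$n_models, temperature = gt$clf_temperature)
  bundle$images <- images
  structure(list(layout = layout,
                 cohort = list(fixations = fixations, responses = responses,
                               maps = maps),
                 bundle = bundle, radius = gt$radius, seed = gt$seed),
            class = "toy_study")
}
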