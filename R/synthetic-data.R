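# Synthetic-study generator: face layouts, group-specific fixation streams,
# response tables and toy-classifier prototypes with known ground truth, so
# every pipeline stage is testable without any recorded eye-tracking data.

LANDMARK_FRACS <- list(
  left_eye  = c(0.36, 0.40), right_eye = c(0.64, 0.40),
  nose      = c(0.50, 0.55), mouth     = c(0.50, 0.70),
  left_ear  = c(0.18, 0.48), right_ear = c(0.82, 0.48),
  forehead  = c(0.50, 0.24), chin      = c(0.50, 0.86))

# Candidate centres for condition-specific dysmorphic-feature regions,
# as (x, y) fractions of the frame.
FEATURE_SPOT_FRACS <- list(
  left_brow  = c(0.36, 0.33), right_brow   = c(0.64, 0.33),
  philtrum   = c(0.50, 0.63), nasal_bridge = c(0.50, 0.46),
  left_jaw   = c(0.36, 0.80), right_jaw    = c(0.64, 0.80),
  left_cheek = c(0.30, 0.60), right_cheek  = c(0.70, 0.60),
  ear_left   = c(0.20, 0.50), ear_right    = c(0.80, 0.50),
  forehead_c = c(0.50, 0.22), chin_tip     = c(0.50, 0.88))

CONDITION_IDS <- c("22q11DS", "BWS", "CdLS", "DS", "KS",
                   "NS", "PWS", "RSTS1", "WHS", "WS")

ellipse_mask <- function(shape, cx, cy, ax, ay) {
  H <- shape[1]; W <- shape[2]
  x <- matrix(rep(seq_len(W) - 1, each = H), H, W)
  y <- matrix(rep(seq_len(H) - 1, times = W), H, W)
  ((x - cx) / ax)^2 + ((y - cy) / ay)^2 <= 1
}

#' Generate a synthetic face layout
#'
#' A deterministic (per seed) stand-in for the study's standardised face
#' images: named landmark centres (eyes, nose, mouth, ears, forehead, chin)
#' at canonical positions with a small seed-specific jitter, an elliptical
#' face mask covering roughly half the frame, and one condition-specific
#' feature region per affected image, drawn from a bank of plausible
#' dysmorphic-feature locations (brows, philtrum, jaw, ears, ...).
#'
#' @param seed Integer seed.
#' @param shape Frame `c(H, W)`; default 720 x 720, the resolution floor of
#'   the study images.
#' @param n_affected,n_unaffected Number of affected / unaffected images
#'   (defaults 10 and 6, the study's image set).
#' @param feature_radius_frac Feature-region disc radius as a fraction of
#'   `min(shape)` (default 0.12, about the footprint of an orbital or
#'   perioral feature on a standardised face crop).
#' @return An object of class `face_layout`: list with `shape`, `landmarks`
#'   (named list of (x, y)), `mask` (a [face_mask()]), `images` (data frame
#'   `image_id`, `affected`) and `feature_regions` (named list of
#'   `list(center, radius)` for affected images).
#' @export
generate_layout <- function(seed = 1L, shape = c(720L, 720L),
                            n_affected = 10L, n_unaffected = 6L,
                            feature_radius_frac = 0.12) {
  H <- as.integer(shape[1]); W <- as.integer(shape[2])
  md <- min(H, W)
  with_seed(mix_seed(seed, "layout"), {
    landmarks <- lapply(LANDMARK_FRACS, function(fr) {
      c(x = fr[1] * W + stats::rnorm(1, 0, 0.01 * W),
        y = fr[2] * H + stats::rnorm(1, 0, 0.01 * H))
    })
    mask <- face_mask(ellipse_mask(c(H, W), 0.5 * W, 0.55 * H,
                                   0.37 * W, 0.46 * H))
    ids_aff <- if (n_affected <= length(CONDITION_IDS))
      CONDITION_IDS[seq_len(n_affected)]
    else c(CONDITION_IDS, sprintf("COND%02d", seq_len(n_affected - 10L)))
    ids_un <- if (n_unaffected > 0) sprintf("UNAFF%d", seq_len(n_unaffected))
      else character(0)
    spots <- sample(names(FEATURE_SPOT_FRACS))
    feature_regions <- stats::setNames(lapply(seq_along(ids_aff), function(i) {
      fr <- FEATURE_SPOT_FRACS[[spots[(i - 1L) %% length(spots) + 1L]]]
      list(center = c(x = fr[1] * W + stats::rnorm(1, 0, 0.015 * W),
                      y = fr[2] * H + stats::rnorm(1, 0, 0.015 * H)),
           radius = feature_radius_frac * md)
    }), ids_aff)
    images <- data.frame(
      image_id = c(ids_aff, ids_un),
      affected = rep(c(TRUE, FALSE), c(length(ids_aff), length(ids_un))),
      stringsAsFactors = FALSE)
    structure(list(shape = c(H, W), landmarks = landmarks, mask = mask,
                   images = images, feature_regions = feature_regions),
              class = "face_layout")
  })
}

#' Define a group gaze profile
#'
#' Describes how a participant group distributes fixations: a mixture over
#' the face landmarks plus the image's condition-feature region, a spatial
#' spread per fixation, a mean fixation count per 7-second trial, an
#' idiosyncrasy scale (each participant gets a fixed gaze offset and a
#' jitter of the mixture weights), and the group's probability of answering
#' the affected/unaffected question correctly.
#'
#' @param weights Named nonnegative weights over
#'   `names(gazemetrics:::LANDMARK_FRACS)` plus `"feature"`, summing to 1
#'   (within 1e-9). For images without a feature region the `"feature"`
#'   weight is re-spread proportionally over the landmarks.
#' @param sigma_frac Per-fixation spatial spread as a fraction of
#'   `min(shape)` (default 0.045).
#' @param n_fixations Mean fixations per trial (default 18, about 2.5 per
#'   second over a 7 s viewing window).
#' @param idiosyncrasy Participant idiosyncrasy scale (default 0.03): gaze
#'   offsets have sd `idiosyncrasy * min(shape)` pixels and log-weights are
#'   jittered with sd `4 * idiosyncrasy`.
#' @param accuracy Probability of a correct affected/unaffected response.
#' @return An object of class `gaze_profile`.
#' @export
gaze_profile <- function(weights, sigma_frac = 0.045, n_fixations = 18,
                         idiosyncrasy = 0.03, accuracy = 0.8) {
  need <- c(names(LANDMARK_FRACS), "feature")
  if (!all(names(weights) %in% need))
    stop("unknown weight names: ",
         paste(setdiff(names(weights), need), collapse = ", "))
  w <- stats::setNames(rep(0, length(need)), need)
  w[names(weights)] <- weights
  if (any(w < 0) || abs(sum(w) - 1) > 1e-9)
    stop("weights must be nonnegative and sum to 1")
  if (accuracy < 0 || accuracy > 1) stop("accuracy must be in [0, 1]")
  structure(list(weights = w, sigma_frac = sigma_frac,
                 n_fixations = n_fixations, idiosyncrasy = idiosyncrasy,
                 accuracy = accuracy),
            class = "gaze_profile")
}

#' Default clinician and non-clinician gaze profiles
#'
#' Both groups concentrate on the eyes, nose and mouth (the common human
#' face-viewing bias); clinicians allocate substantially more attention to
#' the condition-specific feature region, and the accuracies default to the
#' study's observed group rates (85.6% and 76.9%).
#'
#' @return Named list with `clinician` and `nonclinician` [gaze_profile()]s.
#' @export
default_profiles <- function() {
  list(
    clinician = gaze_profile(
      c(left_eye = 0.17, right_eye = 0.17, nose = 0.13, mouth = 0.11,
        left_ear = 0.04, right_ear = 0.04, forehead = 0.04, chin = 0.04,
        feature = 0.26),
      accuracy = 0.856),
    nonclinician = gaze_profile(
      c(left_eye = 0.24, right_eye = 0.24, nose = 0.18, mouth = 0.16,
        left_ear = 0.03, right_ear = 0.03, forehead = 0.02, chin = 0.02,
        feature = 0.08),
      accuracy = 0.769))
}

region_centers <- function(layout, image_id) {
  cen <- lapply(layout$landmarks, function(l) unname(l))
  fr <- layout$feature_regions[[image_id]]
  if (!is.null(fr)) cen$feature <- unname(fr$center)
  cen
}

participant_traits <- function(profile, layout, pseed) {
  md <- min(layout$shape)
  with_seed(pseed, {
    offset <- stats::rnorm(2, 0, profile$idiosyncrasy * md)
    logw <- log(pmax(profile$weights, 1e-12)) +
      stats::rnorm(length(profile$weights), 0, 4 * profile$idiosyncrasy)
    w <- exp(logw); w[profile$weights == 0] <- 0
    list(offset = offset, weights = w / sum(w))
  })
}

simulate_trial <- function(profile, traits, layout, image_id, fseed,
                           window_ms = 7000) {
  H <- layout$shape[1]; W <- layout$shape[2]
  md <- min(H, W)
  cen <- region_centers(layout, image_id)
  w <- traits$weights
  if (is.null(cen$feature)) {
    w <- w[names(w) != "feature"]
    w <- w / sum(w)
  }
  with_seed(fseed, {
    n_fix <- max(1L, stats::rpois(1, profile$n_fixations))
    reg <- sample(names(w), n_fix, replace = TRUE, prob = w)
    sigma <- profile$sigma_frac * md
    xy <- t(vapply(reg, function(r) {
      p <- cen[[r]] + traits$offset + stats::rnorm(2, 0, sigma)
      c(min(max(round(p[1]), 0), W - 1), min(max(round(p[2]), 0), H - 1))
    }, numeric(2)))
    total <- 0.85 * window_ms
    raw <- stats::rgamma(n_fix, shape = 2, rate = 1)
    dur <- pmax(1, floor(total * raw / sum(raw)))
    gap <- max(0, (window_ms - sum(dur))) / (n_fix + 1)
    onset <- floor(cumsum(c(gap, utils::head(dur, -1) + gap)))
    # guard: keep every fixation inside the viewing window
    over <- onset + dur > window_ms
    dur[over] <- pmax(1, window_ms - onset[over])
    data.frame(x = xy[, 1], y = xy[, 2],
               onset_ms = onset, duration_ms = dur)
  })
}

#' Generate a synthetic participant cohort
#'
#' Draws, for every participant and image, a fixation stream from the
#' group's gaze mixture (perturbed by a fixed participant-specific offset
#' and weight jitter), renders attention maps through
#' [render_from_fixations()], and draws affected/unaffected responses with
#' the group's accuracy. Every stream is reproducible from `seed`, and each
#' participant has an independent substream, so enlarging the cohort never
#' perturbs existing participants.
#'
#' @param layout A [generate_layout()] result.
#' @param n_clin,n_nonclin Participants per group (study design: 22 + 22).
#' @param clin_profile,nonclin_profile [gaze_profile()]s; default
#'   [default_profiles()].
#' @param seed Integer master seed.
#' @param radius Rendering kernel radius in pixels, passed to
#'   [render_from_fixations()] (default 25, the study's eye-tracking
#'   radius at 720-pixel scale).
#' @param window_ms Viewing window per image (default 7000 ms).
#' @param render If `TRUE` (default) renders per-participant attention
#'   maps; set `FALSE` to produce only fixations and responses (the maps
#'   for a full 720-pixel 44-participant study occupy several GB).
#' @return List with `fixations` (data frame), `responses` (data frame) and
#'   `maps` (named list `"<participant>|<image>"` of `attention_map`s, or
#'   `NULL` when `render = FALSE`).
#' @export
generate_cohort <- function(layout, n_clin = 22L, n_nonclin = 22L,
                            clin_profile = default_profiles()$clinician,
                            nonclin_profile = default_profiles()$nonclinician,
                            seed = 1L, radius = 25, window_ms = 7000,
                            render = TRUE) {
  stopifnot(n_clin >= 1L, n_nonclin >= 1L)
  groups <- list(clinician = list(n = n_clin, profile = clin_profile),
                 nonclinician = list(n = n_nonclin, profile = nonclin_profile))
  fix_list <- list(); resp_list <- list()
  maps <- if (render) list() else NULL
  for (gname in names(groups)) {
    g <- groups[[gname]]
    missing_feature <- setdiff(
      names(g$profile$weights)[g$profile$weights > 0 &
                               names(g$profile$weights) != "feature"],
      names(layout$landmarks))
    if (length(missing_feature))
      stop("profile references regions absent from the layout: ",
           paste(missing_feature, collapse = ", "))
    for (i in seq_len(g$n)) {
      pid <- sprintf("%s%02d", if (gname == "clinician") "C" else "N", i)
      traits <- participant_traits(g$profile, layout,
                                   mix_seed(seed, gname, i, "traits"))
      for (j in seq_len(nrow(layout$images))) {
        iid <- layout$images$image_id[j]
        trial <- simulate_trial(g$profile, traits, layout, iid,
                                mix_seed(seed, gname, i, iid), window_ms)
        trial <- cbind(participant_id = pid, group = gname, image_id = iid,
                       trial, stringsAsFactors = FALSE)
        fix_list[[length(fix_list) + 1L]] <- trial
        truth <- layout$images$affected[j]
        resp <- with_seed(mix_seed(seed, gname, i, iid, "resp"), {
          ok <- stats::runif(1) < g$profile$accuracy
          named <- if (truth && ok) stats::runif(1) <
            (if (gname == "clinician") 0.35 else 0.08) else FALSE
          list(ok = ok, named = named)
        })
        resp_list[[length(resp_list) + 1L]] <- data.frame(
          participant_id = pid, group = gname, image_id = iid,
          truth_affected = truth,
          response_affected = if (resp$ok) truth else !truth,
          condition_named_correctly = if (truth) resp$named else NA,
          stringsAsFactors = FALSE)
        if (render)
          maps[[paste(pid, iid, sep = "|")]] <-
            render_from_fixations(trial, layout$shape, radius = radius,
                                  group = gname)
      }
    }
  }
  list(fixations = do.call(rbind, fix_list),
       responses = do.call(rbind, resp_list),
       maps = maps)
}

gaussian_bump <- function(shape, center, radius) {
  H <- shape[1]; W <- shape[2]
  x <- matrix(rep(seq_len(W) - 1, each = H), H, W)
  y <- matrix(rep(seq_len(H) - 1, times = W), H, W)
  d2 <- (x - center[1])^2 + (y - center[2])^2
  b <- exp(-d2 / (2 * (radius / 2)^2))
  b[d2 > radius^2] <- 0
  b
}

#' Build toy face images and classifier prototypes for a layout
#'
#' The base face is a flat ellipse with soft bumps at the landmarks; each
#' affected image adds a stronger bump inside its condition-feature region.
#' Classifier prototypes are the ideal image per label, so the prototypes of
#' two labels differ only inside feature regions: occluding anything else
#' changes all label distances equally and yields exactly zero saliency,
#' which makes the truly salient region known by construction. Each of the
#' `n_models` ensemble members adds one shared (per-model) noise field to
#' every prototype, preserving that property.
#'
#' @param layout A [generate_layout()] result.
#' @param seed Integer seed for the per-model noise fields.
#' @param resolution Classifier input side length; `NULL` (default) keeps
#'   prototypes at the layout's native resolution so no resizing occurs.
#' @param n_models Ensemble size (default 5, one per cross-validation fold
#'   in the emulated design).
#' @param temperature Softmax temperature for [prototype_classifier()]
#'   (default 8e-4 on the MSE scale, sharp enough that occluding a box which
#'   spares the discriminative bump leaves the prediction essentially
#'   unchanged).
#' @return List with `images` (named list of full-resolution matrices, one
#'   per image id), `classifiers` (list of `n_models`
#'   [prototype_classifier()]s), `labels` and `truth` (named label per
#'   image id).
#' @export
toy_classifier_bundle <- function(layout, seed = 1L, resolution = NULL,
                                  n_models = 5L, temperature = 8e-4) {
  H <- layout$shape[1]; W <- layout$shape[2]
  base <- 0.15 + 0.45 * ellipse_mask(layout$shape, 0.5 * W, 0.55 * H,
                                     0.37 * W, 0.46 * H)
  for (lm in layout$landmarks)
    base <- base + 0.18 * gaussian_bump(layout$shape, lm, 0.05 * min(H, W))
  images <- list()
  truth <- character(0)
  aff_ids <- names(layout$feature_regions)
  for (j in seq_len(nrow(layout$images))) {
    iid <- layout$images$image_id[j]
    img <- base
    if (layout$images$affected[j]) {
      fr <- layout$feature_regions[[iid]]
      img <- img + 0.6 * gaussian_bump(layout$shape, fr$center, fr$radius)
      truth[iid] <- iid
    } else truth[iid] <- "unaffected"
    images[[iid]] <- img
  }
  labels <- c(aff_ids, "unaffected")
  pshape <- if (is.null(resolution)) c(H, W)
    else if (length(resolution) == 2L) as.integer(resolution)
    else rep(as.integer(resolution), 2L)
  proto0 <- stats::setNames(lapply(labels, function(l) {
    nn_resize(if (l == "unaffected") base else images[[l]], pshape)
  }), labels)
  classifiers <- lapply(seq_len(n_models), function(m) {
    noise <- with_seed(mix_seed(seed, "model", m), {
      matrix(stats::rnorm(prod(pshape), 0, 0.004), pshape[1], pshape[2])
    })
    prototype_classifier(lapply(proto0, function(p) p + noise),
                         temperature = temperature)
  })
  list(images = images, classifiers = classifiers, labels = labels,
       truth = truth, resolution = pshape,
       temperature = temperature, seed = seed)
}

#' Generate a complete desk-scale synthetic study
#'
#' Bundles a face layout, a participant cohort with rendered attention maps,
#' toy-classifier prototypes whose discriminative regions coincide with the
#' layout's feature regions, and the ground-truth labels: the end-to-end
#' fixture every pipeline stage can run on. The default geometry is the
#' study design scaled by one third (240 x 240 frame, kernel radius 8,
#' 8 + 8 participants, 5 affected + 3 unaffected images) so a full pipeline
#' run stays desk-sized; pass study-scale arguments for larger simulations.
#'
#' @param seed Integer master seed.
#' @param shape Frame shape (default `c(240, 240)`).
#' @param n_clin,n_nonclin Participants per group (default 8 each).
#' @param n_affected,n_unaffected Image counts (default 5 and 3).
#' @param radius Rendering kernel radius (default 8, i.e. the study's 25 px
#'   at one-third scale).
#' @param clf_resolution Toy classifier input resolution (default `NULL`,
#'   i.e. the layout's native resolution).
#' @param n_models Ensemble size (default 5).
#' @param clin_profile,nonclin_profile Optional profile overrides.
#' @return An object of class `toy_study`: list with `layout`, `cohort`
#'   (fixations, responses, maps), `bundle` (toy classifier bundle),
#'   `radius` and `seed`.
#' @export
generate_toy_study <- function(seed = 1L, shape = c(240L, 240L),
                               n_clin = 8L, n_nonclin = 8L,
                               n_affected = 5L, n_unaffected = 3L,
                               radius = 8, clf_resolution = NULL,
                               n_models = 5L,
                               clin_profile = default_profiles()$clinician,
                               nonclin_profile = default_profiles()$nonclinician) {
  layout <- generate_layout(seed, shape, n_affected, n_unaffected)
  cohort <- generate_cohort(layout, n_clin, n_nonclin,
                            clin_profile, nonclin_profile,
                            seed = seed, radius = radius)
  bundle <- toy_classifier_bundle(layout, seed = seed,
                                  resolution = clf_resolution,
                                  n_models = n_models)
  structure(list(layout = layout, cohort = cohort, bundle = bundle,
                 radius = radius, seed = seed),
            class = "toy_study")
}
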