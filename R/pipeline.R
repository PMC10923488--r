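# Study orchestration: preprocessing, per-image subgrouping, saliency,
# comparisons, random-effects pooling and report tables.

PAIRS <- c("clin_success_vs_saliency",
           "clin_success_vs_nonclin_success",
           "clin_success_vs_underperforming",
           "nonclin_success_vs_underperforming")

#' Study configuration
#'
#' @param low,high Noise-threshold specs for the two levels; defaults are
#'   coverage fractions 0.07 and 0.035 of the face region, matching the
#'   observed human-map coverages (6-8% at the low threshold, 3-4% at the
#'   high threshold).
#' @param smooth_kernel Odd box-filter width in pixels (default 15 at
#'   720-pixel study scale; scale proportionally for smaller frames).
#' @param occlusion An [occlusion_config()] (default box 20, stride 10).
#' @param B Bootstrap replicates per comparison cell (default 200 for
#'   pipeline runs; [bootstrap_sd()] itself defaults to 1000).
#' @param seed Master seed for the bootstrap substreams.
#' @param eps KL smoothing constant (`NULL` = data-scaled default).
#' @param min_subgroup Minimum participants per subgroup for a comparison
#'   (default 2, the bootstrap minimum); smaller cells are skipped and
#'   logged.
#' @param pairs Subset of the supported comparison pairs to run.
#' @param self_consistency Also compute each participant's affected-versus-
#'   unaffected aggregate-map consistency (default `TRUE`).
#' @return An object of class `study_config`.
#' @export
study_config <- function(low = threshold_spec("coverage_fraction", 0.07),
                         high = threshold_spec("coverage_fraction", 0.035),
                         smooth_kernel = 15L,
                         occlusion = occlusion_config(),
                         B = 200L, seed = 1L, eps = NULL,
                         min_subgroup = 2L,
                         pairs = PAIRS,
                         self_consistency = TRUE) {
  pairs <- match.arg(pairs, PAIRS, several.ok = TRUE)
  structure(list(low = low, high = high, smooth_kernel = smooth_kernel,
                 occlusion = occlusion, B = as.integer(B),
                 seed = as.integer(seed), eps = eps,
                 min_subgroup = as.integer(min_subgroup), pairs = pairs,
                 self_consistency = self_consistency),
            class = "study_config")
}

# Average a list of plain grids, box-smooth, rescale to the pre-smoothing
# max, then coverage/noise threshold. Returns a matrix, or NULL when the
# thresholding is undefined (all-zero map).
prep_group_grid <- function(grids, kernel, spec, mask) {
  avg <- Reduce(`+`, grids) / length(grids)
  pre_max <- max(avg)
  if (pre_max <= 0) return(NULL)
  sm <- if (kernel > 1L) {
    s <- box_filter(avg, kernel)
    s * (pre_max / max(s))
  } else avg
  t <- tryCatch(
    if (spec$mode == "coverage_fraction") coverage_cutoff(sm, mask, spec$value)
    else resolve_cutoff(sm, spec, mask),
    error = function(e) NULL)
  if (is.null(t)) return(NULL)
  if (spec$mode == "coverage_fraction") sm[!mask$mask] <- 0
  sm[sm < t] <- 0
  sm
}

# Shared preprocessing state: map metadata, per-group common attention,
# per-map subtracted grids, and the per-image subgroup lookup.
study_prep <- function(study, cfg) {
  maps <- study$cohort$maps
  if (is.null(maps)) stop("study has no rendered maps")
  responses <- study$cohort$responses
  responses$correct <- responses$response_affected == responses$truth_affected
  meta <- data.frame(
    key = names(maps),
    participant_id = vapply(maps, function(m) m$participant_id, character(1)),
    group = vapply(maps, function(m) m$group, character(1)),
    image_id = vapply(maps, function(m) m$image_id, character(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  sub_grids <- list(); common <- list()
  for (g in c("clinician", "nonclinician")) {
    keys <- meta$key[meta$group == g]
    if (length(keys) == 0L) next
    cg <- Reduce(`+`, lapply(maps[keys], function(m) unclass(m$grid))) /
      length(keys)
    common[[g]] <- cg
    for (k in keys) {
      d <- unclass(maps[[k]]$grid) - cg
      d[d < 0] <- 0
      sub_grids[[k]] <- d
    }
  }
  subgroup_keys <- function(image_id, group, success) {
    ok <- responses$correct[match(
      paste(meta$participant_id, image_id),
      paste(responses$participant_id, responses$image_id))]
    meta$key[meta$group == group & meta$image_id == image_id &
             !is.na(ok) & ok == success]
  }
  list(meta = meta, sub_grids = sub_grids, common = common,
       responses = responses, subgroup_keys = subgroup_keys)
}

# Ensemble occlusion saliency per affected image; images whose ground-truth
# probability is too close to zero are excluded (not errors).
study_saliency <- function(study, cfg) {
  layout <- study$layout
  aff_ids <- layout$images$image_id[layout$images$affected]
  eligible <- intersect(aff_ids, names(study$bundle$images))
  maps <- list(); excluded <- character(0)
  for (iid in eligible) {
    target <- study$bundle$truth[[iid]]
    res <- tryCatch({
      members <- lapply(study$bundle$classifiers, function(clf)
        occlusion_saliency(study$bundle$images[[iid]], clf, target,
                           cfg$occlusion, image_id = iid))
      ensemble_saliency(members)
    }, error = function(e) e)
    if (inherits(res, "error")) excluded <- c(excluded, iid)
    else maps[[iid]] <- res
  }
  list(maps = maps, excluded = excluded, eligible = eligible)
}

#' Preprocess a study into subgroup-average attention maps
#'
#' Runs the attention-map side of the pipeline only: common-attention
#' subtraction, then per image, group, success status and noise level the
#' subtracted maps are averaged, smoothed and thresholded. Useful for
#' inspecting intermediate maps; [run_study()] performs the same steps
#' internally.
#'
#' @param study A study object.
#' @param cfg A [study_config()].
#' @param out_dir Optional directory: writes each group's common-attention
#'   map and every subgroup average as dense TSV plus a manifest.
#' @return Invisibly, a list with `common` (per group) and `averages`
#'   (data frame manifest with a `grid` list-column of matrices).
#' @export
preprocess_study <- function(study, cfg = study_config(), out_dir = NULL) {
  prep <- study_prep(study, cfg)
  mask <- study$layout$mask
  levels_ <- list(low = cfg$low, high = cfg$high)
  rows <- list()
  for (iid in study$layout$images$image_id)
    for (g in c("clinician", "nonclinician"))
      for (st in c(TRUE, FALSE)) {
        keys <- prep$subgroup_keys(iid, g, st)
        if (length(keys) == 0L) next
        for (lv in names(levels_)) {
          gr <- prep_group_grid(prep$sub_grids[keys], cfg$smooth_kernel,
                                levels_[[lv]], mask)
          if (is.null(gr)) next
          rows[[length(rows) + 1L]] <- list(
            image_id = iid, group = g,
            status = if (st) "success" else "underperforming",
            level = lv, n = length(keys), grid = gr)
        }
      }
  averages <- data.frame(
    image_id = vapply(rows, `[[`, character(1), "image_id"),
    group = vapply(rows, `[[`, character(1), "group"),
    status = vapply(rows, `[[`, character(1), "status"),
    level = vapply(rows, `[[`, character(1), "level"),
    n = vapply(rows, `[[`, numeric(1), "n"),
    stringsAsFactors = FALSE)
  averages$grid <- lapply(rows, `[[`, "grid")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (g in names(prep$common))
      write_map_matrix(prep$common[[g]],
                       file.path(out_dir, paste0("common_", g, ".tsv")))
    files <- character(nrow(averages))
    for (i in seq_len(nrow(averages))) {
      files[i] <- sprintf("avg_%s_%s_%s_%s.tsv", averages$image_id[i],
                          averages$group[i], averages$status[i],
                          averages$level[i])
      write_map_matrix(averages$grid[[i]], file.path(out_dir, files[i]))
    }
    man <- averages[, c("image_id", "group", "status", "level", "n")]
    man$file <- files
    write_tsv(man, file.path(out_dir, "average_manifest.tsv"))
  }
  invisible(list(common = prep$common, averages = averages))
}

#' Compute ensemble occlusion saliency for every affected image
#'
#' @param study A study object.
#' @param cfg A [study_config()].
#' @param out_dir Optional directory: writes each ensemble saliency map as
#'   dense TSV plus an exclusion log.
#' @return Invisibly, a list with `maps` (named list of `saliency_map`s) and
#'   `excluded` (image ids whose ground-truth probability was too close to
#'   zero for a reliable map).
#' @export
compute_saliency <- function(study, cfg = study_config(), out_dir = NULL) {
  res <- study_saliency(study, cfg)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (iid in names(res$maps))
      write_map_matrix(res$maps[[iid]]$grid,
                       file.path(out_dir, paste0("saliency_", iid, ".tsv")))
    write_tsv(data.frame(image_id = res$excluded,
                         reason = rep("saliency_unreliable",
                                      length(res$excluded))),
              file.path(out_dir, "saliency_exclusions.tsv"))
  }
  invisible(res[c("maps", "excluded")])
}

#' Pool per-image comparison metrics with the random-effects model
#'
#' Applies [random_effects_pool()] to each pair, level and metric of a
#' comparison table, using the squared bootstrap SDs as within-image
#' variances.
#'
#' @param comparisons A comparison data frame as produced by [run_study()]
#'   (columns `pair`, `level`, `iou`, `iou_sd`, `kl`, `kl_sd`).
#' @return Data frame with one row per pair, level and metric.
#' @export
pool_comparisons <- function(comparisons) {
  pool_rows <- list()
  for (pair in unique(comparisons$pair)) {
    for (level in unique(comparisons$level[comparisons$pair == pair])) {
      d <- comparisons[comparisons$pair == pair & comparisons$level == level, ]
      for (metric in c("iou", "kl")) {
        y <- d[[metric]]; v <- d[[paste0(metric, "_sd")]]^2
        ok <- !is.na(y) & !is.na(v)
        if (!any(ok)) next
        m <- random_effects_pool(y[ok], v[ok])
        pool_rows[[length(pool_rows) + 1L]] <- data.frame(
          pair = pair, level = level, metric = metric,
          pooled = m$pooled, se = m$se, ci_lo = m$ci95[1], ci_hi = m$ci95[2],
          tau2 = m$tau2, k = m$k, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(pool_rows)) do.call(rbind, pool_rows) else
    data.frame(pair = character(0), level = character(0),
               metric = character(0), pooled = numeric(0), se = numeric(0),
               ci_lo = numeric(0), ci_hi = numeric(0), tau2 = numeric(0),
               k = integer(0))
}

# One bootstrap pass returning both metric SDs for a cell.
boot_pair_sds <- function(grids, other, kernel, spec, mask, B, seed, eps) {
  n <- length(grids)
  with_seed(seed, {
    idx <- matrix(sample.int(n, n * B, replace = TRUE), nrow = B)
    vals <- apply(idx, 1L, function(ii) {
      g <- prep_group_grid(grids[ii], kernel, spec, mask)
      if (is.null(g)) return(c(NA_real_, NA_real_))
      c(map_iou(g, other),
        tryCatch(symmetric_kl(g, other, eps = eps, mask = mask),
                 error = function(e) NA_real_))
    })
    c(iou_sd = stats::sd(vals[1L, ], na.rm = TRUE),
      kl_sd = stats::sd(vals[2L, ], na.rm = TRUE),
      n_dropped = sum(is.na(vals[1L, ]) | is.na(vals[2L, ])))
  })
}

#' Run the full comparison study
#'
#' Orchestrates the analysis on an in-memory synthetic (or loaded) study:
#' \enumerate{
#'   \item Build each group's common-attention map over all participants and
#'     images, and subtract it from every individual map.
#'   \item Partition participants per image into successful / underperforming
#'     by group (membership varies by image), and build each subgroup's
#'     average map, smoothed and thresholded at both noise levels.
#'   \item Compute ensemble occlusion saliency per affected image for its
#'     ground-truth label, and coverage-match it to the successful-clinician
#'     reference at each level. Images whose target probability is too close
#'     to zero are excluded from saliency comparisons and logged.
#'   \item Emit IoU / symmetric-KL comparison rows (with bootstrap SDs over
#'     participants) for the configured pairs. Human-versus-human pairs are
#'     never coverage-matched; human-versus-saliency always is.
#'   \item Pool each pair's per-image metrics with the DerSimonian-Laird
#'     random-effects model.
#'   \item Tabulate response accuracy and the clinician/non-clinician
#'     chi-square.
#' }
#'
#' @param study A [generate_toy_study()] / [read_study()] object.
#' @param cfg A [study_config()].
#' @param out_dir Optional directory; when given, all result tables are
#'   written there as TSV (deterministically, so reruns are byte-identical).
#' @return List of data frames: `comparisons`, `pooled`, `self_consistency`,
#'   `accuracy_per_image`, `accuracy_overall`, `chisq`, `exclusions`.
#' @export
run_study <- function(study, cfg = study_config(), out_dir = NULL) {
  layout <- study$layout
  mask <- layout$mask
  prep <- study_prep(study, cfg)
  meta <- prep$meta; sub_grids <- prep$sub_grids
  responses <- prep$responses
  levels_ <- list(low = cfg$low, high = cfg$high)
  subgroup_keys <- prep$subgroup_keys
  avg_grid <- function(keys, level) {
    prep_group_grid(sub_grids[keys], cfg$smooth_kernel, levels_[[level]], mask)
  }

  sal_res <- study_saliency(study, cfg)
  sal <- sal_res$maps; sal_excluded <- sal_res$excluded
  sal_images <- sal_res$eligible

  comp_rows <- list(); excl_rows <- list()
  exclude <- function(image_id, pair, level, reason) {
    excl_rows[[length(excl_rows) + 1L]] <<- data.frame(
      image_id = image_id, pair = pair, level = level, reason = reason,
      stringsAsFactors = FALSE)
  }

  pair_sides <- list(
    clin_success_vs_saliency =
      list(a = c("clinician", TRUE), b = "saliency"),
    clin_success_vs_nonclin_success =
      list(a = c("clinician", TRUE), b = c("nonclinician", TRUE)),
    clin_success_vs_underperforming =
      list(a = c("clinician", TRUE), b = c("clinician", FALSE)),
    nonclin_success_vs_underperforming =
      list(a = c("nonclinician", TRUE), b = c("nonclinician", FALSE)))

  for (pair in cfg$pairs) {
    sides <- pair_sides[[pair]]
    eligible <- if (identical(sides$b, "saliency")) sal_images
      else layout$images$image_id
    for (iid in eligible) {
      keys_a <- subgroup_keys(iid, sides$a[1], as.logical(sides$a[2]))
      keys_b <- if (!identical(sides$b, "saliency"))
        subgroup_keys(iid, sides$b[1], as.logical(sides$b[2])) else NULL
      for (level in names(levels_)) {
        if (identical(sides$b, "saliency") && iid %in% sal_excluded) {
          exclude(iid, pair, level, "saliency_unreliable"); next
        }
        if (length(keys_a) < cfg$min_subgroup) {
          exclude(iid, pair, level, "subgroup_a_too_small"); next
        }
        if (!identical(sides$b, "saliency") &&
            length(keys_b) < cfg$min_subgroup) {
          exclude(iid, pair, level, "subgroup_b_too_small"); next
        }
        ga <- avg_grid(keys_a, level)
        if (is.null(ga)) { exclude(iid, pair, level, "all_zero_map_a"); next }
        gb <- if (identical(sides$b, "saliency")) {
          matched <- tryCatch(
            match_coverage(sal[[iid]],
                           attention_map(ga, "GROUP_AVG", "clinician", iid,
                                         paste0("thresholded_", level)),
                           mask),
            error = function(e) NULL)
          if (is.null(matched)) NULL else unclass(matched$grid)
        } else avg_grid(keys_b, level)
        if (is.null(gb)) { exclude(iid, pair, level, "all_zero_map_b"); next }
        iou <- map_iou(ga, gb)
        kl <- tryCatch(symmetric_kl(ga, gb, eps = cfg$eps, mask = mask),
                       error = function(e) NA_real_)
        if (is.na(iou) || is.na(kl)) {
          exclude(iid, pair, level, "metric_undefined"); next
        }
        sds <- boot_pair_sds(sub_grids[keys_a], gb, cfg$smooth_kernel,
                             levels_[[level]], mask, cfg$B,
                             mix_seed(cfg$seed, pair, iid, level),
                             cfg$eps)
        comp_rows[[length(comp_rows) + 1L]] <- data.frame(
          image_id = iid, pair = pair, level = level,
          iou = iou, iou_sd = sds[["iou_sd"]],
          kl = kl, kl_sd = sds[["kl_sd"]],
          n_pixels_a = sum(ga > 0), n_pixels_b = sum(gb > 0),
          n_a = length(keys_a),
          n_b = if (identical(sides$b, "saliency")) NA_integer_
                else length(keys_b),
          stringsAsFactors = FALSE)
      }
    }
  }

  comparisons <- if (length(comp_rows)) do.call(rbind, comp_rows) else
    data.frame(image_id = character(0), pair = character(0),
               level = character(0), iou = numeric(0), iou_sd = numeric(0),
               kl = numeric(0), kl_sd = numeric(0),
               n_pixels_a = integer(0), n_pixels_b = integer(0),
               n_a = integer(0), n_b = integer(0))
  exclusions <- if (length(excl_rows)) do.call(rbind, excl_rows) else
    data.frame(image_id = character(0), pair = character(0),
               level = character(0), reason = character(0))

  # self-consistency: per participant, affected vs unaffected aggregate
  self_rows <- list()
  if (isTRUE(cfg$self_consistency)) {
    aff_set <- layout$images$image_id[layout$images$affected]
    un_set <- layout$images$image_id[!layout$images$affected]
    for (pid in unique(meta$participant_id)) {
      ka <- meta$key[meta$participant_id == pid & meta$image_id %in% aff_set]
      ku <- meta$key[meta$participant_id == pid & meta$image_id %in% un_set]
      if (length(ka) == 0L || length(ku) == 0L) next
      ga <- prep_group_grid(sub_grids[ka], cfg$smooth_kernel, cfg$low, mask)
      gu <- prep_group_grid(sub_grids[ku], cfg$smooth_kernel, cfg$low, mask)
      if (is.null(ga) || is.null(gu)) next
      self_rows[[length(self_rows) + 1L]] <- data.frame(
        participant_id = pid,
        group = meta$group[match(pid, meta$participant_id)],
        iou = map_iou(ga, gu),
        kl = tryCatch(symmetric_kl(ga, gu, eps = cfg$eps, mask = mask),
                      error = function(e) NA_real_),
        stringsAsFactors = FALSE)
    }
  }
  self_consistency <- if (length(self_rows)) do.call(rbind, self_rows) else
    data.frame(participant_id = character(0), group = character(0),
               iou = numeric(0), kl = numeric(0))

  # random-effects pooling per pair x level x metric
  pooled <- pool_comparisons(comparisons)

  acc <- accuracy_table(responses[, c("participant_id", "group", "image_id",
                                      "truth_affected", "response_affected")])
  ov <- acc$overall
  # degenerate tables (a zero margin, e.g. everyone correct) yield NA rather
  # than aborting the run; the approximation warning is expected at toy sizes
  cs <- tryCatch(
    suppressWarnings(
      chi_square_2x2(ov$correct[ov$group == "clinician"],
                     ov$incorrect[ov$group == "clinician"],
                     ov$correct[ov$group == "nonclinician"],
                     ov$incorrect[ov$group == "nonclinician"])),
    error = function(e) list(statistic = NA_real_, p_value = NA_real_))
  chisq <- data.frame(statistic = cs$statistic, p_value = cs$p_value)

  out <- list(comparisons = comparisons, pooled = pooled,
              self_consistency = self_consistency,
              accuracy_per_image = acc$per_image,
              accuracy_overall = acc$overall,
              chisq = chisq, exclusions = exclusions)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(out))
      write_tsv(out[[nm]], file.path(out_dir, paste0(nm, ".tsv")))
  }
  out
}

#' Run the study pipeline from a directory written by [write_study()]
#'
#' @param dir Input study directory.
#' @param cfg A [study_config()].
#' @param out_dir Output directory for result tables (default
#'   `file.path(dir, "results")`).
#' @return The [run_study()] result list, invisibly.
#' @export
run_study_dir <- function(dir, cfg = study_config(),
                          out_dir = file.path(dir, "results")) {
  invisible(run_study(read_study(dir), cfg, out_dir = out_dir))
}
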