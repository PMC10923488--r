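# Response-table accuracy, chi-square group comparison, and
# DerSimonian-Laird random-effects pooling of per-image metrics.

#' Tabulate affected/unaffected response accuracy
#'
#' A response is correct when `response_affected == truth_affected`. Counts
#' are returned per image and group, together with overall per-group
#' percentages.
#'
#' @param records Data frame with columns `participant_id`, `group`
#'   (`"clinician"`/`"nonclinician"`), `image_id`, `truth_affected`,
#'   `response_affected` (logical), and optionally
#'   `condition_named_correctly`. One row per participant-image pair.
#' @return List with `per_image` (image_id, group, correct, incorrect) and
#'   `overall` (group, correct, incorrect, percent_correct).
#' @export
accuracy_table <- function(records) {
  if (nrow(records) == 0L) stop("no response records")
  key <- paste(records$participant_id, records$image_id, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate participant x image response: ",
         sub("\r", " / ", key[anyDuplicated(key)]))
  records$correct <- records$response_affected == records$truth_affected
  per_image <- do.call(rbind, lapply(
    split(records, list(records$image_id, records$group), drop = TRUE),
    function(d) data.frame(image_id = d$image_id[1L], group = d$group[1L],
                           correct = sum(d$correct),
                           incorrect = sum(!d$correct),
                           stringsAsFactors = FALSE)))
  per_image <- per_image[order(per_image$image_id, per_image$group), ]
  rownames(per_image) <- NULL
  overall <- do.call(rbind, lapply(split(records, records$group), function(d) {
    n_ok <- sum(d$correct)
    data.frame(group = d$group[1L], correct = n_ok,
               incorrect = sum(!d$correct),
               percent_correct = 100 * n_ok / nrow(d),
               stringsAsFactors = FALSE)
  }))
  rownames(overall) <- NULL
  stopifnot(sum(per_image$correct + per_image$incorrect) == nrow(records))
  list(per_image = per_image, overall = overall)
}

#' Expand a printed count table into response records
#'
#' Turns per-image correct/incorrect counts (one row per image and group)
#' into individual pseudo-records so they can flow through
#' [accuracy_table()]. Participant identities are synthetic and per-image.
#'
#' @param counts Data frame with columns `image_id`, `group`, `correct`,
#'   `incorrect`, and optionally `truth_affected` (default `TRUE`).
#' @return A response-record data frame.
#' @export
counts_to_records <- function(counts) {
  if (is.null(counts$truth_affected)) counts$truth_affected <- TRUE
  rows <- lapply(seq_len(nrow(counts)), function(i) {
    r <- counts[i, ]
    n <- r$correct + r$incorrect
    if (n == 0L) return(NULL)
    ok <- rep(c(TRUE, FALSE), c(r$correct, r$incorrect))
    data.frame(
      participant_id = sprintf("%s_%s_p%02d", substr(r$group, 1, 4),
                               r$image_id, seq_len(n)),
      group = r$group, image_id = r$image_id,
      truth_affected = r$truth_affected,
      response_affected = ifelse(ok, r$truth_affected, !r$truth_affected),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Pearson chi-square test on a 2 x 2 table
#'
#' No continuity correction is applied; `df = 1`.
#'
#' @param a,b First row of the table (e.g. group 1 correct / incorrect).
#' @param c,d Second row.
#' @return List with `statistic` and `p_value`.
#' @export
chi_square_2x2 <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  if (any(counts < 0)) stop("counts must be nonnegative")
  m <- matrix(counts, nrow = 2L, byrow = TRUE)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0))
    stop("all table margins must be positive")
  ht <- stats::chisq.test(m, correct = FALSE)
  list(statistic = unname(ht$statistic), p_value = unname(ht$p.value))
}

#' DerSimonian-Laird random-effects pooling
#'
#' Pools per-image metric estimates allowing between-image heterogeneity:
#' `tau2 = max(0, (Q - (k - 1)) / C)` from Cochran's Q under inverse-variance
#' weights, then weights `w_i = 1 / (v_i + tau2)`, pooled mean
#' `sum(w y) / sum(w)`, standard error `sum(w)^(-1/2)` and a 95% Wald
#' interval. Estimates are pooled on their raw scale.
#'
#' @param estimates Numeric vector of per-image metric values (length k >= 1).
#' @param variances Matching within-image variances (e.g. bootstrap SD
#'   squared); zeros are floored at 1e-8 to avoid infinite weights.
#' @return An object of class `meta_result`: list with `pooled`, `se`,
#'   `ci95 = c(lo, hi)`, `tau2`, `k`.
#' @export
random_effects_pool <- function(estimates, variances) {
  k <- length(estimates)
  if (k == 0L) stop("no estimates to pool")
  if (length(variances) != k)
    stop("`estimates` and `variances` must have equal length")
  if (any(variances < 0) || any(is.na(variances)))
    stop("variances must be nonnegative and non-missing")
  v <- pmax(variances, 1e-8)
  if (k == 1L) {
    pooled <- estimates[1L]; se <- sqrt(v[1L]); tau2 <- 0
  } else {
    w0 <- 1 / v
    yw <- sum(w0 * estimates) / sum(w0)
    Q <- sum(w0 * (estimates - yw)^2)
    C <- sum(w0) - sum(w0^2) / sum(w0)
    tau2 <- max(0, (Q - (k - 1)) / C)
    w <- 1 / (v + tau2)
    pooled <- sum(w * estimates) / sum(w)
    se <- 1 / sqrt(sum(w))
  }
  structure(list(pooled = pooled, se = se,
                 ci95 = c(pooled - 1.96 * se, pooled + 1.96 * se),
                 tau2 = tau2, k = k),
            class = "meta_result")
}

#' @export
print.meta_result <- function(x, ...) {
  cat(sprintf("RE model (k = %d): %.4f [%.4f, %.4f], se = %.4f, tau^2 = %.4g\n",
              x$k, x$pooled, x$ci95[1], x$ci95[2], x$se, x$tau2))
  invisible(x)
}
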