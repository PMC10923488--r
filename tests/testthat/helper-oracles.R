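# Independent brute-force oracles and small fixture builders. The oracles
# deliberately use naive pixel loops so they share no code path with the
# package implementations they check.

brute_iou <- function(a, b) {
  inter <- 0L; uni <- 0L
  for (i in seq_len(nrow(a))) for (j in seq_len(ncol(a))) {
    pa <- a[i, j] > 0; pb <- b[i, j] > 0
    if (pa && pb) inter <- inter + 1L
    if (pa || pb) uni <- uni + 1L
  }
  if (uni == 0L) NA_real_ else inter / uni
}

brute_symmetric_kl <- function(a, b, eps) {
  sup <- which(a > 0 | b > 0)
  pa <- numeric(0); pb <- numeric(0)
  for (k in sup) { pa <- c(pa, a[k] + eps); pb <- c(pb, b[k] + eps) }
  pa <- pa / sum(pa); pb <- pb / sum(pb)
  kl1 <- 0; kl2 <- 0
  for (k in seq_along(pa)) {
    kl1 <- kl1 + pa[k] * log(pa[k] / pb[k])
    kl2 <- kl2 + pb[k] * log(pb[k] / pa[k])
  }
  (kl1 + kl2) / 2
}

# Exhaustive occlusion: explicit double loop over box offsets, fresh copies,
# direct per-pixel mean accumulation.
brute_occlusion <- function(image, clf, target, box, stride, fill = 0) {
  H <- nrow(image); W <- ncol(image)
  p0 <- clf$predict(image)[[which(clf$labels == target)]]
  total <- matrix(0, H, W); ncov <- matrix(0, H, W)
  for (r0 in seq(0, H - box, by = stride)) {
    for (c0 in seq(0, W - box, by = stride)) {
      occ <- image
      occ[(r0 + 1):(r0 + box), (c0 + 1):(c0 + box)] <- fill
      p <- clf$predict(occ)[[which(clf$labels == target)]]
      d <- p0 - p
      if (d < 0) d <- 0
      for (i in (r0 + 1):(r0 + box)) for (j in (c0 + 1):(c0 + box)) {
        total[i, j] <- total[i, j] + d
        ncov[i, j] <- ncov[i, j] + 1
      }
    }
  }
  out <- matrix(0, H, W)
  for (i in seq_len(H)) for (j in seq_len(W))
    if (ncov[i, j] > 0) out[i, j] <- total[i, j] / ncov[i, j]
  out
}

rand_grid <- function(h, w, density = 0.5) {
  g <- matrix(stats::runif(h * w), h, w)
  g[g < (1 - density)] <- 0
  g
}

full_mask <- function(h, w) face_mask(matrix(TRUE, h, w))

amap <- function(g, pid = "P1", group = "clinician", image = "IMG",
                 stage = "raw") attention_map(g, pid, group, image, stage)

fix_df <- function(x, y, dur, onset = NULL, pid = "P1", image = "IMG") {
  n <- length(x)
  if (is.null(onset)) onset <- seq(0, by = 300, length.out = n)
  data.frame(participant_id = rep(pid, n), image_id = rep(image, n),
             x = x, y = y, onset_ms = onset, duration_ms = dur,
             stringsAsFactors = FALSE)
}

# a tiny classifier whose target probability is a monotone function of the
# mean intensity inside a fixed region R (and nothing else)
region_classifier <- function(H, W, rows, cols) {
  R <- matrix(FALSE, H, W); R[rows, cols] <- TRUE
  classifier_contract(c("target", "other"), function(img) {
    m <- mean(img[R])
    p <- 1 / (1 + exp(-6 * (m - 0.25)))
    c(target = p, other = 1 - p)
  })
}
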