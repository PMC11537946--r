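# separable Gaussian filtering restricted to the valid region (no padding
# bias), used by the SSIM window statistics
gaussian_kernel <- function(size, sigma) {
  x <- seq_len(size) - (size + 1) / 2
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

filter_valid <- function(x, k) {
  n <- length(k)
  nr <- nrow(x) - n + 1L
  nc <- ncol(x) - n + 1L
  # band matrices implementing 1-D valid convolution along each axis
  band <- function(m_out, m_in) {
    b <- matrix(0, m_out, m_in)
    for (i in seq_len(m_out)) b[i, i:(i + n - 1L)] <- k
    b
  }
  band(nr, nrow(x)) %*% x %*% t(band(nc, ncol(x)))
}

#' Structural similarity index between two maps
#'
#' Mean local SSIM over sliding Gaussian-weighted windows, with the
#' canonical constants (11-px window, sigma 1.5, k1 = 0.01, k2 = 0.03).
#'
#' @param a,b Numeric matrices of identical shape.
#' @param window Window size in pixels (odd).
#' @param sigma Gaussian window SD.
#' @param k1,k2 Stabilizing constants.
#' @param L Dynamic range of the data (1 for `[0, 1]` maps).
#' @return Mean SSIM in `[-1, 1]`, with the full local map as attribute
#'   `ssim_map`.
#' @export
ssim <- function(a, b, window = 11L, sigma = 1.5, k1 = 0.01, k2 = 0.03,
                 L = 1) {
  assert_same_shape(a, b)
  if (any(dim(a) < window)) abort("images smaller than the SSIM window")
  k <- gaussian_kernel(window, sigma)
  c1 <- (k1 * L)^2
  c2 <- (k2 * L)^2
  mu_a <- filter_valid(a, k)
  mu_b <- filter_valid(b, k)
  s_aa <- filter_valid(a * a, k) - mu_a^2
  s_bb <- filter_valid(b * b, k) - mu_b^2
  s_ab <- filter_valid(a * b, k) - mu_a * mu_b
  num <- (2 * mu_a * mu_b + c1) * (2 * s_ab + c2)
  den <- (mu_a^2 + mu_b^2 + c1) * (s_aa + s_bb + c2)
  m <- num / den
  structure(mean(m), ssim_map = m)
}

#' Patch-based contrast quality index between two maps
#'
#' Per patch, three terms are computed from plain patch statistics and
#' combined multiplicatively: a contrast-change term
#' `4/pi * atan((s_ab + c) / (s_aa + c))`, a patch (structure) similarity
#' term `(s_ab + c) / (s_a * s_b + c)`, and a mean-luminance term
#' `exp(-|mu_a - mu_b| / L)`. The score is the mean over patches;
#' identical inputs give exactly 1.
#'
#' @param a Reference map; `b` test map (same shape).
#' @param b Test map.
#' @param window Patch size in pixels.
#' @param stride Patch step in pixels.
#' @param L Dynamic range (1 for `[0, 1]` maps).
#' @param c_stab Stabilizing constant (the canonical 3 on a 0-255 scale,
#'   rescaled to the data range).
#' @return Mean PCQI score, with the per-term means attached as
#'   attribute `terms` (`contrast`, `structure`, `luminance`).
#' @export
pcqi <- function(a, b, window = 11L, stride = 4L, L = 1,
                 c_stab = 3 * (L / 255)^2) {
  assert_same_shape(a, b)
  if (any(dim(a) < window)) abort("images smaller than the PCQI window")
  starts_r <- seq(1L, nrow(a) - window + 1L, by = stride)
  starts_c <- seq(1L, ncol(a) - window + 1L, by = stride)
  offs <- as.vector(outer(0:(window - 1L), (0:(window - 1L)) * nrow(a), "+"))
  anchors <- as.vector(outer(starts_r, (starts_c - 1L) * nrow(a), "+"))
  idx <- outer(anchors, offs, "+")   # patches x window^2
  pa <- matrix(a[idx], nrow(idx))
  pb <- matrix(b[idx], nrow(idx))
  mu_a <- rowMeans(pa)
  mu_b <- rowMeans(pb)
  s_aa <- rowMeans(pa * pa) - mu_a^2
  s_bb <- rowMeans(pb * pb) - mu_b^2
  s_ab <- rowMeans(pa * pb) - mu_a * mu_b
  q_c <- (4 / pi) * atan((s_ab + c_stab) / (s_aa + c_stab))
  q_s <- (s_ab + c_stab) / (sqrt(pmax(s_aa, 0) * pmax(s_bb, 0)) + c_stab)
  q_l <- exp(-abs(mu_a - mu_b) / L)
  structure(mean(q_c * q_s * q_l),
            terms = c(contrast = mean(q_c), structure = mean(q_s),
                      luminance = mean(q_l)))
}

#' Embed a set of maps into fixed-length feature vectors
#'
#' The default `radial_profile_stats` extractor is deterministic and
#' download-free: 9 intensity quantiles, mean and SD, gradient-magnitude
#' mean and SD, and 6 log-power bins of the radially averaged Fourier
#' spectrum (d = 19). An Inception-style network extractor is not
#' shipped; requesting it raises an error pointing at the fallback.
#'
#' @param maps List of numeric matrices (same size).
#' @param extractor `"radial_profile_stats"` or `"inception_v3_pool3"`.
#' @return An n x d numeric matrix with attribute `extractor`.
#' @export
embed_maps <- function(maps, extractor = c("radial_profile_stats",
                                           "inception_v3_pool3")) {
  extractor <- match.arg(extractor)
  if (extractor == "inception_v3_pool3") {
    abort(paste("the Inception extractor needs pretrained weights that are",
                "not bundled; use extractor = 'radial_profile_stats'"))
  }
  if (length(maps) == 0) abort("`maps` must be a non-empty list")
  feats <- purrr::map(maps, radial_profile_stats)
  out <- do.call(rbind, feats)
  attr(out, "extractor") <- extractor
  out
}

radial_profile_stats <- function(x) {
  q <- quantile(x, probs = seq(0.1, 0.9, by = 0.1), names = FALSE)
  gr <- rbind(diff(x), matrix(0, 1L, ncol(x)))
  gc <- cbind(t(diff(t(x))), matrix(0, nrow(x), 1L))
  g <- sqrt(gr^2 + gc^2)
  p <- Mod(fft(x - mean(x)))^2
  nr <- nrow(x); nc <- ncol(x)
  fr <- pmin(0:(nr - 1), nr - 0:(nr - 1)) / nr
  fc <- pmin(0:(nc - 1), nc - 0:(nc - 1)) / nc
  rad <- sqrt(outer(fr^2, fc^2, "+"))
  bins <- cut(rad, breaks = seq(0, 0.75, length.out = 7), include.lowest = TRUE)
  spec <- tapply(p, bins, sum)
  spec[is.na(spec)] <- 0
  c(q, mean(x), sd(x), mean(g), sd(g), log10(as.numeric(spec) + 1e-12))
}

#' Frechet distance between two embedded image sets
#'
#' Fits a Gaussian to each feature set and returns the squared
#' Wasserstein-2 distance
#' `||mu_A - mu_B||^2 + Tr(S_A + S_B - 2 (S_A S_B)^{1/2})`.
#' Covariances are regularized by `+ eps I` against degeneracy; the trace
#' of the matrix square root is computed through the symmetric
#' factorization `sqrt(S_A)^T S_B sqrt(S_A)`.
#'
#' @param feats_a,feats_b n x d feature matrices (n >= 2 each).
#' @param eps Covariance ridge (default 1e-6).
#' @return Non-negative distance, symmetric in its arguments.
#' @export
frechet_distance <- function(feats_a, feats_b, eps = 1e-6) {
  if (!is.matrix(feats_a)) feats_a <- as.matrix(feats_a)
  if (!is.matrix(feats_b)) feats_b <- as.matrix(feats_b)
  if (nrow(feats_a) < 2 || nrow(feats_b) < 2) {
    abort("each feature set needs at least 2 rows")
  }
  if (ncol(feats_a) != ncol(feats_b)) {
    abort("feature sets must have the same dimensionality")
  }
  d <- ncol(feats_a)
  mu_a <- colMeans(feats_a)
  mu_b <- colMeans(feats_b)
  s_a <- stats::cov(feats_a) + diag(eps, d)
  s_b <- stats::cov(feats_b) + diag(eps, d)
  ea <- eigen(s_a, symmetric = TRUE)
  sqrt_a <- ea$vectors %*% (sqrt(pmax(ea$values, 0)) * t(ea$vectors))
  m <- sqrt_a %*% s_b %*% sqrt_a
  ev <- eigen((m + t(m)) / 2, symmetric = TRUE, only.values = TRUE)$values
  tr_sqrt <- sum(sqrt(pmax(ev, 0)))
  max(sum((mu_a - mu_b)^2) + sum(diag(s_a)) + sum(diag(s_b)) - 2 * tr_sqrt, 0)
}

#' Pairwise quality metrics over a paired cohort
#'
#' Computes SSIM and PCQI for every subject's GT-TR image pair.
#'
#' @param manifest Manifest tibble with both arms.
#' @param metrics Subset of `c("ssim", "pcqi")`.
#' @param config A [run_config()].
#' @return Tibble with one row per paired subject (`subject_id`, `group`,
#'   `fov`, requested metric columns). Subjects missing either arm are
#'   dropped.
#' @export
quality_pairs <- function(manifest, metrics = c("ssim", "pcqi"),
                          config = run_config()) {
  metrics <- match.arg(metrics, several.ok = TRUE)
  gt <- manifest[manifest$arm == "GT", ]
  tr <- manifest[manifest$arm == "TR", ]
  ids <- intersect(gt$subject_id, tr$subject_id)
  rows <- purrr::map(ids, function(sid) {
    i <- which(gt$subject_id == sid)[1L]
    j <- which(tr$subject_id == sid)[1L]
    a <- manifest_map(gt, i)
    b <- manifest_map(tr, j)
    out <- tibble::tibble(subject_id = sid, group = gt$group[i],
                          fov = gt$fov[i])
    if ("ssim" %in% metrics) {
      out$ssim <- as.numeric(ssim(a, b, window = config$ssim_window))
    }
    if ("pcqi" %in% metrics) {
      out$pcqi <- as.numeric(pcqi(a, b, window = config$pcqi_window,
                                  stride = config$pcqi_stride))
    }
    out
  })
  dplyr::bind_rows(rows)
}

#' Set-level Frechet distance between the GT and TR arms
#'
#' Embeds all images of each arm within each stratum and reports one
#' Frechet distance per stratum, mirroring per-dataset FID reporting.
#'
#' @param manifest Manifest tibble with both arms.
#' @param by Stratifying columns (default `"fov"`).
#' @param extractor Embedding extractor, see [embed_maps()].
#' @return Tibble with the stratum columns, `n_gt`, `n_tr` and `fid`.
#' @export
quality_fid <- function(manifest, by = "fov",
                        extractor = "radial_profile_stats") {
  strata <- dplyr::distinct(manifest[, by, drop = FALSE])
  rows <- purrr::map(seq_len(nrow(strata)), function(s) {
    sel <- rep(TRUE, nrow(manifest))
    for (col in by) sel <- sel & manifest[[col]] == strata[[col]][s]
    sub <- manifest[sel, ]
    gt_idx <- which(sub$arm == "GT")
    tr_idx <- which(sub$arm == "TR")
    maps_gt <- purrr::map(gt_idx, function(i) manifest_map(sub, i))
    maps_tr <- purrr::map(tr_idx, function(i) manifest_map(sub, i))
    fid <- frechet_distance(embed_maps(maps_gt, extractor),
                            embed_maps(maps_tr, extractor))
    dplyr::bind_cols(strata[s, , drop = FALSE],
                     tibble::tibble(n_gt = length(gt_idx),
                                    n_tr = length(tr_idx), fid = fid))
  })
  dplyr::bind_rows(rows)
}
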