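#' Binarize a projection map into a vessel mask
#'
#' Global Otsu by default; a fixed threshold and a local adaptive mean
#' threshold are available. The method and threshold actually used are
#' recorded in the `source` attribute for traceability. A constant image
#' yields an all-false mask with a warning, never an error.
#'
#' @param map Numeric matrix in `[0, 1]` (intensities are rescaled to the
#'   observed maximum if above 1).
#' @param method `"otsu"`, `"fixed"` or `"adaptive"`.
#' @param threshold Threshold for `method = "fixed"`.
#' @param window Smoothing scale (px) for `method = "adaptive"`.
#' @param offset Offset above the local mean for `method = "adaptive"`.
#' @return Logical matrix with attribute `source = list(method, threshold)`.
#' @export
binarize <- function(map, method = c("otsu", "fixed", "adaptive"),
                     threshold = 0.5, window = 25, offset = 0.02) {
  method <- match.arg(method)
  assert_map(map)
  if (max(map) > 1) map <- map / max(map)
  rng <- range(map)
  if (rng[1] == rng[2]) {
    if (method == "otsu") {
      warn("constant-intensity image: returning an all-false mask")
    }
    mask <- matrix(FALSE, nrow(map), ncol(map))
    attr(mask, "source") <- list(method = method, threshold = NA_real_)
    return(mask)
  }
  mask <- switch(method,
    otsu = {
      th <- EBImage::otsu(EBImage::Image(map), range = c(0, 1), levels = 256)
      structure(map > th, th = th)
    },
    fixed = structure(map > threshold, th = threshold),
    adaptive = {
      local_mean <- blur_mat(map, window / 4)
      structure(map > local_mean + offset, th = NA_real_)
    }
  )
  th <- attr(mask, "th")
  attributes(mask) <- NULL
  dim(mask) <- dim(map)
  attr(mask, "source") <- list(method = method, threshold = unname(th))
  mask
}

#' Skeletonize a vessel mask and decompose it into branches
#'
#' Thins the mask to a 1-px-wide 8-connected centerline (Zhang-Suen),
#' marks junction pixels (>= 3 skeleton neighbours) and endpoints, and
#' traces junction-to-junction / junction-to-endpoint paths as branches.
#' Spur branches shorter than `min_branch_len` pixels that terminate in a
#' free endpoint are pruned. Closed loops (cycles with no junction) are
#' kept but flagged.
#'
#' Each branch records its ordered path, a raw 8-connected chain length
#' (`chain_len_px`: 1 per axial step, sqrt(2) per diagonal), a
#' corner-cut geodesic length (`geodesic_len_px`: the path resampled at
#' every 5th pixel, which tracks true arc length of smooth curves far
#' better than the staircase chain code), and the straight-line endpoint
#' distance (`euclid_len_px`). Thinning retracts the centerline by about
#' half the vessel width at every free end; both length measures are
#' therefore extended at free endpoints by the mask's distance-transform
#' value along the local tangent, restoring the full centerline span.
#'
#' @param mask Logical matrix (vessel = TRUE).
#' @param min_branch_len Spur-pruning length in pixels (default 3).
#' @return An `octa_skeleton` list: `skeleton` (logical matrix),
#'   `branches` (tibble with path list-column and per-branch lengths),
#'   `junctions`, `endpoints` (coordinate matrices), `n_pruned`.
#' @export
skeletonize_mask <- function(mask, min_branch_len = 3) {
  if (!is.logical(mask) || !is.matrix(mask)) {
    abort("`mask` must be a logical matrix")
  }
  skel <- cpp_thin(mask)
  traced <- cpp_trace_branches(skel)
  paths <- traced$paths
  closed <- traced$closed
  empty <- tibble::tibble(branch_id = integer(), path = list(),
                          closed = logical(), chain_len_px = double(),
                          geodesic_len_px = double(),
                          euclid_len_px = double())
  if (length(paths) == 0) {
    return(structure(list(skeleton = skel, branches = empty,
                          junctions = traced$junctions,
                          endpoints = traced$endpoints, n_pruned = 0L),
                     class = "octa_skeleton"))
  }
  dt <- as.matrix(EBImage::distmap(EBImage::Image(mask * 1)))
  tip_tangent <- function(p, at_head) {
    n <- nrow(p)
    end <- if (at_head) p[1L, ] else p[n, ]
    inner <- if (at_head) p[min(5L, n), ] else p[max(1L, n - 4L), ]
    u <- end - inner
    nrm <- sqrt(sum(u^2))
    if (nrm == 0) c(0, 0) else u / nrm
  }
  measure <- function(p, free) {
    n <- nrow(p)
    if (n < 2L) {
      return(c(chain = 0, geo = 0, euc = 0))
    }
    ext_h <- if (free[1L]) dt[p[1L, , drop = FALSE]] else 0
    ext_t <- if (free[2L]) dt[p[n, , drop = FALSE]] else 0
    tip_h <- p[1L, ] + tip_tangent(p, TRUE) * ext_h
    tip_t <- p[n, ] + tip_tangent(p, FALSE) * ext_t
    c(chain = chain_length(p),
      geo = resampled_length(p) + ext_h + ext_t,
      euc = sqrt(sum((tip_t - tip_h)^2)))
  }
  meas <- purrr::map2(paths, seq_along(paths), function(p, s) {
    measure(p, traced$free_end[s, ])
  })
  branches <- tibble::tibble(
    branch_id = seq_along(paths),
    path = paths,
    closed = closed,
    chain_len_px = purrr::map_dbl(meas, "chain"),
    geodesic_len_px = purrr::map_dbl(meas, "geo"),
    euclid_len_px = purrr::map_dbl(meas, "euc")
  )
  # prune short spurs: branches with a free endpoint whose pixel count is
  # below the cutoff (junction-to-junction stubs are kept)
  spur <- purrr::map_lgl(seq_along(paths), function(s) {
    nrow(paths[[s]]) < min_branch_len && any(traced$free_end[s, ])
  })
  n_pruned <- sum(spur)
  branches <- branches[!spur, , drop = FALSE]
  structure(list(skeleton = skel, branches = branches,
                 junctions = traced$junctions, endpoints = traced$endpoints,
                 n_pruned = n_pruned),
            class = "octa_skeleton")
}

#' @export
print.octa_skeleton <- function(x, ...) {
  cat(sprintf("<octa_skeleton> %d branches, %d junctions, %d endpoints, %d spurs pruned\n",
              nrow(x$branches), nrow(x$junctions), nrow(x$endpoints),
              x$n_pruned))
  invisible(x)
}

#' Blood vessel density: vessel area over total image area
#'
#' @param mask Logical vessel mask.
#' @return Ratio in `[0, 1]`.
#' @export
compute_bvd <- function(mask) {
  if (length(mask) == 0) abort("`mask` must be non-empty")
  sum(mask) / length(mask)
}

#' Blood vessel caliber: vessel area over centerline length
#'
#' An average-width proxy: total vessel pixel area divided by total
#' skeleton (centerline) length.
#'
#' @param mask Logical vessel mask.
#' @param skel Skeleton from [skeletonize_mask()] derived from `mask`.
#' @return Caliber in pixels; `NaN` with a warning when the skeleton has
#'   zero length.
#' @export
compute_bvc <- function(mask, skel) {
  if (!identical(dim(mask), dim(skel$skeleton))) {
    abort("`mask` and `skel` shapes do not match")
  }
  len <- sum(skel$branches$geodesic_len_px)
  if (len <= 0) {
    warn("zero-length skeleton: caliber undefined")
    return(NaN)
  }
  sum(mask) / len
}

#' Blood vessel tortuosity: mean geodesic-to-chord ratio over branches
#'
#' For each retained branch, the along-centerline (geodesic) length is
#' divided by the straight-line distance between its endpoints; the
#' unweighted mean over branches is the tortuosity (1 = perfectly
#' straight). Closed or near-closed branches, whose chord is shorter than
#' `eps`, are excluded from the mean.
#'
#' @param skel Skeleton from [skeletonize_mask()].
#' @param eps Chord-length exclusion threshold in pixels (default 1).
#' @return Tortuosity >= 1 (up to rasterization tolerance); `NaN` with a
#'   warning when no branch survives the exclusions. The number of
#'   excluded branches is attached as attribute `n_excluded`.
#' @export
compute_bvt <- function(skel, eps = 1) {
  b <- skel$branches
  keep <- !b$closed & b$euclid_len_px >= eps
  if (!any(keep)) {
    warn("no measurable branches: tortuosity undefined")
    return(structure(NaN, n_excluded = nrow(b)))
  }
  ratios <- pmax(b$geodesic_len_px[keep] / b$euclid_len_px[keep], 1)
  structure(mean(ratios), n_excluded = sum(!keep))
}

#' Vessel perimeter index: boundary contour length over vessel area
#'
#' The boundary is the sub-pixel 0.5-level iso-contour of the mask
#' (marching squares via [grDevices::contourLines()]), summed over all
#' connected components including holes; a pixel-edge count would inflate
#' diagonal boundaries by up to ~41%, the sub-pixel contour does not.
#'
#' @param mask Logical vessel mask.
#' @return Perimeter/area in 1/px; `NaN` with a warning for an empty mask.
#' @export
compute_vpi <- function(mask) {
  area <- sum(mask)
  if (area == 0) {
    warn("empty mask: perimeter index undefined")
    return(NaN)
  }
  # pad with background so components touching the border close properly
  z <- matrix(0, nrow(mask) + 2L, ncol(mask) + 2L)
  z[2:(nrow(mask) + 1L), 2:(ncol(mask) + 1L)] <- as.numeric(mask)
  cl <- contourLines(x = seq_len(nrow(z)), y = seq_len(ncol(z)), z = z,
                     levels = 0.5)
  # corner-cut resampling of each contour polygon: the raw marching-
  # squares polygon inflates smooth boundaries by ~6% through staircase
  # vertices; sampling every 5th vertex removes that bias
  perim <- sum(purrr::map_dbl(cl, function(cc) {
    p <- cbind(cc$x, cc$y)
    if (any(p[1L, ] != p[nrow(p), ])) p <- rbind(p, p[1L, ])
    resampled_length(p)
  }))
  perim / area
}

#' Extract the four morphometry features from one projection map
#'
#' Runs binarization, skeletonization and contour extraction and returns
#' the four vascular features plus their raw intermediates as a one-row
#' tibble. Degenerate inputs (blank image, empty mask) produce sentinel
#' `NaN` feature values with warnings, never an error, so one bad image
#' cannot abort a cohort run.
#'
#' @param map Numeric matrix in `[0, 1]`, or a logical mask (binarization
#'   is skipped).
#' @param config A [run_config()]; controls binarization method, spur
#'   pruning, the chord exclusion threshold and optional per-feature
#'   report scale factors.
#' @return One-row tibble: `bvd`, `bvc`, `bvt`, `vpi`,
#'   `vessel_area_px`, `skeleton_len_px`, `perimeter_px`, `n_branches`,
#'   `n_loops_excluded`, `n_spurs_pruned`, `binarization`, `threshold`.
#' @export
extract_features <- function(map, config = run_config()) {
  if (is.logical(map)) {
    mask <- map
    src <- list(method = "mask-input", threshold = NA_real_)
  } else {
    assert_map(map)
    mask <- withCallingHandlers(
      binarize(map, method = config$binarize_method,
               threshold = config$binarize_threshold),
      warning = function(w) invokeRestart("muffleWarning"))
    src <- attr(mask, "source")
  }
  skel <- skeletonize_mask(mask, min_branch_len = config$min_branch_len)
  bvd <- compute_bvd(mask)
  suppress <- function(expr) {
    withCallingHandlers(expr, warning = function(w) invokeRestart("muffleWarning"))
  }
  bvc <- suppress(compute_bvc(mask, skel))
  bvt <- suppress(compute_bvt(skel, eps = config$bvt_eps))
  vpi <- suppress(compute_vpi(mask))
  s <- config$report_scale
  tibble::tibble(
    bvd = bvd * s[["bvd"]],
    bvc = unname(bvc) * s[["bvc"]],
    bvt = as.numeric(bvt) * s[["bvt"]],
    vpi = unname(vpi) * s[["vpi"]],
    vessel_area_px = sum(mask),
    skeleton_len_px = sum(skel$branches$geodesic_len_px),
    perimeter_px = if (is.nan(unname(vpi))) NaN else unname(vpi) * sum(mask),
    n_branches = nrow(skel$branches),
    n_loops_excluded = as.integer(attr(bvt, "n_excluded") %||% 0L),
    n_spurs_pruned = skel$n_pruned,
    binarization = src$method,
    threshold = src$threshold %||% NA_real_
  )
}

#' Compute morphometry features for every map in a manifest
#'
#' @param manifest Manifest tibble from [make_cohort()] or
#'   [read_manifest()].
#' @param config A [run_config()].
#' @return The manifest's id columns joined with one feature row per
#'   image, as class `octa_features`. A failing image yields sentinel
#'   `NaN` features and the run continues.
#' @export
quantify_cohort <- function(manifest, config = run_config()) {
  feats <- purrr::map(seq_len(nrow(manifest)), function(i) {
    tryCatch(extract_features(manifest_map(manifest, i), config),
             error = function(e) {
               warn(sprintf("image %s/%s failed (%s); recording sentinels",
                            manifest$subject_id[i], manifest$arm[i],
                            conditionMessage(e)))
               tibble::tibble(bvd = NaN, bvc = NaN, bvt = NaN, vpi = NaN,
                              vessel_area_px = NA_integer_,
                              skeleton_len_px = NaN, perimeter_px = NaN,
                              n_branches = NA_integer_,
                              n_loops_excluded = NA_integer_,
                              n_spurs_pruned = NA_integer_,
                              binarization = NA_character_,
                              threshold = NA_real_)
             })
  })
  out <- dplyr::bind_cols(
    dplyr::select(manifest, dplyr::any_of(c("subject_id", "group", "fov",
                                            "arm", "seed"))),
    dplyr::bind_rows(feats))
  class(out) <- c("octa_features", class(out))
  out
}
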