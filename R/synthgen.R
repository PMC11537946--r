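#' Specify a synthetic vascular network
#'
#' Parameters of the stochastic branching random walk used to grow
#' OCTA-like vascular trees. Each root vessel takes unit-pixel steps whose
#' heading is perturbed by `Normal(0, tortuosity_amp)` per step; at each
#' step the vessel bifurcates with probability `branch_prob`, child
#' headings splitting symmetrically about the parent heading and child
#' radii shrinking by `caliber_decay`.
#'
#' @param image_size Pixels per side of the square map.
#' @param n_seeds Number of root vessels.
#' @param branch_prob Per-step bifurcation probability in `[0, 1]`.
#' @param tortuosity_amp SD of the per-step heading perturbation (radians).
#' @param caliber_root_px Root vessel radius in pixels (> 0).
#' @param caliber_decay Child/parent radius ratio in `(0, 1]`.
#' @param min_branch_len_px Minimum steps a branch grows before it may
#'   terminate by bifurcation.
#' @param fov_label Field-of-view label, `"3mm"` or `"6mm"`. `"6mm"`
#'   halves the px/mm scale: the same canvas covers twice the width, so
#'   vessel radii are drawn at half size, mimicking the coarser sampling
#'   of wide-field scans.
#' @param rng_seed Integer seed; identical spec + seed gives bit-identical
#'   output.
#' @return A `vascular_network_spec` list.
#' @export
vascular_network_spec <- function(image_size = 256L, n_seeds = 6L,
                                  branch_prob = 0.03, tortuosity_amp = 0.15,
                                  caliber_root_px = 2.5, caliber_decay = 0.8,
                                  min_branch_len_px = 12L,
                                  fov_label = c("3mm", "6mm"), rng_seed = 1L) {
  fov_label <- match.arg(fov_label)
  check_range(image_size, "image_size", lo = 32)
  check_range(n_seeds, "n_seeds", lo = 0)
  check_range(branch_prob, "branch_prob", lo = 0, hi = 1)
  check_range(tortuosity_amp, "tortuosity_amp", lo = 0)
  check_range(caliber_root_px, "caliber_root_px", lo = 0, strict_lo = TRUE)
  check_range(caliber_decay, "caliber_decay", lo = 0, hi = 1, strict_lo = TRUE)
  check_range(min_branch_len_px, "min_branch_len_px", lo = 1)
  structure(list(image_size = as.integer(image_size),
                 n_seeds = as.integer(n_seeds),
                 branch_prob = branch_prob, tortuosity_amp = tortuosity_amp,
                 caliber_root_px = caliber_root_px,
                 caliber_decay = caliber_decay,
                 min_branch_len_px = as.integer(min_branch_len_px),
                 fov_label = fov_label, rng_seed = as.integer(rng_seed)),
            class = "vascular_network_spec")
}

#' Specify a translation-artifact degradation
#'
#' Parametric model of the imperfections a learned OCT-to-OCTA translator
#' introduces: loss of fine capillaries (dropout of small-caliber
#' branches), caliber errors, blur, contrast drift and pixel noise. The
#' all-identity spec returns the input image bit-for-bit unchanged.
#'
#' @param blur_sigma_px Gaussian blur scale (px, >= 0).
#' @param dropout_frac Fraction of smallest-caliber branches removed,
#'   in `[0, 1]`.
#' @param caliber_jitter SD of multiplicative per-branch radius noise
#'   (>= 0).
#' @param caliber_scale Multiplicative bias on all radii (default 1 =
#'   unbiased); values below 1 systematically thin vessels.
#' @param contrast_gain Multiplicative intensity factor (> 0).
#' @param noise_sd Additive pixel noise SD (>= 0).
#' @param rng_seed Integer seed for the stochastic components.
#' @return A `degradation_spec` list.
#' @export
degradation_spec <- function(blur_sigma_px = 0, dropout_frac = 0,
                             caliber_jitter = 0, caliber_scale = 1,
                             contrast_gain = 1, noise_sd = 0, rng_seed = 1L) {
  check_range(blur_sigma_px, "blur_sigma_px", lo = 0)
  check_range(dropout_frac, "dropout_frac", lo = 0, hi = 1)
  check_range(caliber_jitter, "caliber_jitter", lo = 0)
  check_range(caliber_scale, "caliber_scale", lo = 0, strict_lo = TRUE)
  check_range(contrast_gain, "contrast_gain", lo = 0, strict_lo = TRUE)
  check_range(noise_sd, "noise_sd", lo = 0)
  structure(list(blur_sigma_px = blur_sigma_px, dropout_frac = dropout_frac,
                 caliber_jitter = caliber_jitter, caliber_scale = caliber_scale,
                 contrast_gain = contrast_gain, noise_sd = noise_sd,
                 rng_seed = as.integer(rng_seed)),
            class = "degradation_spec")
}

is_identity_degradation <- function(d) {
  d$blur_sigma_px == 0 && d$dropout_frac == 0 && d$caliber_jitter == 0 &&
    d$caliber_scale == 1 && d$contrast_gain == 1 && d$noise_sd == 0
}

# grow one branch: vectorized random walk; returns the path actually
# inside the canvas and whether it ended by bifurcation
grow_branch <- function(origin, heading, radius, spec, max_len) {
  n_draw <- if (spec$branch_prob > 0) {
    spec$min_branch_len_px + rgeom(1L, spec$branch_prob)
  } else {
    max_len
  }
  n <- max(min(n_draw, max_len), 2L)
  headings <- heading + cumsum(rnorm(n, 0, spec$tortuosity_amp))
  rows <- origin[1L] + cumsum(sin(headings))
  cols <- origin[2L] + cumsum(cos(headings))
  inside <- rows >= 1 & rows <= spec$image_size &
    cols >= 1 & cols <= spec$image_size
  first_out <- which(!inside)[1L]
  exited <- !is.na(first_out)
  keep <- if (exited) seq_len(first_out - 1L) else seq_len(n)
  list(path = cbind(row = c(origin[1L], rows[keep]),
                    col = c(origin[2L], cols[keep])),
       end_heading = if (length(keep)) headings[max(keep)] else heading,
       bifurcate = !exited && n_draw <= max_len && radius * spec$caliber_decay >= 0.4)
}

#' Generate a synthetic OCTA-like projection map
#'
#' Grows a seeded vascular network, rasterizes it (each centerline step
#' stamped as a hard disc of the branch radius, no anti-aliasing), and
#' renders a grayscale map with a thin Gaussian intensity profile. The
#' exact centerline polylines and per-branch radii are returned as the
#' geometry record, which serves as ground truth for morphometry.
#'
#' @param spec A [vascular_network_spec()].
#' @return An object of class `octa_network`: a list with `map` (numeric
#'   matrix in `[0, 1]`), `mask` (logical rasterization truth),
#'   `geometry` (tibble: branch_id, parent_id, radius, n_steps, path
#'   list-column) and `spec`.
#' @export
generate_network <- function(spec) {
  if (!inherits(spec, "vascular_network_spec")) {
    abort("`spec` must be created with vascular_network_spec()")
  }
  sz <- spec$image_size
  fov_scale <- if (spec$fov_label == "6mm") 0.5 else 1
  max_len <- as.integer(round(sz * 0.5))
  geometry <- withr::with_seed(spec$rng_seed, {
    rows <- list()
    if (spec$n_seeds > 0) {
      queue <- lapply(seq_len(spec$n_seeds), function(i) {
        list(origin = c(runif(1, sz * 0.1, sz * 0.9),
                        runif(1, sz * 0.1, sz * 0.9)),
             heading = runif(1, 0, 2 * pi),
             radius = spec$caliber_root_px * fov_scale,
             parent = NA_integer_, depth = 1L)
      })
      bid <- 0L
      while (length(queue) > 0 && bid < 400L) {
        job <- queue[[1L]]
        queue <- queue[-1L]
        br <- grow_branch(job$origin, job$heading, job$radius, spec, max_len)
        if (nrow(br$path) < 2L) next
        bid <- bid + 1L
        rows[[bid]] <- tibble::tibble(branch_id = bid, parent_id = job$parent,
                                      radius = job$radius,
                                      n_steps = nrow(br$path),
                                      path = list(br$path))
        if (br$bifurcate && job$depth < 8L) {
          split <- runif(1, pi / 10, pi / 5)
          tip <- br$path[nrow(br$path), ]
          for (s in c(-1, 1)) {
            queue <- c(queue, list(list(origin = tip,
                                        heading = br$end_heading + s * split,
                                        radius = job$radius * spec$caliber_decay,
                                        parent = bid, depth = job$depth + 1L)))
          }
        }
      }
    }
    if (length(rows)) dplyr::bind_rows(rows) else empty_geometry()
  })
  mask <- rasterize_geometry(geometry, sz)
  structure(list(map = render_grayscale(mask), mask = mask,
                 geometry = geometry, spec = spec),
            class = "octa_network")
}

empty_geometry <- function() {
  tibble::tibble(branch_id = integer(), parent_id = integer(),
                 radius = double(), n_steps = integer(), path = list())
}

rasterize_geometry <- function(geometry, sz) {
  if (nrow(geometry) == 0) {
    return(matrix(FALSE, sz, sz))
  }
  pts <- purrr::map2(geometry$path, geometry$radius, function(p, r) {
    cbind(p, rad = rep(r, nrow(p)))
  })
  pts <- do.call(rbind, pts)
  cpp_stamp_discs(sz, sz, pts[, 1L], pts[, 2L], pts[, 3L])
}

# grayscale rendering: bright vessels on dark background with a thin
# Gaussian edge profile; kept noise-free so Otsu recovers the truth mask
render_grayscale <- function(mask) {
  g <- blur_mat(matrix(as.numeric(mask), nrow(mask)), 0.6)
  clamp01(0.9 * g)
}

#' Apply a translation-artifact degradation to a synthetic network
#'
#' Geometry-level artifacts (branch dropout, caliber jitter/bias) are
#' applied to the network's branch records and the map is re-rasterized;
#' pixel-level artifacts (blur, contrast, noise) then act on the image.
#' An identity spec returns the ground-truth map exactly.
#'
#' @param network An `octa_network` from [generate_network()].
#' @param d A [degradation_spec()].
#' @return A numeric matrix in `[0, 1]`, same size as the input map.
#' @export
degrade <- function(network, d) {
  if (!inherits(network, "octa_network")) {
    abort("`network` must be an octa_network from generate_network()")
  }
  if (!inherits(d, "degradation_spec")) {
    abort("`d` must be created with degradation_spec()")
  }
  if (is_identity_degradation(d)) {
    return(network$map)
  }
  sz <- network$spec$image_size
  geometry <- network$geometry
  withr::with_seed(d$rng_seed, {
    if (nrow(geometry) > 0 && d$dropout_frac > 0) {
      n_drop <- floor(d$dropout_frac * nrow(geometry))
      if (n_drop > 0) {
        ord <- order(geometry$radius, geometry$branch_id)
        geometry <- geometry[-ord[seq_len(n_drop)], , drop = FALSE]
      }
    }
    if (nrow(geometry) > 0 &&
        (d$caliber_jitter > 0 || d$caliber_scale != 1)) {
      jit <- d$caliber_scale + rnorm(nrow(geometry), 0, d$caliber_jitter)
      geometry$radius <- pmax(geometry$radius * pmax(jit, 0), 0)
      geometry <- geometry[geometry$radius > 0.2, , drop = FALSE]
    }
    g <- if (d$dropout_frac > 0 || d$caliber_jitter > 0 ||
             d$caliber_scale != 1) {
      render_grayscale(rasterize_geometry(geometry, sz))
    } else {
      network$map
    }
    g <- blur_mat(g, d$blur_sigma_px)
    g <- g * d$contrast_gain
    if (d$noise_sd > 0) {
      g <- g + matrix(rnorm(length(g), 0, d$noise_sd), nrow(g))
    }
    clamp01(g)
  })
}
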