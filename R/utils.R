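# internal helpers shared across modules

# deterministic 31-bit hash of a string mixed with a master seed, used to
# derive one RNG seed per subject so unbalanced cohorts reproduce exactly
stable_seed <- function(master_seed, key) {
  h <- as.numeric(master_seed) %% 2147483647
  for (code in utf8ToInt(as.character(key))) {
    h <- (h * 131 + code) %% 2147483647
  }
  as.integer(h)
}

# matrix [0,1] Gaussian blur; sigma = 0 returns the input untouched
blur_mat <- function(x, sigma) {
  if (sigma <= 0) return(x)
  as.matrix(EBImage::gblur(x, sigma = sigma))
}

clamp01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

assert_map <- function(x, arg = "map") {
  if (!is.matrix(x) || !is.numeric(x)) {
    abort(sprintf("`%s` must be a numeric matrix", arg))
  }
  if (nrow(x) < 16 || ncol(x) < 16) {
    abort(sprintf("`%s` must be at least 16x16 pixels", arg))
  }
  if (any(!is.finite(x)) || any(x < 0)) {
    abort(sprintf("`%s` must contain finite, non-negative intensities", arg))
  }
  invisible(x)
}

assert_same_shape <- function(a, b) {
  if (!identical(dim(a), dim(b))) {
    abort("images must have identical dimensions")
  }
  invisible(NULL)
}

check_range <- function(value, field, lo = -Inf, hi = Inf, strict_lo = FALSE) {
  bad <- !is.numeric(value) || length(value) != 1L || !is.finite(value) ||
    value > hi || (if (strict_lo) value <= lo else value < lo)
  if (bad) {
    abort(sprintf("field `%s` is invalid: got %s, need value in %s%s, %s]",
                  field, format(value), if (strict_lo) "(" else "[",
                  format(lo), format(hi)))
  }
  invisible(value)
}

# polyline length after corner-cut resampling: every `step`-th vertex plus
# the last; counters the ~5% staircase inflation of raw chain codes
resampled_length <- function(path, step = 5L) {
  n <- nrow(path)
  if (n < 2L) return(0)
  idx <- unique(c(seq(1L, n, by = step), n))
  d <- diff(path[idx, 1L])^2 + diff(path[idx, 2L])^2
  sum(sqrt(d))
}

# raw 8-connected chain length (1 per axial step, sqrt(2) per diagonal)
chain_length <- function(path) {
  n <- nrow(path)
  if (n < 2L) return(0)
  dr <- abs(diff(path[, 1L]))
  dc <- abs(diff(path[, 2L]))
  sum(ifelse(dr + dc == 2L, sqrt(2), 1))
}
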