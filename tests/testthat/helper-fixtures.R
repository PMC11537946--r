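# geometric masks with known analytic morphometry

bar_mask <- function(size = 256L, width = 5L, length = 100L,
                     row0 = 100L, col0 = 50L) {
  m <- matrix(FALSE, size, size)
  m[row0:(row0 + width - 1L), col0:(col0 + length - 1L)] <- TRUE
  m
}

plus_mask <- function(size = 64L) {
  m <- matrix(FALSE, size, size)
  m[30:34, 10:54] <- TRUE
  m[10:54, 30:34] <- TRUE
  m
}

disc_mask <- function(size = 256L, r = 50, cy = 120, cx = 120) {
  idx <- expand.grid(i = seq_len(size), j = seq_len(size))
  matrix(sqrt((idx$i - cy)^2 + (idx$j - cx)^2) <= r, size, size)
}

quarter_arc_mask <- function(size = 256L, r = 80, half_width = 1.5,
                             cy = 120, cx = 120) {
  idx <- expand.grid(i = seq_len(size), j = seq_len(size))
  d <- sqrt((idx$i - cy)^2 + (idx$j - cx)^2)
  ang <- atan2(idx$i - cy, idx$j - cx)
  matrix(abs(d - r) <= half_width & ang >= 0 & ang <= pi / 2, size, size)
}

square_mask <- function(size = 256L, side = 64L, at = 50L) {
  m <- matrix(FALSE, size, size)
  m[at:(at + side - 1L), at:(at + side - 1L)] <- TRUE
  m
}

# small network spec used across tests: sparse enough that branches
# rarely overlap, fast enough for replicated runs
small_net_spec <- function(seed, ...) {
  args <- utils::modifyList(
    list(image_size = 96L, n_seeds = 3L, caliber_root_px = 2,
         rng_seed = seed), list(...))
  do.call(vascular_network_spec, args)
}

# deterministic non-constant image pair for quality-metric tests
wave_pair <- function(n = 32L) {
  i <- matrix(rep(seq_len(n), n), n)
  j <- t(i)
  a <- 0.5 + 0.5 * sin(i / 3) * cos(j / 5)
  b <- pmin(pmax(a + 0.1 * sin(j / 2), 0), 1)
  list(a = a, b = b)
}
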