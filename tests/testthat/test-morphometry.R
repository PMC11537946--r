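test_that("binarization handles blank, bimodal and synthetic inputs", {
  zeros <- matrix(0, 32, 32)
  expect_warning(m <- binarize(zeros), "all-false")
  expect_false(any(m))

  bi <- matrix(0, 32, 32)
  bi[10:20, 5:25] <- 1
  m <- binarize(bi)
  expect_identical(as.vector(m), as.vector(bi == 1))
  expect_equal(attr(m, "source")$method, "otsu")
  expect_true(is.finite(attr(m, "source")$threshold))

  net <- generate_network(small_net_spec(7, image_size = 128L))
  m <- binarize(net$map)
  jac <- sum(m & net$mask) / sum(m | net$mask)
  expect_gte(jac, 0.95)
})

test_that("BVD is exact pixel counting", {
  expect_equal(compute_bvd(matrix(TRUE, 10, 10)), 1)
  expect_equal(compute_bvd(matrix(FALSE, 10, 10)), 0)
  expect_equal(compute_bvd(square_mask()), 4096 / 65536)
  # brute-force equivalence on random masks
  withr::with_seed(77, {
    for (k in 1:25) {
      m <- matrix(runif(400) < runif(1), 20, 20)
      expect_identical(compute_bvd(m), sum(m) / 400)
    }
  })
})

test_that("skeleton of a bar is one branch of near-analytic length", {
  sk <- skeletonize_mask(bar_mask())
  expect_s3_class(sk, "octa_skeleton")
  expect_equal(nrow(sk$branches), 1L)
  expect_lt(abs(sk$branches$geodesic_len_px - 99), 5)
})

test_that("plus-sign decomposes into four branches around one junction", {
  sk <- skeletonize_mask(plus_mask())
  expect_equal(nrow(sk$branches), 4L)
  expect_equal(nrow(sk$junctions), 1L)
})

test_that("empty mask yields an empty skeleton, not an error", {
  sk <- skeletonize_mask(matrix(FALSE, 32, 32))
  expect_equal(nrow(sk$branches), 0L)
})

test_that("BVC matches the width of rectangular vessels", {
  m5 <- bar_mask(width = 5L)
  expect_lt(abs(compute_bvc(m5, skeletonize_mask(m5)) - 5) / 5, 0.1)
  m9 <- bar_mask(width = 9L, row0 = 98L)
  expect_lt(abs(compute_bvc(m9, skeletonize_mask(m9)) - 9) / 9, 0.1)
  expect_warning(v <- compute_bvc(matrix(FALSE, 32, 32),
                                  skeletonize_mask(matrix(FALSE, 32, 32))),
                 "undefined")
  expect_true(is.nan(v))
  expect_error(compute_bvc(matrix(FALSE, 16, 16),
                           skeletonize_mask(matrix(FALSE, 32, 32))),
               "match")
})

test_that("BVT: straight bar exactly 1, arc matches the chord ratio", {
  expect_equal(compute_bvt(skeletonize_mask(bar_mask())), 1,
               ignore_attr = TRUE)
  bvt_arc <- compute_bvt(skeletonize_mask(quarter_arc_mask()))
  expect_lt(abs(bvt_arc - pi / (2 * sqrt(2))), 0.03)
  expect_warning(v <- compute_bvt(skeletonize_mask(matrix(FALSE, 32, 32))),
                 "undefined")
  expect_true(is.nan(v))
})

test_that("BVT of a two-branch skeleton is the mean of per-branch ratios", {
  # one straight bar plus the quarter arc, disjoint in one mask
  m <- bar_mask(row0 = 20L, col0 = 20L)
  m <- m | quarter_arc_mask()
  sk <- skeletonize_mask(m)
  expect_equal(nrow(sk$branches), 2L)
  rho <- sk$branches$geodesic_len_px / sk$branches$euclid_len_px
  expect_equal(as.numeric(compute_bvt(sk)), mean(pmax(rho, 1)))
})

test_that("BVT path-walk brute force agrees on sparse synthetic networks", {
  # independent oracle: per-branch ratio recomputed by walking each
  # branch path directly (every-5th-vertex polyline + tip spans)
  for (s in 1:20) {
    net <- generate_network(vascular_network_spec(
      n_seeds = 1L, branch_prob = 0, tortuosity_amp = 0.2,
      caliber_root_px = 2, image_size = 128L, rng_seed = s))
    sk <- skeletonize_mask(net$mask)
    b <- sk$branches[!sk$branches$closed & sk$branches$euclid_len_px >= 1, ]
    if (nrow(b) == 0) next
    ratios <- vapply(seq_len(nrow(b)), function(k) {
      max(b$geodesic_len_px[k] / b$euclid_len_px[k], 1)
    }, numeric(1))
    expect_equal(as.numeric(compute_bvt(sk)), mean(ratios), tolerance = 1e-12)
    expect_gte(min(ratios), 1)
  }
})

test_that("VPI matches analytic perimeter/area and is duplication-invariant", {
  rect <- square_mask()
  expect_lt(abs(compute_vpi(rect) - 2 * (64 + 64) / (64 * 64)) / 0.0625, 0.05)
  disc <- disc_mask()
  expect_lt(abs(compute_vpi(disc) - 0.04) / 0.04, 0.05)
  dup <- rect
  dup[150:213, 150:213] <- TRUE
  expect_equal(compute_vpi(dup), compute_vpi(rect), tolerance = 1e-10)
  expect_warning(v <- compute_vpi(matrix(FALSE, 32, 32)), "empty")
  expect_true(is.nan(v))
})

test_that("extract_features composes the four features with sentinels", {
  blank <- matrix(0, 64, 64)
  f <- suppressWarnings(extract_features(blank))
  expect_equal(f$bvd, 0)
  expect_true(is.nan(f$bvc) && is.nan(f$bvt) && is.nan(f$vpi))

  net <- generate_network(small_net_spec(13, tortuosity_amp = 0,
                                         branch_prob = 0))
  f <- extract_features(net$map)
  expect_gte(f$bvt, 1)
  expect_lte(f$bvt, 1.05)
  expect_identical(f, extract_features(net$map))
  expect_equal(f$binarization, "otsu")
})

test_that("report scale factors multiply reported features only", {
  net <- generate_network(small_net_spec(13))
  base <- extract_features(net$map)
  scaled <- extract_features(net$map, run_config(report_scale = c(bvd = 100)))
  expect_equal(scaled$bvd, base$bvd * 100)
  expect_equal(scaled$vpi, base$vpi)
  expect_equal(scaled$vessel_area_px, base$vessel_area_px)
})

test_that("median features track their generator knobs monotonically", {
  # scaled-down parameter-recovery screen (full version in acceptance)
  med_bvt <- vapply(c(0.05, 0.4), function(amp) {
    median(vapply(1:8, function(s) {
      net <- generate_network(vascular_network_spec(
        image_size = 96L, n_seeds = 2L, branch_prob = 0.01,
        tortuosity_amp = amp, caliber_root_px = 2, rng_seed = s))
      extract_features(net$map)$bvt
    }, numeric(1)), na.rm = TRUE)
  }, numeric(1))
  expect_lt(med_bvt[1], med_bvt[2])
})
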