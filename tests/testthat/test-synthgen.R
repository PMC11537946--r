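test_that("spec validation names the offending field", {
  expect_error(vascular_network_spec(branch_prob = 1.2), "branch_prob")
  expect_error(vascular_network_spec(caliber_root_px = 0), "caliber_root_px")
  expect_error(vascular_network_spec(tortuosity_amp = -1), "tortuosity_amp")
  expect_error(degradation_spec(dropout_frac = 2), "dropout_frac")
  expect_error(degradation_spec(contrast_gain = 0), "contrast_gain")
})

test_that("degenerate growth specs behave as documented", {
  blank <- generate_network(vascular_network_spec(n_seeds = 0L, rng_seed = 1))
  expect_equal(sum(blank$map), 0)
  expect_equal(nrow(blank$geometry), 0L)

  single <- generate_network(vascular_network_spec(
    n_seeds = 1L, branch_prob = 0, tortuosity_amp = 0, rng_seed = 5))
  expect_equal(nrow(single$geometry), 1L)
})

test_that("generation is a pure function of spec and seed", {
  spec <- vascular_network_spec(rng_seed = 42L, image_size = 96L)
  a <- generate_network(spec)
  b <- generate_network(spec)
  expect_identical(a$map, b$map)
  expect_identical(a$geometry$radius, b$geometry$radius)
  c <- generate_network(vascular_network_spec(rng_seed = 43L, image_size = 96L))
  expect_false(identical(a$map, c$map))
})

test_that("identity degradation returns the GT map bitwise", {
  net <- generate_network(small_net_spec(7))
  expect_identical(degrade(net, degradation_spec()), net$map)
})

test_that("full dropout of small-caliber branches empties the image", {
  net <- generate_network(small_net_spec(7))
  out <- degrade(net, degradation_spec(dropout_frac = 1))
  expect_equal(sum(out), 0)
})

test_that("blur strictly reduces SSIM against the original", {
  net <- generate_network(small_net_spec(11))
  blurred <- degrade(net, degradation_spec(blur_sigma_px = 2))
  expect_lt(as.numeric(ssim(net$map, blurred)), 1)
})

test_that("degradation is seed-deterministic", {
  net <- generate_network(small_net_spec(3))
  d <- degradation_spec(blur_sigma_px = 1, dropout_frac = 0.2,
                        caliber_jitter = 0.1, noise_sd = 0.03, rng_seed = 9L)
  expect_identical(degrade(net, d), degrade(net, d))
})

test_that("skeletonizing a sparse rasterized network recovers its branches", {
  # non-overlapping single vessels: geometry and skeleton must agree
  for (s in 1:5) {
    net <- generate_network(vascular_network_spec(
      n_seeds = 1L, branch_prob = 0, tortuosity_amp = 0.05,
      caliber_root_px = 2, image_size = 128L, rng_seed = s))
    sk <- skeletonize_mask(net$mask)
    expect_lte(abs(nrow(sk$branches) - nrow(net$geometry)),
               nrow(sk$junctions) + 1L)
  }
})

test_that("make_cohort bookkeeping: counts, unbalanced groups, determinism", {
  dir1 <- withr::local_tempdir()
  m1 <- make_cohort(list(NORMAL = list(n = 4), DR = list(n = 2)),
                    master_seed = 21, out_dir = dir1,
                    network = list(image_size = 64L, n_seeds = 2L))
  expect_equal(nrow(m1), 12L)
  expect_equal(sum(m1$group == "NORMAL"), 8L)
  expect_length(list.files(file.path(dir1, "images")), 12L)
  expect_true(file.exists(file.path(dir1, "manifest.csv")))
  expect_true(file.exists(file.path(dir1, "manifest.json")))

  dir2 <- withr::local_tempdir()
  m2 <- make_cohort(list(NORMAL = list(n = 4), DR = list(n = 2)),
                    master_seed = 21, out_dir = dir2,
                    network = list(image_size = 64L, n_seeds = 2L))
  expect_identical(m1$seed, m2$seed)
  same <- vapply(seq_len(nrow(m1)), function(i) {
    identical(read_map(m1$path[i]), read_map(m2$path[i]))
  }, logical(1))
  expect_true(all(same))

  expect_error(make_cohort(list(A = list(n = 0)), master_seed = 1), "n")
})

test_that("a group with higher tortuosity yields higher measured BVT", {
  m <- make_cohort(
    list(LOW = list(n = 8, network = list(tortuosity_amp = 0.05)),
         HIGH = list(n = 8, network = list(tortuosity_amp = 0.4))),
    master_seed = 5,
    network = list(image_size = 128L, n_seeds = 2L, branch_prob = 0.01,
                   caliber_root_px = 2))
  f <- quantify_cohort(m)
  gt <- f[f$arm == "GT", ]
  expect_gt(mean(gt$bvt[gt$group == "HIGH"], na.rm = TRUE),
            mean(gt$bvt[gt$group == "LOW"], na.rm = TRUE))
})

test_that("6mm field of view halves vessel caliber on the same canvas", {
  a <- generate_network(small_net_spec(2, fov_label = "3mm"))
  b <- generate_network(small_net_spec(2, fov_label = "6mm"))
  expect_equal(b$geometry$radius[1], a$geometry$radius[1] / 2)
})
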