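test_that("the texture direction set has the 13 canonical members", {
  dirs <- texture_directions()
  expect_equal(nrow(dirs), 13L)
  expect_true(all(dirs %in% -1:1))
  ## no antipodal duplicates, no origin
  keys <- apply(dirs, 1, paste, collapse = ",")
  anti <- apply(-dirs, 1, paste, collapse = ",")
  expect_length(intersect(keys, anti), 0)
  expect_false("0,0,0" %in% keys)
})

test_that("histogram features honour the degenerate conventions", {
  ## constant lesion: variance 0, entropy 0, energy 1
  ph <- as_level_phantom(array(3L, dim = c(3, 3, 2)))
  f <- compute_intensity_features(ph$levels, ph$mask)
  expect_equal(unname(f["hist_variance"]), 0)
  expect_equal(unname(f["hist_entropy_log2"]), 0)
  expect_equal(unname(f["hist_energy"]), 1)

  ## two levels at 50/50: entropy exactly 1 bit
  ph2 <- as_level_phantom(array(rep(c(1L, 2L), 8), dim = c(4, 4, 1)))
  f2 <- compute_intensity_features(ph2$levels, ph2$mask)
  expect_equal(unname(f2["hist_entropy_log2"]), 1)

  ## single voxel: variance 0, skewness/kurtosis undefined
  ph3 <- as_level_phantom(array(5L, dim = c(1, 1, 1)))
  f3 <- compute_intensity_features(ph3$levels, ph3$mask)
  expect_equal(unname(f3["hist_variance"]), 0)
  expect_true(is.na(f3["hist_skewness"]) && is.na(f3["hist_kurtosis"]))
})

test_that("histogram features match a brute-force computation on a fixed phantom", {
  set.seed(7)
  g <- sample(1:6, 16, replace = TRUE)
  ph <- as_level_phantom(array(g, dim = c(4, 4, 1)))
  f <- compute_intensity_features(ph$levels, ph$mask)
  p <- as.numeric(table(g)) / 16
  expect_equal(unname(f["hist_mean"]), mean(g))
  expect_equal(unname(f["hist_variance"]), mean((g - mean(g))^2))
  expect_equal(unname(f["hist_skewness"]),
               mean((g - mean(g))^3) / mean((g - mean(g))^2)^1.5)
  expect_equal(unname(f["hist_energy"]), sum(p^2))
  expect_equal(unname(f["hist_entropy_log2"]), -sum(p * log2(p)))
  expect_equal(unname(f["hist_median"]), median(g))
})

test_that("shape features reproduce hand-computed volumes and orderings", {
  ## single voxel at 1 x 1 x 2 mm: volume 2 mm^3
  m1 <- array(1L, dim = c(1, 1, 1))
  f1 <- compute_shape_features(m1, c(1, 1, 2))
  expect_equal(unname(f1["shape_volume_mm3"]), 2)
  expect_equal(unname(f1["shape_surface_mm2"]), 2 * 1 + 4 * 2)

  ## 10 x 10 x 5 voxels at 1 x 1 x 2 mm: exactly the 1 cm^3 target threshold
  m2 <- array(0L, dim = c(12, 12, 7)); m2[2:11, 2:11, 2:6] <- 1L
  f2 <- compute_shape_features(m2, c(1, 1, 2))
  expect_equal(unname(f2["shape_volume_mm3"]), 1000)
  expect_equal(unname(f2["shape_volume_cm3"]), 1)

  ## sphere-like phantom is more spherical than a same-volume rod
  sph <- generate_textured_lesion(volume_sim_config(
    grid_shape = c(24, 24, 12), lesion_radius = 6, seed = 1))$mask
  rod <- array(0L, dim = c(24, 24, 12))
  nvox <- sum(sph)
  len <- ceiling(nvox / 4)
  rod[seq_len(min(len, 24)), 1:2, 1:2] <- 1L
  f_s <- compute_shape_features(sph, c(1, 1, 2))
  f_r <- compute_shape_features(rod, c(1, 1, 2))
  expect_gt(f_s[["shape_sphericity"]], f_r[["shape_sphericity"]])
})

test_that("GLCM matrices equal brute-force pair enumeration on small phantoms", {
  set.seed(3)
  ph <- as_level_phantom(array(sample(1:2, 27, replace = TRUE), dim = c(3, 3, 3)))
  dirs <- texture_directions()
  for (r in seq_len(nrow(dirs))) {
    M <- ipithsurv:::glcm_matrix(ph$levels, dirs[r, ], 2L)
    expect_equal(M, bf_glcm(ph$levels, dirs[r, ], 2L))
  }
  ## constant lesion: contrast 0, energy 1
  cph <- as_level_phantom(array(1L, dim = c(3, 3, 2)))
  f <- compute_glcm_features(cph$levels, cph$mask, 1L)
  expect_equal(unname(f["glcm_contrast"]), 0)
  expect_equal(unname(f["glcm_energy"]), 1)
})

test_that("GLCM pair conservation holds against the enumerated pair count", {
  set.seed(11)
  arr <- array(sample(1:4, 125, replace = TRUE), dim = c(5, 5, 5))
  arr[sample(125, 20)] <- NA            # punch holes in the analysis mask
  ph <- as_level_phantom(arr)
  dirs <- texture_directions()
  for (r in c(1, 5, 13)) {
    M <- ipithsurv:::glcm_matrix(ph$levels, dirs[r, ], 4L)
    expect_equal(sum(M), sum(bf_glcm(ph$levels, dirs[r, ], 4L)))
    expect_equal(M, t(M))               # symmetry
  }
})

test_that("GLRLM features reproduce the hand-enumerated run examples", {
  ## 1 x 1 x 5 constant row, single direction along it: one run of length 5
  row5 <- as_level_phantom(array(2L, dim = c(1, 1, 5)))
  f <- compute_glrlm_features(row5$levels, row5$mask,
                              directions = matrix(c(0L, 0L, 1L), 1))
  expect_equal(unname(f["glrlm_lre"]), 25)
  expect_equal(unname(f["glrlm_sre"]), 1 / 25)
  expect_equal(unname(f["glrlm_run_percentage"]), 1 / 5)

  ## [g1,g1,g2,g2,g2] along its axis: 2 runs
  mix <- as_level_phantom(array(c(1L, 1L, 2L, 2L, 2L), dim = c(5, 1, 1)))
  f2 <- compute_glrlm_features(mix$levels, mix$mask,
                               directions = matrix(c(1L, 0L, 0L), 1))
  expect_equal(unname(f2["glrlm_run_percentage"]), 0.4)
  expect_equal(unname(f2["glrlm_sre"]), 0.5 * (1 / 4 + 1 / 9))

  ## checkerboard: every run has length 1 along each grid axis
  idx <- expand.grid(1:4, 1:4, 1:4)
  board <- array(as.integer((rowSums(idx) %% 2) + 1), dim = c(4, 4, 4))
  ph <- as_level_phantom(board)
  axes <- rbind(c(1L, 0L, 0L), c(0L, 1L, 0L), c(0L, 0L, 1L))
  f3 <- compute_glrlm_features(ph$levels, ph$mask, directions = axes)
  expect_equal(unname(f3["glrlm_sre"]), 1)
  expect_equal(unname(f3["glrlm_lre"]), 1)
  expect_equal(unname(f3["glrlm_run_percentage"]), 1)
})

test_that("GLRLM run decomposition matches the line-walking oracle with holes", {
  set.seed(23)
  arr <- array(sample(1:3, 60, replace = TRUE), dim = c(5, 4, 3))
  arr[sample(60, 10)] <- NA
  ph <- as_level_phantom(arr)
  dirs <- texture_directions()
  for (r in seq_len(nrow(dirs))) {
    runs <- ipithsurv:::glrlm_runs(ph$levels, dirs[r, ])
    oracle <- bf_runs(ph$levels, dirs[r, ])
    ## compare as multisets of (level, length)
    expect_equal(table(paste(runs$level, runs$length)),
                 table(paste(oracle$level, oracle$length)))
    ## conservation: run lengths sum to the voxel count
    expect_equal(sum(runs$length), sum(!is.na(ph$levels)))
  }
})

test_that("GLSZM features reproduce the hand-enumerated zone examples", {
  ## constant 2 x 2 x 2 lesion: one zone of size 8
  cph <- as_level_phantom(array(1L, dim = c(2, 2, 2)))
  f <- compute_glszm_features(cph$levels, cph$mask)
  expect_equal(unname(f["glszm_zone_percentage"]), 1 / 8)
  expect_equal(unname(f["glszm_sze"]), 1 / 64)
  expect_equal(unname(f["glszm_nzsn"]), 1)

  ## all-distinct levels: every zone is a singleton
  dph <- as_level_phantom(array(1:8, dim = c(2, 2, 2)))
  f2 <- compute_glszm_features(dph$levels, dph$mask)
  expect_equal(unname(f2["glszm_zone_percentage"]), 1)
  expect_equal(unname(f2["glszm_sze"]), 1)
})

test_that("GLSZM zones equal brute-force 26-connected labeling", {
  set.seed(5)
  arr <- array(sample(1:2, 32, replace = TRUE), dim = c(4, 4, 2))
  ph <- as_level_phantom(arr)
  z <- ipithsurv:::glszm_zones(ph$levels)
  expect_equal(sort(z$sizes), sort(bf_zones(ph$levels)))
  expect_equal(sum(z$sizes), 32)        # zone sizes partition the voxels
})

test_that("full extraction is deterministic and carries the six named IBSI codes", {
  les <- generate_textured_lesion(volume_sim_config(
    grid_shape = c(16, 16, 10), lesion_radius = 4, seed = 13))
  f1 <- extract_features(les$volume, les$mask, les$voxel_size)
  f2 <- extract_features(les$volume, les$mask, les$voxel_size)
  expect_identical(as.numeric(f1), as.numeric(f2))
  expect_true(all(is.finite(f1)))
  reg <- attr(f1, "registry")
  codes <- setNames(reg$ibsi_code, reg$name)
  expect_equal(unname(codes[c("glszm_nzsn", "glszm_sze", "glszm_zone_percentage",
                              "glrlm_lre", "glrlm_run_percentage", "glrlm_sre")]),
               c("VB3A", "5QRC", "P30P", "W4KF", "9ZK5", "22OV"))
  expect_false(any(duplicated(names(f1))))
})
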