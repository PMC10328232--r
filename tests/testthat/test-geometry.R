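test_that("apply_transform handles identity, translation, inversion and composition", {
  I4 <- rigid_transform(diag(4))
  expect_equal(as.numeric(apply_transform(c(1, 2, 3), I4)), c(1, 2, 3))

  Tt <- diag(4); Tt[1, 4] <- 10
  expect_equal(as.numeric(apply_transform(c(0, 0, 0), rigid_transform(Tt))),
               c(10, 0, 0))

  # round trip and composition against the direct matrix oracle
  set.seed(11)
  ang <- runif(3, -pi, pi)
  Rx <- rbind(c(1, 0, 0), c(0, cos(ang[1]), -sin(ang[1])),
              c(0, sin(ang[1]), cos(ang[1])))
  Rz <- rbind(c(cos(ang[2]), -sin(ang[2]), 0),
              c(sin(ang[2]), cos(ang[2]), 0), c(0, 0, 1))
  M1 <- rbind(cbind(Rx, runif(3, -20, 20)), c(0, 0, 0, 1))
  M2 <- rbind(cbind(Rz, runif(3, -20, 20)), c(0, 0, 0, 1))
  T1 <- rigid_transform(M1); T2 <- rigid_transform(M2)
  pts <- matrix(runif(300, -50, 50), ncol = 3)
  back <- apply_transform(apply_transform(pts, T1), transform_inverse(T1))
  expect_lt(max(abs(back - pts)), 1e-9)
  oracle <- t(M2 %*% M1 %*% t(cbind(pts, 1)))[, 1:3]
  expect_lt(max(abs(apply_transform(pts, transform_compose(T2, T1)) - oracle)),
            1e-9)
  expect_lt(max(abs(apply_transform(apply_transform(pts, T1), T2) - oracle)),
            1e-9)
})

test_that("singular or non-orthonormal matrices are rejected", {
  M <- diag(4); M[1, 1] <- 0
  expect_error(rigid_transform(M), "invertible")
  M2 <- diag(4); M2[1, 1] <- 2
  expect_error(rigid_transform(M2), "orthonormal")
  expect_silent(rigid_transform(M2, rigid = FALSE))
})

test_that("world/voxel round trips are exact for random affines", {
  expect_equal(as.numeric(world_to_voxel(c(3, 4, 5),
                                         volume_image(array(0L, c(8, 8, 8))))),
               c(3, 4, 5))
  vol2 <- volume_image(array(0L, c(8, 8, 8)), diag(c(2, 2, 2, 1)))
  expect_equal(as.numeric(world_to_voxel(c(4, 4, 4), vol2)), c(2, 2, 2))
  set.seed(21)
  for (k in 1:5) {
    A <- diag(4)
    A[1:3, 1:3] <- matrix(rnorm(9), 3) + diag(3) * 3
    A[1:3, 4] <- runif(3, -40, 40)
    vol <- volume_image(array(0L, c(6, 7, 8)), A)
    pts <- matrix(runif(60, -30, 30), ncol = 3)
    expect_lt(max(abs(voxel_to_world(world_to_voxel(pts, vol), vol) - pts)),
              1e-9)
  }
})

test_that("sample_label matches exhaustive nearest-voxel-center search", {
  g <- array(sample.int(9, 8^3, replace = TRUE), c(8, 8, 8))
  A <- diag(c(1.5, 2, 1, 1)); A[1:3, 4] <- c(-3, 2, 0.5)
  vol <- volume_image(g, A, kind = "label")

  # exact voxel center carries its own label
  ctr <- voxel_to_world(c(3, 4, 5), vol)
  expect_identical(sample_label(vol, ctr), g[4, 5, 6])
  # far outside the grid
  expect_identical(sample_label(vol, c(1000, 0, 0)), 0L)

  set.seed(31)
  idx <- matrix(runif(6000, -0.45, 7.45), ncol = 3)  # strictly in-grid
  pts <- voxel_to_world(idx, vol)
  got <- sample_label(vol, pts)
  grid_idx <- as.matrix(expand.grid(0:7, 0:7, 0:7))
  centers <- voxel_to_world(grid_idx, vol)
  # the affine is anisotropic, so "nearest center" is nearest in index space
  oracle <- vapply(seq_len(nrow(idx)), function(i) {
    d2 <- rowSums(sweep(grid_idx, 2, idx[i, ])^2)
    g[grid_idx[which.min(d2), , drop = FALSE] + 1]
  }, integer(1))
  expect_equal(mean(got == oracle), 1)
  expect_equal(nrow(idx), 2000)
})

test_that("axis-aligned reslice reproduces the orthogonal slice bit-exactly", {
  set.seed(41)
  g <- array(sample.int(50, 20^3, replace = TRUE), c(20, 20, 20))
  vol <- volume_image(g, kind = "label")
  rs <- reslice_along_trajectory(vol, p0 = c(0, 7, 9), p1 = c(19, 7, 9),
                                 width_mm = 38, spacing_mm = 1)
  # axis 1 = +x, axis 2 = +z; pixels land exactly on voxel centers
  expect_identical(dim(rs$image), c(20L, 39L))
  sub <- rs$image[, rs$t + 9 >= 0 & rs$t + 9 <= 19]
  expect_identical(sub, g[, 8, ])
  expect_equal(rs$p0_pixel[1], 1)
  expect_equal(rs$image[cbind(seq_len(20), 20)], g[, 8, 10])

  const <- volume_image(array(7L, c(10, 10, 10)), kind = "label")
  rc <- reslice_along_trajectory(const, c(2, 2, 2), c(7, 6, 5),
                                 width_mm = 4, spacing_mm = 0.5)
  expect_true(all(rc$image %in% c(7L, 0L)))
  expect_true(all(rc$image[rc$p0_pixel[1]:rc$p1_pixel[1], rc$p0_pixel[2]] == 7L))
})

test_that("reslice forward mapping places a marker voxel at the predicted pixel", {
  g <- array(0L, c(15, 15, 15))
  g[8, 11, 6] <- 99L  # 0-based (7, 10, 5)
  vol <- volume_image(g, kind = "label")
  rs <- reslice_along_trajectory(vol, p0 = c(7, 4, 5), p1 = c(7, 13, 5),
                                 width_mm = 20, spacing_mm = 1)
  marker_world <- c(7, 10, 5)
  rel <- marker_world - rs$origin
  si <- which(abs(rs$s - sum(rel * rs$axis_s)) < 1e-9)
  ti <- which(abs(rs$t - sum(rel * rs$axis_t)) < 1e-9)
  expect_length(si, 1)
  expect_length(ti, 1)
  expect_identical(rs$image[si, ti], 99L)
  expect_error(reslice_along_trajectory(vol, c(1, 1, 1), c(1, 1, 1)),
               "coincide")
})
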