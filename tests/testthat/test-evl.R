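test_that("voxelized enclosing volumes reproduce analytic volumes", {
  g <- array(0L, c(12, 12, 12))
  g[6, 6, 6] <- 1L
  vol <- volume_image(g, kind = "label")
  ev <- build_enclosing_volume(vol, 1L)
  expect_true(is_watertight(ev$boundary))
  expect_equal(mesh_volume(ev$boundary), 1, tolerance = 0.1)

  g2 <- array(0L, c(14, 14, 14))
  g2[3:12, 3:12, 3:12] <- 4L
  vol2 <- volume_image(g2, kind = "label")
  ev2 <- build_enclosing_volume(vol2, 4L)
  expect_true(is_watertight(ev2$boundary))
  expect_equal(mesh_volume(ev2$boundary), 1000, tolerance = 0.05 * 1000)
  expect_error(build_enclosing_volume(vol2, 9L), "9")

  # anisotropic voxels scale the enclosed volume by the affine determinant
  vol3 <- volume_image(g2, diag(c(2, 1, 0.5, 1)), kind = "label")
  ev3 <- build_enclosing_volume(vol3, 4L)
  expect_equal(mesh_volume(ev3$boundary), 1000, tolerance = 50)
})

test_that("lattice alpha complex encloses nearly all label voxel centers", {
  g <- array(0L, c(14, 14, 14))
  g[3:12, 3:12, 3:12] <- 4L
  vol <- volume_image(g, kind = "label")
  ev <- build_enclosing_volume(vol, 4L, method = "alpha_complex")
  expect_true(is_watertight(ev$boundary))
  expect_equal(mesh_volume(ev$boundary), 9^3, tolerance = 1e-6)
  centers <- voxel_to_world(as.matrix(which(g == 4L, arr.ind = TRUE)) - 1, vol)
  inside <- point_in_mesh(centers, ev$boundary, eps = 1e-7)
  expect_gte(mean(inside), 0.99)
  expect_error(build_enclosing_volume(vol, 4L, method = "alpha_complex",
                                      alpha = 0.5), "alpha")
})

test_that("point_in_volume matches the voxel-mask oracle away from the boundary", {
  # spherical blob mask
  idx <- as.matrix(expand.grid(0:16, 0:16, 0:16))
  g <- array(0L, c(17, 17, 17))
  r <- sqrt(rowSums((idx - 8)^2))
  g[idx[r <= 6, , drop = FALSE] + 1] <- 2L
  vol <- volume_image(g, kind = "label")
  ev <- build_enclosing_volume(vol, 2L)
  expect_true(point_in_volume(c(8, 8, 8), ev))        # centroid
  expect_false(point_in_volume(c(108, 8, 8), ev))     # far away
  set.seed(13)
  pts <- matrix(runif(6000, 0, 16), ncol = 3)
  d_to_surf <- abs(sqrt(rowSums(sweep(pts, 2, 8)^2)) - 6)
  pts <- pts[d_to_surf >= 1, , drop = FALSE]
  expect_gte(nrow(pts), 500)
  got <- point_in_volume(pts, ev)
  oracle <- sample_label(vol, pts) == 2L
  expect_equal(mean(got == oracle), 1)
})

test_that("boundary points count as inside", {
  g <- array(0L, c(8, 8, 8)); g[3:6, 3:6, 3:6] <- 1L
  ev <- build_enclosing_volume(volume_image(g, kind = "label"), 1L)
  # exact face, edge and corner points of the cube [1.5, 5.5]^3
  expect_true(all(point_in_volume(rbind(c(1.5, 3, 3), c(1.5, 1.5, 3),
                                        c(1.5, 1.5, 1.5), c(5.5, 5.5, 5.5)),
                                  ev)))
})

test_that("classification follows the subcortical > cortical > white > pial precedence", {
  h <- default_head()
  vols <- default_volumes()
  dth <- 2 * pi / h$n_wedges
  th <- -pi + 1.5 * dth  # middle of wedge 2
  pts <- rbind(
    c(10, 0, 3),                       # white interior
    55 * c(cos(th), sin(th), 0),       # wedge 2 interior
    c(0, 0, 65),                       # outside everything
    h$subcortical_centers[1, ],        # blob 1 center
    h$subcortical_centers[2, ])        # blob 2 center
  el <- electrode("T", pts)
  cls <- classify_contacts(el, h$parcellation, h$labels, h$pial,
                           volumes = vols)
  expect_identical(cls$class,
                   c("white", "cortical_grey", "outside", "subcortical",
                     "subcortical"))
  expect_identical(cls$label[2], 2L)
  expect_identical(cls$label[4:5], c(201L, 202L))
  expect_identical(cls$label[3], 0L)
})

test_that("contacts in a labelled-volume gap but under the pial hull are pial_surface", {
  g <- array(0L, c(21, 21, 21))
  g[9:13, 9:13, 9:13] <- 1L  # small cortical cube far inside a big pial hull
  vol <- volume_image(g, diag(c(1, 1, 1, 1)), kind = "label")
  labs <- label_table(c(0L, 1L), c("Unknown", "ctx-cube"),
                      c("background", "cortical_grey"))
  pial <- icosphere(9, 2, center = c(10, 10, 10))
  el <- electrode("P", rbind(c(10, 10, 10), c(10, 10, 16), c(10, 10, 40)))
  cls <- classify_contacts(el, vol, labs, pial)
  expect_identical(cls$class, c("cortical_grey", "pial_surface", "outside"))
  expect_identical(cls$label, c(1L, 0L, 0L))
})

test_that("export_label_meshes writes one readable STL per label", {
  h <- coarse_head()
  d <- tempfile()
  paths <- export_label_meshes(h$parcellation, h$labels, d)
  expect_length(paths, h$n_wedges + 1 + nrow(h$subcortical_centers))
  expect_true(all(file.exists(paths)))
  expect_match(basename(paths), "^[0-9]+_.+\\.stl$")
  m <- read_stl(paths[1])
  expect_gt(nrow(m$faces), 0)
  empty <- volume_image(array(0L, c(4, 4, 4)), kind = "label")
  expect_error(export_label_meshes(empty, h$labels, d), "no non-background")
})
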