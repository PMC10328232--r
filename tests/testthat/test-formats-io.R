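test_that("NIfTI volumes round-trip grid exactly and affine within 1e-6", {
  set.seed(5)
  g <- array(sample.int(12, 16^3, replace = TRUE) - 1L, c(16, 16, 16))
  A <- diag(c(1.2, 0.9, 1.1, 1)); A[1:3, 4] <- c(-9, -8, -7)
  vol <- volume_image(g, A, kind = "label")
  f <- tempfile(fileext = ".nii.gz")
  write_volume(vol, f)
  back <- read_volume(f, kind = "label")
  expect_identical(back$grid, g)
  expect_lt(max(abs(back$affine - A)), 1e-6)

  bad <- tempfile(fileext = ".nii")
  writeBin(as.raw(1:50), bad)
  expect_error(suppressWarnings(read_volume(bad)), "failed to read NIfTI")
})

test_that("FreeSurfer surfaces round-trip, with surface-RAS offset handling", {
  sph <- icosphere(60, 3)
  f <- tempfile(fileext = ".surf")
  write_surface(sph, f)
  back <- read_surface(f)
  expect_identical(nrow(back$vertices), nrow(sph$vertices))
  expect_identical(back$faces, sph$faces)
  expect_lt(max(abs(back$vertices - sph$vertices)), 1e-4)
  expect_identical(back$frame, "surface_ras")

  # companion volume: written minus center offset, read back plus offset
  vol <- volume_image(array(0L, c(30, 30, 30)),
                      rbind(cbind(diag(3), c(-10, -12, -14)), c(0, 0, 0, 1)))
  f2 <- tempfile(fileext = ".surf")
  write_surface(sph, f2, volume = vol)
  shifted <- read_surface(f2)
  off <- as.numeric(voxel_to_world(dim(vol$grid) / 2, vol))
  expect_lt(max(abs(sweep(shifted$vertices, 2, off, "+") - sph$vertices)),
            1e-3)
  restored <- read_surface(f2, volume = vol)
  expect_lt(max(abs(restored$vertices - sph$vertices)), 1e-3)
  expect_identical(restored$frame, "scanner_ras")

  empty <- tempfile()
  file.create(empty)
  expect_error(read_surface(empty), "magic")
})

test_that("color LUT parsing assigns categories and rejects duplicates", {
  f <- tempfile(fileext = ".lut")
  writeLines(c("# comment line",
               "0 Unknown 0 0 0 0",
               "17 Left-Hippocampus 220 216 20 0",
               "2 Left-Cerebral-White-Matter 245 245 245 0",
               "1021 ctx-lh-pericalcarine 120 100 60 0",
               "42 Mystery-region 1 2 3 0"), f)
  tab <- read_label_table(f)
  expect_identical(tab$category[tab$id == 0], "background")
  expect_identical(tab$category[tab$id == 17], "subcortical_grey")
  expect_identical(tab$category[tab$id == 2], "white")
  expect_identical(tab$category[tab$id == 1021], "cortical_grey")
  expect_identical(tab$category[tab$id == 42], "cortical_grey")  # id-range rule

  # explicit name -> category map wins
  tab2 <- read_label_table(f, category_map = c("Mystery-region" = "csf"))
  expect_identical(tab2$category[tab2$id == 42], "csf")

  writeLines(c("17 A 0 0 0 0", "17 B 0 0 0 0"), f)
  expect_error(read_label_table(f), "17")
})

test_that("contact tables group by electrode preserving order; bad rows error with line", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("electrode,contact,x,y,z",
               sprintf("RA,%d,%g,%g,%g", 1:8, 1:8, (1:8) * 2, 0)), f)
  els <- read_contacts(f)
  expect_length(els, 1)
  expect_identical(n_contacts(els$RA), 8L)
  expect_identical(els$RA$contacts, as.character(1:8))
  expect_identical(els$RA$kind, "depth")

  # interleaved electrodes keep within-electrode file order
  f2 <- tempfile(fileext = ".tsv")
  writeLines(c("electrode\tcontact\tx\ty\tz",
               "A\t1\t0\t0\t0", "B\t1\t9\t0\t0", "A\t2\t0\t5\t0",
               "B\t2\t9\t5\t0", "A\t3\t0\t10\t0"), f2)
  els2 <- read_contacts(f2)
  expect_identical(names(els2), c("A", "B"))
  expect_identical(els2$A$contacts, c("1", "2", "3"))
  expect_equal(els2$A$positions[, 2], c(0, 5, 10))
  expect_identical(els2$B$contacts, c("1", "2"))

  f3 <- tempfile(fileext = ".csv")
  writeLines(c("electrode,contact,x,y,z", "RA,1,1.0,2.0,3.0",
               "RA,3,1.0,foo,2.0"), f3)
  expect_error(read_contacts(f3), "line 3")

  # writer round trip including kinds/shapes on re-read
  out <- tempfile(fileext = ".csv")
  write_contacts(els2, out)
  back <- read_contacts(out, kinds = c(A = "strip"))
  expect_equal(back$A$positions, els2$A$positions, tolerance = 1e-9)
  expect_identical(back$A$kind, "strip")
})

test_that("binary STL round-trips triangle count and vertex positions", {
  sph <- icosphere(25, 2)
  f <- tempfile(fileext = ".stl")
  write_stl(sph, f)
  back <- read_stl(f)
  expect_identical(nrow(back$faces), nrow(sph$faces))
  # vertex sets match within STL float precision
  ord <- function(v) v[order(round(v[, 1], 3), round(v[, 2], 3),
                             round(v[, 3], 3)), ]
  expect_lt(max(abs(ord(back$vertices) - ord(sph$vertices))), 1e-3)
  expect_error(write_stl(surface_mesh(matrix(0, 1, 3),
                                      matrix(integer(0), 0, 3),
                                      check_watertight = FALSE), f),
               "empty")
})

test_that("probability spreadsheet keeps row sums within 1e-6 after round trip", {
  h <- coarse_head()
  el <- make_depth_electrode(h, entry = c(70, 30, 8), target = c(20, 9, 2),
                             n_contacts = 4, name = "RA")
  probs <- ela_label_contacts(el, h$parcellation, h$labels)
  f <- tempfile(fileext = ".csv")
  write_probability_table(probs, f)
  back <- read_probability_table(f)
  expect_identical(nrow(back), 4L)
  expect_gte(ncol(back), 5)
  pc <- grep("^p_", names(back))
  expect_gte(length(pc), 1)
  expect_lt(max(abs(rowSums(back[pc]) - 1)), 1e-6)
  expect_error(write_probability_table(list(), f), "label_probabilities")
})

test_that("BIDS electrodes.tsv is structurally valid and coordinates round-trip", {
  el <- electrode("RA", cbind(seq(0.123456789, by = 5, length.out = 8),
                              rep(1.5, 8), rep(-2.25, 8)),
                  size = c(rep(2.3, 7), NA))
  d <- tempfile()
  paths <- write_bids_electrodes(el, out_dir = d,
                                 coordinate_frame_name = "Other")
  lines <- readLines(paths[1])
  expect_length(lines, 9)  # header + 8 contacts
  fields <- strsplit(lines, "\t")
  expect_length(unique(lengths(fields)), 1)  # constant column count
  hdr <- fields[[1]]
  expect_true(all(c("name", "x", "y", "z", "size", "group", "tissue",
                    "label") %in% hdr))
  expect_false(any(grepl("[ \t]$", lines)))
  x <- as.numeric(vapply(fields[-1], `[[`, "", which(hdr == "x")))
  expect_lt(max(abs(x - el$positions[, 1])), 1e-6)
  expect_identical(vapply(fields[-1], `[[`, "", which(hdr == "size"))[8], "n/a")
  expect_identical(vapply(fields[-1], `[[`, "", which(hdr == "tissue"))[1], "n/a")
  js <- jsonlite::read_json(paths[2])
  expect_identical(js$iEEGCoordinateUnits, "mm")
  expect_identical(js$iEEGCoordinateSystem, "Other")
})
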