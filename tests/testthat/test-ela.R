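test_that("contact_axis uses central/one-sided differences and handles singles", {
  el <- electrode("S", cbind(0, 0, seq(0, 35, by = 5)))
  for (i in 1:8) expect_equal(contact_axis(el, i), c(0, 0, 1))
  single <- electrode("P", matrix(c(1, 2, 3), 1))
  expect_null(contact_axis(single, 1))

  # planar arc: axis equals the normalized neighbour difference by hand
  th <- seq(0, pi / 3, length.out = 6)
  arc <- electrode("A", cbind(30 * cos(th), 30 * sin(th), 0))
  for (i in 2:5) {
    d <- arc$positions[i + 1, ] - arc$positions[i - 1, ]
    expect_lt(max(abs(contact_axis(arc, i) - d / sqrt(sum(d^2)))), 1e-9)
  }
  d1 <- arc$positions[2, ] - arc$positions[1, ]
  expect_lt(max(abs(contact_axis(arc, 1) - d1 / sqrt(sum(d1^2)))), 1e-9)
  dup <- electrode("D", rbind(c(0, 0, 0), c(0, 0, 0), c(0, 0, 5)))
  expect_error(contact_axis(dup, 1), "oincident")
})

test_that("cylinder probabilities are exact in homogeneous and background regions", {
  g <- array(7L, c(21, 21, 21))
  vol <- volume_image(g, kind = "label")
  labs <- label_table(c(0L, 7L), c("Unknown", "ctx-seven"),
                      c("background", "cortical_grey"))
  p <- ela_probabilities(c(10, 10, 10), c(0, 0, 1), vol, labs)
  expect_identical(names(p), "7")
  expect_equal(sum(p), 1, tolerance = 1e-12)

  pbg <- ela_probabilities(c(500, 500, 500), c(0, 0, 1), vol, labs)
  expect_identical(names(pbg), "0")
  expect_equal(as.numeric(pbg), 1)
})

test_that("a contact on a planar label boundary splits mass evenly", {
  g <- array(3L, c(41, 41, 41))
  g[21:41, , ] <- 5L  # boundary plane at x = 19.5 (0-based centers 19|20)
  vol <- volume_image(g, kind = "label")
  labs <- label_table(c(0L, 3L, 5L), c("Unknown", "ctx-a", "ctx-b"),
                      c("background", "cortical_grey", "cortical_grey"))
  params <- ela_params()
  p <- ela_probabilities(c(19.5, 20, 20), axis = c(0, 0, 1), vol, labs,
                         params, half_length = 2)
  expect_equal(sum(p), 1, tolerance = 1e-9)
  expect_lt(abs(p[["3"]] - 0.5), 0.05)
  expect_lt(abs(p[["5"]] - 0.5), 0.05)

  # brute-force lattice count oracle for the same geometry (half-offset
  # cubic lattice about the contact)
  sp <- params$sample_spacing
  m <- ceiling(max(params$r_max, 2) / sp + 0.5)
  o1 <- (seq(-m, m - 1) + 0.5) * sp
  off <- as.matrix(expand.grid(o1, o1, o1))
  ax <- off[, 3]
  radial <- sqrt(off[, 1]^2 + off[, 2]^2)
  keep <- abs(ax) <= 2 + 1e-12
  radii <- seq_len(params$n_radii) * params$r_max / params$n_radii
  fr <- sapply(radii, function(r) {
    sel <- keep & radial <= r + 1e-12
    xs <- 19.5 + off[sel, 1]
    mean(xs < 19.5)  # nearest center below the plane carries label 3
  })
  expect_equal(as.numeric(p[["3"]]), mean(fr), tolerance = 1e-9)
})

test_that("bipolar probabilities live on the pair midpoint with half-gap length", {
  g <- array(7L, c(41, 41, 41))
  vol <- volume_image(g, kind = "label")
  labs <- label_table(c(0L, 7L), c("Unknown", "ctx-seven"),
                      c("background", "cortical_grey"))
  el <- electrode("B", cbind(20, 20, seq(14, 26, by = 4)))
  pb <- bipolar_probabilities(el, 2, vol, labs)
  expect_identical(names(pb), "7")
  direct <- ela_probabilities(c(20, 20, 20), c(0, 0, 1), vol, labs,
                              half_length = 2)
  expect_equal(as.numeric(pb), as.numeric(direct["7"]))
  expect_error(bipolar_probabilities(el, 4, vol, labs), "adjacent")
  expect_error(bipolar_probabilities(el, 0, vol, labs), "adjacent")
})

test_that("assign_region takes the grey argmax with deterministic tie and fallback rules", {
  labs <- label_table(c(0L, 3L, 5L, 7L, 100L),
                      c("Unknown", "ctx-a", "ctx-b", "ctx-c", "White"),
                      c("background", "cortical_grey", "cortical_grey",
                        "cortical_grey", "white"))
  a <- assign_region(c(`7` = 0.6, `100` = 0.4), labs)
  expect_identical(a$label, 7L)
  expect_false(a$fallback)
  b <- assign_region(c(`100` = 1.0), labs)
  expect_identical(b$label, 100L)
  expect_true(b$fallback)
  d <- assign_region(c(`3` = 0.4, `5` = 0.4, `100` = 0.2), labs)
  expect_identical(d$label, 3L)
  expect_equal(d$probability, 0.4)
  expect_true(d$tie)
  expect_error(assign_region(numeric(0), labs), "empty")

  # brute-force argmax oracle on random probability vectors
  set.seed(77)
  for (k in 1:50) {
    ids <- sort(sample(c(0L, 3L, 5L, 7L, 100L), sample(2:5, 1)))
    p <- stats::runif(length(ids)); p <- p / sum(p)
    names(p) <- ids
    got <- assign_region(p, labs)
    grey <- ids %in% c(3L, 5L, 7L) & p > 0
    pool <- if (any(grey)) p[grey] else p
    expect_identical(got$label, as.integer(names(pool)[which.max(pool)]))
    expect_identical(got$fallback, !any(grey))
  }
})

test_that("probabilities normalize and support grows monotonically with radius", {
  h <- default_head()
  el <- make_depth_electrode(h, entry = c(75, 35, 10), target = c(15, 7, 2),
                             n_contacts = 8, name = "RA")
  pr <- ela_label_contacts(el, h$parcellation, h$labels)
  expect_lt(max(abs(rowSums(pr$prob) - 1)), 1e-6)
  expect_true(all(pr$prob >= 0 & pr$prob <= 1))

  radii <- seq_len(6) * 3 / 6
  for (i in c(1, 4, 8)) {
    prev <- character(0)
    for (r in radii) {
      p <- ela_probabilities(el$positions[i, ], contact_axis(el, i),
                             h$parcellation, h$labels,
                             ela_params(r_max = r, n_radii = 1),
                             half_length = 2.5)
      expect_true(all(prev %in% names(p)))
      prev <- names(p)
    }
  }
})

test_that("bipolar mode of the driver labels pairs", {
  h <- coarse_head()
  el <- make_depth_electrode(h, entry = c(70, 30, 8), target = c(20, 9, 2),
                             n_contacts = 4, name = "RA")
  pr <- ela_label_contacts(el, h$parcellation, h$labels,
                           ela_params(mode = "bipolar"))
  expect_identical(nrow(pr$prob), 3L)
  expect_identical(pr$contact, c("1-2", "2-3", "3-4"))
  expect_lt(max(abs(rowSums(pr$prob) - 1)), 1e-6)
})
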