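# Shared fixtures, built once per test run. The default phantom is the
# study condition for the quantitative checks; the coarse phantom keeps
# cheap structural tests fast.
.fixtures <- new.env(parent = emptyenv())

default_head <- function() {
  if (is.null(.fixtures$head)) .fixtures$head <- make_head()
  .fixtures$head
}

coarse_head <- function() {
  if (is.null(.fixtures$coarse))
    .fixtures$coarse <- make_head(voxel_mm = 2, mesh_subdivisions = 2)
  .fixtures$coarse
}

default_volumes <- function() {
  if (is.null(.fixtures$vols)) {
    h <- default_head()
    .fixtures$vols <- build_enclosing_volumes(h$parcellation, h$labels)
  }
  .fixtures$vols
}

# Analytic distance from each point to the nearest label boundary of the
# phantom (sphere shells, wedge half-planes, blob surfaces); used to keep
# oracle comparisons away from discretization-ambiguous points.
truth_boundary_distance <- function(head, pts) {
  p <- as.matrix(pts)
  r <- sqrt(rowSums(p^2))
  rxy <- sqrt(p[, 1]^2 + p[, 2]^2)
  d <- pmin(abs(r - head$R_pial), abs(r - head$R_white))
  shell <- r >= head$R_white & r < head$R_pial
  if (any(shell)) {
    dth <- 2 * pi / head$n_wedges
    theta <- atan2(p[shell, 2], p[shell, 1])
    w <- floor((theta + pi) / dth)
    lo <- -pi + w * dth
    ang <- pmin(theta - lo, lo + dth - theta)
    d[shell] <- pmin(d[shell], rxy[shell] * sin(pmin(ang, pi / 2)))
  }
  for (s in seq_len(nrow(head$subcortical_centers))) {
    ds <- abs(sqrt(rowSums(sweep(p, 2, head$subcortical_centers[s, ])^2)) -
              head$subcortical_radii[s])
    d <- pmin(d, ds)
  }
  d
}

# Deterministic battery of short radial depth electrodes whose contacts all
# sit >= 2 mm inside cortical wedges (radii 52.5 and 57.5 mm).
interior_cortical_electrodes <- function(head) {
  dth <- 2 * pi / head$n_wedges
  els <- list()
  for (w in seq_len(head$n_wedges)) {
    thc <- -pi + (w - 0.5) * dth
    for (dthoff in c(-0.15, 0, 0.15)) {
      for (phi in c(50, 70, 90, 110, 130) * pi / 180) {
        th <- thc + dthoff
        dirv <- c(cos(th) * sin(phi), sin(th) * sin(phi), cos(phi))
        nm <- sprintf("W%d_%+0.2f_%03.0f", w, dthoff, phi * 180 / pi)
        els[[nm]] <- make_depth_electrode(
          head, entry = 70 * dirv, target = 52.5 * dirv,
          n_contacts = 2, spacing_mm = 5, name = nm)
      }
    }
  }
  els
}

# Depth electrodes whose contacts sit >= 2 mm inside the subcortical blobs.
interior_subcortical_electrodes <- function(head) {
  lapply(seq_len(nrow(head$subcortical_centers)), function(s) {
    cen <- head$subcortical_centers[s, ]
    make_depth_electrode(head, entry = cen + c(0, 0, 30),
                         target = cen + c(0, 0, -4),
                         n_contacts = 2, spacing_mm = 5,
                         name = paste0("SUB", s))
  })
}

truth_class <- function(labels_vec, labels) {
  cat_ <- labels$category[match(labels_vec, labels$id)]
  ifelse(labels_vec == 0, "outside",
         ifelse(cat_ == "cortical_grey", "cortical_grey",
                ifelse(cat_ == "subcortical_grey", "subcortical", "white")))
}
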