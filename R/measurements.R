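#' Midpoints of adjacent contact pairs
#'
#' The centre of each bipolar recording pair, in shaft order.
#'
#' @param electrode an [electrode()].
#' @return (n-1) x 3 matrix; zero rows when fewer than two contacts.
#' @export
bipolar_midpoints <- function(electrode) {
  p <- electrode$positions
  n <- nrow(p)
  if (n < 2) return(matrix(numeric(0), 0, 3))
  (p[-n, , drop = FALSE] + p[-1, , drop = FALSE]) / 2
}

#' Nearest mesh vertex to a query point
#'
#' Exact minimum over all vertices (ties break to the lowest index), the
#' operationalization of "distance to the nearest reconstructed vertex" of
#' a cortical surface.
#'
#' @param point 3-vector or n x 3 matrix, world mm.
#' @param mesh a non-empty [surface_mesh()].
#' @return for one point, list(`index`, `distance`); for several, a data
#'   frame with those columns.
#' @export
nearest_vertex <- function(point, mesh) {
  if (nrow(mesh$vertices) == 0) stop("mesh has no vertices")
  p <- as_points_matrix(point)
  v <- mesh$vertices
  vn2 <- rowSums(v^2)
  idx <- integer(nrow(p)); dist <- numeric(nrow(p))
  for (i in seq_len(nrow(p))) {
    d2 <- vn2 - 2 * as.numeric(v %*% p[i, ]) + sum(p[i, ]^2)
    idx[i] <- which.min(d2)
    dist[i] <- sqrt(max(d2[idx[i]], 0))
  }
  if (nrow(p) == 1) list(index = idx, distance = dist)
  else data.frame(index = idx, distance = dist)
}

#' Distances from a bipolar midpoint to the pial and white surfaces
#'
#' @param midpoint 3-vector or n x 3 matrix, world mm.
#' @param pial,white non-empty [surface_mesh()] objects.
#' @return data frame with `dist_pial`, `dist_white` (mm).
#' @export
grey_white_distances <- function(midpoint, pial, white) {
  p <- as_points_matrix(midpoint)
  dp <- nearest_vertex(p, pial)
  dw <- nearest_vertex(p, white)
  data.frame(dist_pial = if (is.list(dp) && !is.data.frame(dp)) dp$distance
             else dp$distance,
             dist_white = if (is.list(dw) && !is.data.frame(dw)) dw$distance
             else dw$distance)
}

#' Euclidean distances between consecutive contacts
#'
#' Recomputed from the picked coordinates as a sanity check on the manual
#' picks (nominal spacing is known from the hardware).
#'
#' @param electrode an [electrode()].
#' @return numeric vector of length n-1 (empty for a single contact).
#' @export
intercontact_distances <- function(electrode) {
  p <- electrode$positions
  n <- nrow(p)
  if (n < 2) return(numeric(0))
  sqrt(rowSums((p[-1, , drop = FALSE] - p[-n, , drop = FALSE])^2))
}

#' Angle between a contact axis and the local cortical axis
#'
#' The cortical-column direction is approximated by the area-weighted
#' vertex normal at the nearest mesh vertex; the angle is
#' `acos(|axis . normal|)`, folded into [0, 90] degrees since the shaft has
#' no preferred sign.
#'
#' @param axis unit 3-vector (e.g. from [contact_axis()]).
#' @param point query position, world mm.
#' @param mesh cortical [surface_mesh()] (pial by default in drivers).
#' @param normals optional precomputed [vertex_normals()] for `mesh`.
#' @return angle in degrees.
#' @export
angle_to_cortical_axis <- function(axis, point, mesh, normals = NULL) {
  axis <- as.numeric(axis)
  L <- sqrt(sum(axis^2))
  if (L < 1e-12) stop("zero-length contact axis")
  axis <- axis / L
  if (is.null(normals)) normals <- vertex_normals(mesh)
  nv <- nearest_vertex(point, mesh)
  n <- normals[nv$index, ]
  acos(pmin(1, abs(sum(axis * n)))) * 180 / pi
}

#' Per-pair anatomical measurements for an electrode
#'
#' For each adjacent contact pair: the midpoint, its distance to the
#' nearest pial and white vertices, the inter-contact distance, and the
#' shaft angle to the local cortical axis at the midpoint. The final row
#' per electrode repeats the last contact with `NA` pair fields so that
#' per-contact tables (BIDS export) can be joined on electrode + contact.
#'
#' @param electrode an [electrode()].
#' @param pial,white [surface_mesh()] objects.
#' @return data frame: electrode, contact, mid_x/y/z, dist_pial,
#'   dist_white, intercontact, angle_deg.
#' @export
contact_measurements <- function(electrode, pial, white) {
  n <- n_contacts(electrode)
  mids <- bipolar_midpoints(electrode)
  ic <- intercontact_distances(electrode)
  normals <- vertex_normals(pial)
  rows <- lapply(seq_len(n), function(i) {
    if (i < n) {
      gw <- grey_white_distances(mids[i, ], pial, white)
      ax <- contact_axis(electrode, i)
      ang <- if (is.null(ax)) NA_real_
             else angle_to_cortical_axis(ax, mids[i, ], pial, normals)
      data.frame(electrode = electrode$name, contact = electrode$contacts[i],
                 mid_x = mids[i, 1], mid_y = mids[i, 2], mid_z = mids[i, 3],
                 dist_pial = gw$dist_pial, dist_white = gw$dist_white,
                 intercontact = ic[i], angle_deg = ang)
    } else {
      data.frame(electrode = electrode$name, contact = electrode$contacts[i],
                 mid_x = NA_real_, mid_y = NA_real_, mid_z = NA_real_,
                 dist_pial = NA_real_, dist_white = NA_real_,
                 intercontact = NA_real_, angle_deg = NA_real_)
    }
  })
  do.call(rbind, rows)
}

#' Tissue-class counts per electrode trajectory
#'
#' Counts contacts per tissue class for each electrode plus a pooled
#' `(all)` row, the per-trajectory summary used to compare grey/white
#' coverage across implants.
#'
#' @param classification a `tissue_classification` data frame from
#'   [classify_contacts()].
#' @return data frame: electrode, one column per class, `total`.
#' @export
trajectory_summary <- function(classification) {
  classes <- c("cortical_grey", "subcortical", "white", "pial_surface",
               "outside")
  mk <- function(sub, name) {
    cnt <- vapply(classes, function(cl) sum(sub$class == cl), 0L)
    out <- data.frame(electrode = name, t(cnt), total = nrow(sub),
                      check.names = FALSE)
    names(out)[2:6] <- classes
    out
  }
  per <- do.call(rbind, lapply(split(classification,
                                     classification$electrode),
                               function(s) mk(s, s$electrode[1])))
  out <- rbind(per, mk(classification, "(all)"))
  rownames(out) <- NULL
  out
}
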