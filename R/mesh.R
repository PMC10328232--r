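#' Triangle surface mesh in world millimetres
#'
#' @param vertices N x 3 numeric matrix, world-RAS mm.
#' @param faces M x 3 integer matrix of 1-based vertex indices.
#' @param frame coordinate frame tag, as for [volume_image()].
#' @param check_watertight verify that every edge is shared by exactly two
#'   faces (required for membership tests and snapping targets).
#' @return object of class `surface_mesh` with fields `vertices`, `faces`
#'   (1-based), `watertight`, `frame`.
#' @export
surface_mesh <- function(vertices, faces, frame = "scanner_ras",
                         check_watertight = TRUE) {
  vertices <- as.matrix(vertices)
  faces <- matrix(as.integer(as.matrix(faces)), ncol = 3)
  if (ncol(vertices) != 3L) stop("'vertices' must be N x 3")
  if (nrow(faces) > 0 && (min(faces) < 1L || max(faces) > nrow(vertices)))
    stop("face indices out of range [1, N]")
  wt <- if (check_watertight) edge_manifold(faces) else NA
  structure(list(vertices = vertices, faces = faces,
                 watertight = isTRUE(wt), frame = frame),
            class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("<surface_mesh> %d vertices, %d faces%s (%s)\n",
              nrow(x$vertices), nrow(x$faces),
              if (isTRUE(x$watertight)) ", watertight" else "", x$frame))
  invisible(x)
}

# TRUE iff every undirected edge occurs in exactly 2 faces
edge_manifold <- function(faces) {
  if (nrow(faces) == 0L) return(FALSE)
  e <- rbind(faces[, c(1, 2)], faces[, c(2, 3)], faces[, c(3, 1)])
  key <- pmin(e[, 1], e[, 2]) * (max(faces) + 1) + pmax(e[, 1], e[, 2])
  all(tabulate(match(key, unique(key))) == 2L)
}

#' Is a mesh watertight (2-manifold closed)?
#' @param mesh a [surface_mesh()].
#' @export
is_watertight <- function(mesh) isTRUE(mesh$watertight) || edge_manifold(mesh$faces)

#' Icosphere mesh
#'
#' Subdivided icosahedron projected onto the sphere; the standard discrete
#' sphere used for the phantom's pial and white surfaces.
#'
#' @param radius sphere radius, mm.
#' @param subdivisions number of 4-to-1 triangle subdivisions (4 gives 2562
#'   vertices / 5120 faces, edge length about 4 mm at R = 60).
#' @param center sphere center, world mm.
#' @export
icosphere <- function(radius = 1, subdivisions = 4, center = c(0, 0, 0)) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdivisions)) {
    midcache <- new.env(hash = TRUE, parent = emptyenv())
    nv <- nrow(v)
    newv <- list(v)
    midpoint <- function(a, b) {
      key <- paste(min(a, b), max(a, b))
      hit <- midcache[[key]]
      if (!is.null(hit)) return(hit)
      m <- (v[a, ] + v[b, ]) / 2
      m <- m / sqrt(sum(m^2))
      nv <<- nv + 1L
      newv[[length(newv) + 1L]] <<- m
      midcache[[key]] <- nv
      nv
    }
    nf <- matrix(0L, nrow(f) * 4L, 3L)
    for (i in seq_len(nrow(f))) {
      a <- f[i, 1]; b <- f[i, 2]; c <- f[i, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, c); ca <- midpoint(c, a)
      nf[4 * i - 3, ] <- c(a, ab, ca)
      nf[4 * i - 2, ] <- c(b, bc, ab)
      nf[4 * i - 1, ] <- c(c, ca, bc)
      nf[4 * i, ] <- c(ab, bc, ca)
    }
    v <- do.call(rbind, newv)
    f <- nf
  }
  v <- v * radius
  v <- sweep(v, 2, center, "+")
  surfm <- surface_mesh(v, f, check_watertight = FALSE)
  surfm$watertight <- TRUE  # closed by construction
  surfm
}

# per-face unit normals and areas
face_normals <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  b <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  n <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
             a[, 3] * b[, 1] - a[, 1] * b[, 3],
             a[, 1] * b[, 2] - a[, 2] * b[, 1])
  len <- sqrt(rowSums(n^2))
  list(normals = n / pmax(len, .Machine$double.eps), areas = len / 2)
}

#' Area-weighted vertex normals
#'
#' Approximates the local cortical-column direction at a surface vertex.
#'
#' @param mesh a [surface_mesh()].
#' @return N x 3 matrix of unit normals.
#' @export
vertex_normals <- function(mesh) {
  fn <- face_normals(mesh)
  wn <- fn$normals * fn$areas
  n <- matrix(0, nrow(mesh$vertices), 3)
  for (k in 1:3) {
    for (j in 1:3) {
      agg <- rowsum(wn[, j], mesh$faces[, k])
      n[as.integer(rownames(agg)), j] <- n[as.integer(rownames(agg)), j] + agg
    }
  }
  n / pmax(sqrt(rowSums(n^2)), .Machine$double.eps)
}

#' Enclosed volume of a watertight mesh (divergence theorem)
#' @param mesh a watertight [surface_mesh()].
#' @return volume in mm^3.
#' @export
mesh_volume <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]; b <- v[f[, 2], , drop = FALSE]
  c <- v[f[, 3], , drop = FALSE]
  abs(sum(a[, 1] * (b[, 2] * c[, 3] - b[, 3] * c[, 2]) +
          a[, 2] * (b[, 3] * c[, 1] - b[, 1] * c[, 3]) +
          a[, 3] * (b[, 1] * c[, 2] - b[, 2] * c[, 1])) / 6)
}

#' Point-in-mesh membership test
#'
#' Ray-parity test against a watertight triangle mesh; points within `eps`
#' of the surface count as inside (boundary points are members).
#'
#' @param points n x 3 world mm.
#' @param mesh a watertight [surface_mesh()].
#' @param eps boundary tolerance in mm.
#' @return logical vector.
#' @export
point_in_mesh <- function(points, mesh, eps = 1e-8) {
  if (!is_watertight(mesh))
    stop("membership test requires a watertight mesh")
  p <- as_points_matrix(points)
  out <- logical(nrow(p))
  # bounding-box prefilter (with eps margin)
  lo <- apply(mesh$vertices, 2, min) - eps
  hi <- apply(mesh$vertices, 2, max) + eps
  inbox <- p[, 1] >= lo[1] & p[, 1] <= hi[1] &
           p[, 2] >= lo[2] & p[, 2] <= hi[2] &
           p[, 3] >= lo[3] & p[, 3] <= hi[3]
  if (any(inbox)) {
    out[inbox] <- cpp_points_in_mesh(p[inbox, , drop = FALSE],
                                     mesh$vertices, mesh$faces - 1L, eps)
  }
  out
}

#' Nearest point on a mesh surface
#'
#' Exact point-to-triangle projection over all faces.
#'
#' @param points n x 3 world mm.
#' @param mesh a [surface_mesh()].
#' @return list with `points` (n x 3 projections), `distance` (n), `face`
#'   (1-based nearest face index).
#' @export
project_to_surface <- function(points, mesh) {
  p <- as_points_matrix(points)
  res <- cpp_nearest_point_on_mesh(p, mesh$vertices, mesh$faces - 1L)
  list(points = res$points, distance = as.numeric(res$distance),
       face = as.integer(res$face) + 1L)
}
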