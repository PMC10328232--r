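# ---- watertight boundary extraction from voxel masks -----------------------

# Quad corner offsets (doubled index units) per face direction, ordered so
# the outward normal matches the direction.
QUAD_OFFSETS <- list(
  `+x` = rbind(c(1,-1,-1), c(1, 1,-1), c(1, 1, 1), c(1,-1, 1)),
  `-x` = rbind(c(-1,-1,-1), c(-1,-1, 1), c(-1, 1, 1), c(-1, 1,-1)),
  `+y` = rbind(c(-1, 1,-1), c(-1, 1, 1), c(1, 1, 1), c(1, 1,-1)),
  `-y` = rbind(c(-1,-1,-1), c(1,-1,-1), c(1,-1, 1), c(-1,-1, 1)),
  `+z` = rbind(c(-1,-1, 1), c(1,-1, 1), c(1, 1, 1), c(-1, 1, 1)),
  `-z` = rbind(c(-1,-1,-1), c(-1, 1,-1), c(1, 1,-1), c(1,-1,-1)))
QUAD_DIRS <- rbind(c(1,0,0), c(-1,0,0), c(0,1,0), c(0,-1,0), c(0,0,1), c(0,0,-1))

# Boundary surface of the union of unit cubes centred on TRUE cells of
# `mask` (cell centres at 0-based index `ind - 1 + origin_shift`), mapped to
# world mm by `affine`. Returns a closed triangle mesh; rare non-manifold
# edges from diagonally touching cubes are resolved by splitting vertex fans
# so each edge is shared by exactly two faces.
voxel_boundary_mesh <- function(mask, affine, origin_shift = 0) {
  d <- dim(mask)
  pad <- array(FALSE, d + 2L)
  pad[seq_len(d[1]) + 1L, seq_len(d[2]) + 1L, seq_len(d[3]) + 1L] <- mask
  corners <- list(); gens <- list()
  for (k in 1:6) {
    dir <- QUAD_DIRS[k, ]
    nb <- pad[seq_len(d[1]) + 1L + dir[1],
              seq_len(d[2]) + 1L + dir[2],
              seq_len(d[3]) + 1L + dir[3]]
    cells <- which(mask & !nb)
    if (length(cells) == 0) next
    ai <- arrayInd(cells, d)
    # doubled 0-based centre coordinates (integers for shift 0 or 0.5)
    cen2 <- 2L * (ai - 1L) + round(2 * origin_shift)
    off <- QUAD_OFFSETS[[k]]
    cc <- matrix(0L, 4L * nrow(cen2), 3L)
    for (q in 1:4)
      cc[seq(q, by = 4L, length.out = nrow(cen2)), ] <-
        cen2 + matrix(off[q, ], nrow(cen2), 3, byrow = TRUE)
    corners[[length(corners) + 1L]] <- cc
    gens[[length(gens) + 1L]] <- rep(cells, each = 1L)
  }
  if (length(corners) == 0) stop("mask is empty")
  cc <- do.call(rbind, corners)
  gen_quad <- unlist(gens)
  M <- 2 * max(d) + 5
  key <- (cc[, 1] + 2) + (cc[, 2] + 2) * M + (cc[, 3] + 2) * M * M
  uk <- unique(key)
  vid <- match(key, uk)
  uverts2 <- cc[!duplicated(key), , drop = FALSE]
  nq <- length(gen_quad)
  q <- matrix(vid, nrow = 4)  # 4 x nq corner ids
  tris <- rbind(cbind(q[1, ], q[2, ], q[3, ]),
                cbind(q[1, ], q[3, ], q[4, ]))
  gen <- c(gen_quad, gen_quad)
  sp <- split_nonmanifold(uverts2, tris, gen)
  # doubled index -> world
  idx <- (sp$verts / 2)
  world <- cbind(idx, 1) %*% t(affine)
  mesh <- surface_mesh(world[, 1:3, drop = FALSE], sp$tris,
                       check_watertight = FALSE)
  mesh$watertight <- edge_manifold(sp$tris)
  mesh
}

# Split vertex fans at edges shared by four faces (two cubes touching along
# an edge): faces generated by the same cube pair together.
split_nonmanifold <- function(verts, tris, gen) {
  n <- nrow(verts)
  ekey <- function(a, b) pmin(a, b) * (n + 1) + pmax(a, b)
  e <- rbind(cbind(tris[, 1], tris[, 2]),
             cbind(tris[, 2], tris[, 3]),
             cbind(tris[, 3], tris[, 1]))
  keys <- ekey(e[, 1], e[, 2])
  cnt <- table(keys)
  bad <- as.numeric(names(cnt)[cnt > 2])
  if (length(bad) == 0) return(list(verts = verts, tris = tris))
  badv <- unique(c(e[keys %in% bad, 1], e[keys %in% bad, 2]))
  vface <- split(rep(seq_len(nrow(tris)), 3), as.vector(tris))
  for (v in badv) {
    fs <- vface[[as.character(v)]]
    if (length(fs) < 2) next
    # adjacency among incident faces: connect across manifold shared edges,
    # and across non-manifold edges only when generated by the same cube
    adj <- matrix(FALSE, length(fs), length(fs))
    for (i in seq_along(fs)) for (j in seq_along(fs)) {
      if (i >= j) next
      shared <- intersect(tris[fs[i], ], tris[fs[j], ])
      if (length(shared) < 2) next
      k2 <- ekey(shared[1], shared[2])
      ok <- if (k2 %in% bad) gen[fs[i]] == gen[fs[j]] else TRUE
      adj[i, j] <- adj[j, i] <- ok
    }
    comp <- rep(0L, length(fs)); cid <- 0L
    for (i in seq_along(fs)) {
      if (comp[i]) next
      cid <- cid + 1L
      queue <- i
      while (length(queue)) {
        cur <- queue[1]; queue <- queue[-1]
        if (comp[cur]) next
        comp[cur] <- cid
        queue <- c(queue, which(adj[cur, ] & comp == 0L))
      }
    }
    for (ci in seq_len(max(comp))[-1]) {
      verts <- rbind(verts, verts[v, , drop = FALSE])
      nv <- nrow(verts)
      for (fi in fs[comp == ci]) tris[fi, tris[fi, ] == v] <- nv
    }
  }
  list(verts = verts, tris = tris)
}

# ---- enclosing volumes ------------------------------------------------------

#' Watertight enclosing volume of one parcellation label
#'
#' The `voxelized` method (default) takes the exact boundary of the union
#' of voxel cubes carrying the label -- the 0.5 isosurface of the binary
#' mask -- so every voxel centre with the label is strictly inside. The
#' `alpha_complex` method builds the alpha complex over the voxel-centre
#' point cloud; on a regular lattice with `alpha >= sqrt(3)/2 * voxel` this
#' is exactly the union of fully occupied 2x2x2 voxel-centre cubes, whose
#' boundary is extracted watertight (thin single-voxel sheets are eroded,
#' which is the expected alpha-shape behaviour).
#'
#' @param parcellation label [volume_image()].
#' @param label label id present in the volume.
#' @param method `"voxelized"` or `"alpha_complex"`.
#' @param alpha alpha radius in mm for `alpha_complex` (default twice the
#'   voxel size).
#' @return object of class `enclosing_volume` with fields `label`,
#'   `boundary` ([surface_mesh()]), `method`.
#' @export
build_enclosing_volume <- function(parcellation, label,
                                   method = c("voxelized", "alpha_complex"),
                                   alpha = NULL) {
  method <- match.arg(method)
  mask <- parcellation$grid == label
  if (!any(mask))
    stop("label ", label, " is absent from the parcellation")
  vox <- mean(sqrt(colSums(parcellation$affine[1:3, 1:3]^2)))
  if (method == "voxelized") {
    boundary <- voxel_boundary_mesh(mask, parcellation$affine)
  } else {
    if (is.null(alpha)) alpha <- 2 * vox
    if (alpha < sqrt(3) / 2 * vox)
      stop("alpha below the lattice circumradius: alpha complex is empty")
    d <- dim(mask)
    if (any(d < 2)) stop("volume too small for an alpha complex")
    i1 <- seq_len(d[1] - 1); j1 <- seq_len(d[2] - 1); k1 <- seq_len(d[3] - 1)
    cells <- mask[i1, j1, k1, drop = FALSE]
    for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
      if (dx + dy + dz == 0) next
      cells <- cells & mask[i1 + dx, j1 + dy, k1 + dz, drop = FALSE]
    }
    if (!any(cells))
      stop("label ", label, " has no fully occupied lattice cube; ",
           "alpha complex is empty")
    boundary <- voxel_boundary_mesh(cells, parcellation$affine,
                                    origin_shift = 0.5)
  }
  structure(list(label = label, boundary = boundary, method = method),
            class = "enclosing_volume")
}

#' Build enclosing volumes for all labellable regions
#'
#' One [build_enclosing_volume()] per cortical-grey, subcortical-grey and
#' white label present in the parcellation.
#'
#' @inheritParams build_enclosing_volume
#' @param labels a [label_table()].
#' @return named list of `enclosing_volume` objects (names = label ids).
#' @export
build_enclosing_volumes <- function(parcellation, labels,
                                    method = "voxelized", alpha = NULL) {
  present <- sort(unique(as.integer(parcellation$grid)))
  present <- present[present != 0L]
  cats <- label_category(labels, present)
  keep <- present[cats %in% c("cortical_grey", "subcortical_grey", "white")]
  out <- lapply(keep, function(l)
    build_enclosing_volume(parcellation, l, method, alpha))
  stats::setNames(out, as.character(keep))
}

#' Is a point inside an enclosing volume?
#'
#' Ray-parity membership against the watertight boundary; boundary points
#' count as inside.
#'
#' @param points n x 3 world mm.
#' @param ev an `enclosing_volume`.
#' @export
point_in_volume <- function(points, ev) {
  point_in_mesh(points, ev$boundary)
}

# five-way classification of bare points (shared by contacts and oracle
# checks); precedence: subcortical > cortical > white > pial hull > outside
classify_points <- function(points, volumes, labels, pial) {
  p <- as_points_matrix(points)
  n <- nrow(p)
  cls <- rep("outside", n)
  lab <- integer(n)
  vol_ids <- as.integer(names(volumes))
  vol_cat <- label_category(labels, vol_ids)
  todo <- rep(TRUE, n)
  for (category in c("subcortical_grey", "cortical_grey", "white")) {
    for (vi in which(vol_cat == category)) {
      if (!any(todo)) break
      hit <- rep(FALSE, n)
      hit[todo] <- point_in_volume(p[todo, , drop = FALSE], volumes[[vi]])
      cls[hit] <- if (category == "subcortical_grey") "subcortical"
                  else if (category == "cortical_grey") "cortical_grey"
                  else "white"
      lab[hit] <- vol_ids[vi]
      todo <- todo & !hit
    }
  }
  if (any(todo)) {
    hit <- rep(FALSE, n)
    hit[todo] <- point_in_mesh(p[todo, , drop = FALSE], pial)
    cls[hit] <- "pial_surface"
  }
  lab[cls %in% c("pial_surface", "outside")] <- 0L
  data.frame(class = cls, label = lab)
}

#' Volumetric tissue classification of electrode contacts
#'
#' Each contact receives exactly one of five classes by precedence: inside
#' a subcortical volume, inside a cortical-grey volume, inside a
#' white-matter volume, inside the pial hull but none of the above
#' (`pial_surface`, surface-array contacts in sulci), else `outside`.
#'
#' @param electrodes an [electrode()] or list of them.
#' @param parcellation label [volume_image()].
#' @param labels a [label_table()].
#' @param pial watertight pial [surface_mesh()].
#' @param method enclosing-volume construction, see
#'   [build_enclosing_volume()].
#' @param volumes optional pre-built [build_enclosing_volumes()] result
#'   (reused across calls).
#' @return `tissue_classification` data frame: electrode, contact, class,
#'   label, label_name.
#' @export
classify_contacts <- function(electrodes, parcellation, labels, pial,
                              method = "voxelized", volumes = NULL) {
  if (!is_watertight(pial)) stop("pial surface must be watertight")
  electrodes <- as_electrode_list(electrodes)
  if (is.null(volumes))
    volumes <- build_enclosing_volumes(parcellation, labels, method)
  out <- do.call(rbind, lapply(electrodes, function(el) {
    res <- classify_points(el$positions, volumes, labels, pial)
    data.frame(electrode = el$name, contact = el$contacts,
               class = res$class, label = res$label,
               label_name = label_name(labels, res$label))
  }))
  rownames(out) <- NULL
  class(out) <- c("tissue_classification", "data.frame")
  out
}

#' Export one STL per parcellation label
#'
#' Writes the enclosing volume of every non-background label present in the
#' parcellation as `<id>_<name>.stl` under `out_dir`.
#'
#' @inheritParams classify_contacts
#' @param out_dir output directory (created if missing).
#' @return invisible character vector of written paths.
#' @export
export_label_meshes <- function(parcellation, labels, out_dir,
                                method = "voxelized") {
  present <- sort(unique(as.integer(parcellation$grid)))
  present <- present[present != 0L]
  if (length(present) == 0)
    stop("parcellation contains no non-background labels")
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  paths <- character(0)
  for (l in present) {
    ev <- build_enclosing_volume(parcellation, l, method)
    fn <- file.path(out_dir, sprintf("%d_%s.stl", l, label_name(labels, l)))
    tryCatch(write_stl(ev$boundary, fn),
             error = function(e) stop("failed writing '", fn, "': ",
                                      conditionMessage(e)))
    paths <- c(paths, fn)
  }
  invisible(paths)
}
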