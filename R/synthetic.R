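#' Synthetic labelled head phantom
#'
#' Builds a spherical head phantom with analytic ground truth, standing in
#' for a FreeSurfer reconstruction: a pial sphere of radius `R_pial`, a
#' white-matter sphere of radius `R_white`, `n_wedges` cortical wedge labels
#' partitioning the shell between them by azimuth, and spherical subcortical
#' blobs inside the white sphere. The parcellation is rendered voxel-exactly
#' from the analytic geometry (deterministic, no randomness), so every
#' downstream labelling and measurement stage can be scored against exact
#' truth.
#'
#' Label ids: 0 background, `1..n_wedges` cortical wedges, 100 white,
#' 201.. subcortical blobs.
#'
#' @param R_pial,R_white pial and white sphere radii, mm (`R_white < R_pial`).
#' @param n_wedges number of azimuthal cortical wedge labels.
#' @param subcortical_centers k x 3 matrix of blob centers, mm.
#' @param subcortical_radii k blob radii, mm; each blob must lie strictly
#'   inside the white sphere so the truth stays unambiguous.
#' @param voxel_mm isotropic voxel size of the parcellation.
#' @param mesh_subdivisions icosphere subdivision level of the surfaces.
#' @return object of class `synthetic_head`: `parcellation`
#'   ([volume_image()]), `pial`, `white` ([surface_mesh()]), `labels`
#'   ([label_table()]), and `truth`, a function mapping n x 3 world points
#'   to analytic label ids.
#' @export
make_head <- function(R_pial = 60, R_white = 50, n_wedges = 8,
                      subcortical_centers = rbind(c(-20, 0, 0), c(20, 0, 0)),
                      subcortical_radii = c(8, 8),
                      voxel_mm = 1.0, mesh_subdivisions = 4) {
  if (R_white <= 0 || R_white >= R_pial)
    stop("need 0 < R_white < R_pial")
  if (n_wedges < 1) stop("n_wedges must be >= 1")
  n_wedges <- as.integer(n_wedges)
  subcortical_centers <- as_points_matrix(subcortical_centers)
  nsub <- nrow(subcortical_centers)
  if (length(subcortical_radii) != nsub)
    stop("one radius per subcortical center required")
  cdist <- sqrt(rowSums(subcortical_centers^2))
  if (any(cdist + subcortical_radii >= R_white))
    stop("subcortical sphere crosses the white-matter boundary")

  truth <- function(points) {
    p <- as_points_matrix(points)
    r <- sqrt(rowSums(p^2))
    lab <- integer(nrow(p))
    shell <- r >= R_white & r < R_pial
    if (any(shell)) {
      theta <- atan2(p[shell, 2], p[shell, 1])
      k <- as.integer(floor((theta + pi) / (2 * pi / n_wedges)))
      k[k >= n_wedges] <- n_wedges - 1L
      lab[shell] <- k + 1L
    }
    deep <- r < R_white
    lab[deep] <- 100L
    for (s in seq_len(nsub)) {
      d2 <- rowSums(sweep(p, 2, subcortical_centers[s, ])^2)
      lab[deep & d2 <= subcortical_radii[s]^2] <- 200L + s
    }
    lab
  }

  half <- ceiling(R_pial / voxel_mm)
  idx <- seq(-half, half)
  n <- length(idx)
  affine <- diag(c(voxel_mm, voxel_mm, voxel_mm, 1))
  affine[1:3, 4] <- -half * voxel_mm
  xs <- idx * voxel_mm
  pts <- cbind(rep(xs, times = n * n),
               rep(rep(xs, each = n), times = n),
               rep(xs, each = n * n))
  grid <- array(truth(pts), dim = c(n, n, n))

  labels <- label_table(
    id = c(0L, seq_len(n_wedges), 100L, 200L + seq_len(nsub)),
    name = c("Unknown", paste0("ctx-wedge-", seq_len(n_wedges)),
             "Cerebral-White-Matter", paste0("Subcortical-blob-", seq_len(nsub))),
    category = c("background", rep("cortical_grey", n_wedges), "white",
                 rep("subcortical_grey", nsub)),
    color = cbind((c(0, seq_len(n_wedges) * 25, 250, 200 + seq_len(nsub))) %% 256,
                  (c(0, seq_len(n_wedges) * 60, 250, 60 * seq_len(nsub))) %% 256,
                  (c(0, seq_len(n_wedges) * 95, 250, 30 * seq_len(nsub))) %% 256))

  structure(list(
    parcellation = volume_image(grid, affine, kind = "label"),
    pial = icosphere(R_pial, mesh_subdivisions),
    white = icosphere(R_white, mesh_subdivisions),
    labels = labels,
    truth = truth,
    R_pial = R_pial, R_white = R_white, n_wedges = n_wedges,
    subcortical_centers = subcortical_centers,
    subcortical_radii = subcortical_radii,
    voxel_mm = voxel_mm), class = "synthetic_head")
}

#' @export
print.synthetic_head <- function(x, ...) {
  cat(sprintf(paste0("<synthetic_head> R_pial=%g R_white=%g, %d wedges, ",
                     "%d subcortical blobs, %s voxels\n"),
              x$R_pial, x$R_white, x$n_wedges,
              nrow(x$subcortical_centers),
              paste(dim(x$parcellation$grid), collapse = "x")), ...)
  invisible(x)
}

#' Synthetic depth electrode
#'
#' Colinear contacts from `target` toward `entry` at exact spacing,
#' mirroring clinical depth electrodes (4-16 contacts, inter-contact
#' spacing 4-10 mm, median 5 mm). The analytic truth label of each contact
#' is attached as `$truth`.
#'
#' @param head a [make_head()] phantom.
#' @param entry,target trajectory endpoints, world mm (`entry != target`);
#'   contact 1 sits at `target`.
#' @param n_contacts number of contacts.
#' @param spacing_mm exact inter-contact spacing.
#' @param name electrode name.
#' @return an [electrode()] of kind `"depth"` with a `truth` field.
#' @export
make_depth_electrode <- function(head, entry, target, n_contacts,
                                 spacing_mm = 5, name = "D1") {
  entry <- as.numeric(entry); target <- as.numeric(target)
  d <- entry - target
  L <- sqrt(sum(d^2))
  if (L < .Machine$double.eps) stop("entry and target coincide")
  if (n_contacts < 1) stop("n_contacts must be >= 1")
  u <- d / L
  pos <- matrix(target, n_contacts, 3, byrow = TRUE) +
    outer((seq_len(n_contacts) - 1) * spacing_mm, u)
  el <- electrode(name, pos, kind = "depth")
  el$truth <- head$truth(pos)
  el
}

#' Synthetic ECoG grid over the phantom
#'
#' Planar `rows x cols` array tangent to the pial sphere at
#' `center_direction * R_pial`, displaced outward by `lift_mm` and optionally
#' jittered, emulating the brain-shift displacement that Step-5 snapping
#' corrects. Deterministic for a fixed seed; the caller's RNG state is left
#' untouched.
#'
#' @param head a [make_head()] phantom.
#' @param center_direction direction of the grid center from the head
#'   origin (normalized internally).
#' @param rows,cols grid dimensions.
#' @param pitch_mm nominal neighbor spacing.
#' @param lift_mm outward displacement along `center_direction`.
#' @param jitter_sd_mm per-coordinate Gaussian jitter SD; requires `seed`.
#' @param seed RNG seed for the jitter.
#' @param name electrode name.
#' @return an [electrode()] of kind `"grid"` (row-major contact order).
#' @export
make_grid <- function(head, center_direction, rows, cols, pitch_mm = 10,
                      lift_mm = 0, jitter_sd_mm = 0, seed = NULL,
                      name = "G1") {
  if (rows < 1 || cols < 1) stop("rows and cols must be >= 1")
  if (jitter_sd_mm > 0 && is.null(seed))
    stop("a seed is required when jitter_sd_mm > 0")
  dirv <- as.numeric(center_direction)
  dirv <- dirv / sqrt(sum(dirv^2))
  e <- if (abs(dirv[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- e - sum(e * dirv) * dirv
  u <- u / sqrt(sum(u^2))
  v <- c(dirv[2] * u[3] - dirv[3] * u[2],
         dirv[3] * u[1] - dirv[1] * u[3],
         dirv[1] * u[2] - dirv[2] * u[1])
  center <- (head$R_pial + lift_mm) * dirv
  ri <- rep(seq_len(rows), each = cols) - (rows + 1) / 2
  ci <- rep(seq_len(cols), times = rows) - (cols + 1) / 2
  pos <- matrix(center, rows * cols, 3, byrow = TRUE) +
    outer(ri * pitch_mm, u) + outer(ci * pitch_mm, v)
  if (jitter_sd_mm > 0) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    set.seed(seed)
    pos <- pos + matrix(stats::rnorm(length(pos), sd = jitter_sd_mm),
                        nrow(pos), 3)
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else rm(".Random.seed", envir = globalenv())
  }
  electrode(name, pos, kind = "grid", grid_shape = c(rows, cols))
}

#' Write a phantom (and optional implants) to disk
#'
#' Emits the four standard inputs the localization stages consume:
#' `parcellation.nii.gz`, `pial.surf` / `white.surf` (FreeSurfer triangle
#' format, surface-RAS convention relative to the parcellation),
#' `labels.lut` and, when electrodes are given, `contacts.csv`.
#'
#' @param head a [make_head()] phantom.
#' @param out_dir output directory (created if missing).
#' @param electrodes optional [electrode()] list for `contacts.csv`.
#' @return invisible named character vector of written paths.
#' @export
write_head <- function(head, out_dir, electrodes = NULL) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  paths <- c(
    parcellation = file.path(out_dir, "parcellation.nii.gz"),
    pial = file.path(out_dir, "pial.surf"),
    white = file.path(out_dir, "white.surf"),
    labels = file.path(out_dir, "labels.lut"))
  write_volume(head$parcellation, paths["parcellation"])
  write_surface(head$pial, paths["pial"], volume = head$parcellation)
  write_surface(head$white, paths["white"], volume = head$parcellation)
  write_label_table(head$labels, paths["labels"])
  if (!is.null(electrodes)) {
    paths <- c(paths, contacts = file.path(out_dir, "contacts.csv"))
    write_contacts(electrodes, paths["contacts"])
  }
  invisible(paths)
}
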