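# Slice axis naming from the affine's dominant world axis per index axis;
# oblique volumes fall back to index-plane names with a warning.
slice_axis_names <- function(vol) {
  R <- vol$affine[1:3, 1:3]
  dom <- apply(abs(R), 2, which.max)
  if (anyDuplicated(dom)) {
    warning("oblique volume: slice panels named by index planes")
    return(c("index-1", "index-2", "index-3"))
  }
  c("sagittal", "coronal", "axial")[dom]
}

draw_slice_panel <- function(slice, title, marker_px) {
  graphics::image(seq_len(nrow(slice)), seq_len(ncol(slice)), slice,
                  col = grDevices::gray.colors(64, 0, 1), axes = FALSE,
                  xlab = "", ylab = "", main = title, useRaster = TRUE)
  graphics::points(marker_px[1], marker_px[2], col = "red", pch = 3,
                   cex = 2, lwd = 2)
}

#' Visual report page for one contact
#'
#' Draws the three orthogonal MRI planes through the contact voxel with a
#' marker at the contact pixel, plus the oblique reslice along the whole
#' electrode shaft (the length-wise view of a depth electrode). The marker
#' pixel positions are the forward projection of the contact through the
#' volume affine, returned in the page descriptor for verification.
#'
#' @param volume a [volume_image()] (label or intensity).
#' @param electrode an [electrode()].
#' @param index contact index; its position must map inside the grid.
#' @param file optional PNG output path; when `NULL` the panels are drawn
#'   on the current graphics device.
#' @param width,height raster size in pixels when writing PNG.
#' @return invisible page descriptor: `electrode`, `contact`, `voxel`
#'   (0-based rounded voxel), `markers` (per-panel marker pixel
#'   coordinates, 1-based), `panel_names`, `file`.
#' @export
contact_page <- function(volume, electrode, index, file = NULL,
                         width = 900, height = 900) {
  pos <- electrode$positions[index, ]
  vx <- as.numeric(world_to_voxel(pos, volume))
  d <- dim(volume$grid)
  if (any(round_half_away(vx) < 0) || any(round_half_away(vx) >= d))
    stop(sprintf("contact %s%s at (%.1f, %.1f, %.1f) lies outside the volume",
                 electrode$name, electrode$contacts[index],
                 pos[1], pos[2], pos[3]))
  iv <- as.integer(round_half_away(vx)) + 1L  # 1-based
  axnames <- slice_axis_names(volume)
  if (!is.null(file)) {
    grDevices::png(file, width = width, height = height, type = "cairo")
    on.exit(grDevices::dev.off())
    graphics::par(mfrow = c(2, 2), mar = c(1, 1, 2, 1))
  } else {
    # drawing on the caller's device: restore its layout afterwards
    op <- graphics::par(mfrow = c(2, 2), mar = c(1, 1, 2, 1))
    on.exit(graphics::par(op), add = TRUE)
  }
  slices <- list(volume$grid[iv[1], , ], volume$grid[, iv[2], ],
                 volume$grid[, , iv[3]])
  markers <- list(iv[c(2, 3)], iv[c(1, 3)], iv[c(1, 2)])
  titles <- sprintf("%s (%s%s)", axnames[c(1, 2, 3)], electrode$name,
                    electrode$contacts[index])
  for (k in 1:3) draw_slice_panel(slices[[k]], titles[k], markers[[k]])
  n <- n_contacts(electrode)
  if (n >= 2) {
    rs <- reslice_along_trajectory(volume, electrode$positions[1, ],
                                   electrode$positions[n, ],
                                   width_mm = 40, spacing_mm = 1,
                                   pad_mm = 5)
    graphics::image(seq_along(rs$s), seq_along(rs$t), rs$image,
                    col = grDevices::gray.colors(64, 0, 1), axes = FALSE,
                    xlab = "", ylab = "", main = "along shaft",
                    useRaster = TRUE)
    # project every contact onto the reslice plane
    rel <- sweep(electrode$positions, 2, rs$origin)
    sc <- as.numeric(rel %*% rs$axis_s)
    tc <- as.numeric(rel %*% rs$axis_t)
    spacing <- rs$s[2] - rs$s[1]
    graphics::points((sc - rs$s[1]) / spacing + 1,
                     (tc - rs$t[1]) / spacing + 1,
                     col = "red", pch = 3, cex = 1.2, lwd = 2)
  } else {
    graphics::plot.new()
    graphics::title("single contact: no shaft view")
  }
  invisible(list(electrode = electrode$name,
                 contact = electrode$contacts[index],
                 voxel = as.integer(round_half_away(vx)),
                 markers = markers, panel_names = axnames, file = file))
}

#' Multi-page per-contact report document
#'
#' One page per contact, ordered by electrode then contact -- the shareable
#' PDF handed to clinical teams to verify implant positions.
#'
#' @param volume a [volume_image()].
#' @param electrodes an [electrode()] or list of them.
#' @param path output PDF path.
#' @return invisible report descriptor: `path`, `n_pages`, `pages` (list of
#'   page descriptors in page order).
#' @export
report_document <- function(volume, electrodes, path) {
  electrodes <- as_electrode_list(electrodes)
  total <- sum(vapply(electrodes, n_contacts, 0L))
  if (total == 0) stop("no contacts to report")
  grDevices::pdf(path, width = 9, height = 9, onefile = TRUE)
  on.exit(grDevices::dev.off())
  pages <- list()
  for (el in electrodes) {
    for (i in seq_len(n_contacts(el))) {
      pages[[length(pages) + 1L]] <- contact_page(volume, el, i)
    }
  }
  invisible(list(path = path, n_pages = length(pages), pages = pages))
}
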